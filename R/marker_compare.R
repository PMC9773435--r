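#' Classify a parent/recombinant center pair
#'
#' Equal centers are invariant.  A recombinant center of 0 or 1 is a loss
#' of heterozygosity (LOH_0 / LOH_1); another center of the same ploidy is
#' a heterozygous change; a center explicable only by a transition to the
#' adjacent ploidy is a ploidy-change candidate whose confirmation is
#' deferred to the depth-of-coverage cross-check; a center explicable by
#' no allowed transition is ambiguous.
#'
#' @param parent_center,recomb_center Ratio-group centers.
#' @param model A [ploidy_model()] (supplies the transition table).
#' @return List with `status`, `matched_transition` (data frame of the
#'   matching transition rows, or `NULL`) and `requires_ndoc`
#'   (`"none"`, `"gain"`, `"loss"`, `"either"`).
#' @export
label_marker <- function(parent_center, recomb_center, model) {
  if (is.na(parent_center) || is.na(recomb_center)) {
    return(list(status = "ambiguous", matched_transition = NULL,
                requires_ndoc = NA_character_))
  }
  if (parent_center == recomb_center) {
    return(list(status = "invariant", matched_transition = NULL,
                requires_ndoc = "none"))
  }
  tr <- model$transitions
  hit <- tr[tr$from_center == parent_center & tr$to_center == recomb_center, ,
            drop = FALSE]
  if (nrow(hit) == 0L) {
    return(list(status = "ambiguous", matched_transition = NULL,
                requires_ndoc = NA_character_))
  }
  reqs <- unique(hit$requires_ndoc)
  same <- hit[hit$requires_ndoc == "none", , drop = FALSE]
  if (nrow(same)) {
    # parsimony: a same-ploidy explanation wins over a cross-ploidy one
    return(list(status = same$event_type[1], matched_transition = same,
                requires_ndoc = "none"))
  }
  req <- if (all(c("gain", "loss") %in% reqs)) "either" else reqs[1]
  list(status = "ploidy_change_candidate", matched_transition = hit,
       requires_ndoc = req)
}

#' Pair parent and recombinant markers and classify each pair
#'
#' For every (already quality-filtered) parental marker, finds the
#' recombinant record at the same chromosome, position and alternate
#' allele, classifies both allele ratios against the ploidy model, and
#' labels the pair.  A parental marker absent from the recombinant VCF is
#' imputed a recombinant ratio of 0 -- variant callers are silent at
#' homozygous-reference sites -- provided the recombinant per-base depth at
#' the position is at least `min_dp`; with less coverage the marker is
#' dropped.  A recombinant record that is present but fails the quality
#' filters also drops the marker (insufficient evidence; it is *not*
#' treated as absent, which would fabricate LOH calls from QC failures).
#'
#' @param parent Parental allele records (filtered; see [apply_filters()]),
#'   sorted by chromosome and position.
#' @param recomb Recombinant allele records, unfiltered (filtering happens
#'   here so that present-but-filtered records can be distinguished from
#'   absent ones).
#' @param recomb_coverage Recombinant per-base coverage (from
#'   [read_doc()]), used for the imputed ratio-0 rule.
#' @param model A [ploidy_model()].
#' @param thresholds A [filter_thresholds()].
#' @return Data frame of marker calls: `chrom`, `pos`, `parent_ratio`,
#'   `parent_center`, `recomb_ratio`, `recomb_center`, `status`,
#'   `requires_ndoc`.  Statuses: `invariant`, `LOH_0`, `LOH_1`,
#'   `het_change`, `ploidy_change_candidate`, `ambiguous`.  Attribute
#'   `dropped` holds the dropped parental markers with a `reason` column
#'   (`low_coverage`, `recomb_filtered`); the calls plus the dropped rows
#'   partition the parental marker set.
#' @export
pair_markers <- function(parent, recomb, recomb_coverage, model,
                         thresholds = filter_thresholds()) {
  for (nm in c("parent", "recomb")) {
    df <- get(nm)
    bad <- unlist(lapply(split_by_chrom(df),
                         function(x) any(diff(x$pos) <= 0)))
    if (any(bad)) stop(nm, " records not sorted by position within ",
                       "chromosome", call. = FALSE)
  }
  recomb_mean_dp <- if (nrow(recomb)) mean(recomb$dp) else
    thresholds$ao_reference_coverage
  recomb_reason <- filter_reasons(recomb, thresholds, recomb_mean_dp)
  recomb_pass <- recomb[is.na(recomb_reason), , drop = FALSE]

  pkey <- paste(parent$chrom, parent$pos, parent$alt, sep = "\r")
  rkey <- paste(recomb$chrom, recomb$pos, recomb$alt, sep = "\r")
  rkey_pass <- paste(recomb_pass$chrom, recomb_pass$pos, recomb_pass$alt,
                     sep = "\r")
  covkey <- paste(recomb_coverage$chrom, recomb_coverage$pos, sep = "\r")
  pposkey <- paste(parent$chrom, parent$pos, sep = "\r")

  m_pass <- match(pkey, rkey_pass)
  m_any <- match(pkey, rkey)
  cov <- recomb_coverage$depth[match(pposkey, covkey)]
  cov[is.na(cov)] <- 0

  parent_cls <- classify_ratios(parent$ratio, model)
  n <- nrow(parent)
  recomb_ratio <- rep(NA_real_, n)
  recomb_center <- rep(NA_real_, n)
  recomb_origin <- rep(NA_character_, n)
  status <- rep(NA_character_, n)
  requires <- rep(NA_character_, n)
  drop_reason <- rep(NA_character_, n)

  matched <- !is.na(m_pass)
  recomb_ratio[matched] <- recomb_pass$ratio[m_pass[matched]]
  if (any(matched)) {
    rc <- classify_ratios(recomb_ratio[matched], model)
    recomb_center[matched] <- rc$center
    recomb_origin[matched] <- rc$origin
  }
  present_filtered <- !matched & !is.na(m_any)
  drop_reason[present_filtered] <- "recomb_filtered"
  absent <- !matched & is.na(m_any)
  imputable <- absent & cov >= thresholds$min_dp
  recomb_ratio[imputable] <- 0
  recomb_center[imputable] <- 0
  recomb_origin[imputable] <- "same"
  drop_reason[absent & !imputable] <- "low_coverage"

  keep <- is.na(drop_reason)
  for (i in which(keep)) {
    lab <- label_marker(parent_cls$center[i], recomb_center[i], model)
    status[i] <- lab$status
    requires[i] <- lab$requires_ndoc
  }
  # a candidate's coverage requirement refines "gain"/"loss"/"either"
  cand <- keep & !is.na(status) & status == "ploidy_change_candidate"
  requires[cand & !is.na(recomb_origin) & recomb_origin %in%
             c("gain", "loss", "either")] <-
    recomb_origin[cand & !is.na(recomb_origin) & recomb_origin %in%
                    c("gain", "loss", "either")]

  calls <- data.frame(chrom = parent$chrom, pos = parent$pos,
                      parent_ratio = parent$ratio,
                      parent_center = parent_cls$center,
                      recomb_ratio = recomb_ratio,
                      recomb_center = recomb_center,
                      status = status,
                      requires_ndoc = requires,
                      stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(calls) <- NULL
  dropped <- data.frame(chrom = parent$chrom, pos = parent$pos,
                        reason = drop_reason,
                        stringsAsFactors = FALSE)[!keep, , drop = FALSE]
  rownames(dropped) <- NULL
  attr(calls, "dropped") <- dropped
  calls
}

#' Build the variant/invariant marker track from classified calls
#'
#' Ambiguous markers are excluded entirely.  Ploidy-change candidate
#' markers are arbitrated against the local NDoC window when windows are
#' supplied: a candidate whose transition requires a coverage gain (loss)
#' is kept as a variant marker -- with its event resolved to `chrom_gain`
#' (`chrom_loss`) -- only when its window carries the matching flag;
#' otherwise the marker is excluded as a classification confounder.
#' Without windows, candidates are kept unresolved (region-level
#' resolution then falls to [attach_ndoc()]).
#'
#' @param calls Output of [pair_markers()].
#' @param windows Optional output of [flag_cnv()].
#' @return Track data frame `chrom`, `pos`, `status` suitable for
#'   [call_regions()].
#' @export
build_track <- function(calls, windows = NULL) {
  keep <- calls$status != "ambiguous"
  trk <- calls[keep, c("chrom", "pos", "status")]
  req <- calls$requires_ndoc[keep]
  cand <- trk$status == "ploidy_change_candidate"
  if (!is.null(windows) && any(cand)) {
    idx <- which(cand)
    wflag <- window_flag_at(windows, trk$chrom[idx], trk$pos[idx])
    resolved <- rep(NA_character_, length(idx))
    resolved[wflag == "gain" & req[idx] %in% c("gain", "either")] <-
      "chrom_gain"
    resolved[wflag == "loss" & req[idx] %in% c("loss", "either")] <-
      "chrom_loss"
    trk$status[idx] <- ifelse(is.na(resolved), "ambiguous", resolved)
    trk <- trk[trk$status != "ambiguous", , drop = FALSE]
  }
  rownames(trk) <- NULL
  trk
}

window_flag_at <- function(windows, chrom, pos) {
  flag <- rep(NA_character_, length(pos))
  for (ch in unique(chrom)) {
    w <- windows[windows$chrom == ch, , drop = FALSE]
    sel <- chrom == ch
    i <- findInterval(pos[sel], w$start)
    ok <- i >= 1 & pos[sel] <= w$end[pmax(i, 1)]
    flag[sel][ok] <- w$flag[i[ok]]
  }
  flag
}

#' Tetrad segregation pattern at one marker
#'
#' Counts the two parental genotypes across the four spores of a tetrad.
#' Mendelian segregation is 2:2 at sites heterozygous in the parent hybrid
#' and 4:0 at homozygous sites; 3:1 (or 1:3) indicates a gene-conversion
#' candidate.
#'
#' @param spore_centers Numeric vector of four haploid marker centers, each
#'   0 or 1 (`NA` allowed: the pattern is then undefined).
#' @param parent_het Whether the parental hybrid is heterozygous at this
#'   site (default `TRUE`).
#' @return List with `pattern` (e.g. `"2:2"`, counting alternate:reference
#'   spores; `NA` if any spore call is missing) and `mendelian` (logical).
#' @export
tetrad_segregation <- function(spore_centers, parent_het = TRUE) {
  stopifnot(length(spore_centers) == 4L)
  if (anyNA(spore_centers)) {
    return(list(pattern = NA_character_, mendelian = NA))
  }
  if (!all(spore_centers %in% c(0, 1))) {
    stop("spore centers must be 0 or 1 (haploid calls)", call. = FALSE)
  }
  n1 <- sum(spore_centers == 1)
  pattern <- paste0(n1, ":", 4L - n1)
  mendelian <- if (parent_het) n1 == 2L else n1 %in% c(0L, 4L)
  list(pattern = pattern, mendelian = mendelian)
}

#' Genotype tetrad spores at the hybrid's heterozygous markers
#'
#' Applies the haploid convention: the marker list is the parent hybrid's
#' heterozygous marker set, and each spore is called 1 when its VCF holds a
#' passing record at the marker (alternate allele present) or 0 when the
#' record is absent but the spore's coverage at the position is at least
#' `min_dp`; otherwise the spore call is missing.
#'
#' @param spores List of four allele-record data frames (one per spore).
#' @param spore_coverage List of four coverage data frames.
#' @param markers Data frame with `chrom`, `pos`, `alt` -- the hybrid's
#'   heterozygous markers.
#' @param thresholds A [filter_thresholds()].
#' @return Matrix (markers x 4) of spore centers (0/1/`NA`).
#' @export
tetrad_genotypes <- function(spores, spore_coverage, markers,
                             thresholds = filter_thresholds()) {
  stopifnot(length(spores) == 4L, length(spore_coverage) == 4L)
  mkey <- paste(markers$chrom, markers$pos, markers$alt, sep = "\r")
  poskey <- paste(markers$chrom, markers$pos, sep = "\r")
  out <- matrix(NA_real_, nrow = nrow(markers), ncol = 4L)
  for (s in 1:4) {
    sp <- spores[[s]]
    reason <- filter_reasons(sp, thresholds, mean(sp$dp))
    sp_pass <- sp[is.na(reason), , drop = FALSE]
    skey <- paste(sp_pass$chrom, sp_pass$pos, sp_pass$alt, sep = "\r")
    skey_any <- paste(sp$chrom, sp$pos, sp$alt, sep = "\r")
    cov <- spore_coverage[[s]]
    ckey <- paste(cov$chrom, cov$pos, sep = "\r")
    depth <- cov$depth[match(poskey, ckey)]
    depth[is.na(depth)] <- 0
    present <- mkey %in% skey
    present_any <- mkey %in% skey_any
    out[present, s] <- 1
    out[!present_any & depth >= thresholds$min_dp, s] <- 0
  }
  out
}
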