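#' Expected allele-ratio group centers for a given ploidy
#'
#' At a biallelic marker in a strain of ploidy `p`, a genotype carrying `k`
#' alternate copies is expected to show an alternate-allele read ratio
#' (AO/DP) near `k/p`.  Centers are rounded to two decimals so that the
#' conventional printed values (0.33, 0.67) are reproduced exactly and all
#' downstream interval arithmetic matches them.
#'
#' @param ploidy Integer in 1..4.  Higher ploidies are not supported.
#' @return Numeric vector of ratio-group centers, ascending, always
#'   including 0 and 1.
#' @examples
#' expected_groups(2) # 0 0.5 1
#' expected_groups(3) # 0 0.33 0.67 1
#' @export
expected_groups <- function(ploidy) {
  check_ploidy(ploidy)
  round(seq(0L, ploidy) / ploidy, 2)
}

check_ploidy <- function(ploidy) {
  if (length(ploidy) != 1L || is.na(ploidy) || ploidy != as.integer(ploidy) ||
      ploidy < 1 || ploidy > 4) {
    stop("ploidy must be a single integer between 1 and 4 (analysis is ",
         "limited to ploidy <= 4n)", call. = FALSE)
  }
  invisible(as.integer(ploidy))
}

#' Tolerance around ratio-group centers from two adjacent centers
#'
#' The classification tolerance is half the distance between two adjacent
#' group centers.  Applied to the closest centers that occur across
#' ploidies -- 0.25 (tetraploid) vs 0.33 (triploid), or symmetrically 0.67
#' vs 0.75 -- this gives the default tolerance of 0.04.
#'
#' @param center_a,center_b Two distinct ratio-group centers.
#' @return Half the absolute difference between the centers.
#' @examples
#' derive_theta(0.25, 0.33) # 0.04
#' @export
derive_theta <- function(center_a, center_b) {
  stopifnot(length(center_a) == 1L, length(center_b) == 1L)
  if (isTRUE(all.equal(center_a, center_b))) {
    stop("centers must be distinct to derive a tolerance", call. = FALSE)
  }
  abs(center_a - center_b) / 2
}

#' Default marker-quality filter thresholds
#'
#' Markers are retained when depth (DP) is at least `min_dp`, site quality
#' (QUAL) exceeds `min_qual`, and the alternate-observation count (AO)
#' reaches a threshold stated for a reference coverage of
#' `ao_reference_coverage` reads and rescaled to the sample's observed mean
#' depth (see [apply_filters()]).
#'
#' @param min_dp Minimum read depth at the site (reads).
#' @param min_qual Minimum Phred-scaled site quality; the comparison is
#'   strict (`qual > min_qual`).
#' @param min_ao Minimum alternate-observation count at the reference
#'   coverage.
#' @param ao_reference_coverage Coverage (reads) at which `min_ao` is
#'   stated; the effective AO threshold scales proportionally with the
#'   sample's mean depth.
#' @return A list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_dp = 20, min_qual = 200, min_ao = 20,
                              ao_reference_coverage = 80) {
  stopifnot(min_dp >= 0, min_qual >= 0, min_ao >= 0,
            ao_reference_coverage > 0)
  structure(list(min_dp = min_dp, min_qual = min_qual, min_ao = min_ao,
                 ao_reference_coverage = ao_reference_coverage),
            class = "filter_thresholds")
}

#' Effective AO threshold at an observed mean depth
#'
#' The AO cutoff is stated for a reference coverage (default 20 reads at
#' 80x) and rescaled proportionally to the sample's genome-wide mean depth,
#' with a floor of 5 reads so that very low-coverage samples do not accept
#' arbitrarily weak evidence.
#'
#' @param thresholds A [filter_thresholds()] object.
#' @param observed_mean_dp Genome-wide mean depth (reads) of the sample the
#'   records come from.
#' @return Integer threshold (reads).
#' @export
effective_ao_threshold <- function(thresholds, observed_mean_dp) {
  stopifnot(observed_mean_dp >= 0)
  max(5L, as.integer(ceiling(
    thresholds$min_ao * observed_mean_dp / thresholds$ao_reference_coverage)))
}

#' Apply marker-quality filters to one allele record
#'
#' Checks, in order: depth (`dp >= min_dp`), site quality
#' (`qual > min_qual`), and alternate observations
#' (`ao >= effective_ao_threshold()`).  The first failing check is reported
#' as the rejection reason.  The AO check is not applied to imputed
#' ratio-zero calls (those never pass through this function; see
#' [pair_markers()]).
#'
#' @param record A list or single-row data frame with fields `dp`, `qual`,
#'   `ao`.
#' @param thresholds A [filter_thresholds()] object.
#' @param observed_mean_dp Genome-wide mean depth of the record's sample.
#' @return List with `pass` (logical) and `reason` (`NA` or one of
#'   `"min_dp"`, `"min_qual"`, `"min_ao"`).
#' @export
apply_filters <- function(record, thresholds = filter_thresholds(),
                          observed_mean_dp = thresholds$ao_reference_coverage) {
  reason <- filter_reasons(data.frame(dp = record$dp, qual = record$qual,
                                      ao = record$ao),
                           thresholds, observed_mean_dp)
  list(pass = is.na(reason), reason = reason)
}

# Vectorised filter: NA = pass, otherwise the first failing reason.
filter_reasons <- function(records, thresholds, observed_mean_dp) {
  ao_min <- effective_ao_threshold(thresholds, observed_mean_dp)
  reason <- rep(NA_character_, nrow(records))
  reason[records$ao < ao_min] <- "min_ao"
  reason[!(records$qual > thresholds$min_qual)] <- "min_qual"
  reason[records$dp < thresholds$min_dp] <- "min_dp"
  reason
}

#' Enumerate allowed ratio transitions for a ploidy
#'
#' Exhaustive copy-number enumeration of how a heterozygous parental state
#' `(a alternate copies out of p)` can change in the recombined strain:
#' same-total transitions (loss of heterozygosity towards ratio 0 or 1, or
#' an internal heterozygous change), whole-set loss transitions to total
#' `p - 1` (requiring a depth-of-coverage loss), and gain transitions to
#' total `p + 1` up to the 4n limit (requiring a coverage gain).  For
#' haploids the marker states are only 0 and 1 and the transitions are the
#' two switches between them.
#'
#' @param ploidy Integer in 1..4.
#' @return Data frame with columns `from_alt`, `from_total`, `to_alt`,
#'   `to_total`, `from_center`, `to_center`, `event_type` (one of
#'   `invariant`, `LOH_0`, `LOH_1`, `het_change`, `chrom_loss`,
#'   `chrom_gain`) and `requires_ndoc` (`none`, `loss`, `gain`).
#' @examples
#' tr <- enumerate_transitions(3)
#' subset(tr, from_center == 0.33 & to_center == 0) # LOH_0
#' @export
enumerate_transitions <- function(ploidy) {
  p <- check_ploidy(ploidy)
  rows <- list()
  add <- function(a, p0, a2, p2, event, ndoc) {
    rows[[length(rows) + 1L]] <<- data.frame(
      from_alt = a, from_total = p0, to_alt = a2, to_total = p2,
      from_center = round(a / p0, 2), to_center = round(a2 / p2, 2),
      event_type = event, requires_ndoc = ndoc,
      stringsAsFactors = FALSE)
  }
  if (p == 1L) {
    add(1L, 1L, 0L, 1L, "LOH_0", "none")
    add(0L, 1L, 1L, 1L, "LOH_1", "none")
  } else {
    for (a in seq_len(p - 1L)) {
      for (a2 in setdiff(0:p, a)) {
        event <- if (a2 == 0L) "LOH_0" else if (a2 == p) "LOH_1" else "het_change"
        add(a, p, a2, p, event, "none")
      }
      if (p - 1L >= 1L) {
        for (a2 in unique(pmax(0L, pmin(p - 1L, c(a - 1L, a))))) {
          add(a, p, a2, p - 1L, "chrom_loss", "loss")
        }
      }
      if (p + 1L <= 4L) {
        for (a2 in c(a, a + 1L)) {
          add(a, p, a2, p + 1L, "chrom_gain", "gain")
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Construct a ploidy model
#'
#' Bundles the expected ratio-group centers for the strain's ploidy, the
#' classification tolerance `theta`, the allowed transition table, and the
#' adjacent-ploidy "candidate" centers used to recognise possible
#' chromosome gains/losses.  Candidate centers are the centers of ploidy
#' `p - 1` and `p + 1` that are not already centers of `p`; each carries
#' the direction of coverage change that would explain it (`gain`, `loss`,
#' or `either` when both neighbours share the center).
#'
#' @param ploidy Integer in 1..4.
#' @param theta Classification tolerance around each center
#'   (dimensionless); default 0.04, half the distance between the adjacent
#'   cross-ploidy centers 0.25 and 0.33.
#' @return A list of class `ploidy_model` with elements `ploidy`,
#'   `centers`, `theta`, `transitions`, `candidates`.
#' @export
ploidy_model <- function(ploidy, theta = 0.04) {
  p <- check_ploidy(ploidy)
  centers <- expected_groups(p)
  if (!(theta > 0)) stop("theta must be positive", call. = FALSE)
  if (2 * theta >= min(diff(centers))) {
    stop("theta too large: intervals around adjacent centers of ploidy ", p,
         " would overlap beyond their midpoint", call. = FALSE)
  }
  cand <- data.frame(center = numeric(0), direction = character(0),
                     stringsAsFactors = FALSE)
  neighbours <- list()
  if (p - 1L >= 1L) neighbours$loss <- expected_groups(p - 1L)
  if (p + 1L <= 4L) neighbours$gain <- expected_groups(p + 1L)
  for (dir in names(neighbours)) {
    extra <- setdiff(neighbours[[dir]], centers)
    if (length(extra)) {
      cand <- rbind(cand, data.frame(center = extra, direction = dir,
                                     stringsAsFactors = FALSE))
    }
  }
  if (nrow(cand)) {
    both <- duplicated(cand$center) | duplicated(cand$center, fromLast = TRUE)
    cand$direction[both] <- "either"
    cand <- unique(cand)
    cand <- cand[order(cand$center), , drop = FALSE]
    rownames(cand) <- NULL
  }
  structure(list(ploidy = p, centers = centers, theta = theta,
                 transitions = enumerate_transitions(p), candidates = cand),
            class = "ploidy_model")
}

#' @export
print.ploidy_model <- function(x, ...) {
  cat("Ploidy model: ", x$ploidy, "n\n", sep = "")
  cat("  centers:   ", paste(x$centers, collapse = ", "), "\n", sep = "")
  cat("  theta:     ", x$theta, "\n", sep = "")
  cat("  candidate centers (adjacent ploidy): ",
      if (nrow(x$candidates)) {
        paste(sprintf("%s (%s)", x$candidates$center, x$candidates$direction),
              collapse = ", ")
      } else "none", "\n", sep = "")
  cat("  transitions: ", nrow(x$transitions), "\n", sep = "")
  invisible(x)
}

#' Classify an observed allele ratio against a ploidy model
#'
#' Returns the unique group center whose `theta`-interval contains the
#' ratio.  Competing explanations from the adjacent ploidies' centers are
#' scored alongside the model's own centers: an exact tie between two
#' centers (e.g. a ratio of 0.29 sitting on the shared boundary of
#' 0.25 + theta and 0.33 - theta) is ambiguous, and among non-tied
#' qualifying centers the nearest wins, with the model's own ploidy
#' preferred over a cross-ploidy explanation at equal distance.
#'
#' @param ratio Observed AO/DP ratio in `[0, 1]`.
#' @param model A [ploidy_model()].
#' @return List with `center` (numeric, `NA` when ambiguous), `origin`
#'   (`"same"`, `"gain"`, `"loss"`, `"either"`, or `NA`) and `ambiguous`
#'   (logical).
#' @examples
#' m <- ploidy_model(3)
#' classify_ratio(0.30, m)$center # 0.33
#' classify_ratio(0.45, m)$ambiguous # TRUE
#' @export
classify_ratio <- function(ratio, model) {
  stopifnot(length(ratio) == 1L)
  if (is.na(ratio) || ratio < 0 || ratio > 1) {
    stop("ratio must be in [0, 1]", call. = FALSE)
  }
  res <- classify_ratios(ratio, model)
  list(center = res$center, origin = res$origin,
       ambiguous = is.na(res$center))
}

# Vectorised classification; returns data.frame(center, origin).
classify_ratios <- function(ratios, model) {
  all_centers <- c(model$centers, model$candidates$center)
  origins <- c(rep("same", length(model$centers)), model$candidates$direction)
  n <- length(ratios)
  # distances rounded to dodge binary-float artefacts around theta
  d <- round(abs(outer(ratios, all_centers, "-")), 10)
  qual <- d <= model$theta
  center <- rep(NA_real_, n)
  origin <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    q <- which(qual[i, ])
    if (length(q) == 0L) next
    dq <- d[i, q]
    best <- q[dq == min(dq)]
    if (length(best) > 1L) next   # exact tie between centers: ambiguous
    center[i] <- all_centers[best]
    origin[i] <- origins[best]
  }
  data.frame(center = center, origin = origin, stringsAsFactors = FALSE)
}
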