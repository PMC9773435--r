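#' Call recombined regions from a variant/invariant marker track
#'
#' A recombined region is a maximal run of ratio-variant markers in which
#' any two successive variant markers are separated by at most
#' `max_invariant_gap` consecutive invariant markers, trimmed so that both
#' ends are variant, and retained only when it holds at least `min_variant`
#' variant markers.  "Adjacent" counts markers in the filtered track, not
#' base pairs.  Ambiguous markers must already have been removed upstream
#' (see [build_track()]).
#'
#' @param track Data frame with columns `chrom`, `pos` (strictly increasing
#'   within chromosome) and `status`.  `status` may be binary (`"V"`/`"I"`)
#'   or carry the full marker classification (`"invariant"` counts as
#'   invariant; every other value counts as variant).
#' @param min_variant Minimum number of variant markers per region.
#' @param max_invariant_gap Maximum run of invariant markers tolerated
#'   between two variant markers inside a region.
#' @return Data frame with columns `chrom`, `start`, `end` (positions of
#'   the outermost variant markers, 1-based inclusive), `n_variant`,
#'   `n_invariant_inside`, `event_type` (dominant variant status by
#'   majority), `mean_ndoc` (`NA` until [attach_ndoc()]).
#' @examples
#' trk <- data.frame(chrom = "chrI", pos = 1:6 * 100,
#'                   status = c("V", "V", "I", "I", "V", "V"))
#' call_regions(trk) # one region, 4 variant markers
#' @export
call_regions <- function(track, min_variant = 4, max_invariant_gap = 2) {
  stopifnot(min_variant >= 1, max_invariant_gap >= 0)
  if (is.null(track) || nrow(track) == 0L) return(empty_regions())
  new_block <- c(TRUE, track$chrom[-1] != track$chrom[-nrow(track)])
  chrom_id <- cumsum(new_block)
  if (anyDuplicated(track$chrom[new_block])) {
    stop("track must be grouped by chromosome", call. = FALSE)
  }
  same <- chrom_id[-1] == chrom_id[-length(chrom_id)]
  if (any(diff(track$pos)[same] <= 0)) {
    stop("track positions must be strictly increasing within chromosome",
         call. = FALSE)
  }
  v_idx <- which(is_variant_status(track$status))
  if (length(v_idx) < min_variant) return(empty_regions())
  # new run when the invariant gap is too long or the chromosome changes
  brk <- diff(v_idx) - 1L > max_invariant_gap |
    chrom_id[v_idx[-1]] != chrom_id[v_idx[-length(v_idx)]]
  grp <- cumsum(c(0L, brk))
  first <- v_idx[!duplicated(grp)]
  last <- v_idx[!duplicated(grp, fromLast = TRUE)]
  count <- tabulate(grp + 1L)
  keep <- count >= min_variant
  if (!any(keep)) return(empty_regions())
  first <- first[keep]; last <- last[keep]; count <- count[keep]
  out <- data.frame(
    chrom = track$chrom[first],
    start = track$pos[first],
    end = track$pos[last],
    n_variant = count,
    n_invariant_inside = (last - first + 1L) - count,
    event_type = vapply(seq_along(first), function(k) {
      s <- track$status[first[k]:last[k]]
      dominant_status(s[is_variant_status(s)])
    }, character(1)),
    mean_ndoc = NA_real_,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

empty_regions <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             n_variant = integer(0), n_invariant_inside = integer(0),
             event_type = character(0), mean_ndoc = numeric(0),
             stringsAsFactors = FALSE)
}

is_variant_status <- function(status) {
  !(status %in% c("I", "invariant"))
}

# majority vote over variant statuses; ties broken by count order of first
# appearance
dominant_status <- function(statuses) {
  tab <- table(factor(statuses, levels = unique(statuses)))
  names(tab)[which.max(tab)]
}

split_by_chrom <- function(df) {
  split(df, factor(df$chrom, levels = unique(df$chrom)))
}

#' Exhaustive reference implementation of region calling
#'
#' Independently enumerates every variant-bounded sub-segment of the track,
#' keeps those that satisfy both rules (at least `min_variant` variant
#' markers; no internal run of invariant markers longer than
#' `max_invariant_gap`), and discards segments contained in a larger
#' satisfying segment.  Intended as a test oracle on short tracks only.
#'
#' @inheritParams call_regions
#' @return Same shape as [call_regions()].
#' @export
oracle_call_regions <- function(track, min_variant = 4, max_invariant_gap = 2) {
  if (is.null(track) || nrow(track) == 0L) return(empty_regions())
  new_block <- c(TRUE, track$chrom[-1] != track$chrom[-nrow(track)])
  offsets <- which(new_block)
  ends <- c(offsets[-1] - 1L, nrow(track))
  acc <- vector("list", length(offsets))
  for (b in seq_along(offsets)) {
    rows <- offsets[b]:ends[b]
    v <- is_variant_status(track$status[rows])
    n <- length(v)
    if (n > 20L) {
      stop("oracle_call_regions is exhaustive; track too long (> 20)",
           call. = FALSE)
    }
    # invariant runs that may not sit fully inside a window
    r <- rle(v)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    bad <- !r$values & r$lengths > max_invariant_gap
    bad_runs <- cbind(run_start[bad], run_end[bad])
    nv <- cumsum(v)
    vi <- which(v)
    keep <- list()
    for (i in vi) {
      for (j in vi) {
        if (j < i) next
        if (nv[j] - nv[i] + 1L < min_variant) next
        if (nrow(bad_runs) &&
            any(bad_runs[, 1] > i & bad_runs[, 2] < j)) next
        keep[[length(keep) + 1L]] <- c(i, j)
      }
    }
    if (!length(keep)) next
    w <- do.call(rbind, keep)
    maximal <- vapply(seq_len(nrow(w)), function(k) {
      !any(w[, 1] <= w[k, 1] & w[, 2] >= w[k, 2] &
             (w[, 1] != w[k, 1] | w[, 2] != w[k, 2]))
    }, logical(1))
    w <- w[maximal, , drop = FALSE]
    w <- w[order(w[, 1]), , drop = FALSE]
    acc[[b]] <- cbind(offsets[b] - 1L + w,
                      nv[w[, 2]] - nv[w[, 1]] + 1L)
  }
  acc <- acc[!vapply(acc, is.null, logical(1))]
  if (!length(acc)) return(empty_regions())
  m <- do.call(rbind, acc)
  out <- data.frame(
    chrom = track$chrom[m[, 1]],
    start = track$pos[m[, 1]],
    end = track$pos[m[, 2]],
    n_variant = m[, 3],
    n_invariant_inside = (m[, 2] - m[, 1] + 1L) - m[, 3],
    event_type = vapply(seq_len(nrow(m)), function(k) {
      s <- track$status[m[k, 1]:m[k, 2]]
      dominant_status(s[is_variant_status(s)])
    }, character(1)),
    mean_ndoc = NA_real_,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Attach normalized depth of coverage to called regions
#'
#' Computes each region's mean NDoC over the coverage windows overlapping
#' it, and resolves regions whose dominant event type is
#' `ploidy_change_candidate`: mean NDoC above `gain_threshold` confirms a
#' chromosome gain, below `loss_threshold` a loss; otherwise the region is
#' demoted to a heterozygous change.  Regions with no overlapping window
#' keep `mean_ndoc = NA` and an unresolved candidate type.
#'
#' @param regions Output of [call_regions()].
#' @param windows Output of [ndoc_normalize()] / [flag_cnv()] (columns
#'   `chrom`, `start`, `end`, `ndoc`).
#' @param loss_threshold,gain_threshold NDoC cutoffs (strict inequalities).
#' @return `regions` with `mean_ndoc` filled and candidate `event_type`
#'   resolved.
#' @export
attach_ndoc <- function(regions, windows, loss_threshold = 0.5,
                        gain_threshold = 1.5) {
  if (loss_threshold >= gain_threshold) {
    stop("loss_threshold must be below gain_threshold", call. = FALSE)
  }
  if (nrow(regions) == 0L) return(regions)
  for (k in seq_len(nrow(regions))) {
    ov <- windows$chrom == regions$chrom[k] &
      windows$start <= regions$end[k] & windows$end >= regions$start[k]
    nd <- windows$ndoc[ov]
    nd <- nd[!is.na(nd)]
    if (!length(nd)) next
    m <- mean(nd)
    regions$mean_ndoc[k] <- m
    if (regions$event_type[k] == "ploidy_change_candidate") {
      regions$event_type[k] <-
        if (m > gain_threshold) "chrom_gain"
        else if (m < loss_threshold) "chrom_loss"
        else "het_change"
    }
  }
  regions
}
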