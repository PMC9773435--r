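#' Genome layout
#'
#' Ordered chromosome names and lengths, used for coverage windowing,
#' output ordering and plot axes.
#'
#' @param lengths Named numeric vector of chromosome lengths in bp
#'   (names are chromosome names), or a data frame with columns `chrom`
#'   and `length`.
#' @return Data frame with columns `chrom` and `length`.
#' @export
genome_layout <- function(lengths) {
  if (is.data.frame(lengths)) {
    stopifnot(all(c("chrom", "length") %in% names(lengths)))
    out <- data.frame(chrom = as.character(lengths$chrom),
                      length = as.numeric(lengths$length),
                      stringsAsFactors = FALSE)
  } else {
    if (is.null(names(lengths)) || any(names(lengths) == "")) {
      stop("chromosome lengths must be named", call. = FALSE)
    }
    out <- data.frame(chrom = names(lengths), length = as.numeric(lengths),
                      stringsAsFactors = FALSE)
  }
  if (anyDuplicated(out$chrom)) stop("chromosome names must be unique",
                                     call. = FALSE)
  if (any(out$length <= 0)) stop("chromosome lengths must be positive",
                                 call. = FALSE)
  out
}

# layout inferred from a coverage table: last covered position per chromosome
layout_from_coverage <- function(coverage) {
  agg <- stats::aggregate(pos ~ chrom, data = coverage, FUN = max)
  agg <- agg[match(unique(coverage$chrom), agg$chrom), ]
  genome_layout(data.frame(chrom = agg$chrom, length = agg$pos))
}

#' Mean depth of coverage in fixed windows
#'
#' Tiles each chromosome with windows of `window_bp` starting at position 1
#' and advancing by `step_bp` (default: non-overlapping 1-kb windows).
#' Positions absent from the coverage table count as depth 0 up to the
#' chromosome length; the last, possibly shorter, window is averaged over
#' its actual span.
#'
#' @param coverage Data frame with columns `chrom`, `pos`, `depth`
#'   (from [read_doc()] or [simulate_pair()]).
#' @param layout A [genome_layout()]; if `NULL`, inferred from the coverage
#'   table (last covered position per chromosome).
#' @param window_bp,step_bp Window size and step in bp, both >= 1.
#' @return Data frame `chrom`, `start`, `end`, `mean_depth`.
#' @export
window_means <- function(coverage, layout = NULL, window_bp = 1000,
                         step_bp = window_bp) {
  if (window_bp < 1 || step_bp < 1) {
    stop("window_bp and step_bp must be >= 1", call. = FALSE)
  }
  if (is.null(layout)) layout <- layout_from_coverage(coverage)
  cov_split <- split(coverage, factor(coverage$chrom, levels = layout$chrom))
  out <- lapply(seq_len(nrow(layout)), function(i) {
    L <- as.integer(layout$length[i])
    cv <- cov_split[[layout$chrom[i]]]
    depth <- numeric(L)
    if (!is.null(cv) && nrow(cv)) {
      if (any(cv$pos < 1 | cv$pos > L)) {
        stop("coverage position outside chromosome ", layout$chrom[i],
             " (length ", L, ")", call. = FALSE)
      }
      depth[cv$pos] <- cv$depth
    }
    cs <- c(0, cumsum(depth))
    starts <- seq.int(1L, L, by = step_bp)
    ends <- pmin(starts + window_bp - 1L, L)
    data.frame(chrom = layout$chrom[i], start = starts, end = ends,
               mean_depth = (cs[ends + 1L] - cs[starts]) / (ends - starts + 1L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Normalized depth of coverage (NDoC) per window
#'
#' Divides the recombinant strain's per-window mean depth by the parent's,
#' correcting for technical depth differences between the two libraries.
#' Windows where the parent mean is zero get an undefined NDoC.
#'
#' @param parent_windows,recomb_windows Outputs of [window_means()] on the
#'   same window grid.
#' @return Data frame `chrom`, `start`, `end`, `parent_mean`,
#'   `recomb_mean`, `ndoc`, `flag` (all `"none"`/`"undefined"`; see
#'   [flag_cnv()] for gain/loss flags).
#' @export
ndoc_normalize <- function(parent_windows, recomb_windows) {
  if (nrow(parent_windows) != nrow(recomb_windows) ||
      !all(parent_windows$chrom == recomb_windows$chrom) ||
      !all(parent_windows$start == recomb_windows$start) ||
      !all(parent_windows$end == recomb_windows$end)) {
    stop("parent and recombinant window grids differ", call. = FALSE)
  }
  ndoc <- ifelse(parent_windows$mean_depth > 0,
                 recomb_windows$mean_depth / parent_windows$mean_depth,
                 NA_real_)
  data.frame(chrom = parent_windows$chrom,
             start = parent_windows$start,
             end = parent_windows$end,
             parent_mean = parent_windows$mean_depth,
             recomb_mean = recomb_windows$mean_depth,
             ndoc = ndoc,
             flag = ifelse(is.na(ndoc), "undefined", "none"),
             stringsAsFactors = FALSE)
}

#' Flag copy-number change from NDoC
#'
#' Marks windows whose NDoC falls strictly below `loss_threshold` as
#' losses and strictly above `gain_threshold` as gains; boundary values
#' are unflagged.
#'
#' @param windows Output of [ndoc_normalize()].
#' @param loss_threshold,gain_threshold Strict NDoC cutoffs
#'   (defaults 0.5 and 1.5).
#' @return `windows` with the `flag` column set to `loss`, `gain`, `none`
#'   or `undefined`.
#' @export
flag_cnv <- function(windows, loss_threshold = 0.5, gain_threshold = 1.5) {
  if (loss_threshold >= gain_threshold) {
    stop("loss_threshold must be below gain_threshold", call. = FALSE)
  }
  flag <- rep("none", nrow(windows))
  flag[is.na(windows$ndoc)] <- "undefined"
  flag[!is.na(windows$ndoc) & windows$ndoc < loss_threshold] <- "loss"
  flag[!is.na(windows$ndoc) & windows$ndoc > gain_threshold] <- "gain"
  windows$flag <- flag
  windows
}
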