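#' Color and glyph conventions for recombination profiles
#'
#' Invariant markers are gray; LOH to ratio 0 is red, LOH to ratio 1 is
#' blue; heterozygous recombination events are black.  Ploidy-change
#' candidates left unresolved by the coverage cross-check, and resolved
#' chromosome gains/losses, are drawn black like other heterozygous-ratio
#' changes -- the copy-number information is carried by the NDoC dots
#' (orange = loss, green = gain).
#'
#' @param marker_colors Named character vector mapping marker statuses to
#'   colors.
#' @param ndoc_colors Named character vector mapping NDoC flags to colors.
#' @return List of class `plot_style`.
#' @export
plot_style <- function(marker_colors = c(invariant = "gray70",
                                         LOH_0 = "red",
                                         LOH_1 = "blue",
                                         het_change = "black",
                                         ploidy_change_candidate = "black",
                                         chrom_gain = "black",
                                         chrom_loss = "black",
                                         V = "black"),
                       ndoc_colors = c(loss = "orange", gain = "green")) {
  structure(list(marker_colors = marker_colors, ndoc_colors = ndoc_colors),
            class = "plot_style")
}

#' Plot a genome-wide recombination profile
#'
#' One horizontal track per chromosome (y axis: chromosome name; x axis:
#' position in bp); markers are drawn as colored vertical lines at their
#' positions, and gain/loss-flagged NDoC windows as dots above the track.
#' When `calls` carries a `strain` column, strains are stacked as facets
#' in input order.
#'
#' @param calls Marker calls ([pair_markers()] output, or any data frame
#'   with `chrom`, `pos`, `status` and optionally `strain`).
#' @param windows Optional flagged NDoC windows ([flag_cnv()] output).
#' @param layout A [genome_layout()]; all call/window chromosomes must
#'   appear in it.
#' @param style A [plot_style()].
#' @param out Optional output path; the device is chosen from the
#'   extension (`.pdf`, `.png`, `.svg`).
#' @param width,height Device size in inches.
#' @return The ggplot object, invisibly.
#' @export
plot_profile <- function(calls, windows = NULL, layout, style = plot_style(),
                         out = NULL, width = 9, height = 6) {
  unknown <- setdiff(unique(calls$chrom), layout$chrom)
  if (length(unknown)) {
    stop("chromosome(s) in calls but not in layout: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  bad_status <- setdiff(unique(calls$status), names(style$marker_colors))
  if (length(bad_status)) {
    stop("no color defined for marker status: ",
         paste(bad_status, collapse = ", "), call. = FALSE)
  }
  chrom_lv <- rev(layout$chrom)   # first chromosome on top
  calls$y <- match(calls$chrom, chrom_lv)
  if ("strain" %in% names(calls)) {
    calls$strain <- factor(calls$strain, levels = unique(calls$strain))
  }
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = calls,
      ggplot2::aes(x = .data$pos, xend = .data$pos,
                   y = .data$y - 0.3, yend = .data$y + 0.3,
                   color = .data$status),
      linewidth = 0.3) +
    ggplot2::scale_color_manual(values = style$marker_colors,
                                name = "marker") +
    ggplot2::scale_y_continuous(breaks = seq_along(chrom_lv),
                                labels = chrom_lv,
                                limits = c(0.4, length(chrom_lv) + 0.8)) +
    ggplot2::labs(x = "position (bp)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(windows)) {
    flagged <- windows[windows$flag %in% names(style$ndoc_colors), ,
                       drop = FALSE]
    unknown_w <- setdiff(unique(flagged$chrom), layout$chrom)
    if (length(unknown_w)) {
      stop("chromosome(s) in windows but not in layout: ",
           paste(unknown_w, collapse = ", "), call. = FALSE)
    }
    if (nrow(flagged)) {
      flagged$y <- match(flagged$chrom, chrom_lv) + 0.42
      flagged$mid <- (flagged$start + flagged$end) / 2
      p <- p + ggplot2::geom_point(
        data = flagged,
        ggplot2::aes(x = .data$mid, y = .data$y, fill = .data$flag),
        shape = 21, size = 1.4, stroke = 0.1) +
        ggplot2::scale_fill_manual(values = style$ndoc_colors,
                                   name = "NDoC")
    }
  }
  if ("strain" %in% names(calls)) {
    p <- p + ggplot2::facet_wrap(~strain, ncol = 1)
  }
  if (!is.null(out)) {
    ext <- tolower(tools::file_ext(out))
    if (!ext %in% c("pdf", "png", "svg")) {
      stop("unsupported plot format: .", ext, " (use pdf, png or svg)",
           call. = FALSE)
    }
    dev <- switch(ext, svg = grDevices::svg, png = grDevices::png,
                  pdf = grDevices::pdf)
    ggplot2::ggsave(out, p, device = dev, width = width, height = height)
  }
  invisible(p)
}

#' @importFrom rlang .data
NULL
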