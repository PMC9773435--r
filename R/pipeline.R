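#' Run the full recombination-detection pipeline
#'
#' Wires the three analysis stages end to end: (1) compute and filter
#' allele ratios from the two VCFs, writing the parental and recombined
#' alleles files; (2) pair and compare ratios, writing the variants and
#' invariant alleles files; (3) segment the variant track into recombined
#' regions, cross-checked against the normalized depth of coverage, and
#' write the region-of-recombination and normalized-coverage files plus
#' per-chromosome profile plots.  A JSON manifest of resolved inputs and
#' parameters is written for reproducibility.
#'
#' @param parent_vcf,sample_vcf Paths to the parental/reference and
#'   potentially recombined strain VCFs, or pre-parsed allele-record data
#'   frames.
#' @param parent_doc,sample_doc Paths to the per-base depth-of-coverage
#'   tables (or data frames).
#' @param out_dir Output directory (created if needed).
#' @param ploidy Strain ploidy, 1..4.
#' @param theta Ratio-classification tolerance (default 0.04).
#' @param min_dp,min_qual,min_ao,ao_reference_coverage Marker filters, see
#'   [filter_thresholds()].
#' @param window_bp,step_bp Coverage window size/step in bp.
#' @param min_variant,max_invariant_gap Region-caller knobs, see
#'   [call_regions()].
#' @param loss_threshold,gain_threshold NDoC cutoffs, see [flag_cnv()].
#' @param layout Optional [genome_layout()] (or path to a two-column
#'   chromosome-length TSV); inferred from the parent coverage table when
#'   absent.
#' @param sample_name Stem used for output file names.
#' @param plot_format `"pdf"`, `"png"`, `"svg"` or `NULL` to skip
#'   plotting.
#' @param allow_multiallelic Passed to [read_vcf()].
#' @return List (invisibly) with the calls, regions, windows, dropped
#'   markers, layout and output paths.
#' @export
run_pipeline <- function(parent_vcf, sample_vcf, parent_doc, sample_doc,
                         out_dir, ploidy, theta = 0.04,
                         min_dp = 20, min_qual = 200, min_ao = 20,
                         ao_reference_coverage = 80,
                         window_bp = 1000, step_bp = window_bp,
                         min_variant = 4, max_invariant_gap = 2,
                         loss_threshold = 0.5, gain_threshold = 1.5,
                         layout = NULL, sample_name = "sample",
                         plot_format = "pdf", allow_multiallelic = FALSE) {
  model <- ploidy_model(ploidy, theta)   # errors beyond 4n
  thresholds <- filter_thresholds(min_dp, min_qual, min_ao,
                                  ao_reference_coverage)
  as_records <- function(x) {
    if (is.data.frame(x)) x else read_vcf(x, allow_multiallelic)
  }
  as_doc <- function(x) if (is.data.frame(x)) x else read_doc(x)
  parent <- as_records(parent_vcf)
  recomb <- as_records(sample_vcf)
  pdoc <- as_doc(parent_doc)
  rdoc <- as_doc(sample_doc)
  if (is.character(layout)) {
    lt <- utils::read.delim(layout, stringsAsFactors = FALSE)
    names(lt)[1:2] <- c("chrom", "length")
    layout <- genome_layout(lt)
  }
  if (is.null(layout)) layout <- layout_from_coverage(pdoc)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(...) file.path(out_dir, paste0(...))

  # stage 1: ratios and filters
  parent_reason <- filter_reasons(parent, thresholds, mean(parent$dp))
  parent_pass <- parent[is.na(parent_reason), , drop = FALSE]
  write_alleles_file(parent_pass, "parental",
                     path(sample_name, "_parental_alleles.txt"), layout)
  recomb_reason <- filter_reasons(recomb, thresholds, mean(recomb$dp))
  write_alleles_file(recomb[is.na(recomb_reason), , drop = FALSE],
                     "recombined",
                     path(sample_name, "_recombined_alleles.txt"), layout)

  # stage 2: pairing and comparison
  calls <- pair_markers(parent_pass, recomb, rdoc, model, thresholds)
  write_marker_files(calls,
                     path(sample_name, "_variants_alleles.txt"),
                     path(sample_name, "_invariant_alleles.txt"), layout)

  # coverage: windows and NDoC
  pw <- window_means(pdoc, layout, window_bp, step_bp)
  rw <- window_means(rdoc, layout, window_bp, step_bp)
  windows <- flag_cnv(ndoc_normalize(pw, rw), loss_threshold, gain_threshold)
  write_ndoc_file(windows, path(sample_name, "_normalized1KB.txt"))

  # stage 3: regions
  track <- build_track(calls, windows)
  regions <- call_regions(track, min_variant, max_invariant_gap)
  regions <- attach_ndoc(regions, windows, loss_threshold, gain_threshold)
  write_regions_file(regions,
                     path(sample_name, "_region_of_recombination.txt"),
                     layout)

  plot_path <- NULL
  if (!is.null(plot_format)) {
    plot_path <- path(sample_name, "_profile.", plot_format)
    plot_profile(calls, windows, layout, out = plot_path)
  }

  manifest <- list(
    inputs = list(
      parent_vcf = if (is.character(parent_vcf)) parent_vcf else "in-memory",
      sample_vcf = if (is.character(sample_vcf)) sample_vcf else "in-memory",
      parent_doc = if (is.character(parent_doc)) parent_doc else "in-memory",
      sample_doc = if (is.character(sample_doc)) sample_doc else "in-memory"),
    parameters = list(ploidy = ploidy, theta = theta, min_dp = min_dp,
                      min_qual = min_qual, min_ao = min_ao,
                      ao_reference_coverage = ao_reference_coverage,
                      window_bp = window_bp, step_bp = step_bp,
                      min_variant = min_variant,
                      max_invariant_gap = max_invariant_gap,
                      loss_threshold = loss_threshold,
                      gain_threshold = gain_threshold),
    n_parent_markers = nrow(parent),
    n_parent_markers_pass = nrow(parent_pass),
    n_calls = nrow(calls),
    n_regions = nrow(regions),
    package_version = as.character(utils::packageVersion("lohscan")),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, path(sample_name, "_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(calls = calls, regions = regions, windows = windows,
                 track = track, dropped = attr(calls, "dropped"),
                 layout = layout, model = model,
                 out_dir = out_dir, plot = plot_path))
}
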