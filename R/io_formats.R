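#' Read allele records from a VCF file
#'
#' Parses a FreeBayes-style VCF and returns one record per biallelic
#' polymorphic marker with its alternate-observation count (AO), total
#' depth (DP), site quality (QUAL) and allele ratio AO/DP.  When the file
#' carries exactly one sample, AO and DP are taken from the per-sample
#' FORMAT fields; with no genotype columns they are taken from INFO; any
#' other layout is rejected as ambiguous.  Records missing AO or DP are
#' skipped with a warning and counted.
#'
#' @param path Path to a VCF v4.x file (plain text or gzipped).
#' @param allow_multiallelic If `FALSE` (default), multiallelic sites are
#'   skipped (counted); if `TRUE`, the alternate allele with the largest AO
#'   is kept (ties: first listed).
#' @return Data frame with columns `chrom`, `pos`, `ref`, `alt`, `type`
#'   (`"SNP"`/`"indel"`), `ao`, `dp`, `qual`, `ratio` (`NA` when
#'   `dp == 0`), sorted by chromosome (order of appearance) then position.
#'   Attributes `n_skipped_missing` and `n_skipped_multiallelic` count
#'   skipped body lines.
#' @export
read_vcf <- function(path, allow_multiallelic = FALSE) {
  if (!file.exists(path)) stop("VCF file not found: ", path, call. = FALSE)
  validate_vcf_lines(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  gt <- v@gt
  n_samples <- if (is.null(gt) || ncol(gt) < 2L) 0L else ncol(gt) - 1L
  if (n_samples > 1L) {
    stop("multi-sample VCF: AO/DP source ambiguous (one strain per file ",
         "expected): ", path, call. = FALSE)
  }
  if (n_samples == 1L) {
    ao_raw <- as.vector(vcfR::extract.gt(v, element = "AO"))
    dp_raw <- as.vector(vcfR::extract.gt(v, element = "DP"))
  } else {
    ao_raw <- vcfR::extract.info(v, element = "AO")
    dp_raw <- vcfR::extract.info(v, element = "DP")
  }
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))

  multi <- grepl(",", alt, fixed = TRUE)
  keep <- rep(TRUE, n)
  n_multi_skipped <- 0L
  ao <- rep(NA_real_, n)
  alt_out <- alt
  for (i in seq_len(n)) {
    ao_i <- suppressWarnings(as.numeric(strsplit(
      if (is.na(ao_raw[i])) "" else ao_raw[i], ",", fixed = TRUE)[[1]]))
    if (multi[i]) {
      if (!allow_multiallelic) {
        keep[i] <- FALSE
        n_multi_skipped <- n_multi_skipped + 1L
        next
      }
      alts <- strsplit(alt[i], ",", fixed = TRUE)[[1]]
      if (length(ao_i) == length(alts) && !anyNA(ao_i)) {
        j <- which.max(ao_i)   # ties: which.max takes the first
        ao[i] <- ao_i[j]
        alt_out[i] <- alts[j]
      }
    } else if (length(ao_i) >= 1L && !is.na(ao_i[1])) {
      ao[i] <- ao_i[1]
    }
  }
  dp <- suppressWarnings(as.numeric(dp_raw))
  missing_fields <- keep & (is.na(ao) | is.na(dp))
  if (any(missing_fields)) {
    warning(sum(missing_fields), " record(s) skipped: missing AO or DP (",
            path, ")", call. = FALSE)
    keep <- keep & !missing_fields
  }
  out <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt_out,
                    type = ifelse(nchar(ref) == 1L & nchar(alt_out) == 1L,
                                  "SNP", "indel"),
                    ao = ao, dp = dp, qual = qual,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out$ratio <- ifelse(out$dp > 0, out$ao / out$dp, NA_real_)
  out <- out[order(match(out$chrom, unique(out$chrom)), out$pos), ,
             drop = FALSE]
  rownames(out) <- NULL
  stopifnot(all(out$ao <= out$dp, na.rm = TRUE))
  attr(out, "n_skipped_missing") <- sum(missing_fields)
  attr(out, "n_skipped_multiallelic") <- n_multi_skipped
  out
}

# cheap structural check so malformed body lines are reported by line number
validate_vcf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !startsWith(lines[1], "##fileformat=VCF")) {
    stop("not a VCF file (missing ##fileformat header): ", path,
         call. = FALSE)
  }
  body <- which(!startsWith(lines, "#"))
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- body[nfield < 8L]
  if (length(bad)) {
    stop("malformed VCF record at line ", bad[1], " of ", path,
         " (fewer than 8 tab-separated fields)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a per-base depth-of-coverage table
#'
#' Consumes the per-locus dialect produced by depth-of-coverage tools: a
#' tab-separated table whose first column is `chrom:pos` and second column
#' the total depth, preceded by one header line.
#'
#' @param path Path to the table.
#' @return Data frame `chrom`, `pos`, `depth`, in file order; positions are
#'   checked to be ascending within each chromosome.
#' @export
read_doc <- function(path) {
  if (!file.exists(path)) stop("coverage file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) stop("empty coverage file: ", path, call. = FALSE)
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (!length(body)) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      depth = integer(0), stringsAsFactors = FALSE))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  locus <- vapply(fields, `[`, character(1), 1L)
  depth_chr <- vapply(fields, function(f) if (length(f) >= 2L) f[2] else NA,
                      character(1))
  ok <- grepl("^.+:[0-9]+$", locus)
  if (!all(ok)) {
    stop("unparsable locus '", locus[which(!ok)[1]], "' at line ",
         which(!ok)[1] + 1L, " of ", path, call. = FALSE)
  }
  sep <- regexpr(":[0-9]+$", locus)
  chrom <- substr(locus, 1L, sep - 1L)
  pos <- as.integer(substr(locus, sep + 1L, nchar(locus)))
  depth <- suppressWarnings(as.integer(depth_chr))
  if (anyNA(depth)) {
    stop("non-integer depth at line ", which(is.na(depth))[1] + 1L, " of ",
         path, call. = FALSE)
  }
  unsorted <- unlist(lapply(split(pos, factor(chrom, levels = unique(chrom))),
                            function(p) any(diff(p) <= 0)))
  if (any(unsorted)) {
    stop("coverage positions not sorted ascending within chromosome ",
         names(unsorted)[unsorted][1], " in ", path, call. = FALSE)
  }
  data.frame(chrom = chrom, pos = pos, depth = depth, stringsAsFactors = FALSE)
}

#' Write an alleles file
#'
#' Writes the parental or recombined alleles table as UTF-8 TSV with one
#' header line, ordered by chromosome (layout order when given, otherwise
#' order of appearance) then position.
#'
#' @param records Allele-record data frame (see [read_vcf()]).
#' @param role `"parental"` or `"recombined"` (recorded in a comment-free
#'   way: the file name is up to the caller).
#' @param path Output path.
#' @param layout Optional [genome_layout()] fixing chromosome order.
#' @return `path`, invisibly.
#' @export
write_alleles_file <- function(records, role = c("parental", "recombined"),
                               path, layout = NULL) {
  role <- match.arg(role)
  ord <- order(chrom_rank(records$chrom, layout), records$pos)
  records <- records[ord, , drop = FALSE]
  out <- data.frame(chrom = records$chrom, pos = records$pos,
                    ref = records$ref, alt = records$alt,
                    type = records$type, AO = records$ao, DP = records$dp,
                    QUAL = records$qual,
                    ratio = fmt_num(records$ratio),
                    stringsAsFactors = FALSE)
  write_tsv(out, path)
}

#' Read back an alleles file written by [write_alleles_file()]
#' @param path Path to the TSV.
#' @return Allele-record data frame (columns as [read_vcf()]).
#' @export
read_alleles_file <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character",
                                         ref = "character",
                                         alt = "character"))
  data.frame(chrom = df$chrom, pos = as.integer(df$pos), ref = df$ref,
             alt = df$alt, type = df$type, ao = as.numeric(df$AO),
             dp = as.numeric(df$DP), qual = as.numeric(df$QUAL),
             ratio = as.numeric(df$ratio), stringsAsFactors = FALSE)
}

#' Write the region-of-recombination file
#'
#' @param regions Output of [call_regions()]/[attach_ndoc()].
#' @param path Output path.
#' @param layout Optional [genome_layout()] fixing chromosome order.
#' @return `path`, invisibly.
#' @export
write_regions_file <- function(regions, path, layout = NULL) {
  ord <- order(chrom_rank(regions$chrom, layout), regions$start)
  regions <- regions[ord, , drop = FALSE]
  out <- data.frame(chrom = regions$chrom, start = regions$start,
                    end = regions$end,
                    n_variant_alleles = regions$n_variant,
                    event_type = regions$event_type,
                    mean_ndoc = fmt_num(regions$mean_ndoc),
                    stringsAsFactors = FALSE)
  write_tsv(out, path)
}

#' Write marker calls (variant and invariant alleles files)
#'
#' Splits the paired-marker calls into the "variants alleles file"
#' (markers whose ratio changed) and the "invariant alleles file".
#'
#' @param calls Output of [pair_markers()].
#' @param variants_path,invariant_path Output paths.
#' @param layout Optional [genome_layout()] fixing chromosome order.
#' @return Named list of the two paths, invisibly.
#' @export
write_marker_files <- function(calls, variants_path, invariant_path,
                               layout = NULL) {
  ord <- order(chrom_rank(calls$chrom, layout), calls$pos)
  calls <- calls[ord, , drop = FALSE]
  cols <- data.frame(chrom = calls$chrom, pos = calls$pos,
                     parent_ratio = fmt_num(calls$parent_ratio),
                     parent_center = fmt_num(calls$parent_center),
                     recomb_ratio = fmt_num(calls$recomb_ratio),
                     recomb_center = fmt_num(calls$recomb_center),
                     status = calls$status, stringsAsFactors = FALSE)
  inv <- calls$status == "invariant"
  amb <- calls$status == "ambiguous"
  write_tsv(cols[!inv & !amb, , drop = FALSE], variants_path)
  write_tsv(cols[inv, , drop = FALSE], invariant_path)
  invisible(list(variants = variants_path, invariant = invariant_path))
}

#' Write the normalized-coverage file
#'
#' Default file name follows the `<sample>_normalized1KB.txt` convention.
#'
#' @param windows Output of [flag_cnv()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ndoc_file <- function(windows, path) {
  out <- data.frame(chrom = windows$chrom, start = windows$start,
                    end = windows$end,
                    parent_mean = fmt_num(windows$parent_mean),
                    recomb_mean = fmt_num(windows$recomb_mean),
                    ndoc = fmt_num(windows$ndoc),
                    flag = windows$flag, stringsAsFactors = FALSE)
  write_tsv(out, path)
}

chrom_rank <- function(chrom, layout = NULL) {
  lv <- if (is.null(layout)) unique(chrom) else layout$chrom
  r <- match(chrom, lv)
  if (anyNA(r)) stop("chromosome(s) not in layout: ",
                     paste(unique(chrom[is.na(r)]), collapse = ", "),
                     call. = FALSE)
  r
}

fmt_num <- function(x, digits = 10) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "g"))
}

write_tsv <- function(df, path) {
  ok <- tryCatch({
    suppressWarnings(
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = TRUE, na = "NA",
                         fileEncoding = "UTF-8"))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}
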