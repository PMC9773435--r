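# Hand-written VCF fixture (independent of the package's own VCF writer)
# so parser tests do not depend on the code they check.
vcf_header <- function(sample = NULL) {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"depth\">",
    "##INFO=<ID=AO,Number=A,Type=Integer,Description=\"alt obs\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"depth\">",
    "##FORMAT=<ID=AO,Number=A,Type=Integer,Description=\"alt obs\">",
    paste(c("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
            if (!is.null(sample)) paste0("FORMAT\t", sample)),
          collapse = "\t"))
}

vcf_info_line <- function(chrom, pos, ref, alt, qual, dp, ao) {
  sprintf("%s\t%d\t.\t%s\t%s\t%s\tPASS\tDP=%d;AO=%s",
          chrom, pos, ref, alt, format(qual), dp,
          paste(ao, collapse = ","))
}

vcf_fmt_line <- function(chrom, pos, ref, alt, qual, dp, ao) {
  sprintf("%s\t%d\t.\t%s\t%s\t%s\tPASS\tDP=%d;AO=%s\tGT:DP:AO\t0/1:%d:%s",
          chrom, pos, ref, alt, format(qual), dp,
          paste(ao, collapse = ","), dp, paste(ao, collapse = ","))
}

write_fixture_vcf <- function(lines, sample = NULL) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  writeLines(c(vcf_header(sample), lines), path)
  path
}

write_fixture_doc <- function(chrom, pos, depth) {
  path <- withr::local_tempfile(fileext = ".doc",
                                .local_envir = parent.frame())
  writeLines(c("Locus\tTotal_Depth\tAverage_Depth",
               sprintf("%s:%d\t%d\t%d", chrom, pos, depth, depth)),
             path)
  path
}

# Exact-ratio allele records at given group centers (no sampling noise),
# for clean-path marker-comparison tests.
clean_records <- function(chrom, pos, ratio, dp = 80, qual = 1000,
                          alt = "G") {
  n <- length(pos)
  data.frame(chrom = rep_len(chrom, n), pos = pos, ref = "A",
             alt = rep_len(alt, n), type = "SNP",
             ao = round(ratio * dp), dp = rep_len(dp, n),
             qual = rep_len(qual, n),
             ratio = round(ratio * dp) / dp, stringsAsFactors = FALSE)
}

flat_coverage <- function(chrom, len, depth) {
  data.frame(chrom = chrom, pos = seq_len(len),
             depth = rep_len(depth, len), stringsAsFactors = FALSE)
}

make_track <- function(statuses, chrom = "chrI", spacing = 100L) {
  data.frame(chrom = rep_len(chrom, length(statuses)),
             pos = seq_along(statuses) * spacing,
             status = statuses, stringsAsFactors = FALSE)
}

# all binary V/I tracks of a given length, one chromosome per track,
# stacked into a single data frame for batch region-calling
all_tracks <- function(len, codes = 0:(2^len - 1)) {
  vbits <- matrix(bitwAnd(rep(codes, each = len), 2^(0:(len - 1))) > 0,
                  nrow = len)
  data.frame(chrom = rep(sprintf("t%06d", codes), each = len),
             pos = rep(seq_len(len) * 10L, length(codes)),
             status = ifelse(as.vector(vbits), "V", "I"),
             stringsAsFactors = FALSE)
}
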