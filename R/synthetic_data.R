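#' Describe a planted recombination / copy-number event
#'
#' @param kind One of `LOH_0`, `LOH_1`, `het_change`, `chrom_loss`,
#'   `chrom_gain`, `segmental_dup`, `segmental_del`.  The `chrom_*` kinds
#'   conventionally span a whole chromosome and the `segmental_*` kinds an
#'   interior interval; both change the local copy number by one, as do
#'   their effects on coverage.
#' @param chrom Chromosome name.
#' @param start,end Interval in bp (1-based, inclusive).
#' @param to_alt Optional fixed alternate-copy count after the event,
#'   applied to every marker in the interval; by default each marker's
#'   state is transformed per kind (LOH_0: to 0 copies; LOH_1: to all
#'   copies; het_change: to the complementary heterozygous state;
#'   loss/deletion: one alternate copy lost with the set; gain/duplication:
#'   the alternate count kept while the total grows).
#' @return A list of class `planted_event`.
#' @export
planted_event <- function(kind = c("LOH_0", "LOH_1", "het_change",
                                   "chrom_loss", "chrom_gain",
                                   "segmental_dup", "segmental_del"),
                          chrom, start, end, to_alt = NULL) {
  kind <- match.arg(kind)
  stopifnot(start >= 1, end >= start)
  structure(list(kind = kind, chrom = chrom, start = start, end = end,
                 to_alt = to_alt),
            class = "planted_event")
}

event_total_change <- function(kind) {
  switch(kind,
         chrom_loss = -1L, segmental_del = -1L,
         chrom_gain = +1L, segmental_dup = +1L,
         0L)
}

# (a, p) -> a' under an event kind; to_alt overrides when non-NULL
event_transform_alt <- function(kind, a, p, to_alt = NULL) {
  p2 <- p + event_total_change(kind)
  if (!is.null(to_alt)) {
    if (to_alt < 0 || to_alt > p2) stop("to_alt outside 0..", p2,
                                        call. = FALSE)
    return(rep(as.integer(to_alt), length(a)))
  }
  switch(kind,
         LOH_0 = rep(0L, length(a)),
         LOH_1 = rep(as.integer(p), length(a)),
         het_change = ifelse(p - a != a, p - a, a + 1L),
         chrom_loss = ,
         segmental_del = pmax(0L, a - 1L),
         chrom_gain = ,
         segmental_dup = a)
}

#' Simulation configuration
#'
#' Defines the genome, marker density, sequencing depth, ploidy and
#' planted events for a matched parent/recombinant simulation.  Marker
#' depths follow `DP ~ Poisson(mean_depth * local_copies / ploidy)` and
#' alternate observations `AO ~ Binomial(DP, a / local_copies)` for `a`
#' alternate copies; per-base coverage tracks are Poisson draws at the
#' same locally rescaled rate.
#'
#' @param seed Integer random seed; identical configurations and seeds
#'   reproduce fixtures exactly.
#' @param ploidy Integer 1..4.
#' @param chromosomes A [genome_layout()]; default three chromosomes of
#'   200, 150 and 100 kb.
#' @param marker_density Markers per kb (default 2, a typical density for
#'   divergent yeast crosses).
#' @param mean_depth Mean sequencing depth in reads (default 80).
#' @param events List of [planted_event()]s, non-overlapping per
#'   chromosome.
#' @param low_qual_fraction Fraction of markers emitted with decoy low
#'   site quality (exercises the QUAL filter); default 0.
#' @param low_qual_value QUAL assigned to decoys.
#' @param indel_fraction Fraction of markers emitted as small indels
#'   rather than SNPs (default 0.05).
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L, ploidy = 2L,
                              chromosomes = genome_layout(
                                c(chrI = 200000, chrII = 150000,
                                  chrIII = 100000)),
                              marker_density = 2, mean_depth = 80,
                              events = list(),
                              low_qual_fraction = 0, low_qual_value = 50,
                              indel_fraction = 0.05) {
  check_ploidy(ploidy)
  stopifnot(marker_density > 0, mean_depth > 0,
            low_qual_fraction >= 0, low_qual_fraction <= 1,
            indel_fraction >= 0, indel_fraction <= 1)
  if (inherits(events, "planted_event")) events <- list(events)
  for (ev in events) {
    stopifnot(inherits(ev, "planted_event"))
    if (!ev$chrom %in% chromosomes$chrom) {
      stop("event chromosome not in layout: ", ev$chrom, call. = FALSE)
    }
    L <- chromosomes$length[chromosomes$chrom == ev$chrom]
    if (ev$end > L) stop("event extends past chromosome ", ev$chrom,
                         call. = FALSE)
    p2 <- ploidy + event_total_change(ev$kind)
    if (p2 < 1L || p2 > 4L) {
      stop("event '", ev$kind, "' would leave total copies outside 1..4",
           call. = FALSE)
    }
  }
  # overlap check per chromosome
  for (ch in unique(vapply(events, `[[`, character(1), "chrom"))) {
    iv <- do.call(rbind, lapply(events[vapply(events, `[[`, character(1),
                                              "chrom") == ch],
                                function(e) c(e$start, e$end)))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (nrow(iv) > 1L && any(iv[-1, 1] <= iv[-nrow(iv), 2])) {
      stop("planted events overlap on ", ch, call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), ploidy = as.integer(ploidy),
                 chromosomes = chromosomes,
                 marker_density = marker_density, mean_depth = mean_depth,
                 events = events, low_qual_fraction = low_qual_fraction,
                 low_qual_value = low_qual_value,
                 indel_fraction = indel_fraction),
            class = "sim_config")
}

#' Simulate a matched parent/recombinant pair with known events
#'
#' Generates parental and recombinant allele records, per-base coverage
#' tracks for both strains, and a truth table of per-marker copy states.
#' Recombinant markers whose alternate-copy count drops to zero are
#' omitted from the recombinant record set (a variant caller is silent at
#' homozygous-reference sites) but remain covered in the recombinant
#' depth track.
#'
#' @param config A [simulation_config()].
#' @param write_dir Optional directory; when given, the fixtures are also
#'   written as `parent.vcf`, `recomb.vcf`, `parent.doc`, `recomb.doc` and
#'   `truth.tsv`.
#' @return List with elements `parent`, `recomb` (allele records),
#'   `parent_doc`, `recomb_doc` (coverage), `truth` (per-marker states and
#'   true centers, including omitted recombinant records), `layout`,
#'   `config`, and (when written) `paths`.
#' @export
simulate_pair <- function(config, write_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  p <- config$ploidy
  lay <- config$chromosomes
  bases <- c("A", "C", "G", "T")

  truth <- list()
  parent_doc <- list()
  recomb_doc <- list()
  for (i in seq_len(nrow(lay))) {
    ch <- lay$chrom[i]
    L <- as.integer(lay$length[i])
    n <- max(1L, round(config$marker_density * L / 1000))
    pos <- sort(sample.int(L, n))
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L),
                  character(1))
    is_indel <- stats::runif(n) < config$indel_fraction
    alt[is_indel] <- paste0(alt[is_indel], sample(bases, sum(is_indel),
                                                  replace = TRUE))
    a <- if (p == 1L) rep(1L, n) else
      sample(seq_len(p - 1L), n, replace = TRUE)
    a2 <- a
    total2 <- rep(p, n)
    event <- rep("none", n)
    copy_rate <- rep(config$mean_depth, L)   # recombinant per-base rate
    for (ev in config$events) {
      if (ev$chrom != ch) next
      sel <- pos >= ev$start & pos <= ev$end
      a2[sel] <- event_transform_alt(ev$kind, a[sel], p, ev$to_alt)
      total2[sel] <- p + event_total_change(ev$kind)
      event[sel] <- ev$kind
      copy_rate[ev$start:ev$end] <-
        config$mean_depth * (p + event_total_change(ev$kind)) / p
    }
    truth[[ch]] <- data.frame(
      chrom = ch, pos = pos, ref = ref, alt = alt,
      type = ifelse(nchar(alt) == 1L, "SNP", "indel"),
      parent_alt = a, parent_total = p,
      recomb_alt = a2, recomb_total = total2,
      parent_center = round(a / p, 2),
      recomb_center = round(a2 / total2, 2),
      event = event, stringsAsFactors = FALSE)
    parent_doc[[ch]] <- data.frame(
      chrom = ch, pos = seq_len(L),
      depth = stats::rpois(L, config$mean_depth), stringsAsFactors = FALSE)
    recomb_doc[[ch]] <- data.frame(
      chrom = ch, pos = seq_len(L),
      depth = stats::rpois(L, copy_rate), stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  parent_doc <- do.call(rbind, parent_doc)
  recomb_doc <- do.call(rbind, recomb_doc)
  rownames(parent_doc) <- rownames(recomb_doc) <- NULL

  nm <- nrow(truth)
  sample_records <- function(alt_copies, total_copies) {
    dp <- stats::rpois(nm, config$mean_depth * total_copies / p)
    ao <- stats::rbinom(nm, dp, alt_copies / pmax(total_copies, 1L))
    qual <- rep(1000, nm)
    decoy <- stats::runif(nm) < config$low_qual_fraction
    qual[decoy] <- config$low_qual_value
    data.frame(chrom = truth$chrom, pos = truth$pos, ref = truth$ref,
               alt = truth$alt, type = truth$type, ao = ao, dp = dp,
               qual = qual, ratio = ifelse(dp > 0, ao / dp, NA_real_),
               stringsAsFactors = FALSE)
  }
  parent <- sample_records(truth$parent_alt, truth$parent_total)
  recomb <- sample_records(truth$recomb_alt, truth$recomb_total)
  recomb <- recomb[truth$recomb_alt > 0L, , drop = FALSE]
  rownames(recomb) <- NULL

  out <- list(parent = parent, recomb = recomb, parent_doc = parent_doc,
              recomb_doc = recomb_doc, truth = truth, layout = lay,
              config = config)
  if (!is.null(write_dir)) {
    dir.create(write_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      parent_vcf = file.path(write_dir, "parent.vcf"),
      recomb_vcf = file.path(write_dir, "recomb.vcf"),
      parent_doc = file.path(write_dir, "parent.doc"),
      recomb_doc = file.path(write_dir, "recomb.doc"),
      truth = file.path(write_dir, "truth.tsv"))
    write_vcf(parent, paths$parent_vcf, sample_name = "parent",
              layout = lay)
    write_vcf(recomb, paths$recomb_vcf, sample_name = "recomb",
              layout = lay)
    write_doc_file(parent_doc, paths$parent_doc)
    write_doc_file(recomb_doc, paths$recomb_doc)
    write_tsv(truth, paths$truth)
    out$paths <- paths
  }
  out
}

#' Write allele records as a minimal FreeBayes-style VCF
#'
#' Emits AO and DP both as INFO keys and as single-sample FORMAT fields,
#' matching the dialect the parser consumes.
#'
#' @param records Allele-record data frame.
#' @param path Output path.
#' @param sample_name Sample column name.
#' @param layout Optional [genome_layout()] for contig header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, sample_name = "sample", layout = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=lohscan-simulator",
           if (!is.null(layout)) {
             sprintf("##contig=<ID=%s,length=%d>", layout$chrom,
                     as.integer(layout$length))
           },
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
           "##INFO=<ID=AO,Number=A,Type=Integer,Description=\"Alternate allele observation count\">",
           "##INFO=<ID=TYPE,Number=A,Type=String,Description=\"Allele type\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=AO,Number=A,Type=Integer,Description=\"Alternate observation count\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  sample_name))
  body <- sprintf(
    "%s\t%d\t.\t%s\t%s\t%s\tPASS\tDP=%d;AO=%d;TYPE=%s\tGT:DP:AO\t0/1:%d:%d",
    records$chrom, records$pos, records$ref, records$alt,
    fmt_num(records$qual), as.integer(records$dp), as.integer(records$ao),
    tolower(records$type), as.integer(records$dp), as.integer(records$ao))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a per-base coverage table in the per-locus dialect
#' @param coverage Data frame `chrom`, `pos`, `depth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_doc_file <- function(coverage, path) {
  writeLines(c("Locus\tTotal_Depth",
               sprintf("%s:%d\t%d", coverage$chrom, coverage$pos,
                       as.integer(coverage$depth))),
             path)
  invisible(path)
}

#' Simulate a four-spore tetrad from a heterozygous diploid hybrid
#'
#' Markers are heterozygous in the hybrid; by default each segregates 2:2,
#' with two spores carrying the reference haplotype and two the alternate.
#' Crossovers exchange the haplotypes of one spore pair beyond a random
#' breakpoint (reciprocal, so 2:2 counts are conserved); a configurable
#' fraction of markers is converted in one random spore, yielding 3:1 or
#' 1:3 gene-conversion patterns.
#'
#' @param config A [simulation_config()] with `ploidy = 2`.
#' @param crossovers_per_chrom Number of crossover breakpoints per
#'   chromosome (default 1).
#' @param conversion_fraction Fraction of markers undergoing gene
#'   conversion (default 0).
#' @return List with `markers` (the hybrid's heterozygous marker list),
#'   `spores` (list of four haploid allele-record data frames carrying the
#'   alternate-allele markers only), `spore_doc` (four per-base coverage
#'   tracks), and `truth` (spore allele matrix, per-marker segregation
#'   pattern, conversion indices, crossover table).
#' @export
make_tetrad <- function(config, crossovers_per_chrom = 1,
                        conversion_fraction = 0) {
  stopifnot(inherits(config, "sim_config"))
  if (config$ploidy != 2L) {
    stop("tetrad simulation requires a diploid hybrid (ploidy = 2)",
         call. = FALSE)
  }
  set.seed(config$seed)
  lay <- config$chromosomes
  bases <- c("A", "C", "G", "T")
  markers <- list()
  alleles <- list()
  crossovers <- list()
  for (i in seq_len(nrow(lay))) {
    ch <- lay$chrom[i]
    L <- as.integer(lay$length[i])
    n <- max(1L, round(config$marker_density * L / 1000))
    pos <- sort(sample.int(L, n))
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L),
                  character(1))
    markers[[ch]] <- data.frame(chrom = ch, pos = pos, ref = ref, alt = alt,
                                stringsAsFactors = FALSE)
    al <- matrix(rep(c(0, 0, 1, 1), each = n), nrow = n)
    if (crossovers_per_chrom > 0) {
      for (k in seq_len(crossovers_per_chrom)) {
        bp <- sample.int(L, 1L)
        s_ref <- sample(1:2, 1L)
        s_alt <- sample(3:4, 1L)
        swap <- pos > bp
        tmp <- al[swap, s_ref]
        al[swap, s_ref] <- al[swap, s_alt]
        al[swap, s_alt] <- tmp
        crossovers[[length(crossovers) + 1L]] <-
          data.frame(chrom = ch, breakpoint = bp, spore_a = s_ref,
                     spore_b = s_alt, stringsAsFactors = FALSE)
      }
    }
    alleles[[ch]] <- al
  }
  markers <- do.call(rbind, markers)
  rownames(markers) <- NULL
  alleles <- do.call(rbind, alleles)
  conv_idx <- integer(0)
  if (conversion_fraction > 0) {
    conv_idx <- which(stats::runif(nrow(markers)) < conversion_fraction)
    for (j in conv_idx) {
      s <- sample(1:4, 1L)
      alleles[j, s] <- 1 - alleles[j, s]
    }
  }
  pattern <- paste0(rowSums(alleles), ":", 4L - rowSums(alleles))

  spores <- list()
  spore_doc <- list()
  for (s in 1:4) {
    carrier <- alleles[, s] == 1
    nc <- sum(carrier)
    dp <- stats::rpois(nc, config$mean_depth)
    spores[[s]] <- data.frame(
      chrom = markers$chrom[carrier], pos = markers$pos[carrier],
      ref = markers$ref[carrier], alt = markers$alt[carrier],
      type = rep("SNP", nc), ao = dp, dp = dp, qual = rep(1000, nc),
      ratio = ifelse(dp > 0, 1, NA_real_), stringsAsFactors = FALSE)
    spore_doc[[s]] <- do.call(rbind, lapply(seq_len(nrow(lay)), function(i) {
      L <- as.integer(lay$length[i])
      data.frame(chrom = lay$chrom[i], pos = seq_len(L),
                 depth = stats::rpois(L, config$mean_depth),
                 stringsAsFactors = FALSE)
    }))
  }
  list(markers = markers, spores = spores, spore_doc = spore_doc,
       truth = list(alleles = alleles, pattern = pattern,
                    conversions = conv_idx,
                    crossovers = if (length(crossovers)) {
                      do.call(rbind, crossovers)
                    } else NULL))
}
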