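test_that("center pairs are labelled per the transition semantics", {
  m2 <- ploidy_model(2)
  m3 <- ploidy_model(3)
  expect_equal(label_marker(0.5, 0.5, m2)$status, "invariant")
  expect_equal(label_marker(0.5, 1.0, m2)$status, "LOH_1")
  expect_equal(label_marker(0.5, 0.0, m2)$status, "LOH_0")
  expect_equal(label_marker(0.33, 0.67, m3)$status, "het_change")

  cand <- label_marker(0.33, 0.25, m3)
  expect_equal(cand$status, "ploidy_change_candidate")
  expect_equal(cand$requires_ndoc, "gain")
  # 0.5 from a triploid is explicable by either a loss (2n) or a gain (4n)
  either <- label_marker(0.33, 0.5, m3)
  expect_equal(either$status, "ploidy_change_candidate")
  expect_equal(either$requires_ndoc, "either")
  # no transition leads away from a homozygous parent state
  expect_equal(label_marker(0, 0.5, m2)$status, "ambiguous")
  expect_equal(label_marker(0.5, NA, m2)$status, "ambiguous")
})

test_that("identical parent and recombinant inputs give only invariant calls", {
  pos <- seq(1000L, 50000L, by = 1000L)
  recs <- clean_records("chrI", pos, 0.5)
  cov <- flat_coverage("chrI", 50000, 80)
  calls <- pair_markers(recs, recs, cov, ploidy_model(2))
  expect_equal(nrow(calls), length(pos))
  expect_true(all(calls$status == "invariant"))
  expect_equal(nrow(attr(calls, "dropped")), 0L)
})

test_that("a parent marker absent from the recombinant VCF imputes ratio 0", {
  parent <- clean_records("chrIV", c(4000L, 5000L), 0.5)
  recomb <- clean_records("chrIV", 4000L, 0.5)
  cov <- flat_coverage("chrIV", 6000, 60)
  calls <- pair_markers(parent, recomb, cov, ploidy_model(2))
  expect_equal(calls$status, c("invariant", "LOH_0"))
  expect_equal(calls$recomb_ratio[2], 0)
  expect_equal(calls$recomb_center[2], 0)
})

test_that("markers with thin recombinant coverage are dropped, not imputed", {
  pos <- seq(1000L, 100000L, by = 1000L) # 100 parent markers
  parent <- clean_records("chrII", pos, 0.5)
  recomb <- parent[0, ]                  # recombinant VCF is empty
  depth <- rep(60L, 100)
  depth[sample.int(100, 10)] <- 8L       # 10 positions under min_dp
  cov <- data.frame(chrom = "chrII", pos = pos, depth = depth)
  calls <- pair_markers(parent, recomb, cov, ploidy_model(2))
  expect_equal(nrow(calls), 90L)
  expect_true(all(calls$status == "LOH_0"))
  dropped <- attr(calls, "dropped")
  expect_equal(nrow(dropped), 10L)
  expect_true(all(dropped$reason == "low_coverage"))
})

test_that("a present-but-filtered recombinant record drops the marker", {
  parent <- clean_records("chrI", c(1000L, 2000L), 0.5)
  recomb <- clean_records("chrI", c(1000L, 2000L), 0.5)
  recomb$qual[2] <- 150   # fails the QUAL filter
  cov <- flat_coverage("chrI", 3000, 80)
  calls <- pair_markers(parent, recomb, cov, ploidy_model(2))
  expect_equal(nrow(calls), 1L)
  dropped <- attr(calls, "dropped")
  expect_equal(dropped$reason, "recomb_filtered")
  expect_equal(dropped$pos, 2000L)
})

test_that("a different alternate allele at the same position is not a match", {
  parent <- clean_records("chrI", 1000L, 0.5, alt = "G")
  recomb <- clean_records("chrI", 1000L, 1.0, alt = "T")
  cov <- flat_coverage("chrI", 2000, 80)
  calls <- pair_markers(parent, recomb, cov, ploidy_model(2))
  # tracked marker is unobserved in the recombinant: imputed LOH_0
  expect_equal(calls$status, "LOH_0")
})

test_that("calls plus dropped markers partition the parent marker set", {
  set.seed(13)
  cfg <- simulation_config(seed = 13, ploidy = 3,
                           chromosomes = genome_layout(c(chrA = 50000)),
                           events = list(planted_event("LOH_0", "chrA",
                                                       10001, 30000)))
  sim <- simulate_pair(cfg)
  th <- filter_thresholds()
  reason <- lohscan:::filter_reasons(sim$parent, th, mean(sim$parent$dp))
  parent_pass <- sim$parent[is.na(reason), ]
  calls <- pair_markers(parent_pass, sim$recomb, sim$recomb_doc,
                        ploidy_model(3), th)
  expect_equal(nrow(calls) + nrow(attr(calls, "dropped")),
               nrow(parent_pass))
  key <- function(df) paste(df$chrom, df$pos)
  expect_setequal(c(key(calls), key(attr(calls, "dropped"))),
                  key(parent_pass))
})

test_that("heterozygous changes are symmetric under strain swap", {
  pos <- seq(1000L, 20000L, by = 1000L)
  parent <- clean_records("chrI", pos, 1 / 3)
  recomb <- clean_records("chrI", pos, 2 / 3)
  cov <- flat_coverage("chrI", 21000, 80)
  m <- ploidy_model(3)
  fwd <- pair_markers(parent, recomb, cov, m)
  rev <- pair_markers(recomb, parent, cov, m)
  expect_true(all(fwd$status == "het_change"))
  expect_true(all(rev$status == "het_change"))
  expect_equal(fwd$parent_center, rev$recomb_center)
  expect_equal(fwd$recomb_center, rev$parent_center)
})

test_that("unsorted inputs are rejected", {
  parent <- clean_records("chrI", c(2000L, 1000L), 0.5)
  cov <- flat_coverage("chrI", 3000, 80)
  expect_error(pair_markers(parent, parent[0, ], cov, ploidy_model(2)),
               "sorted")
})

test_that("candidate markers survive the track only with matching coverage", {
  pos <- seq(1000L, 20000L, by = 1000L)
  parent <- clean_records("chrI", pos, 0.5)
  recomb <- clean_records("chrI", pos, 1 / 3)  # 2n -> 3n signature
  cov <- flat_coverage("chrI", 21000, 80)
  calls <- pair_markers(parent, recomb, cov, ploidy_model(2))
  expect_true(all(calls$status == "ploidy_change_candidate"))
  win <- function(nd) data.frame(chrom = "chrI", start = 1, end = 21000,
                                 ndoc = nd,
                                 flag = ifelse(nd > 1.5, "gain",
                                               ifelse(nd < 0.5, "loss",
                                                      "none")),
                                 stringsAsFactors = FALSE)
  trk_gain <- build_track(calls, win(1.55))
  expect_equal(unique(trk_gain$status), "chrom_gain")
  trk_flat <- build_track(calls, win(1.0))
  expect_equal(nrow(trk_flat), 0L)
  # without windows the candidates are kept for region-level arbitration
  trk_raw <- build_track(calls)
  expect_equal(unique(trk_raw$status), "ploidy_change_candidate")
})

test_that("tetrad segregation counts follow Mendelian expectations", {
  expect_equal(tetrad_segregation(c(1, 1, 0, 0)),
               list(pattern = "2:2", mendelian = TRUE))
  expect_equal(tetrad_segregation(c(1, 1, 1, 1), parent_het = FALSE),
               list(pattern = "4:0", mendelian = TRUE))
  expect_equal(tetrad_segregation(c(0, 0, 0, 0), parent_het = FALSE),
               list(pattern = "0:4", mendelian = TRUE))
  expect_equal(tetrad_segregation(c(1, 1, 1, 0)),
               list(pattern = "3:1", mendelian = FALSE))
  expect_equal(tetrad_segregation(c(1, 1, 1, 1))$mendelian, FALSE)
  und <- tetrad_segregation(c(1, NA, 0, 0))
  expect_true(is.na(und$pattern))
  expect_error(tetrad_segregation(c(0.5, 1, 0, 0)), "0 or 1")
  expect_error(tetrad_segregation(c(1, 0)), "length")
})
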