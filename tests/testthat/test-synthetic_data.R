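small_layout <- function(len = 30000) genome_layout(c(chrA = len))

test_that("simulations are reproducible from the seed", {
  cfg <- simulation_config(seed = 99, ploidy = 3,
                           chromosomes = small_layout(),
                           events = list(planted_event("LOH_1", "chrA",
                                                       5001, 15000)))
  s1 <- simulate_pair(cfg)
  s2 <- simulate_pair(cfg)
  expect_identical(s1$parent, s2$parent)
  expect_identical(s1$recomb, s2$recomb)
  expect_identical(s1$recomb_doc, s2$recomb_doc)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_pair(cfg, write_dir = d1)
  simulate_pair(cfg, write_dir = d2)
  for (f in c("parent.vcf", "recomb.vcf", "parent.doc", "recomb.doc")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("a null simulation leaves every true center unchanged", {
  sim <- simulate_pair(simulation_config(seed = 3, ploidy = 4,
                                         chromosomes = small_layout()))
  expect_true(all(sim$truth$recomb_center == sim$truth$parent_center))
  expect_true(all(sim$truth$event == "none"))
})

test_that("planted events rewrite the truth table as declared", {
  cfg <- simulation_config(seed = 5, ploidy = 3,
                           chromosomes = small_layout(),
                           events = list(planted_event("LOH_0", "chrA",
                                                       5001, 30000)))
  sim <- simulate_pair(cfg)
  inside <- sim$truth$pos >= 5001 & sim$truth$pos <= 30000
  expect_true(all(sim$truth$event[inside] == "LOH_0"))
  expect_true(all(sim$truth$recomb_center[inside] == 0))
  expect_true(all(sim$truth$recomb_alt[inside] == 0L))
  expect_true(all(sim$truth$parent_center[inside] %in% c(0.33, 0.67)))
  expect_gte(sum(inside), 45) # ~2 markers/kb over 25 kb
  # alt-copy-zero markers are absent from the recombinant records but
  # still covered in its depth track
  expect_false(any(sim$recomb$pos %in% sim$truth$pos[inside]))
  expect_true(all(sim$truth$pos[inside] %in% sim$recomb_doc$pos))
})

test_that("sampled marker ratios concentrate on their true centers", {
  sim <- simulate_pair(simulation_config(seed = 17, ploidy = 2,
                                         chromosomes = small_layout(300000)))
  expect_gte(nrow(sim$parent), 500)
  se <- sd(sim$parent$ratio) / sqrt(nrow(sim$parent))
  expect_lt(abs(mean(sim$parent$ratio) - 0.5), 3 * se)
  # depth matches the configured sequencing depth
  expect_equal(mean(sim$parent$dp), 80, tolerance = 0.02)
})

test_that("event validation rejects inconsistent plans", {
  expect_error(simulation_config(events = list(
    planted_event("LOH_0", "chrA", 1, 10), planted_event("LOH_1", "chrA", 5, 20)),
    chromosomes = small_layout()), "overlap")
  expect_error(simulation_config(events = list(
    planted_event("LOH_0", "chrX", 1, 10)), chromosomes = small_layout()),
    "not in layout")
  expect_error(simulation_config(events = list(
    planted_event("LOH_0", "chrA", 1, 1e7)), chromosomes = small_layout()),
    "past chromosome")
  expect_error(simulation_config(ploidy = 4, events = list(
    planted_event("chrom_gain", "chrA", 1, 30000)),
    chromosomes = small_layout()), "outside 1..4")
  expect_error(simulation_config(ploidy = 1, events = list(
    planted_event("chrom_loss", "chrA", 1, 30000)),
    chromosomes = small_layout()), "outside 1..4")
})

test_that("written fixtures survive the production parsers", {
  cfg <- simulation_config(seed = 31, ploidy = 2,
                           chromosomes = genome_layout(c(chrA = 8000)),
                           events = list(planted_event("LOH_1", "chrA",
                                                       2001, 6000)))
  dir <- withr::local_tempdir()
  sim <- simulate_pair(cfg, write_dir = dir)
  back <- read_vcf(sim$paths$parent_vcf)
  expect_equal(back$pos, sim$parent$pos)
  expect_equal(back$ao, sim$parent$ao)
  expect_equal(back$dp, sim$parent$dp)
  expect_equal(back$ratio, sim$parent$ratio)
  expect_equal(back$type, sim$parent$type)
  cov <- read_doc(sim$paths$recomb_doc)
  expect_identical(cov, sim$recomb_doc)
})

test_that("low-quality decoys exercise the QUAL filter", {
  cfg <- simulation_config(seed = 41, ploidy = 2,
                           chromosomes = small_layout(100000),
                           low_qual_fraction = 0.2)
  sim <- simulate_pair(cfg)
  frac <- mean(sim$parent$qual < 200)
  expect_gt(frac, 0.12)
  expect_lt(frac, 0.28)
})

test_that("a diploid segmental duplication is recovered end to end", {
  out <- recover_one("segmental_dup", ploidy = 2, seed = 23)
  expect_true(out$recovered)
  expect_equal(out$regions$event_type, "chrom_gain")
})

test_that("tetrads segregate 2:2 with whole haplotypes absent crossovers", {
  cfg <- simulation_config(seed = 55, ploidy = 2,
                           chromosomes = small_layout())
  tet <- make_tetrad(cfg, crossovers_per_chrom = 0)
  expect_true(all(tet$truth$pattern == "2:2"))
  al <- tet$truth$alleles
  expect_true(all(apply(al, 2, function(x) all(x == x[1]))))
  expect_equal(rowSums(al), rep(2, nrow(al)))
})

test_that("a crossover switches spore haplotypes but conserves 2:2 counts", {
  cfg <- simulation_config(seed = 56, ploidy = 2,
                           chromosomes = small_layout())
  tet <- make_tetrad(cfg, crossovers_per_chrom = 1)
  expect_true(all(tet$truth$pattern == "2:2"))
  bp <- tet$truth$crossovers$breakpoint[1]
  sw <- tet$truth$crossovers$spore_a[1]
  al <- tet$truth$alleles
  before <- al[tet$markers$pos <= bp, sw]
  after <- al[tet$markers$pos > bp, sw]
  expect_true(all(before == before[1]))
  expect_true(all(after == after[1]))
  expect_false(before[1] == after[1])
})

test_that("planted gene conversions are recovered at the expected rate", {
  cfg <- simulation_config(seed = 57, ploidy = 2,
                           chromosomes = genome_layout(c(chrA = 600000)),
                           marker_density = 10 / 3)
  tet <- make_tetrad(cfg, crossovers_per_chrom = 1,
                     conversion_fraction = 0.05)
  n <- nrow(tet$markers)
  expect_gte(n, 2000)
  # genotype the spores through the haploid convention and recover patterns
  centers <- tetrad_genotypes(tet$spores, tet$spore_doc, tet$markers)
  pat <- apply(centers, 1, function(x) tetrad_segregation(x)$pattern)
  expect_equal(pat, tet$truth$pattern)
  frac <- mean(pat != "2:2")
  p0 <- 0.05
  expect_lt(abs(frac - p0), 3 * sqrt(p0 * (1 - p0) / n))
})
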