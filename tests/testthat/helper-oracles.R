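# Independent oracles used by both the unit and the acceptance suites.

# Nearest-center classification oracle: scores the ploidy's own centers and
# the adjacent ploidies' centers, with explicit tie detection.
oracle_classify <- function(ratio, ploidy, theta = 0.04) {
  centers <- unique(c(
    round(0:ploidy / ploidy, 2),
    if (ploidy > 1) round(0:(ploidy - 1) / (ploidy - 1), 2),
    if (ploidy < 4) round(0:(ploidy + 1) / (ploidy + 1), 2)))
  d <- round(abs(ratio - centers), 10)
  q <- centers[d <= theta]
  dq <- d[d <= theta]
  if (length(q) == 0L) return(NA_real_)
  nearest <- q[dq == min(dq)]
  if (length(nearest) != 1L) return(NA_real_)
  nearest
}

# Brute-force transition enumeration: filter ALL candidate state pairs
# (a, p) -> (a2, p2) with |p - p2| <= 1 through explicit predicates.
oracle_transitions <- function(ploidy) {
  g <- expand.grid(a = 0:4, p = 1:4, a2 = 0:4, p2 = 1:4)
  g <- g[g$p == ploidy & abs(g$p2 - g$p) <= 1 &
           g$a <= g$p & g$a2 <= g$p2, ]
  if (ploidy == 1) {
    g <- g[g$p2 == 1 & g$a2 == 1 - g$a, ]
  } else {
    het <- g$a > 0 & g$a < g$p
    same_ok <- g$p2 == g$p & g$a2 != g$a
    loss_ok <- g$p2 == g$p - 1 & (g$a2 == g$a - 1 | g$a2 == g$a) &
      g$a2 >= 0 & g$a2 <= g$p2
    gain_ok <- g$p2 == g$p + 1 & g$p2 <= 4 & (g$a2 == g$a | g$a2 == g$a + 1)
    g <- g[het & (same_ok | loss_ok | gain_ok), ]
  }
  ev <- ifelse(g$p2 < g$p, "chrom_loss",
               ifelse(g$p2 > g$p, "chrom_gain",
                      ifelse(g$a2 == 0, "LOH_0",
                             ifelse(g$a2 == g$p2, "LOH_1", "het_change"))))
  data.frame(from_alt = g$a, from_total = g$p, to_alt = g$a2,
             to_total = g$p2,
             from_center = round(g$a / g$p, 2),
             to_center = round(g$a2 / g$p2, 2),
             event_type = ev,
             requires_ndoc = ifelse(g$p2 < g$p, "loss",
                                    ifelse(g$p2 > g$p, "gain", "none")),
             stringsAsFactors = FALSE)
}

sort_transitions <- function(tr) {
  tr <- tr[order(tr$from_alt, tr$from_total, tr$to_alt, tr$to_total), ]
  rownames(tr) <- NULL
  tr
}

# In-memory pipeline core (no file output), shared by recovery tests.
run_core <- function(sim, ploidy, theta = 0.04,
                     thresholds = filter_thresholds()) {
  model <- ploidy_model(ploidy, theta)
  reason <- lohscan:::filter_reasons(sim$parent, thresholds,
                                     mean(sim$parent$dp))
  parent_pass <- sim$parent[is.na(reason), , drop = FALSE]
  calls <- pair_markers(parent_pass, sim$recomb, sim$recomb_doc, model,
                        thresholds)
  pw <- window_means(sim$parent_doc, sim$layout)
  rw <- window_means(sim$recomb_doc, sim$layout)
  windows <- flag_cnv(ndoc_normalize(pw, rw))
  track <- build_track(calls, windows)
  regions <- attach_ndoc(call_regions(track), windows)
  list(calls = calls, windows = windows, track = track, regions = regions)
}

# One planted event of the given kind; returns whether the pipeline
# recovered it with breakpoints exactly on variant markers of the event.
recover_one <- function(kind, ploidy, seed, to_alt = NULL,
                        chrom_len = 60000L, ev_start = 15001L,
                        ev_end = 40000L) {
  whole <- kind %in% c("chrom_loss", "chrom_gain")
  ev <- planted_event(kind, "chrA",
                      if (whole) 1L else ev_start,
                      if (whole) chrom_len else ev_end, to_alt = to_alt)
  cfg <- simulation_config(seed = seed, ploidy = ploidy,
                           chromosomes = genome_layout(c(chrA = chrom_len)),
                           events = list(ev))
  sim <- simulate_pair(cfg)
  res <- run_core(sim, ploidy)
  ev_pos <- sim$truth$pos[sim$truth$event == kind]
  v_in_event <- res$track$pos[lohscan:::is_variant_status(res$track$status) &
                                res$track$pos %in% ev_pos]
  reg <- res$regions
  list(
    n_regions = nrow(reg),
    recovered = length(v_in_event) > 0L && nrow(reg) == 1L &&
      reg$start[1] == min(v_in_event) && reg$end[1] == max(v_in_event) &&
      reg$start[1] %in% ev_pos && reg$end[1] %in% ev_pos,
    regions = reg)
}
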