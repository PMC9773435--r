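---
title: "Detecting recombination and LOH from allele ratios and read depth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recombination and LOH from allele ratios and read depth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lohscan)
```

## The model

`lohscan` compares two strains of the same species — a parent (or chosen
reference strain) and a potentially recombined strain — at their shared
polymorphic markers. The signal is the allele ratio `AO/DP`: at a marker
where `k` of the strain's `p` chromosome copies carry the alternate
allele and sequencing is unbiased, `AO ~ Binomial(DP, k/p)`, so the
observed ratio concentrates on the *group center* `k/p`. Recombination,
LOH, and copy-number changes move a marker from one center to another;
scanning for runs of markers whose center changed locates the recombined
segments.

Centers are stored rounded to two decimals (0.33, not 1/3) so that the
conventional printed values and all interval arithmetic coincide
exactly. Ratios are classified to the unique center whose
`±θ`-interval contains them. The tolerance `θ = 0.04` is half the
distance between the closest centers that arise across ploidies, 0.25
(one of four) and 0.33 (one of three); the same overlap occurs
symmetrically at 0.67/0.75. A consequence of deriving `θ` this way is
that the 0.25 and 0.33 intervals *touch* at 0.29: a ratio exactly there
is equidistant from two explanations and is discarded as ambiguous, as
is any ratio outside every interval. Classification scores the ploidy's
own centers together with the adjacent ploidies' centers, because a
ratio such as 0.25 in a triploid is precisely the signature of a
chromosome gain and must not be silently absorbed into 0.33's
neighbourhood.

### Binomial noise and the role of marker abundance

At 80× coverage the standard deviation of a heterozygous diploid
marker's ratio is `sqrt(0.25/80) ≈ 0.056`, wider than `θ`. Roughly half
of honest heterozygous markers therefore fall outside their center's
interval and are set aside as ambiguous. This is by design: the method
trades per-marker completeness for per-marker confidence and relies on
marker abundance (yeast crosses provide tens of thousands), since a
recombined region only needs 4 classified variant markers to be called.
Ambiguous markers are removed from the track entirely — they count
neither as variant nor as invariant, so they cannot break up a run of
variant markers.

## Filters

Markers must have depth `DP ≥ 20`, site quality `QUAL > 200` (the
variant caller's Phred-scaled site score), and alternate observations
`AO ≥ 20` stated at a reference coverage of 80×. The AO cutoff is
rescaled proportionally to the sample's genome-wide mean depth
(`ceiling(20 × mean_dp / 80)`, floored at 5 reads), which keeps the
filter meaningful for libraries sequenced deeper or shallower than 80×.
All cutoffs are user-configurable (`filter_thresholds()`).

Two asymmetries in how filters are applied matter:

* A parental marker *absent* from the recombinant's calls is imputed a
  recombinant ratio of 0 — variant callers emit no record at
  homozygous-reference sites, so LOH toward the reference allele is
  only visible through this rule — but only when the recombinant's
  per-base depth at the position is at least `min_dp`. The AO filter is
  not applied to imputed calls (AO is 0 by construction).
* A recombinant record that is *present but fails* the quality filters
  drops the marker altogether. Treating it as absent would convert
  every QC failure into a spurious LOH call.

## From marker calls to regions

Center changes are interpreted through an exhaustive copy-number
transition table (`enumerate_transitions()`): from a heterozygous state
`(a of p)`, same-total transitions lead to LOH (ratio 0 or 1) or an
internal heterozygous change; transitions to totals `p − 1` / `p + 1`
(bounded by 4) are chromosome losses/gains and *require* the matching
depth-of-coverage change. For haploids the marker states are just 0 and
1 and the transitions are the two switches between them (the tetrad
convention: spores are genotyped against the hybrid parent's
heterozygous marker list, with centers {0, 1}).

The ploidy-change requirement is enforced at the marker level when the
track is built (`build_track()`): a candidate marker (say 0.5 → 0.33 in
a diploid) is kept as variant only if its 1-kb NDoC window carries the
corresponding gain/loss flag; otherwise it is discarded as ambiguous.
This gate is what keeps the false-positive rate at zero on event-free
polyploid simulations: binomial noise at 80× places roughly a fifth of
honest triploid markers within `θ` of an adjacent-ploidy center, but
their coverage is normal, so they never survive into the track. The
corroboration the data actually offer is exactly this coupling of ratio
change and coverage change. Regions are additionally annotated with
their mean NDoC (`attach_ndoc()`), which resolves any candidates left
unresolved at the marker level (e.g. when no window overlaps).

A **region** is a maximal run of variant markers where consecutive
variant markers are separated by at most `max_invariant_gap = 2`
invariant ones, trimmed to variant ends, and kept if it holds at least
`min_variant = 4` variant markers. "Adjacent" counts markers in the
filtered track, not base pairs — the method's resolution is marker
resolution, and breakpoint uncertainty extends to the flanking markers.
Several independently tolerated `≤ 2`-invariant gaps may occur within
one region; each variant-to-variant gap is judged on its own. A run of
invariant markers never extends a region's ends. The greedy left-to-right
segmentation is exhaustively checked against an independent
enumerate-and-filter oracle (`oracle_call_regions()`) on every binary
track up to length 16.

## Normalized depth of coverage

`NDoC = recombinant mean depth / parent mean depth`, computed in
windows of 1 kb tiled from position 1 (the step equals the window by
default; a smaller step gives truly sliding windows). Positions missing
from a coverage table count as depth 0 — the upstream per-locus coverage
tool emits every position, so absence means zero or masked coverage.
Windows with NDoC strictly above 1.5 are flagged as gains, strictly
below 0.5 as losses; values on the boundary are unflagged. No
library-size or GC correction is applied beyond the parent/recombinant
ratio itself, which cancels shared technical structure; NDoC is
invariant to any common rescaling of both tracks.

The diploid thresholds deserve a caveat: a 2n → 3n duplication has an
expected NDoC of exactly 1.5, *on* the gain boundary, so individual
windows flag with probability ≈ 1/2 and detection rests on the event
spanning many windows. A 3n → 4n gain (expected NDoC 4/3) or 3n → 2n
loss (2/3) never crosses the default thresholds at all — such events
are visible in the ratio track only through transitions that do not
need coverage corroboration (e.g. loss to a homozygous state, ratio 0).
Users studying higher-ploidy copy changes should tighten
`gain_threshold`/`loss_threshold` accordingly.

## The synthetic-data generator

`simulate_pair()` emulates the data this pipeline consumes: markers
placed uniformly at 2 per kb on three chromosomes of 200/150/100 kb,
`DP ~ Poisson(80 × local_copies / ploidy)`,
`AO ~ Binomial(DP, a / local_copies)`, constant high site quality (1000)
with an optional fraction of low-quality decoys, per-base Poisson
coverage tracks scaled by local copy number, and plantable events
(LOH to 0 or 1, heterozygous change, chromosome gain/loss, segmental
duplication/deletion). Recombinant markers whose alternate-copy count
reaches zero are omitted from the recombinant records but remain in its
coverage track, reproducing variant-caller silence. `make_tetrad()`
produces four haploid spores with reciprocal crossovers and optional
gene conversions (3:1 segregation).

The binomial/Poisson model reproduces the experimentally observed
spread of ratios around their centers, and is the minimal model that
does so; a real dataset additionally shows alignment artefacts,
mappability holes, GC bias and duplicated-region cross-mapping, none of
which are simulated. Passing the recovery suites therefore demonstrates
the correctness of the classification/segmentation machinery under the
stated noise model, not robustness to alignment pathology — the
quality filters are the only line of defence the pipeline offers
against the latter, which is why they are exposed as user-adjustable.

## Test and verification conditions

Problem sizes used by the test suite, chosen to exercise each guarantee
at meaningful scale: exhaustive region-caller equivalence on all binary
tracks of lengths 1–12, 14 and 16; planted-event recovery for each
event kind over ~50 markers (25-kb events, 60-kb chromosome, depth 80)
across 100 seeds per kind, requiring ≥ 95% recovery with breakpoints
exactly on the outermost recovered variant markers of the planted
interval; false-positive control on 100 event-free triploid simulations
of 450 kb, requiring zero called regions. Event kinds are planted at
the ploidy where they are canonically described: LOH and chromosome
gain/loss in diploids (the return-to-growth setting), heterozygous
changes (0.33 ↔ 0.67) in triploids, since a diploid has a single
interior center and admits no internal heterozygous transition.

## Design choices where the design was open

* **AO scaling.** The AO cutoff is stated at 80×; proportional
  rescaling to the sample's mean depth is the only reading that makes
  the reference-coverage qualifier operational, and the floor of 5
  prevents degenerate acceptance in very shallow libraries.
* **Multiallelic sites** are skipped by default (the ratio-group model
  assumes one alternate allele per site); optionally the allele with
  the largest AO is kept.
* **Same position, different alternate allele** counts as
  recombinant-absent: a new allele is a new mutation, not a ratio
  change of the tracked marker.
* **Candidate arbitration at marker level** (described above) rather
  than only per region: the cross-ploidy reading of a ratio is accepted
  only where the coverage actually changed.
* **Windows default to tumbling** (step = width): the per-window output
  files and one-dot-per-window plots imply non-overlapping windows; a
  configurable step preserves the sliding reading.
* **Unresolved candidates** are drawn black in plots, like other
  heterozygous-ratio changes; the NDoC dots carry the copy-number
  evidence.

## Known limitations

Ploidy must be supplied (1–4) and is not estimated from data; ploidies
above 4 are rejected. Breakpoints are reported at marker resolution
only. The NDoC thresholds are diploid-centric (see above). No phasing,
no de novo mutation calling, and no classification of crossover versus
gene-conversion events beyond the tetrad segregation pattern.
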