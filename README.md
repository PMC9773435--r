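# lohscan

Detection of recombined regions, loss of heterozygosity (LOH) and
chromosomal copy-number changes in yeast genomes of ploidy 1n–4n, from
allele ratios and read depth.

## The problem

Genotyping recombination in hybrid or polyploid yeast is hard with
pedigree- or reference-pair-specific tools: most existing methods assume a
specific merged reference and a diploid (or tetrad) design. `lohscan`
instead works from two ordinary single-strain variant-call files — one for
a parent (or reference strain), one for a potentially recombined strain —
and their per-base depth-of-coverage tables, and needs only the strain's
ploidy as biological prior. It serves geneticists mapping meiotic or
mitotic (return-to-growth) recombination, and screeners looking for
recombinant or aneuploid isolates among sequenced clones.

## The method

At a biallelic marker covered by `DP` reads of which `AO` support the
alternate allele, the **allele ratio** `AO/DP` estimates the fraction of
chromosome copies carrying the alternate allele. For ploidy *p*, a
genotype with *k* alternate copies places the ratio near the **group
center** *k/p*: haploids have centers {0, 1}, diploids {0, 0.5, 1},
triploids {0, 0.33, 0.67, 1}, tetraploids {0, 0.25, 0.5, 0.75, 1}.
Observed ratios are classified to the unique center within a tolerance
**θ = 0.04** — half the distance between the closest centers that occur
across ploidies (0.25 vs 0.33, or symmetrically 0.67 vs 0.75); ratios on
the boundary or outside every interval are discarded as ambiguous.

Markers first pass quality filters (depth ≥ 20, site quality > 200, and
AO ≥ 20 at 80× coverage, rescaled to the sample's mean depth). Each
parental marker is then paired with the recombinant strain's record at
the same site; a marker absent from the recombinant calls but well
covered there is read as ratio 0 (the caller is silent at
homozygous-reference sites). Center changes are interpreted through a
copy-number transition table: to 0 or 1 is an LOH (red/blue in the
plots), to another same-ploidy center a heterozygous recombination event
(black), and to an adjacent-ploidy center a chromosome gain/loss
candidate that must be corroborated by the **normalized depth of
coverage** (NDoC) — recombinant/parent mean depth in 1-kb windows, with
gains flagged above 1.5 and losses below 0.5.

A **recombined region** is a run of at least 4 ratio-variant markers, in
which any two variant markers may be separated by at most 2 invariant
ones; region breakpoints sit on the outermost variant markers.

## Worked example

Simulate a diploid with a 25-kb segmental duplication (2n → 3n locally),
then run the full pipeline:

```r
library(lohscan)

cfg <- simulation_config(
  seed = 23, ploidy = 2,
  chromosomes = genome_layout(c(chrA = 60000)),
  events = list(planted_event("segmental_dup", "chrA", 15001, 40000)))
sim <- simulate_pair(cfg)

res <- run_pipeline(sim$parent, sim$recomb, sim$parent_doc, sim$recomb_doc,
                    out_dir = "example_out", ploidy = 2)
res$regions
#>   chrom start   end n_variant n_invariant_inside event_type mean_ndoc
#> 1  chrA 16129 36783        10                  0 chrom_gain  1.499769
```

The duplicated interval shifts heterozygous markers from ratio 0.5 to
1/3 (or 2/3) — a triploid signature inside a diploid — and raises the
local NDoC to ≈ 1.5. The caller reports one region whose breakpoints
(16129–36783) are the outermost corroborated variant markers inside the
planted interval (15001–40000), holding 10 variant markers, and the
coverage cross-check resolves it to a chromosomal gain with mean NDoC
1.50. (At a mean NDoC sitting on the 1.5 flag boundary, only markers in
windows whose sampled coverage exceeds the threshold count as variant —
see the methods vignette.)
`example_out/` contains the parental/recombined alleles files, the
variant/invariant alleles files, the region-of-recombination file, the
`*_normalized1KB.txt` coverage file, the profile plot and a JSON run
manifest.

A shell front end wraps the same functions:

```sh
exec/lohscan run --parent P.vcf --sample R.vcf \
  --parent-doc P.doc --sample-doc R.doc --ploidy 2 --out outdir
exec/lohscan simulate --ploidy 3 --seed 42 --out fixtures/
```

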