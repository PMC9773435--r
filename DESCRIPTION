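Package: lohscan
Title: Recombination and Loss-of-Heterozygosity Detection in Polyploid
    Yeast Genomes from Allele Ratios and Read Depth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects recombined regions, loss-of-heterozygosity (LOH) and
    chromosomal copy-number changes between a parent (or reference) yeast
    strain and a potentially recombined strain of ploidy 1n-4n.  Allele
    ratios (alternate observations over depth, AO/DP) at shared polymorphic
    markers are classified against ploidy-dependent expected ratio groups
    with a fixed tolerance; runs of ratio-variant markers are segmented into
    recombined regions; normalized depth of coverage in 1-kb windows flags
    chromosomal gains and losses.  Includes a synthetic-data generator with
    plantable events (LOH, heterozygous recombination, chromosome gain/loss,
    segmental duplication), per-chromosome recombination-profile plotting,
    and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    grDevices,
    jsonlite,
    rlang,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
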