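Package: rohload
Title: Inbreeding and Mutational-Load Trajectories Through Population Bottlenecks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify the genomic consequences of severe population
    bottlenecks and conservation translocations from multi-sample variant
    callsets. Implements per-individual heterozygosity and windowed
    nucleotide diversity, sliding-window detection of runs of homozygosity
    with the genomic inbreeding coefficient F_ROH, conservation-score
    (GERP) weighted relative mutational load, total and realised load in
    coding regions, the R_xy derived-allele frequency-ratio statistic with
    a delete-one-chromosome jack-knife, and between-population variant
    sharing summaries. Ships a forward diploid Wright-Fisher simulator
    that generates annotated synthetic cohorts (pre-bottleneck samples
    plus two modern populations descended from a single breeding pair and
    separated by a translocation) for validation and power exploration,
    and a pipeline driver that runs the full analysis reproducibly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
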