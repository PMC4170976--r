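Package: conmsat
Title: Cross-Species Conserved Microsatellite Marker Discovery and Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers microsatellite (SSR) loci whose flanking regions are
    conserved across multiple genome assemblies, designs degenerate consensus
    primers for cross-species PCR, and evaluates genotyped markers with
    standard population-genetic statistics. Tandem repeats are detected by a
    scored wraparound self-alignment (period 1-5); conserved loci are found by
    a seeded, repeat-masked local-alignment search of candidate flanks against
    every genome, filtered on percent identity and uniqueness; per-genome
    flanks are multiply aligned and collapsed to an IUPAC degenerate consensus
    from which primer pairs are enumerated under melting-temperature, GC and
    ambiguity constraints. Marker evaluation includes Nei's unbiased expected
    heterozygosity, Monte-Carlo permutation tests for Hardy-Weinberg
    equilibrium and genotypic linkage disequilibrium, Bonferroni correction,
    and the per-species and pooled summaries used to characterise a marker
    panel. A synthetic-data module generates genome sets with planted
    conserved repeats and genotype samples under known inbreeding, providing
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    methods,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
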