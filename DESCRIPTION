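Package: mutbias
Title: Evolution of Mutation Rates and Biases on a Circular Bacterial Chromosome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of how genome-wide and local mutation rates and biases
    evolve in long-term bacterial evolution experiments, using annotated
    mutation tables from metagenomic time series. Provides class-resolved
    cumulative mutation dynamics, six-class point-mutation spectra over time,
    origin-of-replication-centered binned genomic distributions (the "wave"
    pattern), gene-orientation (replication-transcription conflict) bias tests
    against a coding-composition null, gene-set depletion tests in closed form
    and by randomization, a gene-set resampling test for selection on gene
    sets (STIMS style), and Poisson model comparison by AIC of uniform versus
    diversity-informed per-gene mutation rates. Includes a synthetic mutation
    table generator with known ground truth (mutator-genotype timelines,
    genotype-specific spectra, a symmetric rate wave over the origin, and
    orientation bias) for calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
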