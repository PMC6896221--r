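Package: cubevol
Title: Codon Usage Bias and the Strength of Selection on Synonymous Codons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the evolution of codon usage bias in
    transcriptome-scale coding sequence sets. Computes per-gene codon usage
    indices (effective number of codons, frequency of optimal codons, GC and
    GC3s content), identifies preferred and unpreferred codons by
    correspondence analysis of relative synonymous codon usage followed by
    per-codon chi-squared contingency tests, estimates the population-scaled
    selection coefficient S for optimal codon usage under
    mutation-selection-drift equilibrium with a gene-set resampling
    significance test, counts polarized synonymous substitutions on
    ancestor-descendant branches, and provides Nei-Gojobori synonymous
    divergence, silent-site diversity, effective population size and
    divergence time calculators. A synthetic-data generator draws gene sets
    and branches from the equilibrium model so that every stage of the
    pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    vegan
VignetteBuilder: knitr
Config/testthat/edition: 3
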