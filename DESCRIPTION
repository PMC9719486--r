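Package: hairDNA
Title: Simulation, Authentication and Population Affinity Analysis for
    Degraded Single-Stranded Ancient DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for working with heavily degraded ancient DNA sequenced
    from single-stranded libraries, as retrieved from substrates such as
    mummified hair. Provides a generative simulator for ultra-short,
    deamination-damaged DNA fragments with modern-human contaminants and
    environmental background; a compact seed-and-extend read mapper with
    the standard length, base-quality and mapping-quality filters and
    duplicate removal; position-specific C-to-T damage profiling including
    nuclear versus mitochondrial comparisons; a two-component per-read
    likelihood mixture for estimating the modern contaminant fraction from
    base substitution patterns; read-length cutoff exploration via spurious
    alignment simulation; pseudo-haploid genotype calling with EIGENSTRAT
    input/output; and population-affinity statistics (outgroup f3, f4
    cladality tests, least-squares PCA projection) with weighted block
    jackknife standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
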