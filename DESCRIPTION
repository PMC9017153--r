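Package: rbnskit
Title: Quantitative Analysis and Simulation of RNA Bind-n-Seq Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of RNA Bind-n-Seq (RBNS)
    experiments measuring the binding of miRNA-loaded Argonaute (miRISC)
    to a random-sequence RNA pool. Implements quality filtering of RBNS
    sequencing reads, k-mer enrichment statistics with Z-score
    significance, iterative de novo discovery of miRNA binding sites with
    shadow-motif elimination, assignment of reads to site categories,
    maximum-likelihood estimation of absolute dissociation constants
    (K_D), active-protein stock concentration and background from
    site-by-sample read counts, maximum-likelihood estimation of relative
    association and dissociation rate constants (k_on, k_off) from
    time-series counts, an RBNS simulator for validating the estimators,
    and bench-planning calculators (active-protein titration fits,
    equilibration-time estimates, pool copy-number arithmetic).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    S4Vectors,
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
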