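Package: hypoxeeg
Title: Resting-State EEG Spectral, Aperiodic and Connectivity Analysis for
    Two-Condition Hypoxia Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of multichannel resting-state EEG for
    paired two-condition designs such as sea level versus acute high-altitude
    hypoxia. Provides a synthetic-data generator with known ground truth
    (aperiodic 1/f exponent, band-limited oscillations, phase-lagged coupling,
    age effects), deterministic preprocessing (zero-phase FIR and Bessel band
    filtering, resampling, average reference, epoching), Welch spectral
    estimation with relative band power and aperiodic/periodic spectral
    parameterization, multitaper weighted phase lag index (wPLI) functional
    connectivity, proportional-threshold graph topology (efficiency,
    transitivity, clustering, degree) with area-under-curve summaries, and a
    nonparametric statistics layer (paired sign-flip permutation tests,
    Cohen's D, Pearson age correlations, age residualization,
    Benjamini-Hochberg correction), orchestrated by a reproducible study
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    dplyr,
    igraph,
    jsonlite,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
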