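Package: napamyloid
Title: Simulation and Analysis of Compound Nerve Action Potentials Under
    Amyloid-Beta Exposure
Version: 0.1.0
Authors@R:
    person("Nerve", "Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying drug effects on compound nerve action
    potentials (NAPs) recorded from isolated peripheral nerve. Provides a
    seeded synthetic-experiment generator (axon-population recruitment,
    refractoriness, Wallerian amplitude decline, non-monotonic dose
    response), automated extraction of twelve waveform descriptors with
    baseline normalization, four-parameter template registration of
    waveforms (amplitude scale, time stretch, latency shift, offset),
    and the downstream statistical battery: endpoint ANOVA and
    Kruskal-Wallis tests across concentration groups, quadratic dose
    regression, repeated-measures ANOVA over stimulus factors,
    Benjamini-Hochberg FDR screening of Spearman rank correlations,
    significance-count tables with chi-squared tests, and pointwise
    correlation maps along the waveform.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
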