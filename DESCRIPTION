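Package: nemaquant
Title: Quantitative PCR Monitoring of Soil Nematode Assemblages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for DNA sequence signature-based monitoring of soil
    nematode communities with taxon-specific quantitative PCR assays on the
    small-subunit (SSU, 18S) ribosomal RNA gene. Covers the full workflow:
    validating an aligned SSU rDNA reference set against a taxonomy and a
    reference phylogeny (including monophyly checks that decide whether an
    assay is defined at family or genus rank), discovery of taxon-specific
    signature motifs and in-silico primer-pair design at a uniform annealing
    temperature with nearest-neighbor melting temperature calculations,
    calibration of the linear relationship between threshold cycle (Ct) and
    log10 nematode counts from hand-picked dilution series, conversion of
    environmental Ct panels into per-taxon densities (individuals per 100 ml
    soil) with internal-standard extraction correction and feeding-guild
    aggregation, coverage diagnostics against microscopic counts, and the
    seasonal-survey statistics toolbox (moving averages, Mann-Whitney U site
    comparisons, Welch t on log totals, simple and partial Mantel tests).
    Seeded synthetic-data generators reproduce the statistical structure of
    a two-site seasonal survey so the whole pipeline can be exercised and
    validated without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
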