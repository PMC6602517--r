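Package: mktools
Title: McDonald-Kreitman Tests of Adaptive Molecular Evolution
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation of the rate of adaptive molecular evolution from
    polymorphism and divergence data with the McDonald-Kreitman (MK) framework.
    Implements four MK-derived estimators of the fraction of adaptive
    nonsynonymous substitutions (alpha): the standard MK test, the
    Fay-Wyckoff-Wu low-frequency correction, the extended MK test with
    selection-regime fractions (neutral, weakly deleterious, strongly
    deleterious), and the asymptotic MK test with exponential extrapolation of
    alpha across the derived allele frequency spectrum. Builds site frequency
    spectra and divergence counts directly from aligned coding sequences with
    an outgroup (site classification, depth subsampling, outgroup
    polarization, Nei-Gojobori site counting), and supports multi-gene
    cohorts: concatenation, Cochran-Mantel-Haenszel and Breslow-Day-Tarone
    heterogeneity tests, bootstrap sampling distributions of alpha, and
    group-versus-group comparisons. Includes seeded simulators of genes under
    parameterized selection regimes for calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
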