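Package: ptnmr
Title: Polarization-Transfer Solid-State NMR Modelling and Interpretation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward modelling and interpretation of polarization-transfer
    natural-abundance 13C solid-state NMR (PT ssNMR) under magic-angle
    spinning. Computes DP, CP, and refocused-INEPT signal intensities from a
    two-step motional model (C-H bond order parameter, fast and slow
    correlation times) via dipolar spectral densities and the relaxation and
    transfer parameters T2(H/C), T1rho(H), and TCH; renders the correlation
    time by order parameter efficiency map used to read dynamic regimes.
    Ships a curated 13C chemical-shift assignment library for stratum corneum
    components (lipids, cholesterol, keratin core and terminal domains), an
    FID-to-spectrum processing pipeline (apodization, zero-filling, Fourier
    transformation, automatic phasing, baseline correction, glycine
    referencing), a synthetic-spectrum generator emulating stratum corneum
    hydration and temperature series, and a classifier that turns DP/CP/INEPT
    peak triplets into per-segment dynamic-state calls and series-level
    reports such as humidity-transition detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
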