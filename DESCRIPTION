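Package: rnathermo
Title: Base-Pair Resolution Thermodynamics of RNA Thermometers from Imino
    Proton Exchange
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for extracting per-base-pair opening thermodynamics of RNA
    hairpins (such as bacterial RNA thermometers) from NMR-detected imino
    proton solvent exchange in the EX2 regime. Fits selective
    inversion-recovery profiles to obtain exchange rates, globally fits
    temperature and catalyst-concentration series of exchange rates to an
    opening-equilibrium/transfer-rate model yielding dissociation enthalpies
    and entropies per base pair, propagates errors by Monte Carlo simulation
    with confidence ellipses, analyses enthalpy-entropy compensation
    (compensation temperature, offset, and validity against the statistical
    compensation artifact), and fits two-state CD melting curves with linear
    state baselines. Includes a synthetic-data generator emulating the full
    experimental design so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
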