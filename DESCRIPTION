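Package: gshkin
Title: Stable-Isotope Tracer Kinetics of Glutathione Synthesis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates glutathione (GSH) synthesis rates from primed
    constant-infusion [1-13C]cysteine tracer experiments: plasma cysteine
    flux by steady-state isotope dilution with a regression-based plateau
    check, whole-blood GSH fractional and absolute synthesis rates from the
    linear rise of product enrichment, and organ GSH synthesis rates from
    single-time-point single-exponential kinetics. Includes selected-ion
    monitoring enrichment processing with limit-of-quantitation flagging,
    internal-standard isotope-dilution quantification, diet precursor-intake
    arithmetic, group summaries with a normality-screened two-sample test,
    and a seeded synthetic-cohort simulator of a sham-burn/burn experiment
    so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
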