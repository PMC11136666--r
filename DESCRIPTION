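Package: fluxtrace
Title: Stable-Isotope Tracer Flux Analysis and Indirect Calorimetry for
    Mouse Infusion Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes whole-body metabolite kinetics from primed
    constant-infusion stable-isotope tracer experiments in mice:
    natural-abundance correction of GC-MS mass-isotopomer distributions,
    conversion of breath-CO2 isotope-ratio measurements to atom percent
    excess, steady-state dilution rates of appearance (lipolysis via
    glycerol, palmitate turnover, CO2 production via bicarbonate), a
    bicarbonate-anchored palmitate oxidation rate in which the 13CO2
    recovery factor cancels, and tissue-level fractional contribution of
    palmitate to the TCA cycle from citrate isotopomers. Also derives
    respiratory exchange ratio, energy expenditure and photoperiod
    summaries from metabolic-chamber traces, and ships a seeded
    synthetic-study generator (one-pool tracer model, multinomial
    natural-abundance structure, circadian chamber traces) so every
    pipeline stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
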