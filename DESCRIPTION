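Package: mycorisk
Title: Carcinogenic and Non-Carcinogenic Dietary Risk Assessment of
    Elemental Impurities in Edible Mushrooms
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Deterministic and probabilistic health-risk characterization of
    toxic elemental impurities (cadmium, lead, arsenic, mercury, and any
    user-supplied element) in edible mushrooms and other single-commodity
    foods.  Computes estimated daily intake (EDI), target hazard quotients
    (THQ) and the hazard index (HI) for non-carcinogenic risk, and cancer
    slope factor based carcinogenic risk (CR) with its total (TCR), following
    the US EPA ingestion-exposure model.  A Monte Carlo engine propagates
    declared uncertainty distributions (point, uniform, normal with
    truncation, lognormal) for concentrations and exposure factors and
    summarizes risk at the mean, median, and 95th percentile with exceedance
    probabilities.  Includes a synthetic concentration-table generator with
    lognormal replicate noise and non-detect handling so the full pipeline
    can be exercised against known ground truth, plus small helpers for
    percent-inhibition dose-response series and IC50 interpolation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
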