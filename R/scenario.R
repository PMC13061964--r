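#' Exposure scenarios for dietary risk assessment
#'
#' An exposure scenario collects the ingestion-model constants: intake rate
#' IR (kg dry weight per person per day), exposure frequency EF (days/year),
#' exposure duration ED (years), body weight BW (kg), and the averaging
#' times AT (days). Non-carcinogenic risk averages dose over the exposure
#' period itself (AT = EF x ED), while carcinogenic risk averages over a
#' 70-year lifetime (AT = 25,550 days) regardless of age group, because
#' cancer risk is cumulative.
#'
#' `default_scenario()` returns the standard child (ED 6 y, BW 25.6 kg) and
#' adult (ED 26 y, BW 70 kg) scenarios with IR 6.6e-3 kg/day and EF 350
#' days/year.
#'
#' @param group `"child"` or `"adult"` for `default_scenario()`; any label
#'   for a custom scenario.
#' @return An `exposure_scenario` object (a named list).
#' @examples
#' default_scenario("child")$at_noncarc # 2100 days
#' default_scenario("adult")$at_noncarc # 9100 days
#' @export
default_scenario <- function(group = c("adult", "child")) {
  if (length(group) != 1 || !group %in% c("adult", "child")) {
    stop("unknown scenario group: ",
         paste(group, collapse = ", "),
         " (defaults exist for \"adult\" and \"child\")", call. = FALSE)
  }
  defaults <- list(
    child = list(ir = 6.6e-3, ef = 350, ed = 6, bw = 25.6),
    adult = list(ir = 6.6e-3, ef = 350, ed = 26, bw = 70)
  )
  p <- defaults[[group]]
  exposure_scenario(group = group, ir = p$ir, ef = p$ef, ed = p$ed, bw = p$bw)
}

#' @param ir Intake rate, kg per person per day.
#' @param ef Exposure frequency, days per year.
#' @param ed Exposure duration, years.
#' @param bw Body weight, kg.
#' @param at_noncarc Averaging time for non-carcinogenic risk, days;
#'   defaults to `ef * ed`.
#' @param at_carc Averaging time for carcinogenic risk, days; defaults to
#'   the 70-year lifetime, 25,550 days.
#' @rdname default_scenario
#' @export
exposure_scenario <- function(group = "custom", ir, ef, ed, bw,
                              at_noncarc = ef * ed, at_carc = 25550) {
  vals <- c(ir = ir, ef = ef, ed = ed, bw = bw,
            at_noncarc = at_noncarc, at_carc = at_carc)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    bad <- names(vals)[!is.finite(vals) | vals <= 0]
    stop("scenario field(s) must be strictly positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(group = as.character(group), ir = ir, ef = ef, ed = ed, bw = bw,
         at_noncarc = at_noncarc, at_carc = at_carc),
    class = "exposure_scenario"
  )
}

#' @export
print.exposure_scenario <- function(x, ...) {
  cat(sprintf(
    paste0("<exposure_scenario: %s>\n",
           "  IR %.4g kg/day, EF %g d/y, ED %g y, BW %.4g kg\n",
           "  AT %g d (non-carcinogenic), %g d (carcinogenic)\n"),
    x$group, x$ir, x$ef, x$ed, x$bw, x$at_noncarc, x$at_carc))
  invisible(x)
}

#' Risk classification thresholds
#'
#' Hazard-index bands: HI <= 1 indicates no significant non-carcinogenic
#' risk, 1 < HI < 10 a specific risk for the exposed group, and HI >= 10 a
#' significant risk. Carcinogenic risk bands: CR (or TCR) <= 1e-6 is
#' considered no health hazard, values between 1e-6 and 1e-4 an acceptable
#' (tolerable) risk, and >= 1e-4 unacceptable and potentially carcinogenic.
#'
#' @param hi_none,hi_significant HI band edges (default 1 and 10).
#' @param cr_none,cr_unacceptable CR band edges (default 1e-6 and 1e-4).
#' @return A `risk_thresholds` object.
#' @export
risk_thresholds <- function(hi_none = 1.0, hi_significant = 10.0,
                            cr_none = 1e-6, cr_unacceptable = 1e-4) {
  if (!(hi_none < hi_significant)) {
    stop("hi_none must be < hi_significant", call. = FALSE)
  }
  if (!(cr_none < cr_unacceptable)) {
    stop("cr_none must be < cr_unacceptable", call. = FALSE)
  }
  structure(list(hi_none = hi_none, hi_significant = hi_significant,
                 cr_none = cr_none, cr_unacceptable = cr_unacceptable),
            class = "risk_thresholds")
}

#' Read scenario and threshold overrides from a YAML config
#'
#' The config is nested by group, e.g.
#' ```yaml
#' scenarios:
#'   adult: {ir: 6.6e-3, ef: 350, ed: 26, bw: 70}
#' thresholds: {hi_none: 1, hi_significant: 10}
#' ```
#' Fields left out fall back to the defaults for that group (or the default
#' thresholds).
#'
#' @param path Path to a YAML file.
#' @return A list with elements `scenarios` (named list of
#'   [exposure_scenario()]) and `thresholds` ([risk_thresholds()]).
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  scenarios <- list()
  for (group in names(cfg$scenarios)) {
    ov <- cfg$scenarios[[group]]
    base <- if (group %in% c("adult", "child")) {
      unclass(default_scenario(group))
    } else {
      list(group = group)
    }
    merged <- utils::modifyList(base, ov)
    scenarios[[group]] <- exposure_scenario(
      group = group, ir = merged$ir, ef = merged$ef, ed = merged$ed,
      bw = merged$bw,
      at_noncarc = if (is.null(ov$at_noncarc)) merged$ef * merged$ed
                   else ov$at_noncarc,
      at_carc = if (is.null(ov$at_carc)) 25550 else ov$at_carc
    )
  }
  thresholds <- do.call(
    risk_thresholds,
    if (is.null(cfg$thresholds)) list() else cfg$thresholds
  )
  list(scenarios = scenarios, thresholds = thresholds)
}
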