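#' Estimated daily intake (EDI)
#'
#' Computes the estimated daily intake of a contaminant,
#' \deqn{EDI = (MC \times IR \times ED \times EF) / (BW \times AT)}
#' in mg per kg body weight per day, where MC is the concentration in the
#' food (mg/kg dry weight) and the remaining constants come from the
#' exposure scenario. `mode` selects the averaging time: `"noncarc"` uses
#' AT = EF x ED (dose averaged over the exposure period), `"carc"` uses the
#' lifetime averaging time. For scenarios built by [default_scenario()] the
#' non-carcinogenic EDI reduces algebraically to `mc * ir / bw`.
#'
#' @param mc Concentration(s), mg per kg dry weight; non-negative.
#' @param scenario An [exposure_scenario()].
#' @param mode `"noncarc"` or `"carc"`.
#' @return EDI in mg/kg/day, same length as `mc`.
#' @examples
#' edi(1.633, default_scenario("adult"), "noncarc") # 1.539e-4
#' @export
edi <- function(mc, scenario, mode = c("noncarc", "carc")) {
  mode <- match.arg(mode)
  if (!inherits(scenario, "exposure_scenario")) {
    stop("scenario must be an exposure_scenario", call. = FALSE)
  }
  if (any(!is.na(mc) & mc < 0)) {
    stop("concentration must be non-negative", call. = FALSE)
  }
  at <- if (mode == "noncarc") scenario$at_noncarc else scenario$at_carc
  (mc * scenario$ir * scenario$ed * scenario$ef) / (scenario$bw * at)
}

#' Target hazard quotient (THQ)
#'
#' Ratio of the non-carcinogenic estimated daily intake to the element's
#' oral reference dose; THQ = 1 means intake exactly at the RfD.
#'
#' @param edi_noncarc Non-carcinogenic EDI, mg/kg/day.
#' @param rfd Oral reference dose, mg/kg/day; strictly positive.
#' @return Dimensionless hazard quotient(s).
#' @export
thq <- function(edi_noncarc, rfd) {
  if (any(!is.finite(rfd)) || any(rfd <= 0)) {
    stop("rfd must be strictly positive", call. = FALSE)
  }
  edi_noncarc / rfd
}

#' Carcinogenic risk (CR) for one element
#'
#' Incremental lifetime cancer risk: the lifetime-averaged daily intake
#' multiplied by the element's oral cancer slope factor.
#'
#' @param edi_carc Carcinogenic (lifetime-averaged) EDI, mg/kg/day.
#' @param csf Cancer slope factor, (mg/kg/day)^-1; non-negative.
#' @return Dimensionless risk(s).
#' @export
cancer_risk <- function(edi_carc, csf) {
  if (any(!is.finite(csf)) || any(csf < 0)) {
    stop("csf must be non-negative", call. = FALSE)
  }
  edi_carc * csf
}

#' Hazard index and total carcinogenic risk
#'
#' `hazard_index()` sums target hazard quotients over the elements detected
#' in one food item; `total_cancer_risk()` does the same for per-element
#' carcinogenic risks. Non-detect elements carry `NA` and contribute
#' nothing; an empty set sums to zero.
#'
#' @param thqs,crs Numeric vectors of per-element THQ / CR values
#'   (`NA` = not calculated).
#' @return A single dimensionless sum.
#' @export
hazard_index <- function(thqs) {
  sum(thqs, na.rm = TRUE)
}

#' @rdname hazard_index
#' @export
total_cancer_risk <- function(crs) {
  sum(crs, na.rm = TRUE)
}

#' Classify hazard-index and carcinogenic-risk values into bands
#'
#' `classify_hi()`: HI <= 1 is `no_risk`, 1 < HI < 10 `specific_risk`,
#' HI >= 10 `significant_risk`. `classify_cr()`: CR <= 1e-6 is `no_hazard`,
#' 1e-6 < CR < 1e-4 `acceptable`, CR >= 1e-4 `unacceptable`. Ties fall in
#' the band the printed inequality assigns, so every non-negative value
#' maps to exactly one band.
#'
#' @param hi,cr Non-negative numeric vectors.
#' @param thresholds A [risk_thresholds()] object.
#' @return A factor with the band labels above.
#' @examples
#' classify_hi(c(0.421, 4.473))
#' classify_cr(c(8.7e-7, 4.7e-5, 2.1e-3))
#' @export
classify_hi <- function(hi, thresholds = risk_thresholds()) {
  if (any(!is.na(hi) & hi < 0)) {
    stop("hi must be non-negative", call. = FALSE)
  }
  lv <- c("no_risk", "specific_risk", "significant_risk")
  out <- ifelse(is.na(hi), NA_character_,
         ifelse(hi <= thresholds$hi_none, "no_risk",
         ifelse(hi < thresholds$hi_significant, "specific_risk",
                "significant_risk")))
  factor(out, levels = lv)
}

#' @rdname classify_hi
#' @export
classify_cr <- function(cr, thresholds = risk_thresholds()) {
  if (any(!is.na(cr) & cr < 0)) {
    stop("cr must be non-negative", call. = FALSE)
  }
  lv <- c("no_hazard", "acceptable", "unacceptable")
  out <- ifelse(is.na(cr), NA_character_,
         ifelse(cr <= thresholds$cr_none, "no_hazard",
         ifelse(cr < thresholds$cr_unacceptable, "acceptable",
                "unacceptable")))
  factor(out, levels = lv)
}

#' Deterministic risk assessment of a concentration table
#'
#' Runs the full deterministic chain — EDI (both averaging modes), THQ, CR,
#' then HI and TCR with their risk bands — for every species in the table
#' and every requested exposure group. Non-detect elements are reported as
#' "not calculated" (`calculated = FALSE`, numeric fields `NA`) and excluded
#' from the HI and TCR sums.
#'
#' @param concentrations A [concentration_table][validate_concentration_table]
#'   (or coercible data frame).
#' @param groups Character vector of default groups (`"adult"`, `"child"`);
#'   ignored when `scenarios` is given.
#' @param toxicity Toxicity reference table; every detected element must
#'   have an entry.
#' @param scenarios Optional named list of [exposure_scenario()] objects
#'   replacing the defaults.
#' @param thresholds A [risk_thresholds()] object used for the band labels.
#' @return A `risk_assessment` tibble in long format with one row per
#'   species x group x element: `species`, `group`, `element`, `calculated`,
#'   `edi_noncarc`, `edi_carc`, `thq`, `cr`, plus the species-level `hi`,
#'   `tcr`, `hi_category`, `tcr_category` repeated on each element row.
#' @examples
#' res <- assess_risk(mushroom_concentrations())
#' subset(res, species == "Tricholoma scalpturatum" & group == "adult")
#' @export
assess_risk <- function(concentrations,
                        groups = c("adult", "child"),
                        toxicity = default_toxicity(),
                        scenarios = NULL,
                        thresholds = risk_thresholds()) {
  concentrations <- validate_concentration_table(concentrations)
  toxicity <- validate_toxicity(toxicity)
  if (is.null(scenarios)) {
    scenarios <- lapply(groups, default_scenario)
    names(scenarios) <- groups
  }
  stopifnot(length(scenarios) > 0)

  detected_elements <- unique(concentrations$element[concentrations$detected])
  missing_tox <- setdiff(detected_elements, toxicity$element)
  if (length(missing_tox) > 0) {
    stop("no toxicity reference (RfD/CSF) for element(s): ",
         paste(missing_tox, collapse = ", "), call. = FALSE)
  }

  species_order <- unique(concentrations$species)
  rows <- list()
  for (group in names(scenarios)) {
    scen <- scenarios[[group]]
    for (sp in species_order) {
      rec <- concentrations[concentrations$species == sp, ]
      tox_idx <- match(rec$element, toxicity$element)
      edi_nc <- ifelse(rec$detected,
                       edi(rec$mean_conc, scen, "noncarc"), NA_real_)
      edi_c <- ifelse(rec$detected,
                      edi(rec$mean_conc, scen, "carc"), NA_real_)
      thq_v <- ifelse(rec$detected, edi_nc / toxicity$rfd[tox_idx], NA_real_)
      cr_v <- ifelse(rec$detected, edi_c * toxicity$csf[tox_idx], NA_real_)
      hi <- hazard_index(thq_v)
      tcr <- total_cancer_risk(cr_v)
      rows[[length(rows) + 1]] <- tibble::tibble(
        species = sp,
        group = group,
        element = rec$element,
        calculated = rec$detected,
        edi_noncarc = edi_nc,
        edi_carc = edi_c,
        thq = thq_v,
        cr = cr_v,
        hi = hi,
        tcr = tcr,
        hi_category = as.character(classify_hi(hi, thresholds)),
        tcr_category = as.character(classify_cr(tcr, thresholds))
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("risk_assessment", class(out))
  attr(out, "thresholds") <- thresholds
  out
}

#' Write a risk assessment to CSV
#'
#' Long-format CSV with columns `species,group,element,edi_noncarc,
#' edi_carc,thq,cr,hi,tcr,hi_category,tcr_category`; cells for non-detect
#' elements ("NC" in printed tables) are left empty.
#'
#' @param x A `risk_assessment` from [assess_risk()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_risk_csv <- function(x, path) {
  cols <- c("species", "group", "element", "edi_noncarc", "edi_carc",
            "thq", "cr", "hi", "tcr", "hi_category", "tcr_category")
  utils::write.csv(as.data.frame(x)[, cols], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.risk_assessment <- function(x, ...) {
  cat(sprintf(
    "<risk_assessment> %d species x %d group(s); %d element row(s), %d NC\n",
    length(unique(x$species)), length(unique(x$group)),
    nrow(x), sum(!x$calculated)))
  NextMethod()
  invisible(x)
}
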