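#' Percent inhibition of a dose-response assay
#'
#' \deqn{\%\,inhibition = (A_{control} - A_{sample}) / A_{control}
#'       \times 100}
#' where the absorbances come from, e.g., a DPPH radical-scavenging or
#' lipid-peroxidation assay. Scale-invariant in the absorbances: scaling
#' both by the same positive factor leaves the result unchanged.
#'
#' @param a_control Control absorbance(s); strictly positive.
#' @param a_sample Sample absorbance(s).
#' @return Percent inhibition, same length as the inputs.
#' @examples
#' percent_inhibition(1.0, 0.5) # 50
#' @export
percent_inhibition <- function(a_control, a_sample) {
  if (any(!is.finite(a_control)) || any(a_control <= 0)) {
    stop("control absorbance must be strictly positive", call. = FALSE)
  }
  (a_control - a_sample) / a_control * 100
}

#' IC50 from a dose-inhibition series
#'
#' Estimates the half-maximal inhibitory concentration by linear
#' interpolation between the two concentrations bracketing 50% inhibition,
#' on a log-concentration axis (dose-response curves are conventionally
#' near-linear in log dose around the midpoint). A point exactly at 50%
#' is returned as-is. Sigmoid (4-parameter logistic) fitting is
#' deliberately out of scope: bracketing interpolation is assumption-free
#' and deterministic.
#'
#' @param concentration Tested concentrations, mg/mL; strictly positive
#'   and distinct.
#' @param inhibition Percent inhibition at each concentration.
#' @return The interpolated IC50, mg/mL; it always lies within the
#'   bracketing pair.
#' @examples
#' ic50(c(10, 20), c(40, 60)) # 14.142: log-scale midpoint
#' @export
ic50 <- function(concentration, inhibition) {
  if (length(concentration) != length(inhibition) ||
      length(concentration) < 2) {
    stop("need >= 2 (concentration, inhibition) points", call. = FALSE)
  }
  if (any(!is.finite(concentration)) || any(concentration <= 0)) {
    stop("concentrations must be strictly positive", call. = FALSE)
  }
  if (anyDuplicated(concentration)) {
    stop("concentrations must be distinct within a series", call. = FALSE)
  }
  ord <- order(concentration)
  conc <- concentration[ord]
  inh <- inhibition[ord]

  exact <- which(inh == 50)
  if (length(exact) > 0) return(conc[exact[1]])

  crosses <- which((inh[-length(inh)] - 50) * (inh[-1] - 50) < 0)
  if (length(crosses) == 0) {
    stop("50% not crossed in range", call. = FALSE)
  }
  i <- crosses[1]
  f <- (50 - inh[i]) / (inh[i + 1] - inh[i])
  exp(log(conc[i]) + f * (log(conc[i + 1]) - log(conc[i])))
}

#' Read a dose-response CSV and tabulate inhibition with IC50
#'
#' Expects columns `concentration,a_control,a_sample` (one series per
#' file). Returns the per-point percent inhibition and the interpolated
#' IC50.
#'
#' @param path Path to a CSV file.
#' @return A list: `table` (tibble with an `inhibition` column) and `ic50`
#'   (mg/mL, or `NA` when 50% is not crossed in range).
#' @export
read_dose_response_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("concentration", "a_control", "a_sample")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("dose-response CSV lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  inh <- percent_inhibition(raw$a_control, raw$a_sample)
  est <- tryCatch(ic50(raw$concentration, inh), error = function(e) NA_real_)
  list(table = tibble::tibble(concentration = raw$concentration,
                              a_control = raw$a_control,
                              a_sample = raw$a_sample,
                              inhibition = inh),
       ic50 = est)
}
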