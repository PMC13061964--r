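#' Toxicity reference values (oral RfD and cancer slope factor)
#'
#' `default_toxicity()` returns the US EPA oral reference doses (RfD,
#' mg/kg body weight/day) and oral cancer slope factors (CSF,
#' (mg/kg/day)^-1) for the four Class-I elemental impurities. A THQ of 1
#' corresponds to an intake exactly at the RfD; CR is the incremental
#' lifetime cancer probability per unit lifetime-averaged daily dose.
#'
#' @return A tibble with columns `element`, `rfd`, `csf`.
#' @examples
#' default_toxicity()
#' @export
default_toxicity <- function() {
  validate_toxicity(tibble::tibble(
    element = c("As", "Cd", "Hg", "Pb"),
    rfd = c(3e-4, 1e-3, 3e-4, 3.5e-3),
    csf = c(1.5, 6.3, 6.177, 0.0085)
  ))
}

#' @param tox A data frame with columns `element`, `rfd` (> 0), `csf`
#'   (>= 0); element symbols are normalized like concentration tables.
#' @rdname default_toxicity
#' @export
validate_toxicity <- function(tox) {
  tox <- as.data.frame(tox, stringsAsFactors = FALSE)
  required <- c("element", "rfd", "csf")
  missing_cols <- setdiff(required, names(tox))
  if (length(missing_cols) > 0) {
    stop("toxicity table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tox$element <- normalize_element(tox$element)
  tox$rfd <- as.numeric(tox$rfd)
  tox$csf <- as.numeric(tox$csf)
  if (anyDuplicated(tox$element)) {
    stop("duplicate element(s) in toxicity table", call. = FALSE)
  }
  if (any(!is.finite(tox$rfd)) || any(tox$rfd <= 0)) {
    stop("rfd must be strictly positive", call. = FALSE)
  }
  if (any(!is.finite(tox$csf)) || any(tox$csf < 0)) {
    stop("csf must be non-negative", call. = FALSE)
  }
  tibble::as_tibble(tox[, required])
}

#' Read a toxicity reference table from CSV
#'
#' Expected columns: `element,rfd_mg_per_kg_day,csf_per_mg_per_kg_day`.
#'
#' @param path Path to a CSV file.
#' @return A validated toxicity tibble (see [default_toxicity()]).
#' @export
read_toxicity_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("element", "rfd_mg_per_kg_day", "csf_per_mg_per_kg_day")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("toxicity CSV lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  validate_toxicity(data.frame(
    element = raw$element,
    rfd = raw$rfd_mg_per_kg_day,
    csf = raw$csf_per_mg_per_kg_day,
    stringsAsFactors = FALSE
  ))
}
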