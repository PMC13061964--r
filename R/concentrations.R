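#' Validate a table of element concentration measurements
#'
#' A concentration table holds one row per (species, element) pair with the
#' arithmetic mean and standard deviation of the measured concentration in
#' mg per kg dry weight. Non-detects (element below the detection limit) are
#' kept as rows with `detected = FALSE` and no numeric values, so downstream
#' stages can distinguish "not quantifiable" from "measured zero": risk
#' tables report such cells as NC (not calculated) rather than as zeros.
#'
#' Element symbols are normalized case-insensitively to the canonical forms
#' `Cd`, `Pb`, `As`, `Hg`; unrecognized symbols are kept as supplied (the
#' risk model is element-agnostic provided a toxicity reference exists).
#'
#' @param records A data frame with columns `species`, `element`,
#'   `mean_conc` (mg/kg dw), `sd_conc` (mg/kg dw), and optionally `detected`
#'   (logical; inferred as `!is.na(mean_conc)` when absent) and
#'   `n_replicates`.
#' @return A `concentration_table`, a tibble with the columns above,
#'   validated and normalized.
#' @examples
#' validate_concentration_table(data.frame(
#'   species = "Boletus edulis", element = c("cd", "pb"),
#'   mean_conc = c(0.5, 1.2), sd_conc = c(0.1, 0.4)
#' ))
#' @export
validate_concentration_table <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  required <- c("species", "element", "mean_conc", "sd_conc")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("concentration table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"detected" %in% names(records)) {
    records$detected <- !is.na(records$mean_conc)
  }
  if (!"n_replicates" %in% names(records)) {
    records$n_replicates <- rep(NA_integer_, nrow(records))
  }
  records <- records[, c(required, "detected", "n_replicates")]

  if (nrow(records) == 0) {
    out <- tibble::as_tibble(records)
    class(out) <- c("concentration_table", class(out))
    return(out)
  }

  records$species <- as.character(records$species)
  records$element <- normalize_element(records$element)
  records$detected <- as.logical(records$detected)
  records$mean_conc <- as.numeric(records$mean_conc)
  records$sd_conc <- as.numeric(records$sd_conc)

  key <- paste(records$species, records$element, sep = " / ")
  dup <- unique(key[duplicated(key)])
  if (length(dup) > 0) {
    stop("duplicate (species, element) pair(s): ",
         paste(dup, collapse = "; "), call. = FALSE)
  }

  neg <- which(records$mean_conc < 0 | records$sd_conc < 0)
  if (length(neg) > 0) {
    stop("negative concentration value(s) in row(s): ",
         paste(neg, collapse = ", "), call. = FALSE)
  }

  nd <- !records$detected
  if (any(records$detected & is.na(records$mean_conc))) {
    stop("detected rows must carry a numeric mean concentration",
         call. = FALSE)
  }
  # ND rows carry no numbers, matching how risk tables print "NC"
  records$mean_conc[nd] <- NA_real_
  records$sd_conc[nd] <- NA_real_

  out <- tibble::as_tibble(records)
  class(out) <- c("concentration_table", class(out))
  out
}

# canonical symbols for the Class-I impurities; others pass through
normalize_element <- function(x) {
  x <- trimws(as.character(x))
  canon <- c(cd = "Cd", pb = "Pb", as = "As", hg = "Hg")
  hit <- match(tolower(x), names(canon))
  ifelse(is.na(hit), x, canon[hit])
}

#' Read and write concentration tables as CSV
#'
#' The on-disk format has columns
#' `species,element,mean_mg_per_kg,sd_mg_per_kg,detected[,n_replicates]`.
#' Non-detects may be written as `ND` (or left empty) in the numeric columns
#' with `detected = FALSE`. Writing then reading a validated table is the
#' identity on all fields.
#'
#' @param path Path to a CSV file.
#' @return `read_concentration_csv()` returns a validated
#'   [concentration_table][validate_concentration_table];
#'   `write_concentration_csv()` returns `path` invisibly.
#' @export
read_concentration_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("species", "element", "mean_mg_per_kg", "sd_mg_per_kg")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("concentration CSV lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  parse_nd <- function(x) {
    x[trimws(x) %in% c("", "ND", "nd", "NA")] <- NA
    as.numeric(x)
  }
  mean_conc <- parse_nd(raw$mean_mg_per_kg)
  sd_conc <- parse_nd(raw$sd_mg_per_kg)
  detected <- if ("detected" %in% names(raw)) {
    as.logical(toupper(trimws(raw$detected)))
  } else {
    !is.na(mean_conc)
  }
  validate_concentration_table(data.frame(
    species = raw$species,
    element = raw$element,
    mean_conc = mean_conc,
    sd_conc = sd_conc,
    detected = detected,
    n_replicates = if ("n_replicates" %in% names(raw)) {
      as.integer(raw$n_replicates)
    } else {
      NA_integer_
    },
    stringsAsFactors = FALSE
  ))
}

#' @param x A validated concentration table.
#' @rdname read_concentration_csv
#' @export
write_concentration_csv <- function(x, path) {
  x <- validate_concentration_table(x)
  out <- data.frame(
    species = x$species,
    element = x$element,
    mean_mg_per_kg = ifelse(x$detected, format_plain(x$mean_conc), "ND"),
    sd_mg_per_kg = ifelse(x$detected, format_plain(x$sd_conc), "ND"),
    detected = x$detected,
    n_replicates = x$n_replicates,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

format_plain <- function(x) {
  ifelse(is.na(x), "", format(x, scientific = FALSE, trim = TRUE, digits = 15))
}

#' Measured elemental impurity concentrations in six wild mushrooms
#'
#' The packaged study table: mean and standard deviation (mg per kg dry
#' weight, three biological replicates) of Cd, Pb, As, and Hg in six wild
#' edible mushroom species collected in eastern Anatolia, as quantified by
#' ICP-MS. Mercury in *Laccaria laccata* was below the detection limit and
#' is carried as a non-detect.
#'
#' @return A validated [concentration_table][validate_concentration_table]
#'   with 24 rows (6 species x 4 elements).
#' @examples
#' mushroom_concentrations()
#' @export
mushroom_concentrations <- function() {
  path <- system.file("extdata", "mushroom_concentrations.csv",
                      package = "mycorisk", mustWork = TRUE)
  read_concentration_csv(path)
}

#' @export
print.concentration_table <- function(x, ...) {
  n_nd <- sum(!x$detected)
  cat(sprintf(
    "<concentration_table> %d record(s), %d species, %d element(s), %d non-detect(s)\n",
    nrow(x), length(unique(x$species)), length(unique(x$element)), n_nd))
  NextMethod()
  invisible(x)
}
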