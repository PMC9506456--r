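#' Read a residue field-trial table
#'
#' Parses a delimited file of supervised-trial residue measurements.
#' Concentrations written as `"<x"` (for example `<0.001`) are treated as
#' censored below the limit of quantification and imputed according to
#' `censored`; the flag is retained in the `below_loq` column so downstream
#' summaries can report how many substitutions were made.
#'
#' @param path Path to a CSV file with columns `analyte`, `site`,
#'   `interval_days`, `concentration` and optionally `loq`. `concentration`
#'   may contain `"<value"` strings for non-quantifiable results.
#' @param censored Substitution rule for censored values: `"loq"` (full LOQ,
#'   the conservative default), `"half"` (LOQ/2) or `"zero"`.
#' @return A tibble of residue observations with columns `analyte`, `site`,
#'   `interval_days`, `concentration` (mg/kg, numeric, censored values
#'   imputed), `below_loq` (logical) and `loq` (mg/kg).
#' @examples
#' trials <- read_residue_csv(cumrisk_example("scallion_residue_trials.csv"))
#' dplyr::count(trials, analyte, interval_days)
#' @export
read_residue_csv <- function(path, censored = c("loq", "half", "zero")) {
  censored <- match.arg(censored)
  raw <- readr::read_csv(path, col_types = readr::cols(
    analyte = readr::col_character(),
    site = readr::col_character(),
    interval_days = readr::col_integer(),
    concentration = readr::col_character(),
    .default = readr::col_double()
  ))
  assert_has_columns(raw, c("analyte", "site", "interval_days", "concentration"),
                     "residue table")
  if (nrow(raw) == 0L) {
    stop_cumrisk("Residue table is empty.", "cumrisk_parse_error")
  }
  if (!"loq" %in% names(raw)) raw$loq <- NA_real_
  parsed <- parse_censored(raw$concentration, raw$loq, censored)
  bad <- which(!is.finite(parsed$value) | parsed$value < 0)
  if (length(bad) > 0L) {
    stop_cumrisk(sprintf("Unparseable or negative concentration at data line %d: '%s'.",
                         bad[1], raw$concentration[bad[1]]),
                 "cumrisk_parse_error")
  }
  n_cens <- sum(parsed$below_loq)
  if (n_cens > 0L) {
    rlang::inform(sprintf("%d censored (<LOQ) value(s) substituted using rule '%s'.",
                          n_cens, censored),
                  class = "cumrisk_censored_note")
  }
  tibble::tibble(
    analyte = raw$analyte,
    site = raw$site,
    interval_days = as.integer(raw$interval_days),
    concentration = parsed$value,
    below_loq = parsed$below_loq,
    loq = parsed$loq
  )
}

# Turns "<x" strings into imputed numbers; returns value/below_loq/loq.
parse_censored <- function(x, loq, rule) {
  x <- trimws(x)
  below <- startsWith(x, "<")
  num <- suppressWarnings(as.numeric(ifelse(below, substring(x, 2), x)))
  # the printed "<x" bound is the LOQ when no explicit loq column is given
  loq_out <- ifelse(is.na(loq) & below, num, loq)
  sub <- switch(rule, loq = num, half = num / 2, zero = 0)
  list(value = ifelse(below, sub, num), below_loq = below, loq = loq_out)
}

#' Read a maximum-residue-limit (MRL) table
#'
#' @param path CSV with columns `jurisdiction`, `commodity`, `analyte`,
#'   `mrl` (mg/kg, positive).
#' @return A tibble of MRL records.
#' @export
read_mrl_csv <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    jurisdiction = readr::col_character(),
    commodity = readr::col_character(),
    analyte = readr::col_character(),
    mrl = readr::col_double()
  ))
  assert_has_columns(out, c("jurisdiction", "commodity", "analyte", "mrl"), "MRL table")
  if (any(!is.finite(out$mrl) | out$mrl <= 0)) {
    stop_cumrisk("All MRL values must be positive.", "cumrisk_parse_error")
  }
  out
}

#' Read a toxicological reference table
#'
#' @param path CSV with columns `compound`, `noael` (mg/kg bw/day),
#'   `is_index` (logical), `uf_interspecies`, `uf_intraspecies`.
#' @return A tibble with one row per compound and a derived `uf_total`
#'   column (product of the two uncertainty factors).
#' @export
read_tox_csv <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    compound = readr::col_character(),
    noael = readr::col_double(),
    is_index = readr::col_logical(),
    uf_interspecies = readr::col_double(),
    uf_intraspecies = readr::col_double()
  ))
  validate_tox(out)
}

validate_tox <- function(tox) {
  assert_has_columns(tox, c("compound", "noael", "is_index"), "tox table")
  if (any(!is.finite(tox$noael) | tox$noael <= 0)) {
    stop_cumrisk("All NOAEL values must be positive.", "cumrisk_validation_error")
  }
  if (sum(tox$is_index) != 1L) {
    stop_cumrisk("Exactly one compound must be flagged as the index compound.",
                 "cumrisk_validation_error")
  }
  if (!"uf_interspecies" %in% names(tox)) tox$uf_interspecies <- 10
  if (!"uf_intraspecies" %in% names(tox)) tox$uf_intraspecies <- 10
  dplyr::mutate(tibble::as_tibble(tox),
                uf_total = .data$uf_interspecies * .data$uf_intraspecies)
}

#' Path to a packaged example data file
#'
#' @param file File name under the package's `extdata` directory; `NULL`
#'   lists the available files.
#' @return A file path (or a character vector of file names).
#' @export
cumrisk_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "cumrisk"))
  } else {
    p <- system.file("extdata", file, package = "cumrisk")
    if (p == "") stop_cumrisk(sprintf("No packaged file '%s'.", file),
                              "cumrisk_validation_error")
    p
  }
}

#' Packaged reference tables from a supervised scallion residue study
#'
#' Loads the packaged data set used throughout the examples and the
#' acceptance suite: final residues of metalaxyl-M and azoxystrobin in
#' scallion from four supervised field trials (two pre-harvest intervals,
#' duplicate samples per site), liver-toxicity NOAELs with uncertainty
#' factors, per-food-category STMR/HR residues screened for cumulative
#' assessment, jurisdictional MRLs, and LC-MS/MS calibration slopes in
#' solvent and matrix.
#'
#' @param censored Substitution rule for below-LOQ residues
#'   (see [read_residue_csv()]).
#' @return A named list of tibbles: `trials`, `tox`, `categories`, `mrls`,
#'   `calibration`, `kinetics_reference`.
#' @examples
#' ref <- reference_tables()
#' summarize_residues(ref$trials)
#' @export
reference_tables <- function(censored = "loq") {
  list(
    trials = suppressMessages(
      read_residue_csv(cumrisk_example("scallion_residue_trials.csv"),
                       censored = censored)),
    tox = read_tox_csv(cumrisk_example("tox_profiles.csv")),
    categories = readr::read_csv(cumrisk_example("category_residues.csv"),
                                 col_types = readr::cols(
                                   category = readr::col_character(),
                                   compound = readr::col_character(),
                                   crop = readr::col_character(),
                                   .default = readr::col_double())),
    mrls = read_mrl_csv(cumrisk_example("mrl_records.csv")),
    calibration = readr::read_csv(cumrisk_example("calibration_curves.csv"),
                                  col_types = readr::cols(
                                    analyte = readr::col_character(),
                                    medium = readr::col_character(),
                                    .default = readr::col_double())),
    kinetics_reference = readr::read_csv(cumrisk_example("reference_kinetics.csv"),
                                         col_types = readr::cols(
                                           analyte = readr::col_character(),
                                           site = readr::col_character(),
                                           half_life_days = readr::col_double()))
  )
}
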