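#' Relative potency factor (RPF)
#'
#' Toxic potency of a compound relative to the index compound, derived
#' from NOAELs for the common endpoint:
#' `RPF_i = NOAEL_index / NOAEL_i`. A compound more toxic than the index
#' (lower NOAEL) gets an RPF above 1; the index compound itself has RPF 1.
#'
#' @param noael NOAEL of the compound, mg/kg bw/day (positive).
#' @param noael_index NOAEL of the index compound, mg/kg bw/day (positive).
#' @return The dimensionless RPF.
#' @examples
#' compute_rpf(8, 18.2) # metalaxyl-M relative to azoxystrobin
#' @export
compute_rpf <- function(noael, noael_index) {
  assert_scalar_number(noael, "noael", positive = TRUE)
  assert_scalar_number(noael_index, "noael_index", positive = TRUE)
  noael_index / noael
}

#' Add RPFs to a toxicological reference table
#'
#' @param tox Tox tibble with columns `compound`, `noael`, `is_index`
#'   (exactly one `TRUE`), e.g. from [read_tox_csv()].
#' @return The tox tibble with an `rpf` column; the index compound's RPF
#'   is exactly 1.
#' @examples
#' rpf_table(reference_tables()$tox)
#' @export
rpf_table <- function(tox) {
  tox <- validate_tox(tox)
  noael_index <- tox$noael[tox$is_index]
  dplyr::mutate(tox, rpf = ifelse(.data$is_index, 1,
                                  noael_index / .data$noael))
}

#' Cumulate multi-compound residues into index-compound equivalents
#'
#' Collapses per-compound residues within each food category into a single
#' concentration expressed in index-compound equivalents:
#' `C_index,j = sum_i C_i,j * RPF_i`. Compounds absent from a category
#' (missing residue entries) contribute zero.
#'
#' @param categories Tibble with columns `category`, `compound` and the
#'   residue columns named by `basis` (`stmr` and/or `hr`), mg/kg; `NA`
#'   residues are structural zeros.
#' @param tox Tox tibble (see [rpf_table()]); every compound appearing in
#'   `categories` must have a profile.
#' @param basis Which residue estimate to cumulate: `"stmr"` (central,
#'   default) or `"hr"` (worst case).
#' @return A tibble with one row per category: `category`, `basis`,
#'   `c_index` (mg/kg), plus one `share_<compound>` column per compound
#'   giving that compound's fraction of `c_index` (used downstream to
#'   attribute exposure to compounds).
#' @examples
#' ref <- reference_tables()
#' cumulate_residues(ref$categories, ref$tox)
#' @export
cumulate_residues <- function(categories, tox, basis = c("stmr", "hr")) {
  basis <- match.arg(basis)
  assert_has_columns(categories, c("category", "compound", basis), "categories")
  tox <- rpf_table(tox)
  unknown <- setdiff(unique(categories$compound), tox$compound)
  if (length(unknown) > 0L) {
    stop_cumrisk(sprintf("No toxicological profile for compound(s): %s.",
                         paste(unknown, collapse = ", ")),
                 "cumrisk_validation_error")
  }
  terms <- categories |>
    dplyr::left_join(dplyr::select(tox, "compound", "rpf"), by = "compound") |>
    dplyr::mutate(conc = dplyr::coalesce(.data[[basis]], 0),
                  term = .data$conc * .data$rpf)
  if (any(terms$conc < 0)) {
    stop_cumrisk("Residue concentrations must be non-negative.",
                 "cumrisk_validation_error")
  }
  totals <- terms |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(c_index = sum(.data$term), .groups = "drop")
  shares <- terms |>
    dplyr::left_join(totals, by = "category") |>
    dplyr::mutate(share = ifelse(.data$c_index > 0,
                                 .data$term / .data$c_index, 0)) |>
    dplyr::select("category", "compound", "share") |>
    tidyr::pivot_wider(names_from = "compound", values_from = "share",
                       values_fill = 0, names_prefix = "share_")
  totals |>
    dplyr::mutate(basis = basis, .after = "category") |>
    dplyr::left_join(shares, by = "category")
}
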