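#' Supervised trial median residue (STMR)
#'
#' Median residue concentration over supervised field trials at one
#' pre-harvest interval. For an even number of trials the arithmetic mean
#' of the two central order statistics is returned; full floating
#' precision is retained (round only for presentation).
#'
#' @param concentration Numeric vector of residue concentrations (mg/kg),
#'   censored values already imputed.
#' @return The STMR in mg/kg.
#' @examples
#' compute_stmr(c(0.363, 0.190, 1.420, 1.360, 0.314, 0.326, 4.687, 4.687))
#' @export
compute_stmr <- function(concentration) {
  check_residue_vector(concentration)
  median(concentration)
}

#' Highest residue (HR)
#'
#' Maximum residue concentration over supervised field trials at one
#' pre-harvest interval.
#'
#' @inheritParams compute_stmr
#' @return The HR in mg/kg.
#' @export
compute_hr <- function(concentration) {
  check_residue_vector(concentration)
  max(concentration)
}

check_residue_vector <- function(x) {
  if (length(x) == 0L) {
    stop_cumrisk("No residue observations supplied.", "cumrisk_empty_input_error")
  }
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop_cumrisk("Residue concentrations must be finite and non-negative.",
                 "cumrisk_validation_error")
  }
  invisible(x)
}

#' Summarize residue trials into STMR and HR
#'
#' Groups a residue observation table by analyte and harvest interval and
#' computes the supervised trial median residue (STMR), highest residue
#' (HR), trial count and number of censored values. Field replicates are
#' treated as independent observations.
#'
#' @param trials Tibble of residue observations as returned by
#'   [read_residue_csv()] (columns `analyte`, `interval_days`,
#'   `concentration`, optionally `below_loq`).
#' @return A tibble with one row per analyte x interval: `analyte`,
#'   `interval_days`, `n`, `n_censored`, `stmr`, `hr`.
#' @examples
#' summarize_residues(reference_tables()$trials)
#' @export
summarize_residues <- function(trials) {
  assert_has_columns(trials, c("analyte", "interval_days", "concentration"),
                     "trials")
  if (nrow(trials) == 0L) {
    stop_cumrisk("No residue observations supplied.", "cumrisk_empty_input_error")
  }
  if (!"below_loq" %in% names(trials)) trials$below_loq <- FALSE
  trials |>
    dplyr::group_by(.data$analyte, .data$interval_days) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_censored = sum(.data$below_loq),
      stmr = compute_stmr(.data$concentration),
      hr = compute_hr(.data$concentration),
      .groups = "drop"
    )
}

#' Screen trial summaries against maximum residue limits
#'
#' Compares the highest residue (HR) of each analyte x interval summary
#' with every applicable jurisdictional MRL. Compliance requires the HR to
#' be strictly below the MRL. Analytes with no MRL record yield an explicit
#' `"no standard"` row rather than a silent pass.
#'
#' @param summaries Tibble from [summarize_residues()].
#' @param mrls Tibble of MRL records from [read_mrl_csv()].
#' @return A tibble with columns `analyte`, `interval_days`, `hr`,
#'   `jurisdiction`, `commodity`, `mrl`, `compliant` (logical, `NA` when no
#'   standard exists), `margin` (mrl - hr) and `status`.
#' @examples
#' ref <- reference_tables()
#' check_mrl(summarize_residues(ref$trials), ref$mrls)
#' @export
check_mrl <- function(summaries, mrls) {
  assert_has_columns(summaries, c("analyte", "interval_days", "hr"), "summaries")
  assert_has_columns(mrls, c("jurisdiction", "commodity", "analyte", "mrl"), "mrls")
  out <- summaries |>
    dplyr::select("analyte", "interval_days", "hr") |>
    dplyr::left_join(mrls, by = "analyte",
                     relationship = "many-to-many") |>
    dplyr::mutate(
      compliant = ifelse(is.na(.data$mrl), NA, .data$hr < .data$mrl),
      margin = .data$mrl - .data$hr,
      status = dplyr::case_when(
        is.na(.data$mrl) ~ "no standard",
        .data$hr < .data$mrl ~ "pass",
        TRUE ~ "fail"
      )
    )
  n_missing <- sum(out$status == "no standard")
  if (n_missing > 0L) {
    rlang::inform(sprintf("%d summary row(s) have no MRL on record.", n_missing),
                  class = "cumrisk_missing_mrl_note")
  }
  out
}
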