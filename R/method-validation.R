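#' Matrix effect from calibration slopes
#'
#' Relative change of the calibration slope measured in blank matrix
#' extract versus in pure solvent:
#' `ME(%) = 100 * (slope_matrix - slope_solvent) / slope_solvent`.
#' Negative values indicate ion suppression, positive values enhancement.
#'
#' @param slope_matrix Calibration slope in matrix-matched standards.
#' @param slope_solvent Calibration slope in solvent standards (non-zero).
#' @return Matrix effect in percent.
#' @examples
#' matrix_effect(71002, 175194) # strong suppression
#' @export
matrix_effect <- function(slope_matrix, slope_solvent) {
  assert_scalar_number(slope_matrix, "slope_matrix")
  assert_scalar_number(slope_solvent, "slope_solvent")
  if (slope_solvent == 0) {
    stop_cumrisk("Solvent calibration slope must be non-zero.",
                 "cumrisk_validation_error")
  }
  100 * (slope_matrix - slope_solvent) / slope_solvent
}

#' Matrix effects for a calibration-curve table
#'
#' @param calibration Tibble with columns `analyte`, `medium`
#'   (`"solvent"` / `"matrix"`) and `slope`, one solvent and one matrix
#'   curve per analyte.
#' @return A tibble with `analyte`, `slope_matrix`, `slope_solvent` and
#'   `matrix_effect` (percent).
#' @examples
#' matrix_effect_table(reference_tables()$calibration)
#' @export
matrix_effect_table <- function(calibration) {
  assert_has_columns(calibration, c("analyte", "medium", "slope"), "calibration")
  wide <- calibration |>
    dplyr::select("analyte", "medium", "slope") |>
    tidyr::pivot_wider(names_from = "medium", values_from = "slope",
                       names_prefix = "slope_")
  assert_has_columns(wide, c("slope_matrix", "slope_solvent"), "calibration")
  dplyr::mutate(wide, matrix_effect = purrr::map2_dbl(
    .data$slope_matrix, .data$slope_solvent, matrix_effect))
}

#' Recovery mean and relative standard deviation
#'
#' Summarizes replicate spiked-recovery experiments: arithmetic mean
#' recovery and RSD, where `RSD(%) = 100 * sd / mean` with the sample
#' (n - 1) standard deviation, the convention in residue-method
#' validation.
#'
#' @param recoveries Numeric vector of recovery percentages (positive,
#'   at least 2 values for a defined RSD).
#' @return A tibble with `n`, `mean` and `rsd` (percent); `rsd` is `NA`
#'   with a warning when fewer than two replicates are supplied.
#' @examples
#' recovery_stats(c(97.7, 102.3, 99.8, 106.3, 101.1))
#' @export
recovery_stats <- function(recoveries) {
  if (length(recoveries) == 0L) {
    stop_cumrisk("No recoveries supplied.", "cumrisk_empty_input_error")
  }
  if (any(!is.finite(recoveries) | recoveries <= 0)) {
    stop_cumrisk("Recoveries must be finite and positive.",
                 "cumrisk_validation_error")
  }
  m <- mean(recoveries)
  if (length(recoveries) < 2L) {
    warn("RSD is undefined for a single recovery; reported as NA.")
    return(tibble::tibble(n = 1L, mean = m, rsd = NA_real_))
  }
  tibble::tibble(n = length(recoveries), mean = m,
                 rsd = 100 * sd(recoveries) / m)
}
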