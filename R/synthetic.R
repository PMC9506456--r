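#' Generate a synthetic residue field trial with known decay
#'
#' Simulates supervised-trial residue measurements under exact first-order
#' dissipation with multiplicative lognormal noise:
#' `C(t) = true_c0 * exp(-true_k * t) * LN(1, noise_cv)`. Residue data are
#' positive and right-skewed, which the lognormal noise model reflects.
#' Values falling below the limit of quantification are emitted as
#' censored observations (flagged, imputed at the LOQ), matching how real
#' trial tables report non-quantifiable results.
#'
#' @param analyte Analyte label.
#' @param true_c0 True initial deposition, mg/kg (> 0).
#' @param true_k True degradation rate constant, per day (>= 0).
#' @param sample_times Sampling days (default the common dissipation
#'   design 0, 5, 7, 10, 14 d).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (>= 0; 0 gives the exact decay curve).
#' @param n_sites Number of trial sites.
#' @param n_replicates Replicate samples per site and time.
#' @param loq Limit of quantification, mg/kg.
#' @param seed Optional integer seed; generation is deterministic given it.
#' @return A residue-observation tibble (same columns as
#'   [read_residue_csv()] output) with attribute `truth` holding the
#'   generating parameters.
#' @examples
#' tr <- generate_trial(true_c0 = 2, true_k = 0.6, seed = 42)
#' fit_dissipation(tr)
#' @export
generate_trial <- function(analyte = "analyte", true_c0 = 2, true_k = 0.5,
                           sample_times = c(0, 5, 7, 10, 14),
                           noise_cv = 0.1, n_sites = 1, n_replicates = 3,
                           loq = 0.001, seed = NULL) {
  assert_scalar_number(true_c0, "true_c0", positive = TRUE)
  assert_scalar_number(true_k, "true_k", nonneg = TRUE)
  assert_scalar_number(noise_cv, "noise_cv", nonneg = TRUE)
  if (!is.null(seed)) set.seed(seed)
  grid <- tidyr::expand_grid(
    site = paste0("site-", seq_len(n_sites)),
    interval_days = sample_times,
    replicate = seq_len(n_replicates)
  )
  true_conc <- true_c0 * exp(-true_k * grid$interval_days)
  noisy <- true_conc * rlnorm_meancv(nrow(grid), 1, noise_cv)
  below <- noisy < loq
  out <- tibble::tibble(
    analyte = analyte,
    site = grid$site,
    interval_days = as.integer(grid$interval_days),
    concentration = ifelse(below, loq, noisy),
    below_loq = below,
    loq = loq
  )
  attr(out, "truth") <- list(true_c0 = true_c0, true_k = true_k,
                             noise_cv = noise_cv, seed = seed)
  out
}

# Default age schedule for the synthetic population: ten classes from
# toddlers to the elderly with a monotone body-weight ramp. Plausible
# emulation of a national survey's stratification, not survey data.
default_age_schedule <- function() {
  tibble::tibble(
    age_class = c("2-3 y", "4-6 y", "7-10 y", "11-13 y", "14-17 y",
                  "18-29 y", "30-44 y", "45-59 y", "60-69 y", "70+ y"),
    bw_male = c(14, 18, 27, 39, 53, 63, 65, 65, 62, 60),
    bw_female = c(13.5, 17, 25, 37, 48, 54, 56, 56, 54, 52)
  )
}

# Adult reference consumption (g/day) by food category, loosely shaped
# like an East Asian diet: staple-heavy with modest fruit and condiment
# amounts. Synthetic reference values, not survey data.
default_consumption_schedule <- function() {
  tibble::tibble(
    category = c("Rice and products", "Flour and products", "Other cereals",
                 "Potatoes and products", "Legumes and products",
                 "Dark vegetables", "Light vegetables", "Fruits",
                 "Vegetable oil", "Soy sauce"),
    adult_g_day = c(230, 140, 30, 60, 40, 140, 135, 45, 33, 9),
    cv = c(0.5, 0.5, 0.6, 0.6, 0.6, 0.5, 0.5, 0.8, 0.4, 0.5)
  )
}

#' Generate a stratified synthetic population
#'
#' Builds a region x sex x age-class stratification (default
#' 2 x 2 x 10 = 40 groups) with age-dependent body weights and
#' per-category consumption distributions. Consumption scales with body
#' weight as `(bw / 65)^0.75`, so children eat less in absolute terms but
#' more per kilogram of body weight — the structural feature that makes
#' young groups the most exposed. Rural groups get slightly lower body
#' weights and a more staple-leaning, fruit-poorer diet than urban
#' groups. All values are synthetic emulation with known ground truth,
#' not survey data.
#'
#' @param regions Region labels (default urban/rural).
#' @param sexes Sex labels (default male/female).
#' @param age_schedule Tibble `age_class`, `bw_male`, `bw_female` (kg);
#'   default [default_age_schedule()].
#' @param consumption_schedule Tibble `category`, `adult_g_day`, `cv`;
#'   default [default_consumption_schedule()].
#' @param bw_cv Body-weight coefficient of variation within a group.
#' @param seed Optional integer seed (jitters consumption means
#'   reproducibly so groups are not exact scalings of one another; `NULL`
#'   leaves the deterministic schedule).
#' @return A list with `groups` (one row per stratum: `group_id`,
#'   `region`, `sex`, `age_class`, `bw_mean`, `bw_cv`) and `consumption`
#'   (long tibble: `group_id`, `category`, `mean_g_day`, `cv`).
#' @examples
#' pop <- generate_population(seed = 1)
#' nrow(pop$groups) # 40
#' @export
generate_population <- function(regions = c("urban", "rural"),
                                sexes = c("male", "female"),
                                age_schedule = default_age_schedule(),
                                consumption_schedule = default_consumption_schedule(),
                                bw_cv = 0.12, seed = NULL) {
  assert_has_columns(age_schedule, c("age_class", "bw_male", "bw_female"),
                     "age_schedule")
  assert_has_columns(consumption_schedule, c("category", "adult_g_day", "cv"),
                     "consumption_schedule")
  if (anyDuplicated(age_schedule$age_class) || anyDuplicated(regions) ||
      anyDuplicated(sexes) || anyDuplicated(consumption_schedule$category)) {
    stop_cumrisk("Stratum and category labels must be unique.",
                 "cumrisk_validation_error")
  }
  if (!is.null(seed)) set.seed(seed)

  groups <- tidyr::expand_grid(region = regions, sex = sexes,
                               age_class = age_schedule$age_class) |>
    dplyr::left_join(age_schedule, by = "age_class") |>
    dplyr::mutate(
      bw_mean = ifelse(.data$sex == "female", .data$bw_female, .data$bw_male) *
        ifelse(.data$region == "rural", 0.95, 1),
      bw_cv = bw_cv,
      group_id = paste(.data$region, .data$sex, .data$age_class, sep = "_")
    ) |>
    dplyr::select("group_id", "region", "sex", "age_class", "bw_mean", "bw_cv")

  consumption <- tidyr::expand_grid(group_id = groups$group_id,
                                    category = consumption_schedule$category) |>
    dplyr::left_join(groups, by = "group_id") |>
    dplyr::left_join(consumption_schedule, by = "category") |>
    dplyr::mutate(
      # allometric intake scaling: less food in absolute terms for small
      # bodies, more per kg bw
      scale_bw = (.data$bw_mean / 65)^0.75,
      scale_region = dplyr::case_when(
        .data$region == "rural" & .data$category == "Fruits" ~ 0.7,
        .data$region == "rural" ~ 1.05,
        .data$category == "Fruits" ~ 1.2,
        TRUE ~ 1
      ),
      jitter = if (is.null(seed)) 1 else rlnorm_meancv(dplyr::n(), 1, 0.05),
      mean_g_day = .data$adult_g_day * .data$scale_bw * .data$scale_region *
        .data$jitter
    ) |>
    dplyr::select("group_id", "category", "mean_g_day", "cv")

  list(groups = groups, consumption = consumption)
}
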