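#' Fit first-order dissipation kinetics
#'
#' Fits the single first-order decay model `C(t) = C0 * exp(-k t)` to a
#' residue time series and reports the initial deposition `C0`, the
#' degradation rate constant `k` (per day) and the half-life
#' `t1/2 = ln(2)/k`.
#'
#' The default `"log-linear"` method regresses `ln(C)` on `t` by ordinary
#' least squares (`k = -slope`, `C0 = exp(intercept)`), the conventional
#' approach in dissipation studies; `"nonlinear"` refines that start by
#' least squares on the exponential itself, which weights large early
#' residues more heavily. The two agree exactly on noiseless data.
#'
#' @param times Sampling times in days (non-negative, at least 3 distinct).
#' @param concentrations Residue concentrations in mg/kg at `times`;
#'   must be strictly positive for the log-linear method.
#' @param method `"log-linear"` (default) or `"nonlinear"`.
#' @return A `decay_fit` object with fields `c0`, `k`, `half_life`,
#'   `r_squared` (computed on the fitted scale: log scale for log-linear,
#'   original scale for nonlinear), `method`, `n` and `decaying`. A fitted
#'   `k <= 0` is flagged non-decaying and the half-life is `NA`.
#' @examples
#' t <- c(0, 5, 7, 10, 14)
#' fit <- fit_first_order(t, 2 * exp(-0.5 * t))
#' fit$half_life # log(2) / 0.5
#' @export
fit_first_order <- function(times, concentrations,
                            method = c("log-linear", "nonlinear")) {
  method <- match.arg(method)
  if (length(times) != length(concentrations)) {
    stop_cumrisk("`times` and `concentrations` must have equal length.",
                 "cumrisk_validation_error")
  }
  if (length(unique(times)) < 3L) {
    stop_cumrisk("At least 3 distinct time points are required to fit decay kinetics.",
                 "cumrisk_insufficient_data_error")
  }
  if (any(times < 0)) {
    stop_cumrisk("Times must be non-negative.", "cumrisk_validation_error")
  }
  pos <- concentrations > 0
  if (method == "log-linear" && !all(pos)) {
    stop_cumrisk(paste0("Non-positive concentrations cannot be log-transformed; ",
                        "impute censored values above zero or use the nonlinear method."),
                 "cumrisk_validation_error")
  }
  if (sum(pos) < 3L) {
    stop_cumrisk("At least 3 positive concentrations are needed to initialize the fit.",
                 "cumrisk_insufficient_data_error")
  }

  # log-linear fit (on positive observations) doubles as the nls start
  ll <- lm(log(concentrations[pos]) ~ times[pos])
  k <- -unname(coef(ll)[2])
  c0 <- exp(unname(coef(ll)[1]))
  lg <- log(concentrations[pos])
  r2 <- if (sum((lg - mean(lg))^2) > 0) {
    1 - sum(residuals(ll)^2) / sum((lg - mean(lg))^2)
  } else {
    1
  }

  if (method == "nonlinear") {
    # scaleOffset keeps the convergence test defined on zero-residual data
    fit <- nls(concentrations ~ c0 * exp(-k * times),
               start = list(c0 = c0, k = k),
               control = stats::nls.control(warnOnly = TRUE, scaleOffset = 1))
    est <- coef(fit)
    c0 <- unname(est["c0"])
    k <- unname(est["k"])
    ss_res <- sum((concentrations - c0 * exp(-k * times))^2)
    ss_tot <- sum((concentrations - mean(concentrations))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  }

  decaying <- is.finite(k) && k > 0
  if (!decaying) {
    rlang::inform("Fitted rate constant is not positive; series flagged non-decaying.",
                  class = "cumrisk_nondecaying_note")
  }
  structure(
    list(
      c0 = c0,
      k = k,
      half_life = if (decaying) log(2) / k else NA_real_,
      r_squared = r2,
      method = method,
      n = length(times),
      decaying = decaying
    ),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("First-order dissipation fit (%s, n = %d)\n", x$method, x$n))
  cat(sprintf("  C0        = %.4g mg/kg\n", x$c0))
  cat(sprintf("  k         = %.4g / day\n", x$k))
  if (x$decaying) {
    cat(sprintf("  half-life = %.4g days\n", x$half_life))
  } else {
    cat("  half-life = undefined (non-decaying series)\n")
  }
  cat(sprintf("  R^2       = %.4f\n", x$r_squared))
  invisible(x)
}

#' @rdname fit_first_order
#' @param x A `decay_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(
    term = c("c0", "k"),
    estimate = c(x$c0, x$k)
  )
}

#' @rdname fit_first_order
#' @exportS3Method generics::glance
glance.decay_fit <- function(x, ...) {
  tibble::tibble(
    c0 = x$c0, k = x$k, half_life = x$half_life,
    r.squared = x$r_squared, nobs = x$n,
    method = x$method, decaying = x$decaying
  )
}

#' Fit dissipation kinetics for every analyte x site series
#'
#' @param trials Residue observation tibble (columns `analyte`, `site`,
#'   `interval_days`, `concentration`, optionally `below_loq`). Censored
#'   observations are excluded from the regression; series left with
#'   fewer than 3 distinct time points are skipped with a warning.
#' @param method Passed to [fit_first_order()].
#' @return A tibble with one row per fitted series: `analyte`, `site`,
#'   `c0`, `k`, `half_life`, `r_squared`, `nobs`, `decaying`.
#' @export
fit_dissipation <- function(trials, method = "log-linear") {
  assert_has_columns(trials, c("analyte", "site", "interval_days", "concentration"),
                     "trials")
  # censored (<LOQ) observations carry no quantitative information about
  # the decay rate and are excluded from the regression
  if ("below_loq" %in% names(trials)) {
    trials <- dplyr::filter(trials, !.data$below_loq)
  }
  trials |>
    dplyr::group_by(.data$analyte, .data$site) |>
    dplyr::group_modify(function(d, key) {
      if (length(unique(d$interval_days)) < 3L) {
        warn(sprintf("Series %s / %s has < 3 time points; skipped.",
                     key$analyte, key$site))
        return(tibble::tibble())
      }
      f <- fit_first_order(d$interval_days, d$concentration, method = method)
      dplyr::select(glance(f), -"method")
    }) |>
    dplyr::ungroup()
}

#' Percent degradation after a given interval
#'
#' `100 * (1 - exp(-k t))`, the fraction of the initial deposit lost by
#' time `t` under first-order kinetics.
#'
#' @param fit A `decay_fit` object.
#' @param t Time since application, days (non-negative).
#' @return Percent degraded, in `[0, 100)`.
#' @export
degradation_percent <- function(fit, t) {
  check_decay_fit(fit)
  if (any(t < 0)) stop_cumrisk("`t` must be non-negative.", "cumrisk_validation_error")
  100 * (1 - exp(-fit$k * t))
}

#' Predicted residue at a given interval
#'
#' Evaluates the fitted decay curve `C0 * exp(-k t)`.
#'
#' @inheritParams degradation_percent
#' @return Predicted concentration in mg/kg.
#' @export
predict_residue <- function(fit, t) {
  check_decay_fit(fit)
  if (any(t < 0)) stop_cumrisk("`t` must be non-negative.", "cumrisk_validation_error")
  fit$c0 * exp(-fit$k * t)
}

check_decay_fit <- function(fit) {
  if (!inherits(fit, "decay_fit")) {
    stop_cumrisk("`fit` must be a `decay_fit` object.", "cumrisk_validation_error")
  }
  if (!fit$decaying) {
    stop_cumrisk("Fit is flagged non-decaying (k <= 0); half-life and decay predictions are undefined.",
                 "cumrisk_validation_error")
  }
  invisible(fit)
}

#' @exportS3Method ggplot2::autoplot
autoplot.decay_fit <- function(object, tmax = NULL, ...) {
  tmax <- tmax %||% (5 * object$half_life)
  grid <- tibble::tibble(t = seq(0, tmax, length.out = 200))
  grid$conc <- predict_residue(object, grid$t)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$t, y = .data$conc)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "days after application", y = "residue (mg/kg)",
                  title = sprintf("First-order dissipation: t1/2 = %.2f d", object$half_life))
}
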