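#' Draw one inner (variability) loop of dietary exposure samples
#'
#' Simulates chronic dietary exposure for one population group by Monte
#' Carlo: each iteration draws a body weight, a consumption amount per
#' food category, and a residue concentration per category (fixed
#' index-equivalent value, or an empirical draw when per-trial samples are
#' supplied), then combines them as
#' `E = sum_j CONS_j * C_index,j / bw` with consumption converted from
#' g/day to kg/day. Exposures are in mg/kg bw/day.
#'
#' Body weight and consumption use lognormal distributions matched to the
#' supplied mean and CV (a CV of 0 is a point mass); lognormal draws are
#' strictly positive, and any non-positive body weight (possible only with
#' user-supplied degenerate inputs) is redrawn and counted.
#'
#' @param group One-row tibble (or list) with `group_id`, `bw_mean` (kg)
#'   and `bw_cv`.
#' @param consumption Tibble with columns `category`, `mean_g_day`, `cv`
#'   for this group; categories present in `c_index` but absent here
#'   contribute zero consumption.
#' @param c_index Tibble from [cumulate_residues()] (columns `category`,
#'   `c_index`, optional `share_*` compound-attribution columns, optional
#'   `samples` list-column of per-trial index-equivalent residues for
#'   empirical redraws).
#' @param n_inner Number of Monte Carlo iterations (>= 1).
#' @param seed Optional integer seed for this loop's RNG stream.
#' @return An `exposure_samples` object: list with `group_id`, `e_total`
#'   (length `n_inner`), matrices `e_by_category` and `e_by_compound`
#'   (rows = iterations), and `n_redraws`.
#' @export
sample_inner_loop <- function(group, consumption, c_index, n_inner,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  assert_scalar_number(n_inner, "n_inner", positive = TRUE)
  assert_has_columns(c_index, c("category", "c_index"), "c_index")
  assert_has_columns(consumption, c("category", "mean_g_day", "cv"), "consumption")
  bw_mean <- group$bw_mean
  bw_cv <- group$bw_cv %||% 0
  assert_scalar_number(bw_mean, "bw_mean", positive = TRUE)

  cats <- c_index$category
  j_idx <- match(cats, consumption$category)
  cons_mean <- ifelse(is.na(j_idx), 0, consumption$mean_g_day[j_idx])
  cons_cv <- ifelse(is.na(j_idx), 0, consumption$cv[j_idx])
  if (any(cons_mean < 0) || any(cons_cv < 0)) {
    stop_cumrisk("Consumption means and CVs must be non-negative.",
                 "cumrisk_validation_error")
  }

  n <- as.integer(n_inner)
  bw <- rlnorm_meancv(n, bw_mean, bw_cv)
  n_redraws <- 0L
  while (any(bw <= 0)) { # unreachable for lognormal; guards degenerate input
    bad <- bw <= 0
    n_redraws <- n_redraws + sum(bad)
    bw[bad] <- rlnorm_meancv(sum(bad), bw_mean, bw_cv)
  }

  has_samples <- "samples" %in% names(c_index)
  e_by_category <- matrix(0, nrow = n, ncol = length(cats),
                          dimnames = list(NULL, cats))
  for (j in seq_along(cats)) {
    cons_j <- rlnorm_meancv(n, cons_mean[j], cons_cv[j])
    smp <- if (has_samples) c_index$samples[[j]] else NULL
    conc_j <- if (!is.null(smp) && length(smp) > 0) {
      smp[sample.int(length(smp), n, replace = TRUE)]
    } else {
      rep(c_index$c_index[j], n)
    }
    e_by_category[, j] <- (cons_j / 1000) * conc_j / bw
  }
  e_total <- rowSums(e_by_category)
  if (any(!is.finite(e_total))) {
    stop_cumrisk("Non-finite exposure sample encountered; check input distributions.",
                 "cumrisk_simulation_error")
  }

  share_cols <- grep("^share_", names(c_index), value = TRUE)
  e_by_compound <- if (length(share_cols) > 0) {
    shares <- as.matrix(c_index[, share_cols, drop = FALSE])
    colnames(shares) <- sub("^share_", "", share_cols)
    e_by_category %*% shares
  } else {
    matrix(e_total, ncol = 1, dimnames = list(NULL, "total"))
  }

  structure(
    list(group_id = group$group_id %||% "group", e_total = e_total,
         e_by_category = e_by_category, e_by_compound = e_by_compound,
         n_redraws = n_redraws),
    class = "exposure_samples"
  )
}

#' Risk quotient from cumulative exposure
#'
#' Characterizes chronic dietary risk as a percentage of the health-based
#' reference dose of the index compound:
#' `R(%) = 100 * E / (NOAEL_index / UF_total)`, where `UF_total` is the
#' product of the inter- and intra-species uncertainty factors (default
#' 10 x 10 = 100). Values below 100% are deemed acceptable.
#'
#' @param e Cumulative exposure(s) in index-compound equivalents,
#'   mg/kg bw/day (vectorized).
#' @param tox Tox tibble with the index compound flagged
#'   (see [read_tox_csv()]).
#' @return Risk quotient(s) in percent.
#' @examples
#' characterize_risk(0.0014450, reference_tables()$tox)
#' @export
characterize_risk <- function(e, tox) {
  tox <- validate_tox(tox)
  idx <- which(tox$is_index)
  noael_index <- tox$noael[idx]
  uf_total <- tox$uf_total[idx]
  if (uf_total <= 0) {
    stop_cumrisk("Total uncertainty factor must be positive.",
                 "cumrisk_validation_error")
  }
  100 * e / (noael_index / uf_total)
}

#' Two-dimensional (nested) Monte Carlo risk assessment
#'
#' Runs the nested simulation separating population variability from
#' parameter uncertainty. The inner loop (default 2000 iterations) draws
#' individual body weights, consumption amounts and residue concentrations
#' and converts each exposure into a risk quotient; within each inner loop
#' the requested percentiles of the risk distribution are computed. The
#' outer loop (default 500 replicates) re-realizes uncertain parameters
#' and repeats the inner loop; the spread of each percentile across outer
#' replicates gives its confidence band.
#'
#' With `uncertainty = "bootstrap"` each outer replicate re-draws every
#' group's per-category consumption mean as the mean of a pseudo-sample of
#' `pseudo_n` consumption records, and re-draws each category's empirical
#' residue set by bootstrap where per-trial `samples` are available (fixed
#' `c_index` values carry no sampling uncertainty and stay fixed). With
#' `uncertainty = "none"` the outer replicates differ only by inner-loop
#' sampling noise.
#'
#' RNG substreams are derived deterministically from the master seed, the
#' group label and the outer-replicate index, so results are byte-identical
#' across runs and invariant to group ordering.
#'
#' @param groups Tibble with one row per population group: `group_id`,
#'   `bw_mean`, `bw_cv` and any stratification columns (`region`, `sex`,
#'   `age_class`) to carry through to the output.
#' @param consumption Long tibble: `group_id`, `category`, `mean_g_day`,
#'   `cv`.
#' @param c_index Per-category residue table from [cumulate_residues()].
#' @param tox Tox tibble with the index compound flagged.
#' @param n_inner Inner (variability) iterations, >= 100.
#' @param n_outer Outer (uncertainty) replicates, >= 2.
#' @param seed Master seed (integer).
#' @param probs Percentile levels to report (default P50, P97.5, P99.9).
#' @param ci `"two-sided"` (bands at the 2.5th/97.5th percentiles of the
#'   outer-loop distribution, default) or `"one-sided"` (5th/95th).
#' @param uncertainty `"bootstrap"` (default) or `"none"`.
#' @param pseudo_n Pseudo-sample size for the consumption bootstrap.
#' @return A `risk_assessment` object; `tidy()` returns the per-group
#'   summary tibble (`group_id`, stratifiers, `statistic`, `estimate`
#'   = median across outer replicates, `lower`, `upper`, all in percent),
#'   `glance()` the run configuration.
#' @examples
#' pop <- generate_population(seed = 1)
#' ref <- reference_tables()
#' cx <- cumulate_residues(ref$categories, ref$tox)
#' ra <- run_two_dimensional(pop$groups[1:2, ], pop$consumption, cx,
#'                           ref$tox, n_inner = 200, n_outer = 10, seed = 1)
#' tidy(ra)
#' @export
run_two_dimensional <- function(groups, consumption, c_index, tox,
                                n_inner = 2000, n_outer = 500, seed = 1,
                                probs = c(0.5, 0.975, 0.999),
                                ci = c("two-sided", "one-sided"),
                                uncertainty = c("bootstrap", "none"),
                                pseudo_n = 100) {
  ci <- match.arg(ci)
  uncertainty <- match.arg(uncertainty)
  assert_has_columns(groups, c("group_id", "bw_mean"), "groups")
  if (anyDuplicated(groups$group_id)) {
    stop_cumrisk("Duplicate group_id in `groups`.", "cumrisk_validation_error")
  }
  if (n_inner < 100) {
    stop_cumrisk("n_inner must be at least 100.", "cumrisk_validation_error")
  }
  if (n_outer < 2) {
    stop_cumrisk("n_outer must be at least 2.", "cumrisk_validation_error")
  }
  tox <- validate_tox(tox)

  stat_names <- paste0("P", formatC(100 * probs, format = "g"))
  n_groups <- nrow(groups)
  # stats[g, r, p]: percentile p of the risk distribution in replicate r
  stats <- array(NA_real_, dim = c(n_groups, n_outer, length(probs)))

  for (r in seq_len(n_outer)) {
    cx_r <- realize_residue_uncertainty(c_index, seed, r, uncertainty)
    for (g in seq_len(n_groups)) {
      grp <- groups[g, ]
      cons_g <- dplyr::filter(consumption, .data$group_id == grp$group_id)
      cons_r <- realize_consumption_uncertainty(cons_g, grp$group_id, seed, r,
                                                uncertainty, pseudo_n)
      s <- sample_inner_loop(grp, cons_r, cx_r, n_inner,
                             seed = substream_seed(seed, grp$group_id, r))
      risk <- characterize_risk(s$e_total, tox)
      stats[g, r, ] <- quantile(risk, probs, type = 7, names = FALSE)
    }
  }

  band <- if (ci == "two-sided") c(0.025, 0.975) else c(0.05, 0.95)
  strat_cols <- intersect(c("region", "sex", "age_class"), names(groups))
  summaries <- purrr::map_dfr(seq_len(n_groups), function(g) {
    purrr::map_dfr(seq_along(probs), function(p) {
      v <- stats[g, , p]
      tibble::tibble(
        group_id = groups$group_id[g],
        statistic = stat_names[p],
        estimate = median(v),
        lower = quantile(v, band[1], type = 7, names = FALSE),
        upper = quantile(v, band[2], type = 7, names = FALSE)
      )
    })
  }) |>
    dplyr::left_join(dplyr::select(groups, "group_id",
                                   dplyr::all_of(strat_cols)),
                     by = "group_id") |>
    dplyr::relocate(dplyr::all_of(strat_cols), .after = "group_id")

  structure(
    list(summaries = summaries,
         config = list(n_inner = as.integer(n_inner),
                       n_outer = as.integer(n_outer),
                       seed = as.integer(seed), probs = probs,
                       ci = ci, uncertainty = uncertainty,
                       pseudo_n = pseudo_n)),
    class = "risk_assessment"
  )
}

# Outer-replicate realization of residue-concentration uncertainty:
# bootstrap the empirical per-trial sample sets; fixed values stay fixed.
realize_residue_uncertainty <- function(c_index, seed, r, uncertainty) {
  if (uncertainty != "bootstrap" || !"samples" %in% names(c_index)) {
    return(c_index)
  }
  set.seed(substream_seed(seed, "residue-bootstrap", r))
  c_index$samples <- purrr::map(c_index$samples, function(s) {
    if (is.null(s) || length(s) == 0) s else s[sample.int(length(s), replace = TRUE)]
  })
  c_index
}

# Outer-replicate realization of consumption-parameter uncertainty:
# each category mean is replaced by the mean of a pseudo-sample of
# `pseudo_n` records, emulating survey re-sampling.
realize_consumption_uncertainty <- function(cons, group_id, seed, r,
                                            uncertainty, pseudo_n) {
  if (uncertainty != "bootstrap") return(cons)
  set.seed(substream_seed(seed, paste0("consumption-bootstrap|", group_id), r))
  cons$mean_g_day <- purrr::map2_dbl(cons$mean_g_day, cons$cv, function(m, cv) {
    mean(rlnorm_meancv(pseudo_n, m, cv))
  })
  cons
}

#' @export
print.risk_assessment <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Two-dimensional Monte Carlo risk assessment (%d groups, %d x %d, seed %d)\n",
              length(unique(x$summaries$group_id)), cfg$n_inner, cfg$n_outer, cfg$seed))
  cat(sprintf("  uncertainty: %s; CI: %s\n", cfg$uncertainty, cfg$ci))
  print(x$summaries, n = 12)
  invisible(x)
}

#' @rdname run_two_dimensional
#' @param x A `risk_assessment` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.risk_assessment <- function(x, ...) {
  x$summaries
}

#' @rdname run_two_dimensional
#' @exportS3Method generics::glance
glance.risk_assessment <- function(x, ...) {
  cfg <- x$config
  tibble::tibble(n_groups = length(unique(x$summaries$group_id)),
                 n_inner = cfg$n_inner, n_outer = cfg$n_outer,
                 seed = cfg$seed, ci = cfg$ci, uncertainty = cfg$uncertainty)
}

#' @exportS3Method ggplot2::autoplot
autoplot.risk_assessment <- function(object, statistic = "P97.5", ...) {
  d <- dplyr::filter(object$summaries, .data$statistic == !!statistic)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate,
                                  y = stats::reorder(.data$group_id, .data$estimate))) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lower, xmax = .data$upper)) +
    ggplot2::geom_vline(xintercept = 100, linetype = "dashed") +
    ggplot2::labs(x = sprintf("risk quotient at %s (%% of reference dose)", statistic),
                  y = NULL)
}
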