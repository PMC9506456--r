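# Independent brute-force oracles used across tests. These deliberately
# avoid the package's own code paths.

# full-sort median: mean of the two central order statistics for even n
oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# linear-scan pairwise maximum
oracle_max <- function(x) {
  m <- x[1]
  for (v in x[-1]) if (v > m) m <- v
  m
}

# two-pass mean / sample-sd
oracle_mean_sd <- function(x) {
  m <- sum(x) / length(x)
  s <- sqrt(sum((x - m)^2) / (length(x) - 1))
  c(mean = m, sd = s)
}

# dense grid-search least squares for C(t) = c0 * exp(-k t);
# scale = "log" minimizes log-scale SSE (the log-linear objective),
# scale = "linear" the original-scale SSE (the nonlinear objective)
oracle_grid_fit <- function(times, conc, k_range, c0_range,
                            k_step = 1e-3, c0_step = 1e-3,
                            scale = c("log", "linear")) {
  scale <- match.arg(scale)
  ks <- seq(k_range[1], k_range[2], by = k_step)
  c0s <- seq(c0_range[1], c0_range[2], by = c0_step)
  best <- c(k = NA_real_, c0 = NA_real_)
  best_sse <- Inf
  for (c0 in c0s) {
    for (k in ks) {
      pred <- c0 * exp(-k * times)
      sse <- if (scale == "log") {
        sum((log(conc) - log(pred))^2)
      } else {
        sum((conc - pred)^2)
      }
      if (sse < best_sse) {
        best_sse <- sse
        best <- c(k = k, c0 = c0)
      }
    }
  }
  best
}

# naive double loop over a long residue table: sum_i C_i,j * RPF_i
oracle_cumulate <- function(categories, rpfs) {
  cats <- unique(categories$category)
  out <- numeric(length(cats))
  names(out) <- cats
  for (j in seq_along(cats)) {
    rows <- categories[categories$category == cats[j], ]
    total <- 0
    for (i in seq_len(nrow(rows))) {
      conc <- rows$stmr[i]
      if (is.na(conc)) conc <- 0
      total <- total + conc * rpfs[[rows$compound[i]]]
    }
    out[j] <- total
  }
  out
}

# small degenerate (point-mass) scenario used by several engine tests
point_mass_scenario <- function(cons_g_day = 100, c_index = 0.867,
                                bw = 60) {
  list(
    group = tibble::tibble(group_id = "g1", region = "urban", sex = "female",
                           age_class = "adult", bw_mean = bw, bw_cv = 0),
    consumption = tibble::tibble(group_id = "g1", category = "cat-1",
                                 mean_g_day = cons_g_day, cv = 0),
    c_index = tibble::tibble(category = "cat-1", basis = "stmr",
                             c_index = c_index),
    e_expected = (cons_g_day / 1000) * c_index / bw
  )
}

ref_tables <- function() reference_tables()
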