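test_that("point-mass inner loop reproduces the hand-computed exposure", {
  sc <- point_mass_scenario()
  s <- sample_inner_loop(sc$group, sc$consumption, sc$c_index,
                         n_inner = 200, seed = 1)
  expect_equal(s$e_total, rep(sc$e_expected, 200)) # 0.001445 mg/kg bw/day
  expect_equal(s$n_redraws, 0L)

  none <- dplyr::mutate(sc$consumption, mean_g_day = 0)
  s0 <- sample_inner_loop(sc$group, none, sc$c_index, n_inner = 50, seed = 1)
  expect_equal(s0$e_total, rep(0, 50))
})

test_that("exposure decomposition sums match the total within 1e-9 relative", {
  ref <- ref_tables()
  cx <- cumulate_residues(ref$categories, ref$tox)
  pop <- generate_population(seed = 3)
  s <- sample_inner_loop(pop$groups[5, ], pop$consumption, cx,
                         n_inner = 500, seed = 9)
  expect_equal(rowSums(s$e_by_category), s$e_total, tolerance = 1e-9)
  expect_equal(rowSums(s$e_by_compound), s$e_total, tolerance = 1e-9)
  expect_true(all(s$e_by_category >= 0))
})

test_that("lognormal consumption gives the closed-form exposure mean", {
  # E = cons * c / (1000 * bw) with fixed c and bw is lognormal with a
  # known arithmetic mean; the empirical mean must fall within 3 SE
  sc <- point_mass_scenario()
  cons <- dplyr::mutate(sc$consumption, cv = 0.6)
  n <- 4000
  s <- sample_inner_loop(sc$group, cons, sc$c_index, n_inner = n, seed = 13)
  closed_mean <- (100 / 1000) * 0.867 / 60
  se <- sd(s$e_total) / sqrt(n)
  expect_lt(abs(mean(s$e_total) - closed_mean), 3 * se)
})

test_that("risk characterization follows R = 100 E UF / NOAEL_index", {
  tox <- ref_tables()$tox
  expect_equal(characterize_risk(0.0014450, tox), 0.79395604395604395)
  expect_equal(characterize_risk(0, tox), 0)
  expect_equal(characterize_risk(18.2 / 100, tox), 100)

  uf1 <- dplyr::mutate(tox, uf_interspecies = 1, uf_intraspecies = 1)
  expect_equal(characterize_risk(18.2, uf1), 100)
})

test_that("degenerate distributions collapse every percentile and band", {
  sc <- point_mass_scenario()
  tox <- ref_tables()$tox
  ra <- run_two_dimensional(sc$group, sc$consumption, sc$c_index, tox,
                            n_inner = 100, n_outer = 3, seed = 4)
  expected_risk <- 100 * sc$e_expected / (18.2 / 100)
  out <- tidy(ra)
  expect_equal(out$estimate, rep(expected_risk, 3))
  expect_equal(out$lower, rep(expected_risk, 3))
  expect_equal(out$upper, rep(expected_risk, 3))
})

test_that("risk summaries are reproducible and invariant to group order", {
  ref <- ref_tables()
  cx <- cumulate_residues(ref$categories, ref$tox)
  pop <- generate_population(seed = 2)
  g <- pop$groups[c(1, 10, 25), ]

  ra1 <- run_two_dimensional(g, pop$consumption, cx, ref$tox,
                             n_inner = 150, n_outer = 4, seed = 11)
  ra2 <- run_two_dimensional(g, pop$consumption, cx, ref$tox,
                             n_inner = 150, n_outer = 4, seed = 11)
  expect_identical(tidy(ra1), tidy(ra2))

  shuffled <- g[c(3, 1, 2), ]
  ra3 <- run_two_dimensional(shuffled, pop$consumption, cx, ref$tox,
                             n_inner = 150, n_outer = 4, seed = 11)
  expect_identical(dplyr::arrange(tidy(ra1), .data$group_id, .data$statistic),
                   dplyr::arrange(tidy(ra3), .data$group_id, .data$statistic))

  ra4 <- run_two_dimensional(g, pop$consumption, cx, ref$tox,
                             n_inner = 150, n_outer = 4, seed = 12)
  expect_false(identical(tidy(ra1), tidy(ra4)))
})

test_that("percentile estimates are ordered and bracketed by their bands", {
  ref <- ref_tables()
  cx <- cumulate_residues(ref$categories, ref$tox)
  pop <- generate_population(seed = 6)
  ra <- run_two_dimensional(pop$groups[1:3, ], pop$consumption, cx, ref$tox,
                            n_inner = 200, n_outer = 6, seed = 21)
  wide <- tidy(ra) |>
    dplyr::select("group_id", "statistic", "estimate") |>
    tidyr::pivot_wider(names_from = "statistic", values_from = "estimate")
  expect_true(all(wide$P50 <= wide$P97.5 & wide$P97.5 <= wide$P99.9))
  out <- tidy(ra)
  expect_true(all(out$lower <= out$estimate + 1e-12 &
                    out$estimate <= out$upper + 1e-12))
})

test_that("risk responds monotonically to consumption and body weight", {
  sc <- point_mass_scenario()
  cons <- dplyr::mutate(sc$consumption, cv = 0.4)
  grp <- dplyr::mutate(sc$group, bw_cv = 0.1)
  tox <- ref_tables()$tox

  base <- run_two_dimensional(grp, cons, sc$c_index, tox,
                              n_inner = 150, n_outer = 3, seed = 31)
  more <- run_two_dimensional(grp, dplyr::mutate(cons, mean_g_day = mean_g_day * 1.5),
                              sc$c_index, tox,
                              n_inner = 150, n_outer = 3, seed = 31)
  heavier <- run_two_dimensional(dplyr::mutate(grp, bw_mean = bw_mean * 2),
                                 cons, sc$c_index, tox,
                                 n_inner = 150, n_outer = 3, seed = 31)
  expect_true(all(tidy(more)$estimate >= tidy(base)$estimate))
  expect_true(all(tidy(heavier)$estimate <= tidy(base)$estimate))
  # exact scaling under common random numbers: doubling bw halves risk
  expect_equal(tidy(heavier)$estimate, tidy(base)$estimate / 2,
               tolerance = 1e-12)
})

test_that("outer-loop bands narrow along an n_inner/n_outer ladder", {
  sc <- point_mass_scenario()
  cons <- dplyr::mutate(sc$consumption, cv = 0.5)
  grp <- dplyr::mutate(sc$group, bw_cv = 0.1)
  tox <- ref_tables()$tox
  width_at <- function(n_inner, n_outer) {
    ra <- run_two_dimensional(grp, cons, sc$c_index, tox,
                              n_inner = n_inner, n_outer = n_outer,
                              seed = 41, uncertainty = "none")
    med <- dplyr::filter(tidy(ra), .data$statistic == "P50")
    med$upper - med$lower
  }
  w <- c(width_at(100, 8), width_at(900, 16), width_at(8100, 32))
  expect_lt(w[2], w[1])
  expect_lt(w[3], w[2])
})

test_that("engine preconditions are enforced", {
  sc <- point_mass_scenario()
  tox <- ref_tables()$tox
  expect_error(run_two_dimensional(sc$group, sc$consumption, sc$c_index, tox,
                                   n_inner = 50, n_outer = 5, seed = 1),
               class = "cumrisk_validation_error")
  expect_error(run_two_dimensional(sc$group, sc$consumption, sc$c_index, tox,
                                   n_inner = 100, n_outer = 1, seed = 1),
               class = "cumrisk_validation_error")
  dup <- dplyr::bind_rows(sc$group, sc$group)
  expect_error(run_two_dimensional(dup, sc$consumption, sc$c_index, tox,
                                   n_inner = 100, n_outer = 2, seed = 1),
               class = "cumrisk_validation_error")
})
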