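azoxy_7d <- c(0.363, 0.190, 1.420, 1.360, 0.314, 0.326, 4.687, 4.687)

test_that("STMR is the trial median, averaging the central pair for even n", {
  expect_equal(compute_stmr(azoxy_7d), 0.8615)
  expect_equal(compute_stmr(0.5), 0.5)

  set.seed(101)
  for (i in 1:5) {
    x <- rlnorm(200, meanlog = -1, sdlog = 1)
    expect_equal(compute_stmr(x), oracle_median(x))
    x_odd <- x[-1]
    expect_equal(compute_stmr(x_odd), oracle_median(x_odd))
  }
})

test_that("STMR is permutation-invariant and bounded by the sample range", {
  set.seed(202)
  for (i in 1:20) {
    x <- rlnorm(sample(2:30, 1))
    shuffled <- sample(x)
    expect_identical(compute_stmr(x), compute_stmr(shuffled))
    expect_gte(compute_stmr(x), min(x))
    expect_lte(compute_stmr(x), max(x))
  }
})

test_that("HR is the trial maximum", {
  expect_equal(compute_hr(azoxy_7d), 4.687)
  expect_equal(compute_hr(0.5), 0.5)
  set.seed(303)
  for (i in 1:10) {
    x <- rlnorm(sample(1:50, 1))
    expect_equal(compute_hr(x), oracle_max(x))
  }
})

test_that("empty or invalid residue vectors are rejected", {
  expect_error(compute_stmr(numeric(0)), class = "cumrisk_empty_input_error")
  expect_error(compute_hr(numeric(0)), class = "cumrisk_empty_input_error")
  expect_error(compute_stmr(c(0.1, -0.2)), class = "cumrisk_validation_error")
})

test_that("packaged trial table reproduces all four STMR/HR pairs", {
  smry <- summarize_residues(ref_tables()$trials)
  get <- function(a, d) smry[smry$analyte == a & smry$interval_days == d, ]

  m7 <- get("metalaxyl-M", 7)
  m10 <- get("metalaxyl-M", 10)
  a7 <- get("azoxystrobin", 7)
  a10 <- get("azoxystrobin", 10)

  expect_equal(m7$stmr, 0.0025)
  expect_equal(m10$stmr, 0.0035)
  expect_equal(m7$hr, 0.088)
  expect_equal(m10$hr, 0.049)
  expect_equal(a7$stmr, 0.8615)
  expect_equal(a10$stmr, 0.3635)
  expect_equal(a7$hr, 4.687)
  expect_equal(a10$hr, 4.368)
  expect_true(all(smry$n == 8))
  expect_true(all(smry$stmr <= smry$hr))
})

test_that("the median of the censored analyte is insensitive to the imputation rule", {
  # the two <LOQ values are the extreme low order statistics of n = 8,
  # so any substitution at or below the LOQ leaves the median unchanged
  path <- cumrisk_example("scallion_residue_trials.csv")
  stmrs <- vapply(c("loq", "half", "zero"), function(rule) {
    trials <- suppressMessages(read_residue_csv(path, censored = rule))
    smry <- summarize_residues(trials)
    smry$stmr[smry$analyte == "metalaxyl-M" & smry$interval_days == 7]
  }, numeric(1))
  expect_true(all(stmrs == 0.0025))
})

test_that("censored concentrations parse with the requested substitution", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("analyte,site,interval_days,concentration,loq",
               "a,s,7,<0.001,0.001", "a,s,7,0.05,0.001"), f)
  loq <- suppressMessages(read_residue_csv(f, censored = "loq"))
  half <- suppressMessages(read_residue_csv(f, censored = "half"))
  zero <- suppressMessages(read_residue_csv(f, censored = "zero"))
  expect_equal(loq$concentration, c(0.001, 0.05))
  expect_equal(half$concentration, c(0.0005, 0.05))
  expect_equal(zero$concentration, c(0, 0.05))
  expect_equal(loq$below_loq, c(TRUE, FALSE))
  expect_message(read_residue_csv(f), class = "cumrisk_censored_note")
})

test_that("MRL screening passes on strict inequality and flags missing standards", {
  ref <- ref_tables()
  report <- suppressMessages(check_mrl(summarize_residues(ref$trials), ref$mrls))

  azoxy7_china <- report[report$analyte == "azoxystrobin" &
                           report$interval_days == 7 &
                           report$jurisdiction == "China", ]
  expect_equal(azoxy7_china$status, "pass")
  expect_equal(azoxy7_china$margin, 7 - 4.687)

  meta_eu <- report[report$analyte == "metalaxyl-M" &
                      report$interval_days == 7 &
                      report$jurisdiction == "EU", ]
  expect_equal(meta_eu$status, "pass")

  # boundary: HR exactly at the MRL fails (compliance requires HR < MRL)
  at_limit <- tibble::tibble(analyte = "x", interval_days = 7L, hr = 1.0)
  mrl <- tibble::tibble(jurisdiction = "J", commodity = "c", analyte = "x",
                        mrl = 1.0)
  expect_equal(check_mrl(at_limit, mrl)$status, "fail")

  # analyte without a standard is reported explicitly, not silently passed
  orphan <- tibble::tibble(analyte = "unknown", interval_days = 7L, hr = 0.1)
  expect_message(rep_orphan <- check_mrl(orphan, mrl),
                 class = "cumrisk_missing_mrl_note")
  expect_equal(rep_orphan$status, "no standard")
  expect_true(is.na(rep_orphan$compliant))
})
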