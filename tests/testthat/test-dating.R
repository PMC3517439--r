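tigger_window <- calibration_window("TIGGER1", "TBel", 100, 190)
ant_window <- calibration_window("Mariner-28_SIn", "SIn", 140, 140)

test_that("divergence-ratio scaling reproduces the published age arithmetic", {
  est <- estimate_age_range(15.0, 21.2, tigger_window)
  expect_equal(est$raw_min, 15.0 / 21.2 * 100, tolerance = 1e-12)
  expect_equal(est$raw_max, 15.0 / 21.2 * 190, tolerance = 1e-12)
  expect_equal(est$reported_max, 134)
  expect_false(est$upper_bound_only)

  ant <- estimate_age_range(6.3, 20.1, ant_window)
  expect_equal(ant$raw_max, 6.3 / 20.1 * 140, tolerance = 1e-12)
  expect_equal(ant$reported_max, 44)  # raw 43.88; published rounding gives 43
  expect_true(ant$upper_bound_only)
})

test_that("equal divergences return the calibration window itself", {
  est <- estimate_age_range(21.2, 21.2, tigger_window)
  expect_equal(c(est$raw_min, est$raw_max), c(100, 190))
})

test_that("degenerate calibration divergence errors", {
  expect_error(estimate_age_range(10, 0, tigger_window), "> 0")
  expect_error(estimate_age_range(-1, 10, tigger_window), ">= 0")
})

test_that("phylogenetic caps clip the upper bound and surface contradictions", {
  est <- estimate_age_range(15.0, 21.2, tigger_window)
  capped <- apply_constraint(est, 100)
  expect_equal(capped$reported_max, 100)
  expect_equal(capped$reported_min, est$reported_min)
  expect_equal(capped$constraint_applied, 100)

  inactive <- apply_constraint(estimate_age_range(5, 50, tigger_window), 100)
  expect_true(is.na(inactive$constraint_applied))

  expect_error(apply_constraint(est, 60), "constraint excludes estimate")
})

test_that("estimates are scale-equivariant and monotone in family divergence", {
  withr::with_seed(23, {
    for (i in 1:20) {
      df <- runif(1, 1, 30)
      dc <- runif(1, 5, 30)
      k <- runif(1, 0.1, 10)
      e1 <- estimate_age_range(df, dc, tigger_window)
      e2 <- estimate_age_range(k * df, k * dc, tigger_window)
      expect_equal(e1$raw_min, e2$raw_min, tolerance = 1e-9)
      expect_equal(e1$raw_max, e2$raw_max, tolerance = 1e-9)
      e3 <- estimate_age_range(df * 1.01, dc, tigger_window)
      expect_gt(e3$raw_min, e1$raw_min)
      expect_gt(e3$raw_max, e1$raw_max)
    }
  })
})

test_that("date_all reproduces every published age from the bundled tables", {
  ages <- date_all(mariner_divergences(), mariner_calibrations(), mariner_caps())
  get <- function(fam, gen) ages[ages$family == fam & ages$genome == gen, ]
  ts <- get("Mariner-1_Tbel", "TBel")   # ~134 to ~70, adjusted to 100 to 70
  expect_lte(abs(ts$reported_min - 70), 1)
  expect_equal(ts$reported_max, 100)
  hh <- get("Mariner-1_Tbel", "EEu")    # ~131 to ~69, adjusted to 100 to 69
  expect_lte(abs(hh$reported_min - 69), 1)
  expect_equal(hh$reported_max, 100)
  expect_lte(abs(get("Mariner-1_Tbel", "PBa")$reported_max - 43), 1)
  expect_lte(abs(get("Mariner-1_Tbel", "HSa")$reported_max - 50), 1)
  bt <- get("Mariner1_BT", "BT")        # 90 to 85
  expect_lte(abs(bt$reported_min - 85), 1)
  expect_equal(bt$reported_max, 90)
  tt <- get("Mariner1_BT", "TTr")       # 90 to 63
  expect_lte(abs(tt$reported_min - 63), 1)
  expect_equal(tt$reported_max, 90)
})

test_that("date_all handles empty input and missing calibrations", {
  empty <- date_all(mariner_divergences()[0, ], mariner_calibrations())
  expect_equal(nrow(empty), 0)
  fams <- tibble::tibble(family = "X", genome = "nowhere", divergence_pct = 5)
  expect_error(date_all(fams, mariner_calibrations()), "nowhere")
})

test_that("dating recovers a simulated relative age of half the calibration", {
  # focal burst at 50 MYA, calibration at 100 MYA, same clock
  ests <- vapply(1:10, function(i) {
    cal <- simulate_burst(burst_scenario(ancestral_length = 2000,
                                         burst_age = 100, copy_count = 50,
                                         rate = 0.002, seed = 100 + i),
                          family = "cal")
    foc <- simulate_burst(burst_scenario(ancestral_length = 2000,
                                         burst_age = 50, copy_count = 50,
                                         rate = 0.002, seed = 200 + i),
                          family = "foc")
    d_cal <- 100 * mean(tidy(cal)$d)
    d_foc <- 100 * mean(tidy(foc)$d)
    win <- calibration_window("cal", "g", 100, 100)
    estimate_age_range(d_foc, d_cal, win)$raw_max
  }, numeric(1))
  se <- stats::sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 50), 3 * se + 0.05 * 50)
})
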