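ifr_series <- function(times, rates) {
  structure(list(times = times, rates = rates), class = "ifr_series")
}

test_that("dynamic index is peak ramp-end rate minus the rate 0.5 s into the hold", {
  fx <- force_truth_trial()
  re <- fx$trial$ramp_end_time_s
  ifr <- ifr_series(
    times = c(re - 0.4, re - 0.05, re + 0.2, re + 0.5),
    rates = c(55, 100, 70, 40)
  )
  res <- dynamic_index(fx$trial, ifr)
  expect_equal(res$di, 60)
  expect_equal(res$peak_ifr_ramp_end, 100)
  expect_equal(res$ifr_at_hold, 40)
  expect_equal(as.character(res$velocity_bin), "10-20")

  # constant-rate train: DI = 0
  flat <- ifr_series(times = c(re - 0.1, re + 0.3, re + 0.5),
                     rates = c(30, 30, 30))
  expect_equal(dynamic_index(fx$trial, flat)$di, 0)

  # invariant to adding a constant rate
  up <- ifr_series(ifr$times, ifr$rates + 17)
  expect_equal(dynamic_index(fx$trial, up)$di, 60)
})

test_that("dynamic index refuses holds shorter than 0.5 s and sawtooths", {
  short <- make_truth_trial(peak_velocity = 20, peak_accel = 1400)
  tr <- short$trial
  tr$ramp_end_time_s <- tr$t[length(tr$t)] - 0.2 # pretend late ramp end
  ifr <- compute_ifr(tr$spike_times)
  expect_error(dynamic_index(tr, ifr), "not computable")
  saw <- make_truth_trial(stretch_type = "sawtooth")
  expect_error(dynamic_index(saw$trial, compute_ifr(saw$trial$spike_times)),
               "ramp-hold-release")
})

test_that("initial-burst detection is confined to the onset transient", {
  dyn <- force_truth_trial()
  ifr <- compute_ifr(dyn$trial$spike_times)
  ib <- detect_initial_burst(dyn$trial, ifr, dyn$channels)
  # window ends at the first acceleration zero-crossing, well before release
  expect_lt(ib$window_s["end"], dyn$trial$ramp_end_time_s)
  expect_gt(ib$window_s["start"], 4.9)
  expect_false(ib$no_spikes)
  # the release acceleration peak produces no burst event: the detected
  # peak dF/dt belongs to the onset window, not the (larger-|a|) release
  expect_lt(ib$window_s["end"], dyn$trial$ramp_end_time_s)

  # without a dF/dt pathway there is no onset burst above the ramp rate
  flat_truth <- spindle_truth("force", k = c(30, 0), b = c(0.3, 0),
                              lambda_ms = 10)
  flat <- make_truth_trial(flat_truth)
  ib0 <- detect_initial_burst(flat$trial, compute_ifr(flat$trial$spike_times),
                              flat$channels)
  expect_lt(ib0$iba, 0.5 * ib$iba)
})

test_that("initial-burst amplitude grows with onset acceleration", {
  lo <- make_truth_trial(peak_accel = 700)
  hi <- make_truth_trial(peak_accel = 1400)
  iba_lo <- detect_initial_burst(lo$trial, compute_ifr(lo$trial$spike_times),
                                 lo$channels)$iba
  iba_hi <- detect_initial_burst(hi$trial, compute_ifr(hi$trial$spike_times),
                                 hi$channels)$iba
  expect_gt(iba_hi, iba_lo)
})

test_that("burst regression matches ordinary least squares", {
  x <- c(1, 2, 3)
  y <- c(2, 4, 7)
  # replicate to reach the 12-trial minimum without changing the line fit
  reg <- iba_regression(rep(y, 4), rep(x, 4))
  expect_equal(reg$slope, 2.5)
  expect_equal(reg$intercept, -2 / 3, tolerance = 1e-10)
  expect_equal(reg$r2, 0.98684, tolerance = 1e-4)
  expect_lt(reg$p, 0.05)

  # closed-form normal-equations oracle on random inputs
  set.seed(42)
  for (i in 1:20) {
    xx <- rnorm(15, sd = runif(1, 0.5, 5))
    yy <- 2 * xx + rnorm(15)
    r <- iba_regression(yy, xx)
    slope_cf <- sum((xx - mean(xx)) * (yy - mean(yy))) / sum((xx - mean(xx))^2)
    intercept_cf <- mean(yy) - slope_cf * mean(xx)
    expect_equal(r$slope, slope_cf, tolerance = 1e-10)
    expect_equal(r$intercept, intercept_cf, tolerance = 1e-10)
    expect_equal(r$r2, 1 - sum((yy - slope_cf * xx - intercept_cf)^2) /
                   sum((yy - mean(yy))^2), tolerance = 1e-10)
  }

  expect_error(iba_regression(1:10, 1:10), "at least 12")
  expect_error(iba_regression(rnorm(12), rep(1, 12)), "degenerate")
  # collinear points: perfect fit (lm warns that the fit is exact)
  perfect <- suppressWarnings(iba_regression(2 * (1:12) + 1, 1:12))
  expect_equal(perfect$r2, 1)
  expect_lt(perfect$p, 1e-12)
  # shuffling the pairing of a collinear set destroys the relation
  set.seed(7)
  shuffled <- iba_regression(2 * (1:12) + 1, sample(1:12))
  expect_lt(shuffled$r2, 0.3)
})

test_that("the metrics table binds DI and burst statistics per trial", {
  ds <- small_dataset()
  af <- ds$afferents$dyn
  m <- spindle_metrics(af$trials, af$channels)
  expect_equal(nrow(m), length(af$trials))
  expect_true(all(!is.na(m$di[m$stretch_type == "ramp_hold_release"])))
  expect_true(all(is.na(m$di[m$stretch_type == "sawtooth"])))
  # DI increases with stretch velocity for this dynamic afferent
  d10 <- mean(m$di[m$peak_velocity_mm_s == 10], na.rm = TRUE)
  d40 <- mean(m$di[m$peak_velocity_mm_s == 40], na.rm = TRUE)
  expect_gt(d40, d10)
})
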