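test_that("IFR is the reciprocal ISI assigned at the later spike", {
  ifr <- compute_ifr(c(0.1, 0.2, 0.3))
  expect_equal(ifr$rates, c(10, 10))
  expect_equal(ifr$times, c(0.2, 0.3))

  ifr2 <- compute_ifr(c(0.0, 0.05, 0.15))
  expect_equal(ifr2$rates, c(20, 10))

  # evenly spaced train: exactly 1/delta everywhere
  sp <- seq(0, 2, by = 0.025)
  expect_equal(compute_ifr(sp)$rates, rep(40, length(sp) - 1))

  empty <- compute_ifr(0.4)
  expect_length(empty$rates, 0)
  expect_length(empty$times, 0)
  expect_error(compute_ifr(c(0.1, 0.1, 0.2)), "duplicate")
  expect_error(compute_ifr(c(0.2, 0.1)), "sorted")
})

test_that("differentiation uses central differences with one-sided ends", {
  expect_equal(differentiate(rep(5, 10), 100), rep(0, 10))
  t <- (0:99) / 2000
  expect_equal(differentiate(2 * t, 2000), rep(2, 100), tolerance = 1e-10)
  d <- differentiate(c(0, 1, 4, 9), 1)
  expect_equal(d[2:3], c(2, 4)) # hand central differences
  expect_equal(d[1], 1)
  expect_equal(d[4], 5)
  expect_error(differentiate(c(1, 2), 10), "3 samples")
})

test_that("differentiating a trapezoid-integrated smooth signal recovers it", {
  fs <- 2000
  t <- (0:7999) / fs
  x <- sin(2 * pi * 3 * t) + 0.5 * cos(2 * pi * 7 * t)
  xi <- cumsum(c(0, (x[-1] + x[-length(x)]) / 2)) / fs
  xr <- differentiate(xi, fs)
  interior <- 10:7990
  expect_lt(max(abs(xr[interior] - x[interior])) / max(abs(x)), 1e-3)
})

test_that("zero-phase low-pass preserves DC and attenuates far-band input", {
  x <- rep(3.7, 1500)
  y <- lowpass(x, 50, 2000)
  expect_lt(max(abs(y - 3.7)) / 3.7, 1e-9)
  # idempotent on constants
  expect_lt(max(abs(lowpass(y, 50, 2000) - 3.7)) / 3.7, 1e-9)

  t <- (0:3999) / 2000
  s <- sin(2 * pi * 250 * t) # 5x the cutoff
  out <- lowpass(s, 50, 2000)
  expect_lt(sqrt(mean(out^2)), 0.05 * sqrt(mean(s^2)))

  # passband phase: a slow sinusoid passes essentially unchanged
  slow <- sin(2 * pi * 2 * t)
  expect_lt(max(abs(lowpass(slow, 50, 2000) - slow)), 0.02)

  expect_error(lowpass(x, 1000, 2000), "Nyquist")
  expect_error(lowpass(x, 0, 2000), "Nyquist")
})

test_that("channel cutoffs follow the recording convention", {
  fx <- force_truth_trial()
  cut <- fx$channels$cutoffs_hz
  expect_equal(unname(cut["force"]), 50)
  expect_equal(unname(cut["dfdt"]), 100)
  expect_equal(unname(cut["velocity"]), 40)
  expect_equal(unname(cut["accel"]), 40)
})

test_that("lag shifting delays by whole samples with held leading edge", {
  x <- sin((1:100) / 7)
  expect_identical(lag_shift(x, 0, 2000), x)
  s2 <- lag_shift(x, 1, 2000) # 2 samples at 2 kHz
  expect_equal(s2[3:100], x[1:98])
  expect_equal(s2[1:2], rep(x[1], 2))
  s30 <- lag_shift(x, 15, 2000)
  expect_equal(s30[1:30], rep(x[1], 30))
  expect_equal(s30[31:100], x[1:70])
  # composition
  expect_equal(lag_shift(lag_shift(x, 3, 2000), 4, 2000),
               lag_shift(x, 7, 2000))
  expect_error(lag_shift(x, 0.3, 2000), "whole number")
})

test_that("trial QC requires 50 spikes and honors the exclusion flag", {
  t <- (0:4000) / 2000
  mk <- function(n_spk, flag = FALSE) {
    trial_record("t", "a", t, rep(0, length(t)), rep(0.1, length(t)),
                 seq(0.1, 1.9, length.out = n_spk), exclude_flag = flag)
  }
  expect_false(trial_qc(mk(49))$include)
  expect_true(trial_qc(mk(50))$include)
  expect_true(trial_qc(mk(500))$include)
  expect_false(trial_qc(mk(500, flag = TRUE))$include)
})

test_that("afferent QC requires 40 passing trials", {
  t <- (0:4000) / 2000
  mk <- function(n_spk) {
    trial_record("t", "a", t, rep(0, length(t)), rep(0.1, length(t)),
                 seq(0.1, 1.9, length.out = n_spk))
  }
  good <- mk(60)
  bad <- mk(10)
  expect_false(afferent_qc(c(replicate(39, good, simplify = FALSE),
                             list(bad)))$include)
  expect_true(afferent_qc(replicate(40, good, simplify = FALSE))$include)
  expect_true(afferent_qc(replicate(120, good, simplify = FALSE))$include)
  expect_error(afferent_qc(list()), "empty")
})

test_that("trial records validate their invariants", {
  t <- (0:100) / 2000
  x <- rep(0, 101)
  expect_error(trial_record("t", "a", t, x[-1], x, numeric(0)), "match")
  expect_error(trial_record("t", "a", rev(t), x, x, numeric(0)),
               "increasing")
  expect_error(trial_record("t", "a", t, x, x, c(10)), "span")
  expect_error(trial_record("t", "a", t, x, x, numeric(0), fs = -1),
               "positive")
})
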