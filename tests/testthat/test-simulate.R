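test_that("length profiles realize the requested kinematic peaks", {
  p <- stretch_protocol("ramp_hold_release", 3, 20, 1400)
  prof <- make_length_profile(p)
  v <- differentiate(prof$length_mm, p$fs)
  a <- differentiate(v, p$fs)
  expect_lt(abs(max(v) - 20), 0.1)
  expect_lt(abs(max(a) - 1400) / 1400, 0.01)
  expect_equal(max(prof$length_mm), 3, tolerance = 1e-9)
  # isometric hold: no length change between ramp end and release
  hold <- prof$t > prof$ramp_end_time_s + 0.01 &
    prof$t < prof$ramp_end_time_s + p$hold_s - 0.01
  expect_lt(diff(range(prof$length_mm[hold])), 1e-9)
})

test_that("matched-velocity profiles differ only in their onset acceleration", {
  p700 <- stretch_protocol("ramp_hold_release", 3, 20, 700)
  p1400 <- stretch_protocol("ramp_hold_release", 3, 20, 1400)
  v700 <- differentiate(make_length_profile(p700)$length_mm, 2000)
  v1400 <- differentiate(make_length_profile(p1400)$length_mm, 2000)
  expect_equal(max(v700), max(v1400), tolerance = 1e-6)
  a700 <- max(differentiate(v700, 2000))
  a1400 <- max(differentiate(v1400, 2000))
  expect_lt(abs(a700 - 700) / 700, 0.01)
  expect_lt(abs(a1400 - 1400) / 1400, 0.01)
})

test_that("kinematically impossible protocols are rejected", {
  expect_error(
    make_length_profile(stretch_protocol("ramp_hold_release", 1, 50, 200)),
    "infeasible"
  )
  expect_error(stretch_protocol("ramp_hold_release", 3, 20, 1400, rest_s = 2),
               "rest_s")
})

test_that("quiescent muscle relaxes to its elastic operating point", {
  # hold a constant length: cross-bridge force decays, leaving rest tension
  L <- rep(0, 5 * 2000)
  f <- simulate_force(L, muscle_force_params(), fs = 2000)
  expect_equal(f[length(f)], 0.1, tolerance = 1e-6)
  expect_lt(max(abs(diff(f))), 1e-6)
})

test_that("simulated force carries the four history-dependence signatures", {
  params <- muscle_force_params()
  # (a) onset dF/dt transient after rest beats mid-ramp dF/dt (>1.5x)
  # (b) monotone force decay during the hold
  for (p in list(stretch_protocol("ramp_hold_release", 3, 20, 1400),
                 stretch_protocol("ramp_hold_release", 2, 4, 200))) {
    prof <- make_length_profile(p)
    f <- simulate_force(prof$length_mm, params)
    shell <- trial_record("t", "a", prof$t, prof$length_mm, f, numeric(0),
                          stretch_type = "ramp_hold_release",
                          ramp_end_time_s = prof$ramp_end_time_s)
    ch <- derive_channels(shell, fascicle = FALSE)
    i_on <- which(ch$x[, "velocity"] > 0.5)[1]
    onset <- max(ch$x[i_on:(i_on + 100), "dfdt"]) # first 50 ms
    t_mid <- p$rest_s + (prof$ramp_end_time_s - p$rest_s) / 2
    mid <- ch$x[which.min(abs(prof$t - t_mid)), "dfdt"]
    expect_gt(onset, 1.5 * mid)
    hold <- prof$t > prof$ramp_end_time_s + 0.005 &
      prof$t < prof$ramp_end_time_s + p$hold_s - 0.005
    expect_true(all(diff(f[hold]) <= 1e-12))
  }
  # (c) first sawtooth stretch develops the greatest peak force
  ps <- stretch_protocol("sawtooth", 3, 20, 1400)
  profs <- make_length_profile(ps)
  fsaw <- simulate_force(profs$length_mm, params)
  cyc <- 2 * (profs$ramp_end_time_s - ps$rest_s)
  peaks <- vapply(0:4, function(i) {
    idx <- profs$t >= ps$rest_s + i * cyc & profs$t < ps$rest_s + (i + 1) * cyc
    max(fsaw[idx])
  }, numeric(1))
  expect_true(all(peaks[1] > peaks[-1]))
  # (d) higher onset acceleration yields a higher onset dF/dt peak
  onset_dfdt <- vapply(c(700, 1400), function(acc) {
    p <- stretch_protocol("ramp_hold_release", 3, 20, acc)
    prof <- make_length_profile(p)
    f <- simulate_force(prof$length_mm, params)
    shell <- trial_record("t", "a", prof$t, prof$length_mm, f, numeric(0),
                          stretch_type = "ramp_hold_release",
                          ramp_end_time_s = prof$ramp_end_time_s)
    ch <- derive_channels(shell, fascicle = FALSE)
    i_on <- which(ch$x[, "velocity"] > 0.5)[1]
    max(ch$x[i_on:(i_on + 100), "dfdt"])
  }, numeric(1))
  expect_gt(onset_dfdt[2], onset_dfdt[1])
})

test_that("deterministic spiking emits the exact-rate train", {
  sp <- generate_spikes(rep(10, 2001), 2000, "deterministic")
  expect_length(sp, 10)
  expect_equal(diff(sp), rep(0.1, 9), tolerance = 1e-9)
  # doubling the rate halves the mean ISI
  sp2 <- generate_spikes(rep(20, 2001), 2000, "deterministic")
  expect_equal(mean(diff(sp2)), mean(diff(sp)) / 2, tolerance = 1e-6)
  # the IFR samples a time-varying rate exactly at the spike times
  fx <- force_truth_trial()
  ifr <- compute_ifr(fx$trial$spike_times)
  r_at <- stats::approx(fx$channels$t, fx$rate, xout = ifr$times)$y
  expect_lt(stats::quantile(abs(ifr$rates - r_at) / r_at, 0.9), 1e-3)
  expect_length(generate_spikes(rep(0, 1000), 2000, "deterministic"), 0)
})

test_that("poisson spiking reproduces Poisson count statistics at shape 1", {
  sp <- generate_spikes(rep(10, 100 * 2000 + 1), 2000, "poisson", seed = 42)
  # 1000 expected; 3 sigma ~ 95
  expect_gt(length(sp), 1000 - 95)
  expect_lt(length(sp), 1000 + 95)
  # same seed, same train; different seed, different train
  sp_a <- generate_spikes(rep(30, 4001), 2000, "poisson", seed = 9)
  sp_b <- generate_spikes(rep(30, 4001), 2000, "poisson", seed = 9)
  expect_identical(sp_a, sp_b)
  expect_false(identical(sp_a, generate_spikes(rep(30, 4001), 2000,
                                               "poisson", seed = 10)))
  # larger shape: more regular train at the same rate
  cv_of <- function(shape) {
    s <- generate_spikes(rep(50, 60 * 2000), 2000, "poisson", seed = 3,
                         shape = shape)
    stats::sd(diff(s)) / mean(diff(s))
  }
  expect_lt(cv_of(50), 0.25)
  expect_gt(cv_of(1), 0.8)
})

test_that("generated datasets are QC-clean and bit-stable", {
  ds <- small_dataset()
  af <- ds$afferents$dyn
  expect_true(all(vapply(af$trials, function(tr) trial_qc(tr)$include,
                         logical(1))))
  expect_true(afferent_qc(af$trials)$include)
  ds2 <- make_dataset(list(dyn = truth_force_dynamic()),
                      trials_per_afferent = 42, seed = 3)
  expect_identical(
    lapply(af$trials, `[[`, "spike_times"),
    lapply(ds2$afferents$dyn$trials, `[[`, "spike_times")
  )
  # poisson afferents are reproducible through the master seed too
  mk <- function() make_dataset(
    list(p = truth_force_dynamic(spike_mode = "poisson")),
    trials_per_afferent = 40, seed = 8,
    protocols = default_protocol_grid()[seq(1, 40, by = 4)]
  )
  expect_identical(lapply(mk()$afferents$p$trials, `[[`, "spike_times"),
                   lapply(mk()$afferents$p$trials, `[[`, "spike_times"))
})

test_that("dynamic-index ordering follows the ground-truth dF/dt weight", {
  protos <- default_protocol_grid()[seq(1, 40, by = 4)]
  truths <- list(
    low = spindle_truth("force", k = c(30, 0.2), b = c(0.3, 0)),
    mid = spindle_truth("force", k = c(30, 0.7), b = c(0.3, 0)),
    high = spindle_truth("force", k = c(30, 1.4), b = c(0.3, 0))
  )
  ds <- make_dataset(truths, trials_per_afferent = 40, seed = 13,
                     protocols = protos)
  mean_di <- vapply(ds$afferents, function(af) {
    m <- spindle_metrics(af$trials, af$channels)
    mean(m$di, na.rm = TRUE)
  }, numeric(1))
  expect_true(mean_di["low"] < mean_di["mid"])
  expect_true(mean_di["mid"] < mean_di["high"])
})
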