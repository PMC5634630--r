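fake_channels <- function(force, dfdt = rep(0, length(force)), fs = 2000) {
  structure(
    list(t = (seq_along(force) - 1) / fs, fs = fs,
         x = cbind(force = force, dfdt = dfdt),
         cutoffs_hz = c(force = 50, dfdt = 100)),
    class = "derived_channels"
  )
}

test_that("model specs fix the predictor sets and parameter counts", {
  expect_equal(model_spec("force")$predictors, c("force", "dfdt"))
  expect_equal(model_spec("force")$n_params, 4)
  expect_length(model_spec("all")$predictors, 11)
  expect_equal(model_spec("all")$n_params, 22)
  expect_equal(model_spec("length_power")$n_params, 7)
  expect_true(model_spec("force")$competing_allowed)
  expect_false(model_spec("length")$competing_allowed)
})

test_that("pseudolinear prediction follows both rectification conventions", {
  ch <- fake_channels(c(-1, 0, 2))
  pars <- model_params(k = c(3, 0), b = c(1, 0), lambda_ms = 0)
  t_eval <- ch$t
  printed <- predict_ifr(pars, ch, t_eval,
                         config = spindle_config(model = list(rectify_order = "as_printed")))
  expect_equal(printed, c(3, 3, 9)) # rectify, then offset, then weight
  thresh <- predict_ifr(pars, ch, t_eval,
                        config = spindle_config(model = list(rectify_order = "threshold")))
  expect_equal(thresh, c(0, 3, 9)) # offset acts as rectification threshold
  # all-zero parameters give an all-zero prediction
  zero <- predict_ifr(model_params(c(0, 0), c(0, 0)), ch, t_eval)
  expect_equal(zero, c(0, 0, 0))
})

test_that("prediction is positively homogeneous in the weights at zero offset", {
  fx <- force_truth_trial()
  t_eval <- fx$trial$spike_times[10:60]
  p1 <- model_params(c(10, 0.5), c(0, 0), lambda_ms = 5)
  p2 <- model_params(c(20, 1.0), c(0, 0), lambda_ms = 5)
  expect_equal(2 * predict_ifr(p1, fx$channels, t_eval, model_spec("force")),
               predict_ifr(p2, fx$channels, t_eval, model_spec("force")))
})

test_that("the model lag equals pre-shifting the channels", {
  fx <- force_truth_trial()
  t_eval <- fx$trial$spike_times[20:80]
  pars_lag <- model_params(c(30, 1.2), c(0.3, 0), lambda_ms = 1)
  with_lag <- predict_ifr(pars_lag, fx$channels, t_eval, model_spec("force"))
  shifted <- fx$channels
  shifted$x <- apply(fx$channels$x, 2, lag_shift, lambda_ms = 1, fs = 2000)
  pars0 <- model_params(c(30, 1.2), c(0.3, 0), lambda_ms = 0)
  expect_equal(predict_ifr(pars0, shifted, t_eval, model_spec("force")),
               with_lag)
})

test_that("competing influences zero the smaller component", {
  # dF/dt component identically zero: competing equals plain
  ch0 <- fake_channels(c(0.5, 1, 2), dfdt = c(0, 0, 0))
  pars <- model_params(k = c(10, 5), b = c(0, 0))
  expect_equal(competing_predict(pars, ch0, ch0$t),
               predict_ifr(pars, ch0, ch0$t, model_spec("force")))
  # components 10 vs 25 at one sample: the larger one survives
  ch <- fake_channels(force = 1, dfdt = 5)
  pars2 <- model_params(k = c(10, 5), b = c(0, 0)) # components 10 and 25
  expect_equal(competing_predict(pars2, ch, 0), 25)
  # exact tie keeps the force component
  ch_tie <- fake_channels(force = 1, dfdt = 2)
  pars3 <- model_params(k = c(10, 5), b = c(0, 0)) # components 10 and 10
  expect_equal(competing_predict(pars3, ch_tie, 0), 10)
})

test_that("competing output never exceeds the plain output", {
  fx <- force_truth_trial()
  t_eval <- fx$trial$spike_times[-1]
  pars <- model_params(c(30, 1.2), c(0.3, 0.5), lambda_ms = 10)
  plain <- predict_ifr(pars, fx$channels, t_eval, model_spec("force"))
  comp <- competing_predict(pars, fx$channels, t_eval)
  expect_true(all(comp <= plain + 1e-12))
})

test_that("variant choice requires a strictly better competing mean R2", {
  expect_equal(choose_competing(c(a = 0.75), c(a = 0.80)), "competing")
  expect_equal(choose_competing(c(0.8, 0.8), c(0.8, 0.8)), "plain")
  expect_equal(choose_competing(0.8, 0.75), "plain")
  expect_error(choose_competing(c(0.1, 0.2), 0.3), "same observation sets")
})

test_that("the fractional-power model reduces to the length model at a = 1", {
  fx <- force_truth_trial()
  t_eval <- fx$trial$spike_times[10:100]
  k <- c(12, 1.4, 0.01)
  b <- c(0.2, 0, 0)
  plain <- predict_ifr(model_params(k, b, lambda_ms = 5), fx$channels,
                       t_eval, model_spec("length"))
  pow <- predict_ifr(model_params(k, b, lambda_ms = 5, a = 1), fx$channels,
                     t_eval, model_spec("length_power"))
  # identical where velocity is non-negative; rectified-velocity base
  # otherwise, so compare on a positive-velocity window
  vel <- spindlefit:::channel_design(fx$channels, "velocity", t_eval, 5)
  pos <- vel[, 1] >= 0
  expect_equal(pow[pos], plain[pos])
})

test_that("fascicle predictors approach musculotendon predictors for a stiff tendon", {
  fx <- force_truth_trial()
  cfg_rigid <- spindle_config(tendon = list(compliance_high_per_mm = 1e6))
  ch <- derive_channels(fx$trial, cfg_rigid)
  t_eval <- fx$trial$spike_times[10:100]
  k <- c(12, 1.4, 0.01)
  b <- c(0.2, 0, 0)
  mt <- predict_ifr(model_params(k, b), ch, t_eval, model_spec("length"))
  fa <- predict_ifr(model_params(k, b), ch, t_eval, model_spec("fascicle_high"))
  expect_equal(fa, mt, tolerance = 1e-3)
})
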