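# Shared synthetic fixtures. Heavy objects are built once per test run and
# cached; every fixture is generated in code from fixed seeds.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

test_config <- function(...) spindle_config(...)

# One ramp-hold-release trial with spikes from a ground-truth encoder.
make_truth_trial <- function(truth = truth_force_dynamic(),
                             peak_length = 3, peak_velocity = 20,
                             peak_accel = 1400,
                             stretch_type = "ramp_hold_release",
                             config = spindle_config(),
                             force_params = muscle_force_params(),
                             seed = NULL) {
  p <- stretch_protocol(stretch_type, peak_length, peak_velocity, peak_accel)
  prof <- make_length_profile(p)
  f <- simulate_force(prof$length_mm, force_params)
  shell <- trial_record(
    "trial", "afferent", prof$t, prof$length_mm, f, numeric(0),
    stretch_type = stretch_type, peak_length_mm = peak_length,
    peak_velocity_mm_s = peak_velocity, peak_accel_mm_s2 = peak_accel,
    ramp_end_time_s = prof$ramp_end_time_s
  )
  channels <- derive_channels(shell, config)
  rate <- truth_rate(truth, channels, config)
  spikes <- if (truth$spike_mode == "deterministic") {
    generate_spikes(rate, p$fs, "deterministic")
  } else {
    generate_spikes(rate, p$fs, "poisson", seed = seed,
                    shape = truth$isi_shape)
  }
  trial <- trial_record(
    "trial", "afferent", prof$t, prof$length_mm, f, spikes,
    stretch_type = stretch_type, peak_length_mm = peak_length,
    peak_velocity_mm_s = peak_velocity, peak_accel_mm_s2 = peak_accel,
    ramp_end_time_s = prof$ramp_end_time_s
  )
  list(trial = trial, channels = channels, rate = rate, profile = prof)
}

# Canonical noiseless force-truth trial used by several fitting tests.
force_truth_trial <- function() {
  cached("force_truth_trial", function() make_truth_trial())
}

# 20-trial recovery fixture (spec-scale): diverse protocols, one truth.
recovery_trials <- function(truth, seed) {
  key <- sprintf("recovery_%s_%d", truth$spike_mode, seed)
  cached(key, function() {
    protos <- default_protocol_grid()[seq(1, 40, by = 2)]
    ds <- make_dataset(stats::setNames(list(truth), "afX"),
                       trials_per_afferent = 40, seed = seed,
                       protocols = protos)
    af <- ds$afferents$afX
    list(trials = af$trials[1:20], channels = af$channels[1:20])
  })
}

# Compact dataset for metrics / small-pipeline tests.
small_dataset <- function() {
  cached("small_dataset", function() {
    make_dataset(list(dyn = truth_force_dynamic()),
                 trials_per_afferent = 42, seed = 3)
  })
}

# Full-scale selection runs shared by the model-selection and nesting
# checks: 120 trials per afferent (30 test trials per split) and the full
# 100-iteration cross-validation over all six candidates.
force_truth_cv <- function() {
  cached("force_truth_cv", function() {
    ds <- make_dataset(list(af_force = truth_force_dynamic()),
                       trials_per_afferent = 120, seed = 1)
    cross_validate(ds$afferents$af_force, seed = 101)
  })
}

length_truth_cv <- function() {
  cached("length_truth_cv", function() {
    # history-dependence off: purely elastic muscle (k_xb = 0)
    ds <- make_dataset(list(af_len = truth_length()),
                       trials_per_afferent = 120, seed = 2,
                       force_params = muscle_force_params(k_xb = 0))
    cross_validate(ds$afferents$af_len, seed = 202)
  })
}
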