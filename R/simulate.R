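#' Stretch protocol description
#'
#' @param stretch_type `"ramp_hold_release"` or `"sawtooth"`.
#' @param peak_length_mm peak length change (mm), 1--4.
#' @param peak_velocity_mm_s plateau velocity (mm/s), 4--50.
#' @param peak_accel_mm_s2 ramp acceleration (mm/s^2), 200--3500.
#' @param hold_s hold duration for ramp-hold-release (s), default 1.
#' @param n_repeats number of back-to-back ramp-release triangles for
#'   sawtooth stretches, default 5.
#' @param rest_s isometric rest preceding the stretch (s), at least 5.
#' @param post_s quiet recording appended after the stretch (s), default 1.
#' @param fs sampling rate (Hz), default 2000.
#' @return An object of class `stretch_protocol`.
#' @export
stretch_protocol <- function(stretch_type = c("ramp_hold_release", "sawtooth"),
                             peak_length_mm, peak_velocity_mm_s,
                             peak_accel_mm_s2, hold_s = 1, n_repeats = 5,
                             rest_s = 5, post_s = 1, fs = 2000) {
  stretch_type <- match.arg(stretch_type)
  stopifnot(
    peak_length_mm >= 1, peak_length_mm <= 4,
    peak_velocity_mm_s >= 4, peak_velocity_mm_s <= 50,
    peak_accel_mm_s2 >= 200, peak_accel_mm_s2 <= 3500,
    rest_s >= 5, fs > 0
  )
  structure(
    list(
      stretch_type = stretch_type,
      peak_length_mm = peak_length_mm,
      peak_velocity_mm_s = peak_velocity_mm_s,
      peak_accel_mm_s2 = peak_accel_mm_s2,
      hold_s = hold_s,
      n_repeats = as.integer(n_repeats),
      rest_s = rest_s,
      post_s = post_s,
      fs = fs
    ),
    class = "stretch_protocol"
  )
}

# One acceleration-limited trapezoidal-velocity ramp of duration t_ramp:
# accelerate at +a to v, cruise, decelerate at -a to rest, covering L mm.
ramp_piece <- function(tt, L, v, a) {
  t_a <- v / a
  d_a <- v^2 / (2 * a)
  d_c <- L - 2 * d_a
  t_c <- d_c / v
  t_ramp <- 2 * t_a + t_c
  y <- numeric(length(tt))
  ph1 <- tt <= t_a
  ph2 <- tt > t_a & tt <= t_a + t_c
  ph3 <- tt > t_a + t_c & tt <= t_ramp
  ph4 <- tt > t_ramp
  y[ph1] <- a * tt[ph1]^2 / 2
  y[ph2] <- d_a + v * (tt[ph2] - t_a)
  y[ph3] <- L - a * (t_ramp - tt[ph3])^2 / 2
  y[ph4] <- L
  y
}

#' Generate the length profile of a stretch protocol
#'
#' Ramps are acceleration-limited with a trapezoidal velocity profile, so
#' the protocol's peak velocity and peak acceleration are both realized
#' exactly (before filtering). Sawtooth stretches concatenate
#' ramp-up/ramp-down triangles with no hold in between. The profile is
#' preceded by the protocol's isometric rest and followed by `post_s` of
#' quiet.
#'
#' @param protocol a [stretch_protocol()].
#' @return List with `t` (s), `length_mm` (0 at rest),
#'   `ramp_end_time_s` (end of the first ramp-up), and `protocol`.
#' @export
make_length_profile <- function(protocol) {
  stopifnot(inherits(protocol, "stretch_protocol"))
  L <- protocol$peak_length_mm
  v <- protocol$peak_velocity_mm_s
  a <- protocol$peak_accel_mm_s2
  fs <- protocol$fs
  if (v^2 / a > L) {
    stop(sprintf(
      "infeasible protocol: velocity %g mm/s unreachable within %g mm at %g mm/s^2",
      v, L, a
    ))
  }
  t_ramp <- 2 * (v / a) + (L - v^2 / a) / v
  move_dur <- switch(protocol$stretch_type,
    ramp_hold_release = 2 * t_ramp + protocol$hold_s,
    sawtooth = 2 * t_ramp * protocol$n_repeats
  )
  total <- protocol$rest_s + move_dur + protocol$post_s
  n <- floor(total * fs) + 1L
  t <- (seq_len(n) - 1L) / fs
  tt <- t - protocol$rest_s # time since movement onset
  y <- numeric(n)
  if (protocol$stretch_type == "ramp_hold_release") {
    up <- tt >= 0 & tt < t_ramp + protocol$hold_s
    y[up] <- ramp_piece(tt[up], L, v, a)
    dn <- tt >= t_ramp + protocol$hold_s
    y[dn] <- L - ramp_piece(tt[dn] - t_ramp - protocol$hold_s, L, v, a)
  } else {
    cyc <- 2 * t_ramp
    inmove <- tt >= 0 & tt < protocol$n_repeats * cyc
    tc <- tt[inmove] %% cyc
    seg <- ifelse(tc < t_ramp, ramp_piece(tc, L, v, a),
                  L - ramp_piece(tc - t_ramp, L, v, a))
    y[inmove] <- seg
  }
  list(
    t = t,
    length_mm = y,
    ramp_end_time_s = protocol$rest_s + t_ramp,
    protocol = protocol
  )
}

#' History-dependent muscle force parameters
#'
#' Phenomenological whole-muscle force: a parallel elastic element plus a
#' Maxwell-slip cross-bridge element whose stiffness re-engages after
#' quiescence. The element reproduces the short-range stiffness transient
#' in dF/dt at stretch onset after rest, force relaxation during holds,
#' and first-stretch force enhancement in sawtooths.
#'
#' @param k_passive parallel elastic stiffness (N/mm), default 0.5.
#' @param k_xb cross-bridge stiffness (N/mm), default 3.
#' @param s0 slip length scale (mm), default 0.2: cross-bridge force
#'   saturates after about this much travel.
#' @param tau isometric detachment/relaxation time constant (s), default 0.5.
#' @param eta thixotropic stiffness gain, default 1: fully rested muscle
#'   has cross-bridge stiffness `k_xb * (1 + eta)`.
#' @param s_r slip travel over which the rested state is destroyed (mm),
#'   default 2.
#' @param tau_rec recovery time constant of the rested state (s), default 5.
#' @param f_rest resting tension (N), default 0.1.
#' @return An object of class `muscle_force_params`.
#' @export
muscle_force_params <- function(k_passive = 0.5, k_xb = 3, s0 = 0.2,
                                tau = 0.5, eta = 1, s_r = 2, tau_rec = 5,
                                f_rest = 0.1) {
  stopifnot(k_passive > 0, k_xb >= 0, s0 > 0, tau > 0, eta >= 0, s_r > 0,
            tau_rec > 0, f_rest > 0)
  structure(
    list(k_passive = k_passive, k_xb = k_xb, s0 = s0, tau = tau, eta = eta,
         s_r = s_r, tau_rec = tau_rec, f_rest = f_rest),
    class = "muscle_force_params"
  )
}

#' Simulate whole-muscle force under an imposed length profile
#'
#' `F(t) = f_rest + k_passive * (L - L0) + F_xb(t)` with the cross-bridge
#' state integrated at the sampling rate:
#' `dF_xb/dt = k_xb * (1 + eta * R) * v - |v| * F_xb / s0 - F_xb / tau`,
#' where the rested-state fraction `R` builds toward 1 during quiescence
#' and is destroyed by movement (`dR/dt = (1 - R)/tau_rec - |v| R / s_r`).
#' The fast slip element gives short-range stiffness and force relaxation;
#' the slow rested state carries first-stretch enhancement across a
#' sawtooth. The measured force is floored at zero: the musculotendon goes
#' slack rather than pushing when rapid shortening drives the model force
#' negative.
#'
#' @param length_mm imposed length series (mm).
#' @param params a [muscle_force_params()].
#' @param fs sampling rate (Hz).
#' @return Force series (N), same length as `length_mm`.
#' @export
simulate_force <- function(length_mm, params = muscle_force_params(),
                           fs = 2000) {
  stopifnot(inherits(params, "muscle_force_params"))
  n <- length(length_mm)
  if (n < 2L) stop("length series too short")
  v <- c(0, diff(length_mm)) * fs
  fxb <- .simulate_xb(v, 1 / fs, params$k_xb, params$s0, params$tau,
                      params$eta, params$s_r, params$tau_rec)
  pmax(params$f_rest + params$k_passive * (length_mm - length_mm[1L]) + fxb, 0)
}

#' Ground-truth spindle encoder
#'
#' Generative twin of a fitted candidate model: the firing rate is the
#' pseudolinear combination of the trial's processed predictor channels,
#' lagged by `lambda_ms` and floored at `rate_floor` (resting discharge).
#'
#' @param model_id candidate model generating the rate (see [model_spec()]).
#' @param k,b weights and offsets per predictor of that model.
#' @param lambda_ms neuromechanical lag (integer ms, 0--15), default 10.
#' @param spike_mode `"deterministic"` (exact-IFR substrate) or
#'   `"poisson"` (stochastic renewal spiking, see [generate_spikes()]).
#' @param rate_floor resting discharge floor (imp/s), default 5.
#' @param isi_shape ISI regularity (gamma shape) used when
#'   `spike_mode = "poisson"`; 1 is a pure Poisson process at constant
#'   rate, the default 50 gives the near-regular discharge (ISI CV about
#'   0.14) characteristic of Ia afferents.
#' @param a velocity exponent when `model_id = "length_power"`.
#' @param competing generate with force and dF/dt as competing influences
#'   (force model only; see [competing_predict()]).
#' @return An object of class `spindle_truth`.
#' @export
spindle_truth <- function(model_id = "force", k, b, lambda_ms = 10,
                          spike_mode = c("deterministic", "poisson"),
                          rate_floor = 5, isi_shape = 50, a = NA_real_,
                          competing = FALSE) {
  spike_mode <- match.arg(spike_mode)
  spec <- model_spec(model_id)
  stopifnot(length(k) == length(spec$predictors),
            length(b) == length(spec$predictors))
  if (competing && !spec$competing_allowed) {
    stop("competing ground truth is defined for the force model only")
  }
  structure(
    list(
      model_id = spec$model_id,
      spec = spec,
      params = model_params(k, b, lambda_ms = lambda_ms, a = a),
      spike_mode = spike_mode,
      rate_floor = rate_floor,
      isi_shape = isi_shape,
      competing = isTRUE(competing)
    ),
    class = "spindle_truth"
  )
}

#' Ground-truth firing rate of a trial
#'
#' @param truth a [spindle_truth()].
#' @param channels [derive_channels()] output for the trial.
#' @param config a [spindle_config()].
#' @return Rate series (imp/s) on the trial grid.
#' @export
truth_rate <- function(truth, channels, config = spindle_config()) {
  stopifnot(inherits(truth, "spindle_truth"))
  fs <- channels$fs
  X <- channels$x[, truth$spec$predictors, drop = FALSE]
  if (truth$spec$has_power) {
    vc <- grep("velocity", colnames(X))
    X[, vc] <- pmax(X[, vc], 0)^truth$params$a
  }
  X <- apply(X, 2L, lag_shift, lambda_ms = truth$params$lambda_ms, fs = fs)
  r <- pseudolinear_eval(X, truth$params$k, truth$params$b,
                         rectify_order = config$model$rectify_order,
                         competing = isTRUE(truth$competing),
                         competing_threshold = config$model$competing_threshold)
  pmax(r, truth$rate_floor)
}

#' Generate a spike train from a rate series
#'
#' Deterministic mode emits the train whose instantaneous firing rate
#' samples the rate exactly: each spike time satisfies
#' `(t_i - t_{i-1}) * r(t_i) = 1` (for a constant rate this is the uniform
#' train of that rate). Poisson mode is the stochastic twin: each
#' inter-spike interval satisfies `(t_i - t_{i-1}) * r(t_i) = G_i` with
#' independent gamma-distributed unit-mean thresholds `G_i` of the given
#' `shape`. For a constant rate with `shape = 1` this is exactly a Poisson
#' process; larger shapes give more regular trains at the same rate
#' profile, and `shape -> Inf` recovers the deterministic rule.
#'
#' @param rate rate series (imp/s), non-negative.
#' @param fs sampling rate (Hz).
#' @param mode `"deterministic"` or `"poisson"`.
#' @param seed integer seed (poisson mode).
#' @param shape gamma shape of the unit thresholds (poisson mode),
#'   default 1.
#' @param t0 time of the first sample (s), default 0.
#' @return Sorted spike times (s).
#' @export
generate_spikes <- function(rate, fs, mode = c("deterministic", "poisson"),
                            seed = NULL, shape = 1, t0 = 0) {
  mode <- match.arg(mode)
  if (any(rate < 0)) stop("rate must be non-negative")
  if (all(rate == 0)) return(numeric(0))
  dt <- 1 / fs
  if (mode == "deterministic") {
    return(as.numeric(.spikes_rate_sampled(rate, dt, t0, numeric(0))))
  }
  lam_max <- sum((rate[-1L] + rate[-length(rate)]) / 2 * dt)
  if (lam_max < .Machine$double.eps) return(numeric(0))
  n_draw <- ceiling(1.5 * lam_max + 10 * sqrt(lam_max / shape) + 20)
  draw <- function() stats::rgamma(n_draw, shape = shape, rate = shape)
  thresholds <- if (is.null(seed)) draw() else with_preserved_rng(seed, draw())
  as.numeric(.spikes_rate_sampled(rate, dt, t0, thresholds))
}

# ---- dataset assembly ------------------------------------------------------

#' Default stretch-protocol grid
#'
#' Enumerates the kinematically feasible combinations of peak length
#' (2, 3 mm), plateau velocity (4--40 mm/s) and ramp acceleration
#' (200--2800 mm/s^2) as ramp-hold-release stretches, plus 3 mm sawtooth
#' stretches at 10 and 20 mm/s, mirroring the diversity of the recorded
#' protocols.
#'
#' @param fs sampling rate (Hz).
#' @return List of [stretch_protocol()] objects.
#' @export
default_protocol_grid <- function(fs = 2000) {
  protos <- list()
  for (L in c(2, 3)) {
    for (v in c(4, 10, 20, 30, 40)) {
      for (a in c(200, 700, 1400, 2800)) {
        if (v^2 / a <= L) {
          protos[[length(protos) + 1L]] <- stretch_protocol(
            "ramp_hold_release", L, v, a, fs = fs
          )
        }
      }
    }
  }
  for (v in c(10, 20)) {
    for (a in c(700, 1400)) {
      protos[[length(protos) + 1L]] <- stretch_protocol(
        "sawtooth", 3, v, a, fs = fs
      )
    }
  }
  protos
}

protocol_key <- function(p) {
  sprintf("%s_L%g_v%g_a%g", p$stretch_type, p$peak_length_mm,
          p$peak_velocity_mm_s, p$peak_accel_mm_s2)
}

# Trial template shared across afferents: profile, force, channels.
build_template <- function(protocol, force_params, config) {
  prof <- make_length_profile(protocol)
  force <- simulate_force(prof$length_mm, force_params, fs = protocol$fs)
  tmp_trial <- trial_record(
    trial_id = "template", afferent_id = "template",
    t = prof$t, length_mm = prof$length_mm, force_n = force,
    spike_times = numeric(0), fs = protocol$fs,
    stretch_type = protocol$stretch_type,
    peak_length_mm = protocol$peak_length_mm,
    peak_velocity_mm_s = protocol$peak_velocity_mm_s,
    peak_accel_mm_s2 = protocol$peak_accel_mm_s2,
    ramp_end_time_s = prof$ramp_end_time_s
  )
  channels <- derive_channels(tmp_trial, config)
  list(profile = prof, force = force, channels = channels,
       protocol = protocol)
}

#' Generate a synthetic spindle dataset
#'
#' Builds `trials_per_afferent` stretch trials for each ground-truth
#' afferent by cycling deterministically through the protocol grid,
#' simulating history-dependent whole-muscle force, deriving the filtered
#' predictor channels, applying the afferent's ground-truth encoder, and
#' generating spikes. All randomness (poisson spike mode only) flows from
#' `seed`; regeneration with the same arguments is bit-identical.
#'
#' @param truths named list of [spindle_truth()] objects, one per afferent
#'   (names become afferent ids).
#' @param trials_per_afferent trials per afferent, default 120 (at least
#'   40 so afferent-level QC can pass).
#' @param seed master seed, default 1.
#' @param config a [spindle_config()].
#' @param force_params a [muscle_force_params()].
#' @param protocols protocol list, default [default_protocol_grid()].
#' @return An object of class `spindle_dataset`: list with `afferents`
#'   (per afferent: `truth`, `trials`, `channels`), `seed`, `config`.
#' @export
make_dataset <- function(truths, trials_per_afferent = 120, seed = 1,
                         config = spindle_config(),
                         force_params = muscle_force_params(),
                         protocols = default_protocol_grid(config$sampling$fs)) {
  if (is.null(names(truths)) || any(!nzchar(names(truths)))) {
    stop("truths must be a named list (names are afferent ids)")
  }
  if (trials_per_afferent < 40) {
    stop("need at least 40 trials per afferent to satisfy afferent QC")
  }
  templates <- lapply(protocols, build_template, force_params = force_params,
                      config = config)
  names(templates) <- vapply(templates, function(tp) protocol_key(tp$protocol),
                             character(1))
  order_idx <- rep(seq_along(templates),
                   length.out = trials_per_afferent)

  afferents <- with_preserved_rng(seed, {
    lapply(seq_along(truths), function(ai) {
      truth <- truths[[ai]]
      aff_id <- names(truths)[ai]
      trials <- vector("list", trials_per_afferent)
      channels <- vector("list", trials_per_afferent)
      for (ti in seq_len(trials_per_afferent)) {
        tp <- templates[[order_idx[ti]]]
        rate <- truth_rate(truth, tp$channels, config)
        spikes <- if (truth$spike_mode == "deterministic") {
          generate_spikes(rate, tp$protocol$fs, mode = "deterministic")
        } else {
          generate_spikes(rate, tp$protocol$fs, mode = "poisson",
                          shape = truth$isi_shape)
        }
        trials[[ti]] <- trial_record(
          trial_id = sprintf("%s_t%03d_%s", aff_id, ti,
                             protocol_key(tp$protocol)),
          afferent_id = aff_id,
          t = tp$profile$t,
          length_mm = tp$profile$length_mm,
          force_n = tp$force,
          spike_times = spikes,
          fs = tp$protocol$fs,
          stretch_type = tp$protocol$stretch_type,
          peak_length_mm = tp$protocol$peak_length_mm,
          peak_velocity_mm_s = tp$protocol$peak_velocity_mm_s,
          peak_accel_mm_s2 = tp$protocol$peak_accel_mm_s2,
          ramp_end_time_s = tp$profile$ramp_end_time_s
        )
        channels[[ti]] <- tp$channels
      }
      list(afferent_id = aff_id, truth = truth, trials = trials,
           channels = channels)
    })
  })
  names(afferents) <- names(truths)
  structure(
    list(afferents = afferents, seed = seed, config = config,
         force_params = force_params),
    class = "spindle_dataset"
  )
}

#' @export
print.spindle_dataset <- function(x, ...) {
  cat(sprintf(
    "<spindle_dataset: %d afferent(s) x %d trials (seed %s)>\n",
    length(x$afferents), length(x$afferents[[1]]$trials),
    format(x$seed)
  ))
  for (af in x$afferents) {
    cat(sprintf(
      "  %s: %s truth, %s spiking, lag %d ms\n",
      af$afferent_id, af$truth$model_id, af$truth$spike_mode,
      af$truth$params$lambda_ms
    ))
  }
  invisible(x)
}

#' Ground-truth parameter sets used throughout the examples and checks
#'
#' Convenience constructors for the canonical synthetic afferents: a
#' dynamic force-encoding afferent (large dF/dt weight), a static
#' force-encoding afferent, and a length-encoding afferent (for use with a
#' non-history-dependent muscle, `k_xb = 0`).
#'
#' @param spike_mode passed to [spindle_truth()].
#' @return A [spindle_truth()].
#' @name canonical_truths
NULL

#' @rdname canonical_truths
#' @export
truth_force_dynamic <- function(spike_mode = "deterministic") {
  spindle_truth("force", k = c(30, 1.2), b = c(0.3, 0), lambda_ms = 10,
                spike_mode = spike_mode)
}

#' @rdname canonical_truths
#' @export
truth_force_static <- function(spike_mode = "deterministic") {
  spindle_truth("force", k = c(40, 0.25), b = c(0.25, 0), lambda_ms = 10,
                spike_mode = spike_mode)
}

#' @rdname canonical_truths
#' @export
truth_length <- function(spike_mode = "deterministic") {
  spindle_truth("length", k = c(15, 1.5, 0.02), b = c(0.5, 0, 0),
                lambda_ms = 10, spike_mode = spike_mode)
}
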