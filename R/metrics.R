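#' Velocity bin label for a stretch trial
#'
#' Five 10 mm/s bins over 0--50 mm/s.
#'
#' @param peak_velocity_mm_s trial peak velocity (mm/s).
#' @return Factor with levels `"0-10"` ... `"40-50"`.
#' @export
velocity_bin <- function(peak_velocity_mm_s) {
  breaks <- seq(0, 50, by = 10)
  labels <- paste(breaks[-length(breaks)], breaks[-1], sep = "-")
  cut(peak_velocity_mm_s, breaks = breaks, labels = labels,
      include.lowest = TRUE, right = TRUE)
}

#' Dynamic index of a ramp-hold-release trial
#'
#' Classical dynamic-sensitivity metric: the peak IFR in a window ending at
#' the ramp end, minus the IFR measured 0.5 s after the ramp ends (taken
#' from the last spike at or before that instant).
#'
#' @param trial a [trial_record()] of type `ramp_hold_release` with a known
#'   `ramp_end_time_s` and at least 0.5 s of hold.
#' @param ifr the trial's [compute_ifr()] series.
#' @param window_s width of the ramp-end peak window (s), default 0.15,
#'   extended 10 ms past the ramp end to catch the final ramp spike.
#' @return A list with `di` (imp/s), `peak_ifr_ramp_end`, `ifr_at_hold`,
#'   and `velocity_bin`.
#' @export
dynamic_index <- function(trial, ifr, window_s = 0.15) {
  stopifnot(inherits(trial, "trial_record"), inherits(ifr, "ifr_series"))
  if (!identical(trial$stretch_type, "ramp_hold_release")) {
    stop("dynamic index is defined for ramp-hold-release trials")
  }
  ramp_end <- trial$ramp_end_time_s
  if (is.na(ramp_end)) stop("ramp_end_time_s is required")
  t_hold <- ramp_end + 0.5
  t_max <- trial$t[length(trial$t)]
  if (t_hold > t_max) stop("hold shorter than 0.5 s: DI not computable")
  # still holding 0.5 s in? length must not have moved since ramp end
  i_end <- which.min(abs(trial$t - ramp_end))
  i_hold <- which.min(abs(trial$t - t_hold))
  if (abs(trial$length_mm[i_hold] - trial$length_mm[i_end]) > 1e-3) {
    stop("hold shorter than 0.5 s: DI not computable")
  }
  in_ramp_win <- ifr$times >= ramp_end - window_s &
    ifr$times <= ramp_end + 0.01
  if (!any(in_ramp_win)) stop("no IFR samples in the ramp-end window")
  peak <- max(ifr$rates[in_ramp_win])
  at_or_before <- which(ifr$times <= t_hold + 1e-9)
  if (!length(at_or_before)) stop("no IFR sample at or before ramp end + 0.5 s")
  hold_rate <- ifr$rates[max(at_or_before)]
  list(
    di = peak - hold_rate,
    peak_ifr_ramp_end = peak,
    ifr_at_hold = hold_rate,
    velocity_bin = velocity_bin(trial$peak_velocity_mm_s)
  )
}

#' Detect the initial burst of a stretch trial
#'
#' The initial-burst window runs from stretch onset to the first
#' zero-crossing of acceleration after onset (the end of the onset
#' acceleration transient); this restriction keeps the deceleration and
#' release transients out of the burst statistics. The burst amplitude is
#' the peak IFR inside the window, paired with the peak dF/dt and peak
#' acceleration in the same window.
#'
#' @param trial a [trial_record()].
#' @param ifr the trial's [compute_ifr()] series.
#' @param channels [derive_channels()] output for the trial.
#' @param onset_velocity_mm_s velocity threshold defining stretch onset
#'   (default 0.5 mm/s).
#' @return A list with `iba` (imp/s; 0 with `no_spikes = TRUE` when the
#'   window contains no IFR sample), `peak_dfdt_n_s`, `peak_accel_mm_s2`,
#'   `window_s` (start/end times), `no_spikes`.
#' @export
detect_initial_burst <- function(trial, ifr, channels,
                                 onset_velocity_mm_s = 0.5) {
  stopifnot(inherits(trial, "trial_record"),
            inherits(channels, "derived_channels"))
  v <- channels$x[, "velocity"]
  a <- channels$x[, "accel"]
  t <- channels$t
  i_on <- which(v > onset_velocity_mm_s)[1L]
  if (is.na(i_on)) stop("no stretch onset found (velocity never rises)")
  after <- seq(i_on, length(a))
  i_zc_rel <- which(a[after] <= 0)[1L]
  i_end <- if (is.na(i_zc_rel)) length(t) else after[i_zc_rel]
  w0 <- t[i_on]
  w1 <- t[i_end]
  seg <- seq(i_on, i_end)
  in_win <- ifr$times >= w0 & ifr$times <= w1
  iba <- if (any(in_win)) max(ifr$rates[in_win]) else 0
  list(
    iba = iba,
    peak_dfdt_n_s = max(channels$x[seg, "dfdt"]),
    peak_accel_mm_s2 = max(a[seg]),
    window_s = c(start = w0, end = w1),
    no_spikes = !any(in_win)
  )
}

#' Regress initial-burst amplitude on a mechanical peak
#'
#' Ordinary least squares `iba = b1 * x + b2` of burst amplitude on the
#' preceding peak dF/dt or peak acceleration across trials, with the
#' standard slope t-test. Requires at least 12 paired trials.
#'
#' @param iba initial-burst amplitudes (imp/s).
#' @param x predictor peaks (N/s or mm/s^2), same length.
#' @param min_trials minimum number of pairs (default 12).
#' @return A list with `slope`, `intercept`, `r2`, `p`, `n`.
#' @export
iba_regression <- function(iba, x, min_trials = 12) {
  if (length(iba) != length(x)) stop("iba and x must be paired")
  if (length(iba) < min_trials) {
    stop(sprintf("need at least %d trials, got %d", min_trials, length(iba)))
  }
  if (stats::var(x) == 0) stop("degenerate predictor: zero variance")
  fit <- stats::lm(iba ~ x)
  sm <- summary(fit)
  list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r2 = sm$r.squared,
    p = unname(sm$coefficients[2L, 4L]),
    n = length(iba)
  )
}

#' Per-trial spindle metrics table
#'
#' Convenience wrapper computing the dynamic index (ramp-hold-release
#' trials only) and initial-burst statistics for a set of trials.
#'
#' @param trials list of [trial_record()] objects.
#' @param channels_list aligned list of [derive_channels()] outputs.
#' @return A data frame with one row per trial: `trial_id`, `stretch_type`,
#'   `peak_velocity_mm_s`, `velocity_bin`, `di`, `iba`, `peak_dfdt_n_s`,
#'   `peak_accel_mm_s2`. `di` is `NA` where not computable.
#' @export
spindle_metrics <- function(trials, channels_list) {
  stopifnot(length(trials) == length(channels_list))
  rows <- Map(function(tr, ch) {
    ifr <- compute_ifr(tr$spike_times)
    di <- tryCatch(dynamic_index(tr, ifr)$di, error = function(e) NA_real_)
    ib <- detect_initial_burst(tr, ifr, ch)
    data.frame(
      trial_id = tr$trial_id,
      stretch_type = tr$stretch_type,
      peak_velocity_mm_s = tr$peak_velocity_mm_s,
      velocity_bin = as.character(velocity_bin(tr$peak_velocity_mm_s)),
      di = di,
      iba = ib$iba,
      peak_dfdt_n_s = ib$peak_dfdt_n_s,
      peak_accel_mm_s2 = ib$peak_accel_mm_s2,
      stringsAsFactors = FALSE
    )
  }, trials, channels_list)
  do.call(rbind, rows)
}
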