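#' Construct a single stretch-trial record
#'
#' A trial bundles the synchronized musculotendon length and force series,
#' the afferent spike times, and the stretch metadata needed downstream
#' (stretch type, kinematic peaks, ramp end time for the dynamic index).
#'
#' @param trial_id,afferent_id character identifiers.
#' @param t time vector (s), strictly increasing with uniform spacing `1/fs`.
#' @param length_mm musculotendon length (mm), same length as `t`. Stored
#'   relative to the pre-stretch rest length (0 at rest).
#' @param force_n musculotendon force (N), same length as `t`.
#' @param spike_times sorted afferent spike times (s) within `range(t)`.
#' @param fs sampling rate (Hz), default 2000.
#' @param stretch_type `"ramp_hold_release"` or `"sawtooth"`.
#' @param peak_length_mm,peak_velocity_mm_s,peak_accel_mm_s2 trial metadata.
#' @param ramp_end_time_s time the (first) ramp phase ends, for the dynamic
#'   index; `NA` when not applicable.
#' @param exclude_flag logical; set `TRUE` to force exclusion of a trial on
#'   grounds outside the spike-count rule (stands in for visual
#'   signal-to-noise screening of real recordings).
#'
#' @return An object of class `trial_record`.
#' @export
trial_record <- function(trial_id, afferent_id, t, length_mm, force_n,
                         spike_times, fs = 2000,
                         stretch_type = c("ramp_hold_release", "sawtooth"),
                         peak_length_mm = NA_real_,
                         peak_velocity_mm_s = NA_real_,
                         peak_accel_mm_s2 = NA_real_,
                         ramp_end_time_s = NA_real_,
                         exclude_flag = FALSE) {
  stretch_type <- match.arg(stretch_type)
  stopifnot(is.numeric(t), is.numeric(length_mm), is.numeric(force_n))
  if (fs <= 0) stop("fs must be positive")
  n <- length(t)
  if (n < 2L) stop("trial needs at least 2 samples")
  if (length(length_mm) != n || length(force_n) != n) {
    stop("length and force series must match the time vector")
  }
  dt <- diff(t)
  if (any(dt <= 0)) stop("time vector must be strictly increasing")
  if (max(abs(dt - 1 / fs)) > 1e-6 / fs) {
    stop("time vector spacing must equal 1/fs")
  }
  spike_times <- as.numeric(spike_times)
  if (is.unsorted(spike_times, strictly = FALSE)) {
    stop("spike_times must be sorted")
  }
  if (length(spike_times) &&
      (spike_times[1] < t[1] - 1e-9 || spike_times[length(spike_times)] > t[n] + 1e-9)) {
    stop("spike_times must lie within the trial time span")
  }
  structure(
    list(
      trial_id = as.character(trial_id),
      afferent_id = as.character(afferent_id),
      fs = fs,
      t = t,
      length_mm = length_mm,
      force_n = force_n,
      spike_times = spike_times,
      stretch_type = stretch_type,
      peak_length_mm = peak_length_mm,
      peak_velocity_mm_s = peak_velocity_mm_s,
      peak_accel_mm_s2 = peak_accel_mm_s2,
      ramp_end_time_s = ramp_end_time_s,
      exclude_flag = isTRUE(exclude_flag)
    ),
    class = "trial_record"
  )
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf(
    "<trial_record %s | afferent %s | %s | %.2f s @ %g Hz | %d spikes>\n",
    x$trial_id, x$afferent_id, x$stretch_type,
    x$t[length(x$t)] - x$t[1], x$fs, length(x$spike_times)
  ))
  invisible(x)
}

#' Trial-level inclusion rule
#'
#' A trial is included when it carries at least 50 recorded action
#' potentials and its exclusion flag is not set.
#'
#' @param trial a [trial_record()].
#' @param min_spikes inclusion threshold on the spike count (default 50).
#' @return A list with `include` (logical) and `reason` (character, `""`
#'   when included).
#' @export
trial_qc <- function(trial, min_spikes = 50) {
  stopifnot(inherits(trial, "trial_record"))
  if (isTRUE(trial$exclude_flag)) {
    return(list(include = FALSE, reason = "exclusion flag set"))
  }
  n_spk <- length(trial$spike_times)
  if (n_spk < min_spikes) {
    return(list(
      include = FALSE,
      reason = sprintf("only %d spikes (minimum %d)", n_spk, min_spikes)
    ))
  }
  list(include = TRUE, reason = "")
}

#' Afferent-level inclusion rule
#'
#' An afferent is retained when at least 40 of its trials pass [trial_qc()],
#' which guarantees enough held-out trials for cross-validation.
#'
#' @param trials list of [trial_record()] objects sharing one `afferent_id`.
#' @param min_trials inclusion threshold on passing trials (default 40).
#' @param min_spikes per-trial spike threshold passed to [trial_qc()].
#' @return A list with `include`, `n_passing`, and the logical vector
#'   `trial_pass`.
#' @export
afferent_qc <- function(trials, min_trials = 40, min_spikes = 50) {
  if (!length(trials)) stop("empty trial list")
  ids <- vapply(trials, function(tr) tr$afferent_id, character(1))
  if (length(unique(ids)) != 1L) {
    stop("all trials must share one afferent_id")
  }
  pass <- vapply(
    trials,
    function(tr) trial_qc(tr, min_spikes = min_spikes)$include,
    logical(1)
  )
  list(
    include = sum(pass) >= min_trials,
    n_passing = sum(pass),
    trial_pass = pass
  )
}
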