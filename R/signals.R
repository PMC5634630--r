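#' Instantaneous firing rate of a spike train
#'
#' The IFR is the reciprocal inter-spike interval, assigned at the time of
#' the later spike of each pair so that predictors evaluated at or before a
#' spike precede the rate sample they explain.
#'
#' @param spike_times sorted spike times (s).
#' @return An object of class `ifr_series`: list with `times` (s, from the
#'   second spike onward) and `rates` (imp/s). With fewer than two spikes
#'   both fields are empty.
#' @examples
#' compute_ifr(c(0.1, 0.2, 0.3))$rates # 10 10
#' @export
compute_ifr <- function(spike_times) {
  spike_times <- as.numeric(spike_times)
  if (is.unsorted(spike_times)) stop("spike_times must be sorted")
  if (anyDuplicated(spike_times)) stop("duplicate spike times")
  if (length(spike_times) < 2L) {
    out <- list(times = numeric(0), rates = numeric(0))
  } else {
    isi <- diff(spike_times)
    out <- list(times = spike_times[-1L], rates = 1 / isi)
  }
  structure(out, class = "ifr_series")
}

#' @export
print.ifr_series <- function(x, ...) {
  cat(sprintf(
    "<ifr_series: %d rate samples%s>\n", length(x$rates),
    if (length(x$rates)) {
      sprintf(", %.1f-%.1f imp/s", min(x$rates), max(x$rates))
    } else {
      ""
    }
  ))
  invisible(x)
}

#' Numerical differentiation of a uniformly sampled series
#'
#' Second-order central differences in the interior, one-sided differences
#' at the endpoints.
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz).
#' @return Derivative series, same length as `x`, in `units(x)` per second.
#' @export
differentiate <- function(x, fs) {
  n <- length(x)
  if (n < 3L) stop("differentiate needs at least 3 samples")
  d <- numeric(n)
  d[1L] <- (x[2L] - x[1L]) * fs
  d[n] <- (x[n] - x[n - 1L]) * fs
  d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) * fs / 2
  d
}

# Steady-state initial filter state for stats-style direct-form II
# transposed filtering: filtering a constant c from state zi * c returns c
# exactly. Port of the usual companion-matrix construction.
filter_zi <- function(b, a) {
  if (a[1] != 1) {
    b <- b / a[1]
    a <- a / a[1]
  }
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  if (n == 1L) return(numeric(0))
  IminusA <- diag(n - 1L)
  # companion matrix of a, transposed
  comp <- matrix(0, n - 1L, n - 1L)
  comp[1L, ] <- -a[-1L]
  if (n > 2L) comp[cbind(2:(n - 1L), 1:(n - 2L))] <- 1
  IminusA <- diag(n - 1L) - t(comp)
  B <- b[-1L] - a[-1L] * b[1L]
  as.numeric(solve(IminusA, B))
}

#' Zero-phase low-pass filtering
#'
#' 4th-order Butterworth applied forward and backward so that no phase lag
#' is introduced (any latency between a predictor and the firing rate is
#' then carried solely by the model's fitted lag). The series is extended
#' at both ends by odd reflection and the filter is started from its
#' steady-state initial conditions, so a constant series passes through
#' unchanged to machine precision.
#'
#' @param x numeric series.
#' @param cutoff cutoff frequency (Hz), `0 < cutoff < fs/2`.
#' @param fs sampling rate (Hz).
#' @param order filter order (default 4).
#' @return Filtered series, same length as `x`.
#' @export
lowpass <- function(x, cutoff, fs, order = 4) {
  if (!(cutoff > 0 && cutoff < fs / 2)) {
    stop("cutoff must lie strictly between 0 and the Nyquist frequency")
  }
  n <- length(x)
  bf <- signal::butter(order, 2 * cutoff / fs, type = "low")
  b <- bf$b
  a <- bf$a
  npad <- min(n - 1L, 3L * (max(length(a), length(b)) - 1L) * 10L)
  # odd reflection about the end values suppresses edge transients
  pre <- 2 * x[1L] - x[seq(npad + 1L, 2L, by = -1L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - npad, by = -1L)]
  ext <- c(pre, x, post)
  zi <- filter_zi(b, a)
  fwd <- .iir_filter(b, a, ext, zi * ext[1L])
  rev_in <- rev(fwd)
  bwd <- .iir_filter(b, a, rev_in, zi * rev_in[1L])
  out <- rev(bwd)
  out[(npad + 1L):(npad + n)]
}

#' Shift a series back in time by a whole-sample lag
#'
#' Returns `x(t - lambda)` on the original grid: the series is delayed by
#' `lambda_ms`, the leading gap is held at the first value, and the length
#' is preserved. Used to advance muscle variables relative to the firing
#' rate they predict.
#'
#' @param x numeric series.
#' @param lambda_ms lag in milliseconds; `lambda_ms * fs / 1000` must be a
#'   whole number of samples.
#' @param fs sampling rate (Hz).
#' @return Shifted series, same length as `x`.
#' @export
lag_shift <- function(x, lambda_ms, fs) {
  shift <- lambda_ms * fs / 1000
  if (abs(shift - round(shift)) > 1e-9) {
    stop("lag must correspond to a whole number of samples")
  }
  shift <- as.integer(round(shift))
  if (shift < 0L) stop("lag must be non-negative")
  if (shift == 0L) return(x)
  n <- length(x)
  if (shift >= n) return(rep(x[1L], n))
  c(rep(x[1L], shift), x[seq_len(n - shift)])
}

#' Derived mechanical channels of a trial
#'
#' Computes the filtered predictor channels of one trial: filtered force,
#' dF/dt, velocity and acceleration of the musculotendon, and (optionally)
#' fascicle length, velocity and acceleration under low- and
#' high-compliance series tendons. Derivatives are taken after filtering
#' the parent channel and then filtered at their own stated cutoff
#' (velocity 40 Hz, acceleration 40 Hz, force 50 Hz, dF/dt 100 Hz).
#'
#' @param trial a [trial_record()].
#' @param config a [spindle_config()].
#' @param fascicle include fascicle-based channels (default TRUE).
#' @return An object of class `derived_channels`: list with the channel
#'   matrix `x` (one column per channel), `t`, `fs`, and `cutoffs_hz`
#'   recording the cutoff applied to each channel.
#' @export
derive_channels <- function(trial, config = spindle_config(),
                            fascicle = TRUE) {
  stopifnot(inherits(trial, "trial_record"))
  fs <- trial$fs
  fl <- config$filters

  force_f <- lowpass(trial$force_n, fl$force_hz, fs)
  dfdt <- lowpass(differentiate(force_f, fs), fl$dfdt_hz, fs)
  velocity <- lowpass(differentiate(trial$length_mm, fs), fl$velocity_hz, fs)
  accel <- lowpass(differentiate(velocity, fs), fl$accel_hz, fs)

  x <- cbind(
    force = force_f,
    dfdt = dfdt,
    length = trial$length_mm,
    velocity = velocity,
    accel = accel
  )
  cutoffs <- c(
    force = fl$force_hz, dfdt = fl$dfdt_hz, length = NA_real_,
    velocity = fl$velocity_hz, accel = fl$accel_hz
  )

  if (fascicle) {
    for (lev in c("low", "high")) {
      cc <- if (lev == "low") {
        config$tendon$compliance_low_per_mm
      } else {
        config$tendon$compliance_high_per_mm
      }
      tm <- tendon_model(compliance_c = cc, f_ref = config$tendon$f_ref_n)
      # zero-phase filtering can undershoot slightly below zero near slack;
      # the elongation model sees the non-negative tension
      lf <- trial$length_mm - tendon_elongation(pmax(force_f, 0), tm)
      vf <- lowpass(differentiate(lf, fs), fl$velocity_hz, fs)
      af <- lowpass(differentiate(vf, fs), fl$accel_hz, fs)
      add <- cbind(lf, vf, af)
      colnames(add) <- paste0(c("fasc_length_", "fasc_velocity_", "fasc_accel_"), lev)
      x <- cbind(x, add)
      cutoffs <- c(
        cutoffs,
        stats::setNames(
          c(NA_real_, fl$velocity_hz, fl$accel_hz),
          colnames(add)
        )
      )
    }
  }

  structure(
    list(t = trial$t, fs = fs, x = x, cutoffs_hz = cutoffs),
    class = "derived_channels"
  )
}

#' @export
print.derived_channels <- function(x, ...) {
  cat(sprintf(
    "<derived_channels: %d samples x %d channels (%s)>\n",
    nrow(x$x), ncol(x$x), paste(colnames(x$x), collapse = ", ")
  ))
  invisible(x)
}
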