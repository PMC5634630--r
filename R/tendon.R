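#' Exponential series-tendon model
#'
#' The tendon is assumed exponential-elastic: stiffness grows linearly with
#' force, `dF/d(elongation) = c * F`, which integrates to an elongation of
#' `(1/c) * log(F / f_ref)` above the reference force. `c` is the tendon
#' compliance constant in 1/mm; the study brackets it with 2 (compliant)
#' and 6 (stiff) per mm.
#'
#' @param compliance_c tendon constant (1/mm), positive.
#' @param f_ref reference force (N) at which elongation is defined as zero;
#'   defaults to the 0.1 N resting tension.
#' @return An object of class `tendon_model`.
#' @export
tendon_model <- function(compliance_c, f_ref = 0.1) {
  stopifnot(compliance_c > 0, f_ref > 0)
  structure(
    list(compliance_c = compliance_c, f_ref = f_ref),
    class = "tendon_model"
  )
}

#' Tendon elongation under a force trace
#'
#' `elong(F) = (1/c) * log(F / f_ref)` for `F >= f_ref`, clamped at zero
#' below the reference force (slack region). Negative force samples are
#' clamped to `f_ref` with a warning (a tension recording should never be
#' negative).
#'
#' @param force_n force series (N).
#' @param model a [tendon_model()].
#' @return Elongation series (mm), same length as `force_n`.
#' @examples
#' tendon_elongation(exp(1) * 0.1, tendon_model(2)) # 0.5 mm
#' @export
tendon_elongation <- function(force_n, model) {
  stopifnot(inherits(model, "tendon_model"))
  f <- as.numeric(force_n)
  if (any(f < 0)) {
    warning("negative force samples clamped to f_ref")
  }
  f <- pmax(f, model$f_ref)
  log(f / model$f_ref) / model$compliance_c
}

#' Fascicle-based kinematic channels of a trial
#'
#' Fascicle length is the musculotendon length minus the estimated tendon
#' elongation (pinnation is ignored; a constant pinnation angle would only
#' rescale the channels, which the model weights absorb). Velocity and
#' acceleration follow by numerical differentiation with the same cutoffs
#' as the musculotendon channels.
#'
#' @param trial a [trial_record()].
#' @param model a [tendon_model()].
#' @param config a [spindle_config()].
#' @return A list with `length_mm`, `velocity_mm_s`, `accel_mm_s2`.
#' @export
fascicle_channels <- function(trial, model, config = spindle_config()) {
  stopifnot(inherits(trial, "trial_record"))
  fs <- trial$fs
  fl <- config$filters
  force_f <- lowpass(trial$force_n, fl$force_hz, fs)
  # zero-phase filtering can undershoot slightly below zero near slack
  lf <- trial$length_mm - tendon_elongation(pmax(force_f, 0), model)
  vf <- lowpass(differentiate(lf, fs), fl$velocity_hz, fs)
  af <- lowpass(differentiate(vf, fs), fl$accel_hz, fs)
  list(length_mm = lf, velocity_mm_s = vf, accel_mm_s2 = af)
}
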