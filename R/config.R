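#' Pipeline configuration
#'
#' Builds the nested configuration list that every pipeline stage consults.
#' Defaults are the study conditions: 2 kHz sampling; low-pass cutoffs of
#' 40 Hz for velocity and acceleration, 50 Hz for force and 100 Hz for dF/dt;
#' a 0--15 ms neuromechanical lag grid in 1 ms steps; 100 cross-validation
#' iterations at a 75/25 train/test split; exponential series-tendon
#' compliances of 2 and 6 per mm referenced to 0.1 N resting tension.
#'
#' @param ... named overrides, e.g. `cv = list(n_iter = 20)`. Overrides are
#'   merged recursively into the defaults, so only the fields being changed
#'   need to be supplied.
#'
#' @return A named list of class `spindle_config` with sections `sampling`,
#'   `filters`, `lag`, `cv`, `tendon`, `selection`, `model`, `fitting` and
#'   `qc`.
#'
#' @examples
#' cfg <- spindle_config(cv = list(n_iter = 10))
#' cfg$filters$force_hz
#' @export
spindle_config <- function(...) {
  cfg <- list(
    sampling = list(fs = 2000),
    filters = list(
      velocity_hz = 40,
      accel_hz    = 40,
      force_hz    = 50,
      dfdt_hz     = 100
    ),
    lag = list(grid_ms = 0:15),
    cv = list(n_iter = 100, train_frac = 0.75),
    tendon = list(
      compliance_low_per_mm  = 2,
      compliance_high_per_mm = 6,
      f_ref_n = 0.1
    ),
    selection = list(
      # "standard" = AICc with the usual additive small-sample correction;
      # "as_printed" flips its sign (see the methods vignette for why the
      # standard form is the default).
      aicc_form = "standard"
    ),
    model = list(
      # "threshold": sum_i k_i * pos(x_i + b_i); "as_printed":
      # sum_i k_i * (pos(x_i) + b_i). pos() is half-wave rectification.
      rectify_order = "threshold",
      competing_threshold = 0,
      power_grid = seq(0.1, 1, by = 0.05)
    ),
    fitting = list(
      # weight upper bound = weight_bound_mult * max exploratory fit;
      # offsets bounded by the predictor's max absolute value.
      weight_bound_mult = 3,
      n_explore_trials  = 20,
      maxit = 200
    ),
    qc = list(min_spikes_per_trial = 50, min_trials_per_afferent = 40)
  )
  overrides <- list(...)
  if (length(overrides)) {
    stopifnot(!is.null(names(overrides)), all(nzchar(names(overrides))))
    cfg <- modify_list_deep(cfg, overrides)
  }
  class(cfg) <- "spindle_config"
  cfg
}

modify_list_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_list_deep(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

#' @export
print.spindle_config <- function(x, ...) {
  cat("<spindle_config>\n")
  cat(sprintf("  sampling: %g Hz\n", x$sampling$fs))
  cat(sprintf(
    "  filters (Hz): velocity %g, accel %g, force %g, dF/dt %g\n",
    x$filters$velocity_hz, x$filters$accel_hz,
    x$filters$force_hz, x$filters$dfdt_hz
  ))
  cat(sprintf(
    "  lag grid: %d--%d ms; CV: %d iters at %.0f/%.0f\n",
    min(x$lag$grid_ms), max(x$lag$grid_ms), x$cv$n_iter,
    100 * x$cv$train_frac, 100 * (1 - x$cv$train_frac)
  ))
  cat(sprintf(
    "  tendon compliance: %g and %g /mm (f_ref %g N); AICc: %s\n",
    x$tendon$compliance_low_per_mm, x$tendon$compliance_high_per_mm,
    x$tendon$f_ref_n, x$selection$aicc_form
  ))
  invisible(x)
}
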