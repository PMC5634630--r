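MODEL_IDS <- c("force", "length", "length_power",
               "fascicle_low", "fascicle_high", "all")

model_predictors <- list(
  force = c("force", "dfdt"),
  length = c("length", "velocity", "accel"),
  length_power = c("length", "velocity", "accel"),
  fascicle_low = c("fasc_length_low", "fasc_velocity_low", "fasc_accel_low"),
  fascicle_high = c("fasc_length_high", "fasc_velocity_high", "fasc_accel_high"),
  all = c(
    "force", "dfdt", "length", "velocity", "accel",
    "fasc_length_low", "fasc_velocity_low", "fasc_accel_low",
    "fasc_length_high", "fasc_velocity_high", "fasc_accel_high"
  )
)

#' Candidate encoding-model specification
#'
#' The six candidate models of Ia instantaneous firing rate:
#' \describe{
#'   \item{force}{whole-muscle force and dF/dt (the only model with a
#'     competing-influence variant)}
#'   \item{length}{musculotendon length, velocity, acceleration}
#'   \item{length_power}{as `length`, with velocity raised to a fitted
#'     fractional power in \[0.1, 1\]}
#'   \item{fascicle_low, fascicle_high}{fascicle length, velocity and
#'     acceleration estimated with tendon constants 2 and 6 per mm}
#'   \item{all}{free regression on all 11 predictors}
#' }
#'
#' @param model_id one of `"force"`, `"length"`, `"length_power"`,
#'   `"fascicle_low"`, `"fascicle_high"`, `"all"`.
#' @return An object of class `model_spec` with fields `model_id`,
#'   `predictors`, `n_params` (weights + offsets, +1 for the velocity
#'   exponent), `competing_allowed` and `has_power`.
#' @export
model_spec <- function(model_id = MODEL_IDS) {
  model_id <- match.arg(model_id)
  preds <- model_predictors[[model_id]]
  has_power <- identical(model_id, "length_power")
  structure(
    list(
      model_id = model_id,
      predictors = preds,
      n_params = 2L * length(preds) + as.integer(has_power),
      competing_allowed = identical(model_id, "force"),
      has_power = has_power
    ),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf(
    "<model_spec %s: %d predictors (%s), %d parameters%s>\n",
    x$model_id, length(x$predictors), paste(x$predictors, collapse = ", "),
    x$n_params, if (x$has_power) ", velocity exponent fitted" else ""
  ))
  invisible(x)
}

#' Parameters of a candidate model
#'
#' @param k weights, one per predictor (imp/s per predictor unit).
#' @param b offsets, one per predictor (predictor units). Under the default
#'   threshold form these act as (negated) rectification thresholds.
#' @param lambda_ms shared neuromechanical lag (integer ms in 0--15).
#' @param a velocity exponent for the `length_power` model (in \[0.1, 1\]),
#'   `NA` otherwise.
#' @return An object of class `model_params`.
#' @export
model_params <- function(k, b, lambda_ms = 0, a = NA_real_) {
  stopifnot(length(k) == length(b))
  if (!(lambda_ms >= 0 && lambda_ms <= 15 &&
          abs(lambda_ms - round(lambda_ms)) < 1e-9)) {
    stop("lambda_ms must be an integer in 0..15")
  }
  if (!is.na(a) && !(a >= 0.1 && a <= 1)) stop("a must lie in [0.1, 1]")
  structure(
    list(k = as.numeric(k), b = as.numeric(b),
         lambda_ms = as.integer(round(lambda_ms)), a = a),
    class = "model_params"
  )
}

# Raw (unrectified) predictor matrix at the evaluation times, with the
# model's lag applied by integer sample shift and held-first-value padding.
# t_eval is mapped to the nearest sample of the trial grid. For the
# length_power model the velocity column is rectified then raised to a.
channel_design <- function(channels, predictors, t_eval, lambda_ms,
                           a = NA_real_) {
  stopifnot(inherits(channels, "derived_channels"))
  missing_pred <- setdiff(predictors, colnames(channels$x))
  if (length(missing_pred)) {
    stop("unknown predictor(s): ", paste(missing_pred, collapse = ", "))
  }
  fs <- channels$fs
  shift <- lambda_ms * fs / 1000
  if (abs(shift - round(shift)) > 1e-9) {
    stop("lag must correspond to a whole number of samples")
  }
  shift <- as.integer(round(shift))
  idx <- as.integer(round((t_eval - channels$t[1L]) * fs)) + 1L
  n <- nrow(channels$x)
  if (any(idx < 1L) || any(idx > n)) {
    stop("t_eval outside the trial's channel coverage")
  }
  idx_lag <- pmax(idx - shift, 1L)
  X <- channels$x[idx_lag, predictors, drop = FALSE]
  if (!is.na(a)) {
    vel_cols <- grep("velocity", predictors)
    for (jc in vel_cols) X[, jc] <- pmax(X[, jc], 0)^a
  }
  X
}

# Core pseudolinear evaluator shared by prediction and (in mirror form) the
# compiled fitting objective. Returns the predicted rate, floored at zero.
pseudolinear_eval <- function(X, k, b, rectify_order = "threshold",
                              competing = FALSE, competing_threshold = 0) {
  stopifnot(ncol(X) == length(k), length(k) == length(b))
  comp <- if (identical(rectify_order, "threshold")) {
    sweep(X, 2L, b, "+")
  } else if (identical(rectify_order, "as_printed")) {
    pmax(X, 0) # offsets added after rectification below
  } else {
    stop("unknown rectify_order: ", rectify_order)
  }
  if (identical(rectify_order, "threshold")) {
    comp <- pmax(comp, 0)
    comp <- sweep(comp, 2L, k, "*")
  } else {
    comp <- sweep(comp, 2L, b, "+")
    comp <- sweep(comp, 2L, k, "*")
  }
  if (competing) {
    if (ncol(comp) != 2L) stop("competing evaluation needs exactly 2 components")
    c1 <- comp[, 1L]
    c2 <- comp[, 2L]
    both <- c1 > competing_threshold & c2 > competing_threshold
    # smaller-magnitude component zeroed; ties keep the force component
    drop1 <- both & abs(c2) > abs(c1)
    drop2 <- both & !drop1
    c1[drop1] <- 0
    c2[drop2] <- 0
    pred <- c1 + c2
  } else {
    pred <- rowSums(comp)
  }
  as.numeric(pmax(pred, 0))
}

#' Predict instantaneous firing rate from a candidate model
#'
#' Evaluates `sum_i k_i * pos(x_i(t - lambda) + b_i)` (default threshold
#' form) or `sum_i k_i * (pos(x_i(t - lambda)) + b_i)` (literal printed
#' form) at the requested times, floored at zero since a firing rate cannot
#' be negative. `pos()` denotes half-wave rectification.
#'
#' @param params a [model_params()].
#' @param channels a [derived_channels()] covering the evaluation times.
#' @param t_eval evaluation times (s), typically the spike times.
#' @param spec a [model_spec()]; defaults to the force model.
#' @param config a [spindle_config()] (supplies `model$rectify_order`).
#' @return Predicted rates (imp/s) at `t_eval`.
#' @export
predict_ifr <- function(params, channels, t_eval, spec = model_spec("force"),
                        config = spindle_config()) {
  stopifnot(inherits(params, "model_params"), inherits(spec, "model_spec"))
  X <- channel_design(channels, spec$predictors, t_eval, params$lambda_ms,
                      a = if (spec$has_power) params$a else NA_real_)
  pseudolinear_eval(X, params$k, params$b,
                    rectify_order = config$model$rectify_order)
}

#' Predict with force and dF/dt as competing influences
#'
#' At time points where the force and dF/dt components are simultaneously
#' above the significance threshold, the smaller-magnitude component is set
#' to zero and the remaining components are summed as usual. Zeroing the
#' smaller component never changes which component is larger, so a single
#' pass over the time points is already the fixed point of the iteration.
#' Ties keep the force component (the tonic pathway).
#'
#' @inheritParams predict_ifr
#' @return Predicted rates (imp/s) at `t_eval`.
#' @export
competing_predict <- function(params, channels, t_eval,
                              config = spindle_config()) {
  spec <- model_spec("force")
  stopifnot(inherits(params, "model_params"))
  if (length(params$k) != 2L) {
    stop("competing prediction is defined for the force model only")
  }
  X <- channel_design(channels, spec$predictors, t_eval, params$lambda_ms)
  pseudolinear_eval(
    X, params$k, params$b,
    rectify_order = config$model$rectify_order,
    competing = TRUE,
    competing_threshold = config$model$competing_threshold
  )
}

#' Choose between the plain and competing force-model variants
#'
#' The competing variant is retained only when it achieves a strictly
#' higher mean R-squared across the same observations.
#'
#' @param r2_plain,r2_competing per-trial (or per-observation-set) R-squared
#'   values for the two variants, aligned element-wise.
#' @return `"competing"` or `"plain"`.
#' @export
choose_competing <- function(r2_plain, r2_competing) {
  if (length(r2_plain) != length(r2_competing)) {
    stop("variant fits must cover the same observation sets")
  }
  if (!is.null(names(r2_plain)) && !is.null(names(r2_competing)) &&
      !identical(names(r2_plain), names(r2_competing))) {
    stop("variant fits must cover the same observation sets")
  }
  if (mean(r2_competing) > mean(r2_plain)) "competing" else "plain"
}
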