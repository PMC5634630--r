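#' Normalized fitting cost J = SSE / SSM
#'
#' Sum of squared errors between recorded and predicted rates, normalized
#' by the total sum of squares of the recorded rates about their mean.
#' `J = 1 - R^2` identically.
#'
#' @param y recorded rates (imp/s).
#' @param f predicted rates (imp/s), same length.
#' @return Non-negative scalar cost.
#' @examples
#' cost_j(c(1, 2, 3), c(2, 2, 2)) # 1
#' @export
cost_j <- function(y, f) {
  if (length(y) != length(f)) stop("y and f must have equal length")
  if (length(y) < 2L) stop("need at least 2 observations")
  ssm <- sum((y - mean(y))^2)
  if (ssm == 0) stop("degenerate target: all recorded rates equal")
  sum((y - f)^2) / ssm
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SSE/SSM`; may be negative when the prediction is worse than
#' the mean of the data.
#'
#' @inheritParams cost_j
#' @return Scalar, at most 1.
#' @export
r_squared <- function(y, f) 1 - cost_j(y, f)

# ---- internal fitting machinery -------------------------------------------

# Observations of one trial for one model at one lag: recorded IFR samples
# and the raw predictor matrix at the spike times.
trial_observations <- function(spec, trial, channels, lambda_ms,
                               a = NA_real_) {
  ifr <- compute_ifr(trial$spike_times)
  if (length(ifr$rates) < 2L) stop("trial has fewer than 2 IFR samples")
  X <- channel_design(channels, spec$predictors, ifr$times, lambda_ms,
                      a = if (spec$has_power) a else NA_real_)
  list(y = ifr$rates, X = X, t = ifr$times)
}

# Default search limits when no exploratory fits are available yet:
# weights in [0, 10 * max(y) / scale(x_j)], offsets in [-max|x_j|, max|x_j|].
default_bounds <- function(X, y) {
  p <- ncol(X)
  sx <- pmax(apply(abs(X), 2L, max), 1e-8)
  k_up <- 10 * max(max(y), 1e-8) / sx
  list(lower = c(rep(0, p), -sx), upper = c(k_up, sx))
}

# Bounded nonlinear least squares by deterministic multi-start L-BFGS-B on
# the compiled objective. starts: list of theta vectors; NULL entries are
# skipped. Returns theta, sse, and convergence of the winning start.
fit_bounded <- function(X, y, bounds, starts = NULL,
                        rectify_order = "threshold", competing = FALSE,
                        competing_threshold = 0, maxit = 200) {
  p <- ncol(X)
  lower <- bounds$lower
  upper <- bounds$upper
  stopifnot(length(lower) == 2L * p, length(upper) == 2L * p)
  threshold_form <- identical(rectify_order, "threshold")

  if (is.null(starts)) starts <- list()
  clamp <- function(th) pmin(pmax(th, lower), upper)
  base_starts <- list(
    zeros = clamp(rep(0, 2L * p)),
    midpoints = (lower + upper) / 2
  )
  starts <- c(base_starts, lapply(starts, clamp))

  cache <- new.env(parent = emptyenv())
  fn <- function(th) {
    o <- .sse_objective(th, X, y, threshold_form, competing,
                        competing_threshold)
    cache$theta <- th
    cache$grad <- o$gradient
    o$value
  }
  gr <- function(th) {
    if (!is.null(cache$theta) && identical(cache$theta, th)) {
      return(cache$grad)
    }
    .sse_objective(th, X, y, threshold_form, competing,
                   competing_threshold)$gradient
  }

  best <- NULL
  for (th0 in starts) {
    res <- tryCatch(
      stats::optim(
        th0, fn, gr,
        method = "L-BFGS-B", lower = lower, upper = upper,
        control = list(maxit = maxit)
      ),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("optimizer failed to converge from every start")
  list(theta = best$par, sse = best$value, convergence = best$convergence)
}

# Fit one design (fixed lag). For the length_power model the velocity
# exponent is swept over config$model$power_grid with an inner bounded fit,
# warm starting each grid point from the previous solution.
fit_design <- function(spec, make_X, y, bounds = NULL, explore_start = NULL,
                       config = spindle_config(), competing = FALSE) {
  ssm <- sum((y - mean(y))^2)
  if (ssm == 0) stop("degenerate target: all recorded rates equal")
  rectify <- config$model$rectify_order
  maxit <- config$fitting$maxit
  if (competing && !spec$competing_allowed) {
    stop("competing fitting is defined for the force model only")
  }

  run_one <- function(X, starts, bnds) {
    fit_bounded(X, y, bnds, starts = starts, rectify_order = rectify,
                competing = competing,
                competing_threshold = config$model$competing_threshold,
                maxit = maxit)
  }

  if (!is.null(explore_start) && !is.list(explore_start)) {
    explore_start <- list(explore_start)
  }
  if (!spec$has_power) {
    X <- make_X(NA_real_)
    bnds <- if (is.null(bounds)) default_bounds(X, y) else bounds
    starts <- if (is.null(explore_start)) list() else explore_start
    fit <- run_one(X, starts, bnds)
    a_best <- NA_real_
  } else {
    grid <- config$model$power_grid
    fit <- NULL
    a_best <- NA_real_
    warm <- NULL
    bnds <- bounds
    for (a in grid) {
      X <- make_X(a)
      if (is.null(bnds)) bnds <- default_bounds(X, y)
      starts <- c(
        if (is.null(warm)) list() else list(warm),
        if (is.null(explore_start)) list() else explore_start
      )
      f <- run_one(X, starts, bnds)
      warm <- f$theta
      if (is.null(fit) || f$sse < fit$sse) {
        fit <- f
        a_best <- a
      }
    }
  }
  p <- length(spec$predictors)
  list(
    k = fit$theta[seq_len(p)],
    b = fit$theta[p + seq_len(p)],
    a = a_best,
    sse = fit$sse,
    J = fit$sse / ssm,
    r2 = 1 - fit$sse / ssm,
    theta = fit$theta
  )
}

# ---- public fitting operations --------------------------------------------

#' Fit a candidate model to one trial across the lag sweep
#'
#' For every lag on the 0--15 ms grid (16 values), solves the bounded
#' least-squares problem over the weights and offsets (and the velocity
#' exponent for `length_power`) against the trial's IFR samples, and
#' returns the lag and parameters with the highest R-squared.
#'
#' @param spec a [model_spec()].
#' @param trial a [trial_record()].
#' @param channels [derive_channels()] output for the trial.
#' @param config a [spindle_config()].
#' @param bounds optional list with `lower` and `upper` over
#'   `(k_1..k_p, b_1..b_p)`; derived from the data when omitted.
#' @param competing fit the competing-influence variant (force model only).
#' @return An object of class `fit_result`: `model_id`, `params`
#'   ([model_params()]), `r2`, `J` (`= 1 - r2`), `n_obs`, `lag_ms_best`,
#'   and `per_lag_r2` (named vector over the full sweep).
#' @export
fit_trial <- function(spec, trial, channels, config = spindle_config(),
                      bounds = NULL, competing = FALSE) {
  stopifnot(inherits(spec, "model_spec"), inherits(trial, "trial_record"))
  grid <- config$lag$grid_ms
  best <- NULL
  per_lag <- stats::setNames(rep(NA_real_, length(grid)), grid)
  for (lam in grid) {
    obs <- trial_observations(spec, trial, channels, lam)
    make_X <- function(a) {
      channel_design(channels, spec$predictors, obs$t, lam,
                     a = if (spec$has_power) a else NA_real_)
    }
    f <- fit_design(spec, make_X, obs$y, bounds = bounds, config = config,
                    competing = competing)
    per_lag[as.character(lam)] <- f$r2
    if (is.null(best) || f$r2 > best$r2) {
      best <- f
      best$lag <- lam
    }
  }
  structure(
    list(
      model_id = spec$model_id,
      params = model_params(best$k, best$b, lambda_ms = best$lag,
                            a = best$a),
      r2 = best$r2,
      J = best$J,
      n_obs = length(trial$spike_times) - 1L,
      lag_ms_best = best$lag,
      per_lag_r2 = per_lag
    ),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result %s: R2 %.4f (J %.4f), lag %d ms, %d obs>\n",
    x$model_id, x$r2, x$J, x$lag_ms_best, x$n_obs
  ))
  invisible(x)
}

#' Consolidate per-trial best lags into a single afferent lag
#'
#' Arithmetic mean of the per-trial best lags, rounded to the nearest
#' integer millisecond (halves round up). The consolidated lag is frozen
#' before cross-validation.
#'
#' @param lags_ms numeric vector of per-trial best lags (ms).
#' @return Integer lag in ms.
#' @examples
#' consolidate_lag(c(9, 10)) # 10
#' @export
consolidate_lag <- function(lags_ms) {
  if (!length(lags_ms)) stop("no lags to consolidate")
  as.integer(floor(mean(lags_ms) + 0.5))
}

#' Fit one parameter set to the pooled observations of several trials
#'
#' Concatenates the IFR observations of all trials (equal per-observation
#' weight) at a fixed lag and minimizes the pooled cost.
#'
#' @param spec a [model_spec()].
#' @param trials list of [trial_record()] objects.
#' @param channels_list list of [derive_channels()] outputs aligned with
#'   `trials`.
#' @param lambda_ms the frozen lag (ms).
#' @param config a [spindle_config()].
#' @param bounds optional search limits as in [fit_trial()].
#' @param explore_start optional warm-start parameter vector
#'   `(k_1..k_p, b_1..b_p)` from exploratory fits.
#' @param competing fit the competing-influence variant (force model only).
#' @return A `fit_result` (with `lag_ms_best` equal to the frozen lag).
#' @export
fit_pooled <- function(spec, trials, channels_list, lambda_ms,
                       config = spindle_config(), bounds = NULL,
                       explore_start = NULL, competing = FALSE) {
  stopifnot(length(trials) >= 1L, length(trials) == length(channels_list))
  obs <- Map(
    function(tr, ch) trial_observations(spec, tr, ch, lambda_ms),
    trials, channels_list
  )
  y <- unlist(lapply(obs, `[[`, "y"), use.names = FALSE)
  if (spec$has_power) {
    # pooled raw designs per trial; exponent applied per grid point
    ts <- lapply(obs, `[[`, "t")
    make_X <- function(a) {
      do.call(rbind, Map(
        function(ch, tt) {
          channel_design(ch, spec$predictors, tt, lambda_ms, a = a)
        },
        channels_list, ts
      ))
    }
  } else {
    X0 <- do.call(rbind, lapply(obs, `[[`, "X"))
    make_X <- function(a) X0
  }
  f <- fit_design(spec, make_X, y, bounds = bounds,
                  explore_start = explore_start, config = config,
                  competing = competing)
  structure(
    list(
      model_id = spec$model_id,
      params = model_params(f$k, f$b, lambda_ms = lambda_ms, a = f$a),
      r2 = f$r2,
      J = f$J,
      n_obs = length(y),
      lag_ms_best = as.integer(lambda_ms),
      per_lag_r2 = NULL
    ),
    class = "fit_result"
  )
}
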