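#' Exploratory per-trial fits: lags, search limits, warm starts
#'
#' Fits each candidate model trial-by-trial over the full 0--15 ms lag
#' sweep on a deterministic subset of the afferent's QC-passing trials
#' (default 20, evenly spaced through the trial list). The per-trial best
#' lags are averaged into the afferent's frozen lag for that model; the
#' fitted weights set the cross-validation search limits (weights bounded
#' by 3x the largest exploratory value, offsets by the largest predictor
#' magnitude); the best exploratory parameter vector seeds the pooled
#' fits. When `check_competing` is set, the force model is fitted in both
#' its plain and competing-influence variants and the variant with the
#' higher mean R-squared is retained for this afferent.
#'
#' @param afferent one element of a [make_dataset()] `afferents` list
#'   (fields `afferent_id`, `trials`, `channels`).
#' @param specs list of [model_spec()]s, default all six candidates.
#' @param config a [spindle_config()].
#' @param check_competing also evaluate the competing force variant
#'   (default FALSE).
#' @return A list keyed by model id: `lambda_ms` (frozen lag), `bounds`,
#'   `start` (warm start), `trial_fits`, plus `force_variant`
#'   (`"plain"` or `"competing"`).
#' @export
explore_afferent <- function(afferent, specs = lapply(MODEL_IDS, model_spec),
                             config = spindle_config(),
                             check_competing = FALSE) {
  keep <- vapply(afferent$trials, function(tr) trial_qc(
    tr, min_spikes = config$qc$min_spikes_per_trial
  )$include, logical(1))
  trials <- afferent$trials[keep]
  channels <- afferent$channels[keep]
  n <- length(trials)
  if (!n) stop("no QC-passing trials")
  n_ex <- min(config$fitting$n_explore_trials, n)
  idx <- unique(round(seq(1, n, length.out = n_ex)))

  out <- list()
  for (spec in specs) {
    fits <- lapply(idx, function(i) {
      fit_trial(spec, trials[[i]], channels[[i]], config = config)
    })
    lags <- vapply(fits, `[[`, numeric(1), "lag_ms_best")
    lambda <- consolidate_lag(lags)
    kmat <- vapply(fits, function(f) f$params$k,
                   numeric(length(spec$predictors)))
    kmat <- matrix(kmat, nrow = length(spec$predictors))
    k_up <- config$fitting$weight_bound_mult *
      pmax(apply(kmat, 1L, max), 1e-6)
    # offset limits from the predictor magnitudes at the frozen lag
    sx <- Reduce(pmax, lapply(idx, function(i) {
      obs <- trial_observations(spec, trials[[i]], channels[[i]], lambda)
      apply(abs(obs$X), 2L, max)
    }))
    sx <- pmax(sx, 1e-8)
    best_i <- which.max(vapply(fits, `[[`, numeric(1), "r2"))
    start <- c(fits[[best_i]]$params$k, fits[[best_i]]$params$b)
    out[[spec$model_id]] <- list(
      lambda_ms = lambda,
      bounds = list(lower = c(rep(0, length(sx)), -sx),
                    upper = c(k_up, sx)),
      start = start,
      trial_fits = fits,
      mean_r2 = mean(vapply(fits, `[[`, numeric(1), "r2"))
    )
  }

  # The free regression nests every sub-model: its search limits must
  # admit each sub-model's limits on the predictors they share.
  if ("all" %in% names(out)) {
    all_preds <- model_predictors$all
    p_all <- length(all_preds)
    up <- out$all$bounds$upper
    lo <- out$all$bounds$lower
    for (mid in setdiff(names(out), c("all", "length_power"))) {
      pos <- match(model_predictors[[mid]], all_preds)
      p_sub <- length(pos)
      up[pos] <- pmax(up[pos], out[[mid]]$bounds$upper[seq_len(p_sub)])
      up[p_all + pos] <- pmax(up[p_all + pos],
                              out[[mid]]$bounds$upper[p_sub + seq_len(p_sub)])
      lo[p_all + pos] <- pmin(lo[p_all + pos],
                              out[[mid]]$bounds$lower[p_sub + seq_len(p_sub)])
    }
    out$all$bounds <- list(lower = lo, upper = up)
  }

  force_variant <- "plain"
  if (check_competing && "force" %in% names(out)) {
    spec <- model_spec("force")
    comp_fits <- lapply(idx, function(i) {
      fit_trial(spec, trials[[i]], channels[[i]], config = config,
                competing = TRUE)
    })
    r2_plain <- vapply(out$force$trial_fits, `[[`, numeric(1), "r2")
    r2_comp <- vapply(comp_fits, `[[`, numeric(1), "r2")
    force_variant <- choose_competing(r2_plain, r2_comp)
    if (identical(force_variant, "competing")) {
      lags <- vapply(comp_fits, `[[`, numeric(1), "lag_ms_best")
      out$force$lambda_ms <- consolidate_lag(lags)
      best_i <- which.max(r2_comp)
      out$force$start <- c(comp_fits[[best_i]]$params$k,
                           comp_fits[[best_i]]$params$b)
      out$force$trial_fits <- comp_fits
    }
  }
  out$force_variant <- force_variant
  out
}

#' Cross-validated model comparison for one afferent
#'
#' Runs the full selection procedure: trial- and afferent-level QC,
#' exploratory lag/bound estimation (unless supplied), `n_iter` randomized
#' 75/25 train/test splits stratified by stretch type, pooled bounded
#' least-squares fits on each training set at the frozen per-model lag,
#' held-out cost and R-squared on each test set, AICc per model and
#' iteration (likelihood proxied by the reciprocal held-out cost, `n` =
#' test trial count), the per-iteration winner, and Akaike weights from
#' the mean AICc. Models for which the AICc small-sample condition
#' `n > k + 1` fails on a split are recorded `NA`, cannot win, and are
#' excluded from the weights (with one warning).
#'
#' @inheritParams explore_afferent
#' @param seed integer seed driving the split randomization.
#' @param explore optional precomputed [explore_afferent()] result.
#' @return A `selection_summary` (scope `"afferent"`) whose `details`
#'   field carries the per-iteration table, frozen lags, the force-model
#'   variant, and the exploration object.
#' @export
cross_validate <- function(afferent, config = spindle_config(), seed = 1,
                           specs = lapply(MODEL_IDS, model_spec),
                           explore = NULL, check_competing = FALSE) {
  keep <- vapply(afferent$trials, function(tr) trial_qc(
    tr, min_spikes = config$qc$min_spikes_per_trial
  )$include, logical(1))
  trials <- afferent$trials[keep]
  channels <- afferent$channels[keep]
  aqc <- afferent_qc(afferent$trials,
                     min_trials = config$qc$min_trials_per_afferent,
                     min_spikes = config$qc$min_spikes_per_trial)
  if (!aqc$include) {
    stop(sprintf("afferent %s fails QC (%d passing trials)",
                 afferent$afferent_id, aqc$n_passing))
  }
  if (is.null(explore)) {
    explore <- explore_afferent(
      list(afferent_id = afferent$afferent_id, trials = trials,
           channels = channels),
      specs = specs, config = config, check_competing = check_competing
    )
  }

  ids <- vapply(trials, `[[`, character(1), "trial_id")
  stype <- vapply(trials, `[[`, character(1), "stretch_type")
  splits <- make_splits(ids, n_iter = config$cv$n_iter, seed = seed,
                        train_frac = config$cv$train_frac,
                        stratify = factor(stype),
                        min_trials = config$qc$min_trials_per_afferent)

  # Precompute per-trial observations at each model's frozen lag. For the
  # length_power model the velocity column stays raw; the exponent is
  # applied per candidate value inside the fit.
  model_obs <- list()
  for (spec in specs) {
    lam <- explore[[spec$model_id]]$lambda_ms
    obs <- Map(function(tr, ch) {
      ifr <- compute_ifr(tr$spike_times)
      X <- channel_design(ch, spec$predictors, ifr$times, lam, a = NA_real_)
      list(y = ifr$rates, X = X)
    }, trials, channels)
    names(obs) <- ids
    model_obs[[spec$model_id]] <- obs
  }
  apply_power <- function(X, spec, a) {
    if (!spec$has_power || is.na(a)) return(X)
    vc <- grep("velocity", spec$predictors)
    X[, vc] <- pmax(X[, vc], 0)^a
    X
  }

  # Map a fitted sub-model parameter vector into the ALL model's
  # coordinates (zero weight on the predictors it lacks); these nested warm
  # starts let the free regression always reach at least the best
  # sub-model solution.
  all_spec <- Filter(function(s) identical(s$model_id, "all"), specs)
  embed_into_all <- function(sub_spec, theta) {
    if (!length(all_spec)) return(NULL)
    preds <- all_spec[[1L]]$predictors
    pos <- match(sub_spec$predictors, preds)
    if (anyNA(pos)) return(NULL)
    p_sub <- length(sub_spec$predictors)
    k <- numeric(length(preds))
    b <- numeric(length(preds))
    k[pos] <- theta[seq_len(p_sub)]
    b[pos] <- theta[p_sub + seq_len(p_sub)]
    c(k, b)
  }

  small_sample_warned <- FALSE
  rows <- vector("list", length(splits) * length(specs))
  winners <- character(length(splits))
  ri <- 0L
  for (sp in splits) {
    it_aicc <- c()
    it_npar <- c()
    it_theta <- list()
    for (spec in specs) {
      mid <- spec$model_id
      obs <- model_obs[[mid]]
      ytr <- unlist(lapply(obs[sp$train_ids], `[[`, "y"), use.names = FALSE)
      Xtr_raw <- do.call(rbind, lapply(obs[sp$train_ids], `[[`, "X"))
      competing <- identical(mid, "force") &&
        identical(explore$force_variant, "competing")
      make_X <- function(a) apply_power(Xtr_raw, spec, a)
      starts <- list(explore[[mid]]$start)
      if (identical(mid, "all")) {
        for (prev in names(it_theta)) {
          emb <- embed_into_all(
            Filter(function(s) identical(s$model_id, prev), specs)[[1L]],
            it_theta[[prev]]
          )
          if (!is.null(emb)) starts <- c(starts, list(emb))
        }
      }
      f <- fit_design(spec, make_X, ytr,
                      bounds = explore[[mid]]$bounds,
                      explore_start = starts,
                      config = config, competing = competing)
      if (!spec$has_power && !competing) it_theta[[mid]] <- f$theta
      yte <- unlist(lapply(obs[sp$test_ids], `[[`, "y"), use.names = FALSE)
      Xte <- apply_power(do.call(rbind, lapply(obs[sp$test_ids], `[[`, "X")),
                         spec, f$a)
      pred <- .pseudolinear_pred(
        f$theta, Xte,
        identical(config$model$rectify_order, "threshold"),
        competing, config$model$competing_threshold
      )
      j_test <- cost_j(yte, pred)
      n_test <- length(sp$test_ids)
      ac <- tryCatch(
        aicc(spec$n_params, 1 / max(j_test, 1e-15), n_test,
             form = config$selection$aicc_form),
        error = function(e) NA_real_
      )
      if (is.na(ac) && !small_sample_warned) {
        warning(sprintf(
          "model %s inadmissible for AICc (test n = %d <= k + 1 = %d); excluded from selection",
          mid, n_test, spec$n_params + 1L
        ), call. = FALSE)
        small_sample_warned <- TRUE
      }
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        iteration = sp$iteration, model_id = mid,
        r2_test = 1 - j_test, j_test = j_test, aicc = ac,
        n_train = length(sp$train_ids), n_test = n_test,
        stringsAsFactors = FALSE
      )
      it_aicc[mid] <- ac
      it_npar[mid] <- spec$n_params
    }
    winners[sp$iteration] <- select_per_iteration(it_aicc, it_npar)
  }
  iter_tab <- do.call(rbind, rows)

  model_ids <- vapply(specs, `[[`, character(1), "model_id")
  agg <- lapply(model_ids, function(mid) {
    sub <- iter_tab[iter_tab$model_id == mid, ]
    data.frame(
      model_id = mid,
      mean_r2 = mean(sub$r2_test),
      sd_r2 = stats::sd(sub$r2_test),
      mean_aicc = if (all(is.na(sub$aicc))) NA_real_ else mean(sub$aicc),
      n_wins = sum(winners == mid),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, agg)
  finite <- is.finite(tab$mean_aicc)
  tab$delta <- NA_real_
  tab$w <- NA_real_
  if (sum(finite) >= 2L) {
    tab$delta[finite] <- tab$mean_aicc[finite] - min(tab$mean_aicc[finite])
    tab$w[finite] <- akaike_weights(tab$mean_aicc[finite])
  }
  tab$selection_frequency <- tab$n_wins / length(splits)
  tab <- tab[, c("model_id", "mean_r2", "sd_r2", "mean_aicc", "delta", "w",
                 "n_wins", "selection_frequency")]

  structure(
    list(
      scope = "afferent",
      table = tab,
      n_iter = length(splits),
      afferent_ids = afferent$afferent_id,
      details = list(
        iterations = iter_tab,
        winners = winners,
        lambda_ms = vapply(model_ids, function(m) explore[[m]]$lambda_ms,
                           numeric(1)),
        force_variant = explore$force_variant,
        explore = explore,
        seed = seed
      )
    ),
    class = "selection_summary"
  )
}
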