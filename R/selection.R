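#' Randomized train/test split plans
#'
#' Reproducible cross-validation splits at the trial level: roughly 75%
#' of trials train, 25% test, with rounding toward the training set, never
#' splitting within a trial, and stratified by stretch type when a
#' stratification factor is supplied (so test sets contain unseen
#' perturbation waveforms of each type).
#'
#' @param trial_ids character vector of trial identifiers.
#' @param n_iter number of independent splits (default 100).
#' @param seed integer seed; the same seed reproduces the same plans.
#' @param train_frac training fraction (default 0.75).
#' @param stratify optional factor aligned with `trial_ids` (e.g. stretch
#'   type).
#' @param min_trials minimum admissible number of trials (default 40).
#' @return List of split plans, each a list with `iteration`, `train_ids`,
#'   `test_ids`.
#' @export
make_splits <- function(trial_ids, n_iter = 100, seed = 1,
                        train_frac = 0.75, stratify = NULL,
                        min_trials = 40) {
  n <- length(trial_ids)
  if (n < min_trials) {
    stop(sprintf("too few trials for cross-validation (%d < %d)", n, min_trials))
  }
  if (anyDuplicated(trial_ids)) stop("trial_ids must be unique")
  if (!is.null(stratify) && length(stratify) != n) {
    stop("stratify must align with trial_ids")
  }
  groups <- if (is.null(stratify)) {
    list(seq_len(n))
  } else {
    split(seq_len(n), stratify)
  }
  with_preserved_rng(seed, {
    lapply(seq_len(n_iter), function(it) {
      train_idx <- unlist(lapply(groups, function(g) {
        n_tr <- ceiling(train_frac * length(g))
        if (length(g) == 1L) g else sample(g, n_tr)
      }), use.names = FALSE)
      train_idx <- sort(train_idx)
      list(
        iteration = it,
        train_ids = trial_ids[train_idx],
        test_ids = trial_ids[-train_idx]
      )
    })
  })
}

# Evaluate expr with a local RNG stream; the caller's RNG state is
# untouched.
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Corrected Akaike information criterion
#'
#' `AICc = 2 * (k - ln(L) + k(k+1)/(n-k-1))` in the default standard form,
#' where the likelihood is proxied by the reciprocal of the held-out
#' normalized cost (`L = 1/J_test`) and `n` counts the stretch trials in
#' the test set. `form = "as_printed"` flips the sign of the small-sample
#' term (see the methods vignette for why the standard sign is the
#' default).
#'
#' @param k_params number of estimable parameters of the model.
#' @param L_hat likelihood proxy, positive.
#' @param n number of test-set trials; must exceed `k_params + 1`.
#' @param form `"standard"` or `"as_printed"`.
#' @return Scalar AICc.
#' @examples
#' aicc(4, 5, 30, form = "as_printed") # 3.1812...
#' @export
aicc <- function(k_params, L_hat, n,
                 form = c("standard", "as_printed")) {
  form <- match.arg(form)
  if (!(L_hat > 0)) stop("L_hat must be positive")
  if (n <= k_params + 1) {
    stop(sprintf(
      "small sample: n = %d does not exceed k + 1 = %d", n, k_params + 1
    ))
  }
  corr <- k_params * (k_params + 1) / (n - k_params - 1)
  sgn <- if (form == "standard") 1 else -1
  2 * (k_params - log(L_hat) + sgn * corr)
}

#' Akaike weights of a candidate set
#'
#' `w_j = exp(-Delta_j / 2) / sum_r exp(-Delta_r / 2)` with
#' `Delta_j = AICc_j - min(AICc)`. Invariant to adding a constant to every
#' AICc.
#'
#' @param aicc_values numeric vector of AICc values (all finite).
#' @return Weights in (0, 1] summing to 1, named like the input.
#' @export
akaike_weights <- function(aicc_values) {
  if (length(aicc_values) < 2L) stop("need at least 2 AICc values")
  if (any(!is.finite(aicc_values))) stop("all AICc values must be finite")
  delta <- aicc_values - min(aicc_values)
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Winner of one cross-validation iteration
#'
#' The winning model minimizes AICc; ties are broken toward the model with
#' fewer parameters, then by the fixed candidate order. Models with `NA`
#' AICc (inadmissible on this split) cannot win.
#'
#' @param aicc_values named numeric vector of per-model AICc values.
#' @param n_params named numeric vector of per-model parameter counts,
#'   aligned with `aicc_values`.
#' @return The winning model id (character).
#' @export
select_per_iteration <- function(aicc_values, n_params) {
  stopifnot(!is.null(names(aicc_values)),
            identical(names(aicc_values), names(n_params)))
  ok <- is.finite(aicc_values)
  if (!any(ok)) stop("no admissible model in this iteration")
  ids <- names(aicc_values)[ok]
  av <- aicc_values[ok]
  np <- n_params[ok]
  ord <- order(av, np, seq_along(ids))
  ids[ord[1L]]
}

#' Aggregate per-afferent selection summaries into a population summary
#'
#' Population mean R-squared and mean AICc are unweighted means of the
#' per-afferent means; population Akaike weights are recomputed from the
#' averaged AICc values; the population selection frequency is total wins
#' over total iterations.
#'
#' @param summaries list of per-afferent `selection_summary` objects (as
#'   produced by [cross_validate()]).
#' @return A `selection_summary` with scope `"population"`.
#' @export
population_summary <- function(summaries) {
  if (!length(summaries)) stop("no afferent summaries supplied")
  tabs <- lapply(summaries, `[[`, "table")
  ids <- tabs[[1L]]$model_id
  for (tb in tabs) {
    if (!identical(tb$model_id, ids)) stop("mismatched model sets")
  }
  mean_r2 <- rowMeans(vapply(tabs, `[[`, numeric(length(ids)), "mean_r2"))
  r2_mat <- vapply(tabs, `[[`, numeric(length(ids)), "mean_r2")
  sd_r2 <- if (length(summaries) > 1L) {
    apply(matrix(r2_mat, nrow = length(ids)), 1L, stats::sd)
  } else {
    tabs[[1L]]$sd_r2
  }
  aicc_mat <- vapply(tabs, `[[`, numeric(length(ids)), "mean_aicc")
  mean_aicc <- rowMeans(matrix(aicc_mat, nrow = length(ids)))
  wins <- rowSums(vapply(tabs, `[[`, numeric(length(ids)), "n_wins"))
  n_iter <- sum(vapply(summaries, `[[`, numeric(1), "n_iter"))
  finite <- is.finite(mean_aicc)
  delta <- rep(NA_real_, length(ids))
  w <- rep(NA_real_, length(ids))
  if (sum(finite) >= 2L) {
    delta[finite] <- mean_aicc[finite] - min(mean_aicc[finite])
    w[finite] <- akaike_weights(mean_aicc[finite])
  }
  tab <- data.frame(
    model_id = ids,
    mean_r2 = mean_r2,
    sd_r2 = sd_r2,
    mean_aicc = mean_aicc,
    delta = delta,
    w = w,
    n_wins = wins,
    selection_frequency = wins / n_iter,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      scope = "population",
      table = tab,
      n_iter = n_iter,
      afferent_ids = unlist(lapply(summaries, `[[`, "afferent_ids"))
    ),
    class = "selection_summary"
  )
}

#' @export
print.selection_summary <- function(x, digits = 3, ...) {
  cat(sprintf(
    "<selection_summary [%s] over %d iterations (%s)>\n",
    x$scope, x$n_iter, paste(x$afferent_ids, collapse = ", ")
  ))
  tab <- x$table
  tab$mean_r2 <- round(tab$mean_r2, digits)
  tab$sd_r2 <- round(tab$sd_r2, digits)
  tab$mean_aicc <- round(tab$mean_aicc, 1)
  tab$delta <- round(tab$delta, 1)
  tab$w <- round(tab$w, digits)
  tab$selection_frequency <- round(tab$selection_frequency, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}
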