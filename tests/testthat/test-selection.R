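test_that("split plans are reproducible 75/25 partitions at the trial level", {
  ids <- sprintf("t%02d", 1:40)
  sp <- make_splits(ids, n_iter = 100, seed = 5)
  expect_length(sp, 100)
  expect_length(sp[[1]]$train_ids, 30)
  expect_length(sp[[1]]$test_ids, 10)
  for (s in sp[c(1, 50, 100)]) {
    expect_length(intersect(s$train_ids, s$test_ids), 0)
    expect_setequal(c(s$train_ids, s$test_ids), ids)
  }
  sp2 <- make_splits(ids, n_iter = 100, seed = 5)
  expect_identical(sp, sp2)
  expect_false(identical(sp, make_splits(ids, n_iter = 100, seed = 6)))
  expect_error(make_splits(ids[1:30], seed = 1), "too few")
})

test_that("stratified splits keep both stretch types in every test set", {
  ids <- sprintf("t%02d", 1:48)
  strat <- factor(rep(c("ramp_hold_release", "sawtooth"), c(40, 8)))
  sp <- make_splits(ids, n_iter = 25, seed = 2, stratify = strat)
  for (s in sp) {
    expect_true(any(s$test_ids %in% ids[41:48]))
    expect_true(any(s$test_ids %in% ids[1:40]))
  }
})

test_that("AICc matches direct evaluation in both forms", {
  # k = 4, J_test = 0.2 so L = 5, n = 30
  expect_equal(aicc(4, 5, 30, form = "as_printed"),
               2 * (4 - log(5) - 20 / 25))
  expect_equal(aicc(4, 5, 30, form = "as_printed"), 3.1812, tolerance = 1e-4)
  expect_equal(aicc(4, 5, 30, form = "standard"),
               2 * (4 - log(5) + 20 / 25))
  # equal likelihood, equal complexity: equal AICc
  expect_equal(aicc(6, 2, 30), aicc(6, 2, 30))
  # monotone decreasing in the likelihood proxy
  expect_gt(aicc(4, 2, 30), aicc(4, 4, 30))
  expect_error(aicc(4, -1, 30), "positive")
  expect_error(aicc(22, 5, 10), "small sample")
})

test_that("Akaike weights normalize relative likelihoods", {
  expect_equal(akaike_weights(rep(3.3, 6)), rep(1 / 6, 6))
  w <- akaike_weights(c(0, 2))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-9)
  expect_equal(w, c(0.7311, 0.2689), tolerance = 1e-4)
  x <- c(12.3, 9.1, 15.8, 9.0)
  expect_equal(akaike_weights(x), akaike_weights(x + 100))
  expect_equal(sum(akaike_weights(x)), 1, tolerance = 1e-9)
  expect_error(akaike_weights(c(1, NA)), "finite")
  expect_error(akaike_weights(3), "at least 2")
})

test_that("per-iteration winners minimize AICc with deterministic ties", {
  a <- c(force = 10, length = 12, all = 30)
  np <- c(force = 4, length = 6, all = 22)
  expect_equal(select_per_iteration(a, np), "force")
  # tie broken toward fewer parameters
  a2 <- c(force = 10, length = 10, all = 30)
  expect_equal(select_per_iteration(a2, np), "force")
  a3 <- c(m1 = 10, m2 = 10)
  np3 <- c(m1 = 6, m2 = 6)
  expect_equal(select_per_iteration(a3, np3), "m1") # fixed order
  # inadmissible models cannot win
  a4 <- c(force = 10, all = NA)
  expect_equal(select_per_iteration(a4, np[c("force", "all")]), "force")
})

test_that("population summaries average afferents and renormalize weights", {
  mk <- function(r2s, aiccs, wins, id) {
    tab <- data.frame(
      model_id = c("force", "length"), mean_r2 = r2s, sd_r2 = c(0.01, 0.01),
      mean_aicc = aiccs, delta = aiccs - min(aiccs),
      w = akaike_weights(aiccs), n_wins = wins,
      selection_frequency = wins / sum(wins), stringsAsFactors = FALSE
    )
    structure(list(scope = "afferent", table = tab, n_iter = sum(wins),
                   afferent_ids = id), class = "selection_summary")
  }
  s1 <- mk(c(0.8, 0.5), c(10, 20), c(90, 10), "a1")
  s2 <- mk(c(0.6, 0.4), c(12, 18), c(80, 20), "a2")
  pop <- population_summary(list(s1, s2))
  expect_equal(pop$table$mean_r2, c(0.7, 0.45))
  expect_equal(pop$table$mean_aicc, c(11, 19))
  expect_equal(pop$table$w, akaike_weights(c(11, 19)))
  expect_equal(pop$table$selection_frequency, c(170, 30) / 200)
  expect_equal(sum(pop$table$w), 1, tolerance = 1e-9)
  expect_equal(sum(pop$table$selection_frequency), 1)
  # single afferent: population equals the afferent summary
  pop1 <- population_summary(list(s1))
  expect_equal(pop1$table$mean_r2, s1$table$mean_r2)
  expect_equal(pop1$table$w, s1$table$w)
  # mismatched model sets are rejected
  s3 <- s2
  s3$table$model_id <- c("force", "all")
  expect_error(population_summary(list(s1, s3)), "mismatched")
})
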