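# build a sample table with controllable feature-label structure
make_samples <- function(n_per_year, years, label_fun, seed = 1) {
  set.seed(seed)
  out <- NULL
  id0 <- 0
  for (y in years) {
    f <- matrix(rnorm(n_per_year * 18), n_per_year, 18,
                dimnames = list(NULL, sbwrisk:::feature_names()))
    d <- data.frame(tile_id = id0 + seq_len(n_per_year), year = y)
    d <- cbind(d, as.data.frame(f))
    d$label <- label_fun(d)
    id0 <- id0 + n_per_year
    out <- rbind(out, d)
  }
  out[, c("tile_id", "year", "label", sbwrisk:::feature_names())]
}

test_that("roc_threshold and roc_auc reproduce the hand-traced example", {
  prob <- c(0.9, 0.8, 0.6, 0.7, 0.2)
  lab <- c(1, 1, 1, 0, 0)
  expect_equal(roc_threshold(prob, lab), 0.8)      # TPR - FPR = 2/3
  expect_equal(roc_auc(prob, lab), 5 / 6)          # 5 concordant pairs of 6
})

test_that("roc functions agree with exhaustive brute force, including ties", {
  set.seed(99)
  for (i in 1:300) {
    n <- sample(4:50, 1)
    prob <- round(runif(n), sample(c(1, 2, 6), 1))  # coarse rounding forces ties
    lab <- rbinom(n, 1, 0.5)
    if (length(unique(lab)) < 2) next
    want <- oracle_roc(prob, lab)
    expect_equal(roc_threshold(prob, lab), want$threshold)
    expect_equal(roc_auc(prob, lab), want$auc, tolerance = 1e-12)
  }
})

test_that("roc_auc matches an independent ROC implementation", {
  set.seed(5)
  prob <- runif(200); lab <- rbinom(200, 1, plogis(3 * prob - 1.5))
  expect_equal(roc_auc(prob, lab),
               as.numeric(pROC::auc(pROC::roc(lab, prob, quiet = TRUE))))
})

test_that("perfect separation gives AUC 1 and the tie rule picks the highest cutoff", {
  prob <- c(0.9, 0.85, 0.3, 0.2)
  lab <- c(1, 1, 0, 0)
  expect_equal(roc_auc(prob, lab), 1)
  expect_equal(roc_threshold(prob, lab), 0.85)     # highest cutoff in the gap
})

test_that("temporal folds train strictly on earlier years", {
  s <- make_samples(40, 2008:2011, function(d) rbinom(nrow(d), 1, 0.5))
  m <- fit_full_series(s, rf_params(seed = 2))
  expect_equal(names(m$folds), c("2009", "2010", "2011"))
  f11 <- m$folds[["2011"]]
  expect_equal(f11$train_years, 2008:2010)
  expect_equal(f11$n_train, sum(s$year < 2011))
  expect_true(all(f11$test$year == 2011))
  # no pooled test sample predates its fold
  expect_true(all(m$pooled$year >= 2009))
})

test_that("a perfectly separable feature yields pooled AUC 1", {
  s <- make_samples(40, 2008:2010, function(d) as.integer(d$PA_focal > 0))
  m <- fit_full_series(s, rf_params(seed = 3))
  expect_equal(m$auc, 1, tolerance = 0.005)
})

test_that("label-shuffled features give chance-level pooled AUC", {
  s <- make_samples(125, 2008:2011, function(d) rbinom(nrow(d), 1, 0.5),
                    seed = 17)
  m <- fit_full_series(s, rf_params(seed = 4))
  expect_gte(nrow(m$pooled), 300)
  expect_lt(abs(m$auc - 0.5), 0.07)
})

test_that("annual models stratify folds and are seed-deterministic", {
  s <- make_samples(10, 2010, function(d) rep(c(0, 1), 5))
  m <- fit_annual(s, 2010, rf_params(seed = 5))
  sizes <- vapply(m$folds, `[[`, 0, "n_test")
  expect_true(all(sizes == 2))
  for (f in m$folds) expect_equal(sum(f$test$label), 1)   # one of each class

  s2 <- make_samples(60, 2010, function(d) as.integer(d$LPI_focal < 0))
  a <- fit_annual(s2, 2010, rf_params(seed = 6))
  b <- fit_annual(s2, 2010, rf_params(seed = 6))
  expect_identical(a$pooled$prob, b$pooled$prob)
  # separable-by-one-feature construction is learned almost perfectly
  expect_gt(mean(vapply(a$folds, `[[`, 0, "accuracy")), 0.9)
})

test_that("probabilities are probabilities and AUC is rank-invariant", {
  s <- make_samples(50, 2008:2010,
                    function(d) rbinom(nrow(d), 1, plogis(d$LPI_focal)))
  m <- fit_full_series(s, rf_params(seed = 7))
  expect_true(all(m$pooled$prob >= 0 & m$pooled$prob <= 1))
  expect_equal(roc_auc(qlogis(pmin(pmax(m$pooled$prob, 1e-6), 1 - 1e-6)),
                       m$pooled$label), m$auc)
  p <- predict(m, s)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("permutation importance singles out the label-defining feature", {
  s <- make_samples(60, 2008:2010, function(d) as.integer(d$COHESION_3x3 > 0))
  m <- fit_full_series(s, rf_params(seed = 8))
  imp <- permutation_importance(m, n_perm = 20, seed = 9)
  expect_equal(imp$feature[1], "COHESION_3x3")
  expect_gt(imp$mean_decrease[1], 5 * max(imp$mean_decrease[-1]))
})

test_that("partial dependence is flat for an unused feature and refuses extrapolation", {
  # the label is perfectly decided by PA_focal, so trees never split elsewhere
  s <- make_samples(80, 2008:2010, function(d) as.integer(d$PA_focal > 0))
  m <- fit_full_series(s, rf_params(seed = 10))
  pd <- partial_dependence(m, "SHAPE_5x5")
  expect_lt(max(pd$pd) - min(pd$pd), 1e-9)
  pd2 <- partial_dependence(m, "PA_focal")
  expect_gt(max(pd2$pd) - min(pd2$pd), 0.5)        # strong learned response
  expect_error(partial_dependence(m, "PA_focal",
                                  grid = max(s$PA_focal) + 1),
               "extrapolat")
  expect_error(partial_dependence(m, "NOT_A_FEATURE"), "unknown")
})

test_that("metric-level partial dependence clamps all scale copies together", {
  s <- make_samples(60, 2008:2010, function(d) as.integer(d$LPI_focal > 0))
  m <- fit_full_series(s, rf_params(seed = 11))
  pd <- partial_dependence(m, "LPI")
  expect_equal(nrow(pd), 20)
  expect_gt(pd$pd[20], pd$pd[1])                   # rises with LPI here
})
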