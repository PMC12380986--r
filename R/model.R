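#' Random forest hyperparameters
#'
#' The four stated parameters of the likelihood models: 100 trees, minimum
#' terminal-leaf size 9, maximum depth 10, and all available features
#' considered at every split. Remaining details follow the ranger defaults
#' for probability forests (bootstrap sampling, Gini impurity) and are
#' recorded in the run manifest.
#'
#' @param n_trees number of decision trees.
#' @param min_leaf minimum samples per terminal leaf.
#' @param max_depth maximum tree depth.
#' @param features_per_split features tried at each split; `NULL` means all.
#' @param seed integer seed controlling tree growing, fold assignment and
#'   balancing draws.
#' @return validated list of class `sbw_rf_params`.
#' @export
rf_params <- function(n_trees = 100, min_leaf = 9, max_depth = 10,
                      features_per_split = NULL, seed = 1) {
  stopifnot(n_trees >= 1, min_leaf >= 1, max_depth >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 min_leaf = as.integer(min_leaf),
                 max_depth = as.integer(max_depth),
                 features_per_split = features_per_split,
                 seed = as.integer(seed)),
            class = "sbw_rf_params")
}

# ---- ROC machinery -------------------------------------------------------

#' ROC curve points
#'
#' @param probabilities numeric scores.
#' @param labels binary labels (1 = positive).
#' @return data.frame of `threshold`, `tpr`, `fpr`, one row per distinct
#'   score used as a `>=` cutoff, ordered by decreasing threshold, plus the
#'   (0,0) end point at threshold `Inf`.
#' @export
roc_curve <- function(probabilities, labels) {
  stopifnot(length(probabilities) == length(labels))
  cuts <- sort(unique(probabilities), decreasing = TRUE)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  tpr <- vapply(cuts, function(c) sum(probabilities >= c & labels == 1) / np, 0)
  fpr <- vapply(cuts, function(c) sum(probabilities >= c & labels == 0) / nn, 0)
  data.frame(threshold = c(Inf, cuts), tpr = c(0, tpr), fpr = c(0, fpr))
}

#' Area under the ROC curve
#'
#' Mann-Whitney form: the proportion of (positive, negative) pairs ranked
#' concordantly, ties counting one half.
#'
#' @inheritParams roc_curve
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(probabilities, labels) {
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(probabilities)
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' ROC threshold maximizing TPR - FPR
#'
#' Evaluates `TPR - FPR` (Youden's J) at every distinct probability used as
#' a `>=` cutoff and returns the cutoff attaining the maximum; ties resolve
#' to the highest cutoff (the most conservative choice).
#'
#' @inheritParams roc_curve
#' @return the selected threshold.
#' @export
#' @examples
#' roc_threshold(c(0.9, 0.8, 0.6, 0.7, 0.2), c(1, 1, 1, 0, 0))  # 0.8
roc_threshold <- function(probabilities, labels) {
  if (length(probabilities) == 0) stop("no probabilities to threshold")
  rc <- roc_curve(probabilities, labels)
  rc <- rc[is.finite(rc$threshold), ]
  j <- rc$tpr - rc$fpr
  best <- max(j)
  # rows are ordered by decreasing threshold: first attaining row is highest
  rc$threshold[which(j >= best - 1e-12)[1]]
}

# ---- fitting -------------------------------------------------------------

robust_scale_stats <- function(x, quantiles) {
  med <- apply(x, 2, median)
  qr <- apply(x, 2, function(v) diff(quantile(v, quantiles, names = FALSE)))
  drop <- qr <= 0
  if (any(drop))
    warning("dropping constant feature(s): ",
            paste(colnames(x)[drop], collapse = ", "))
  list(median = med, range = qr, keep = colnames(x)[!drop])
}

apply_scale <- function(x, stats) {
  x <- x[, stats$keep, drop = FALSE]
  sweep(sweep(x, 2, stats$median[stats$keep]), 2, stats$range[stats$keep], "/")
}

fit_ranger <- function(x, y, params) {
  mtry <- if (is.null(params$features_per_split)) ncol(x)
          else min(params$features_per_split, ncol(x))
  ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                 probability = TRUE, num.trees = params$n_trees,
                 mtry = mtry, min.node.size = params$min_leaf,
                 max.depth = params$max_depth, seed = params$seed,
                 num.threads = 1)
}

predict_prob <- function(model, x) {
  ranger::predictions(predict(model, data = x, num.threads = 1))[, "1"]
}

new_sbw_rf <- function(type, folds, pooled, params, feature_cfg, scaling,
                       samples, final_model, final_stats) {
  auc <- roc_auc(pooled$prob, pooled$label)
  thr <- roc_threshold(pooled$prob, pooled$label)
  structure(list(type = type, folds = folds, pooled = pooled,
                 auc = auc, threshold = thr,
                 roc = roc_curve(pooled$prob, pooled$label),
                 params = params, feature_cfg = feature_cfg,
                 scaling = scaling, samples = samples,
                 final_model = final_model, final_stats = final_stats),
            class = "sbw_rf")
}

fold_eval <- function(model, stats, test, feature_cols) {
  xte <- apply_scale(as.matrix(test[, feature_cols]), stats)
  prob <- predict_prob(model, xte)
  list(prob = prob,
       accuracy = mean((prob >= 0.5) == (test$label == 1)),
       auc = roc_auc(prob, test$label),
       threshold = roc_threshold(prob, test$label))
}

#' Fit the full time-series likelihood model
#'
#' Expanding-window temporal cross-validation: the fold for year `y` trains
#' a random forest on all samples from years before `y` and tests on year
#' `y` (the first year anchors the window and has no fold). Out-of-fold
#' probabilities pooled across folds give the overall ROC, AUC and
#' TPR-FPR-maximizing threshold. Robust feature scaling (median / 5-95
#' quantile range) is fitted on each fold's training data and applied to its
#' test data (`scaling = "train"`); `scaling = "global"` fits the statistics
#' once on all samples. A final model refitted on all samples backs
#' [predict.sbw_rf()] and [partial_dependence()].
#'
#' @param samples balanced feature table from [build_features()] /
#'   [balance_samples()], several years bound together.
#' @param params an [rf_params()].
#' @param feature_cfg an [feature_config()] (supplies scaling quantiles).
#' @param scaling `"train"` (per-fold, leakage-free; default) or `"global"`.
#' @return object of class `sbw_rf` with elements `folds` (per-year models,
#'   test indices, accuracy, ROC, AUC, threshold), `pooled` (out-of-fold
#'   probabilities), `auc`, `threshold`, `roc`, and the refitted
#'   `final_model`.
#' @export
fit_full_series <- function(samples, params = rf_params(),
                            feature_cfg = feature_config(),
                            scaling = c("train", "global")) {
  scaling <- match.arg(scaling)
  fc <- feature_names()
  fc <- fc[fc %in% names(samples)]
  years <- sort(unique(samples$year))
  if (length(years) < 2) stop("temporal CV needs at least two years")
  global_stats <- robust_scale_stats(as.matrix(samples[, fc]),
                                     feature_cfg$scale_quantiles)
  folds <- list()
  pooled <- NULL
  for (y in years[-1]) {
    train <- samples[samples$year < y, ]
    test <- samples[samples$year == y, ]
    if (nrow(test) == 0 || length(unique(train$label)) < 2) next
    stats <- if (scaling == "train")
      robust_scale_stats(as.matrix(train[, fc]), feature_cfg$scale_quantiles)
    else global_stats
    xtr <- apply_scale(as.matrix(train[, fc]), stats)
    model <- fit_ranger(xtr, train$label, params)
    ev <- fold_eval(model, stats, test, fc)
    folds[[as.character(y)]] <- list(year = y, model = model,
                                     scale_stats = stats,
                                     train_years = years[years < y],
                                     n_train = nrow(train),
                                     n_test = nrow(test),
                                     test = test,
                                     prob = ev$prob,
                                     accuracy = ev$accuracy,
                                     auc = ev$auc, threshold = ev$threshold)
    pooled <- rbind(pooled, data.frame(tile_id = test$tile_id,
                                       year = test$year, prob = ev$prob,
                                       label = test$label))
  }
  if (is.null(pooled)) stop("no usable temporal fold")
  final_model <- fit_ranger(apply_scale(as.matrix(samples[, fc]),
                                        global_stats),
                            samples$label, params)
  new_sbw_rf("full_series", folds, pooled, params, feature_cfg, scaling,
             samples, final_model, global_stats)
}

#' Fit an annual likelihood model
#'
#' Stratified 5-fold cross-validation within one year's (radius-filtered,
#' balanced) samples: folds preserve the class ratio, each fold's model is
#' tested on the held-out fold, and out-of-fold probabilities are pooled for
#' the year's ROC, AUC and threshold.
#'
#' @param samples feature table (one or more years; only `year` is used).
#' @param year the year to model.
#' @param params an [rf_params()].
#' @param feature_cfg an [feature_config()].
#' @param k number of folds (default 5).
#' @param scaling `"train"` or `"global"`, as in [fit_full_series()].
#' @return object of class `sbw_rf` (`type = "annual"`).
#' @export
fit_annual <- function(samples, year, params = rf_params(),
                       feature_cfg = feature_config(), k = 5,
                       scaling = c("train", "global")) {
  scaling <- match.arg(scaling)
  fc <- feature_names()
  fc <- fc[fc %in% names(samples)]
  d <- samples[samples$year == year, ]
  if (nrow(d) == 0 || length(unique(d$label)) < 2)
    stop("year ", year, " has no samples of both classes")
  set.seed(params$seed)
  fold_of <- integer(nrow(d))
  for (cls in c(0, 1)) {
    idx <- which(d$label == cls)
    fold_of[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  global_stats <- robust_scale_stats(as.matrix(d[, fc]),
                                     feature_cfg$scale_quantiles)
  folds <- list()
  pooled <- NULL
  for (f in seq_len(k)) {
    train <- d[fold_of != f, ]
    test <- d[fold_of == f, ]
    if (nrow(test) == 0 || length(unique(train$label)) < 2) next
    stats <- if (scaling == "train")
      robust_scale_stats(as.matrix(train[, fc]), feature_cfg$scale_quantiles)
    else global_stats
    xtr <- apply_scale(as.matrix(train[, fc]), stats)
    model <- fit_ranger(xtr, train$label, params)
    ev <- fold_eval(model, stats, test, fc)
    folds[[f]] <- list(fold = f, model = model, scale_stats = stats,
                       n_train = nrow(train), n_test = nrow(test),
                       test = test, prob = ev$prob,
                       accuracy = ev$accuracy, auc = ev$auc,
                       threshold = ev$threshold)
    pooled <- rbind(pooled, data.frame(tile_id = test$tile_id,
                                       year = test$year, prob = ev$prob,
                                       label = test$label))
  }
  if (is.null(pooled)) stop("year ", year, " yielded no usable fold")
  final_model <- fit_ranger(apply_scale(as.matrix(d[, fc]), global_stats),
                            d$label, params)
  new_sbw_rf("annual", folds, pooled, params, feature_cfg, scaling,
             d, final_model, global_stats)
}

# ---- diagnostics ---------------------------------------------------------

#' Permutation feature importance
#'
#' For every feature and each of `n_perm` shuffles, the feature's column is
#' permuted within every cross-validation fold's held-out data, the fold
#' models re-predict, and the decrease of the model's pooled out-of-fold
#' accuracy (at the 0.5 cutoff) relative to its unshuffled pooled accuracy
#' is recorded. Measuring on held-out folds keeps a feature that the forest
#' merely memorised from registering as important, and pooling before the
#' accuracy comparison keeps per-fold chance skill (which shuffling cannot
#' remove fold by fold) from inflating every feature's apparent importance.
#'
#' Two standard errors accompany the mean decrease. `se` is the Monte-Carlo
#' standard error over shuffles; it measures how precisely the decrease has
#' been estimated for *this* test set and shrinks with `n_perm`. The
#' decrease itself, however, is an accuracy difference estimated on a finite
#' held-out sample: `se_sampling` is the test-set sampling standard error of
#' that difference (standard deviation over samples of the per-sample
#' correctness change, divided by the square root of the pooled test size,
#' averaged over shuffles). Judging whether a feature's importance is
#' distinguishable from zero is a question about the population decrease,
#' so it is `se_sampling` that the answer must be measured against.
#'
#' @param object an `sbw_rf`.
#' @param n_perm shuffles per feature (default 100).
#' @param seed integer seed for the shuffles.
#' @return data.frame of `feature`, `mean_decrease`, `se` and `se_sampling`,
#'   sorted by decreasing mean; the full decrease distribution (features x
#'   shuffles) is attached as attribute `"distribution"`.
#' @export
permutation_importance <- function(object, n_perm = 100, seed = 1) {
  stopifnot(inherits(object, "sbw_rf"))
  set.seed(seed)
  fc <- object$final_stats$keep
  folds <- object$folds
  base_corr <- (object$pooled$prob >= 0.5) == (object$pooled$label == 1)
  base <- mean(base_corr)
  n_pool <- length(base_corr)
  xte <- lapply(folds, function(fold) {
    cols <- feature_names()[feature_names() %in% names(fold$test)]
    apply_scale(as.matrix(fold$test[, cols]), fold$scale_stats)
  })
  ytrue <- lapply(folds, function(fold) fold$test$label == 1)
  dist <- matrix(NA_real_, length(fc), n_perm, dimnames = list(fc, NULL))
  se_samp <- numeric(length(fc))
  for (j in seq_along(fc)) {
    sd_sum <- 0
    for (p in seq_len(n_perm)) {
      corr <- unlist(lapply(seq_along(folds), function(k) {
        xp <- xte[[k]]
        xp[, fc[j]] <- xp[sample(nrow(xp)), fc[j]]
        (predict_prob(folds[[k]]$model, xp) >= 0.5) == ytrue[[k]]
      }))
      diff <- as.numeric(base_corr) - as.numeric(corr)
      dist[j, p] <- mean(diff)
      sd_sum <- sd_sum + sd(diff)
    }
    se_samp[j] <- (sd_sum / n_perm) / sqrt(n_pool)
  }
  out <- data.frame(feature = fc,
                    mean_decrease = rowMeans(dist),
                    se = apply(dist, 1, sd) / sqrt(n_perm),
                    se_sampling = se_samp)
  out <- out[order(-out$mean_decrease), ]
  rownames(out) <- NULL
  attr(out, "distribution") <- dist
  out
}

#' Partial dependence of the fitted likelihood on one feature
#'
#' Standard partial dependence from the final (all-data) model: the feature
#' is clamped to each grid point in turn and the predicted disturbance
#' probability is averaged over all training samples. The default grid is
#' 20 evenly spaced quantiles of the training values between the 5th and
#' 95th percentile (the same robust band the feature scaling uses; the
#' extreme tails are excluded because clamping every sample to a value seen
#' almost nowhere is extrapolation, not dependence). A user-supplied grid
#' outside the training range is refused rather than silently extrapolated.
#'
#' When `feature` names a configuration metric (e.g. `"LPI"`) rather than a
#' single feature column, the metric's focal, 3 x 3 and 5 x 5 copies are
#' clamped together at rank-matched values: at grid rank `q` each scale's
#' column is set to its own `q`-quantile. The three copies of one metric are
#' strongly dependent, and clamping one while the others keep their sample
#' values would average the model over joint combinations the training data
#' never contained; rank-matched clamping traces the dependence on the
#' metric itself, one curve per metric as likelihood models of this kind
#' are usually displayed.
#'
#' @param object an `sbw_rf`.
#' @param feature a feature column name (unscaled, e.g. `"LPI_focal"`) or a
#'   metric name (e.g. `"LPI"`, clamping all scale copies rank-consistently).
#' @param grid optional numeric grid of (unscaled) feature values; only
#'   valid with a single feature column.
#' @param grid_size number of quantile grid points when `grid` is `NULL`.
#' @return data.frame of `value` (feature value; for a metric, the focal
#'   copy's value) and `pd` (mean predicted probability of disturbance).
#' @export
partial_dependence <- function(object, feature, grid = NULL, grid_size = 20) {
  stopifnot(inherits(object, "sbw_rf"))
  fc <- feature_names()
  fc <- fc[fc %in% names(object$samples)]
  x <- as.matrix(object$samples[, fc])
  probs <- seq(0.05, 0.95, length.out = grid_size)
  if (feature %in% METRIC_NAMES) {
    if (!is.null(grid))
      stop("a numeric grid only applies to a single feature column")
    cols <- paste0(feature, "_", SCALE_TAGS)
    cols <- cols[cols %in% object$final_stats$keep]
    if (length(cols) == 0) stop("metric ", feature, " has no usable feature")
    qv <- lapply(cols, function(cl)
      quantile(object$samples[[cl]], probs, names = FALSE))
    pd <- vapply(seq_along(probs), function(i) {
      xg <- x
      for (j in seq_along(cols)) xg[, cols[j]] <- qv[[j]][i]
      mean(predict_prob(object$final_model,
                        apply_scale(xg, object$final_stats)))
    }, 0)
    return(data.frame(value = qv[[1]], pd = pd))
  }
  if (!feature %in% object$final_stats$keep)
    stop("unknown or dropped feature: ", feature)
  v <- object$samples[[feature]]
  if (is.null(grid)) {
    grid <- unique(quantile(v, probs, names = FALSE))
  } else if (any(grid < min(v) | grid > max(v))) {
    stop("grid extends outside the training range of ", feature,
         " [", signif(min(v), 4), ", ", signif(max(v), 4),
         "]; refusing to extrapolate")
  }
  pd <- vapply(grid, function(g) {
    xg <- x
    xg[, feature] <- g
    mean(predict_prob(object$final_model,
                      apply_scale(xg, object$final_stats)))
  }, 0)
  data.frame(value = grid, pd = pd)
}

# ---- S3 methods ----------------------------------------------------------

#' @export
print.sbw_rf <- function(x, ...) {
  cat(sprintf("sbw_rf (%s): %d fold(s), %d pooled test samples\n",
              x$type, length(x$folds), nrow(x$pooled)))
  cat(sprintf("  pooled AUC %.3f, threshold %.3f\n", x$auc, x$threshold))
  invisible(x)
}

#' @export
summary.sbw_rf <- function(object, ...) {
  per_fold <- data.frame(
    fold = names(object$folds),
    n_train = vapply(object$folds, `[[`, 0, "n_train"),
    n_test = vapply(object$folds, `[[`, 0, "n_test"),
    accuracy = vapply(object$folds, `[[`, 0, "accuracy"),
    auc = vapply(object$folds, `[[`, 0, "auc"),
    threshold = vapply(object$folds, `[[`, 0, "threshold"))
  rownames(per_fold) <- NULL
  out <- list(type = object$type, per_fold = per_fold,
              pooled_auc = object$auc, threshold = object$threshold,
              n = nrow(object$pooled))
  class(out) <- "summary.sbw_rf"
  out
}

#' @export
print.summary.sbw_rf <- function(x, ...) {
  cat(sprintf("%s likelihood model: pooled AUC %.3f, threshold %.3f (n = %d)\n",
              x$type, x$pooled_auc, x$threshold, x$n))
  print(x$per_fold, digits = 3)
  invisible(x)
}

#' Predict disturbance probabilities for new tile samples
#'
#' @param object an `sbw_rf`.
#' @param newdata data.frame with the model's feature columns (unscaled,
#'   weighted as produced by [build_features()]).
#' @param ... unused.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
predict.sbw_rf <- function(object, newdata, ...) {
  fc <- feature_names()
  fc <- fc[fc %in% names(newdata)]
  predict_prob(object$final_model,
               apply_scale(as.matrix(newdata[, fc]), object$final_stats))
}

#' Plot the pooled ROC curve with the selected threshold
#'
#' @param x an `sbw_rf`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sbw_rf <- function(x, ...) {
  rc <- x$roc
  graphics::plot(rc$fpr, rc$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC (%s): AUC %.2f", x$type, x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  at <- which.min(abs(rc$threshold - x$threshold))
  graphics::points(rc$fpr[at], rc$tpr[at], pch = 19, col = "red")
  graphics::text(rc$fpr[at], rc$tpr[at],
                 sprintf(" thr %.2f", x$threshold), adj = c(0, 1), col = "red")
  invisible(x)
}
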