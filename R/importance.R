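# shared input checks + per-model complete-case filtering
.importance_prepare <- function(X, y, min_n = 30) {
  X <- as.data.frame(X)
  for (j in seq_along(X)) if (is.character(X[[j]])) X[[j]] <- factor(X[[j]])
  ok <- stats::complete.cases(X) & !is.na(y)
  dropped <- sum(!ok)
  if (dropped) {
    message(dropped, " row(s) with missing predictor/response dropped ",
            "for this importance model")
  }
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  if (length(y) < min_n) {
    stop("importance models need at least ", min_n, " complete observations")
  }
  if (stats::var(y) == 0) stop("response is constant; importance undefined")
  list(X = X, y = y, n = length(y))
}

#' Permutation random-forest moderator importance
#'
#' Fits a random forest of `y` (effect sizes) on the moderator table and
#' reports each predictor's percentage increase in mean squared error when
#' its values are permuted (%IncMSE). A permutation p-value per predictor
#' is obtained by refitting the forest `n_perm` times on a response
#' permuted against the predictors: the p-value is the fraction of
#' permuted refits whose importance is at least the observed one
#' (with the +1 correction).
#'
#' @param X Moderator data frame (continuous and categorical columns;
#'   rows with missing values are dropped per model).
#' @param y Numeric effect sizes.
#' @param n_perm Number of response permutations for p-values (0 skips
#'   them; 99 or more is recommended for a stable p).
#' @param seed RNG seed (forest fitting and permutations).
#' @param ntree,mtry Forest size and split candidates
#'   (default `ceiling(p/3)`).
#' @return Data frame (`importance_result`) with `predictor`, `inc_mse`,
#'   `p_perm`, `n_obs`, sorted by decreasing importance.
#' @export
rf_importance <- function(X, y, n_perm = 99, seed = 1, ntree = 1000,
                          mtry = NULL) {
  d <- .importance_prepare(X, y)
  mtry <- mtry %||% max(1, ceiling(ncol(d$X) / 3))
  set.seed(seed)
  rf <- randomForest::randomForest(d$X, d$y, ntree = ntree, mtry = mtry,
                                   importance = TRUE)
  obs <- randomForest::importance(rf, type = 1, scale = TRUE)[, 1]
  p_perm <- rep(NA_real_, length(obs))
  if (n_perm > 0) {
    exceed <- numeric(length(obs))
    for (b in seq_len(n_perm)) {
      yp <- sample(d$y)
      rfp <- randomForest::randomForest(d$X, yp, ntree = ntree, mtry = mtry,
                                        importance = TRUE)
      imp_p <- randomForest::importance(rfp, type = 1, scale = TRUE)[, 1]
      exceed <- exceed + (imp_p >= obs)
    }
    p_perm <- (exceed + 1) / (n_perm + 1)
  }
  out <- data.frame(predictor = names(obs), inc_mse = unname(obs),
                    p_perm = unname(p_perm), n_obs = d$n)
  out <- out[order(-out$inc_mse), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("importance_result", "data.frame")
  out
}

#' Boosted-tree relative influence of moderators
#'
#' Gradient-boosted regression trees of the effect sizes on the moderators;
#' each predictor's importance is its relative influence -- the share of the
#' ensemble's split gain attributable to it -- normalised to sum to 100
#' across predictors. Categorical moderators are one-hot encoded internally
#' and their encoded columns' influence summed back to the parent
#' predictor.
#'
#' @inheritParams rf_importance
#' @param n_trees Number of boosting iterations (> 0).
#' @param learning_rate Shrinkage per iteration.
#' @param max_depth Tree interaction depth.
#' @return Data frame (`importance_result`) with `predictor`,
#'   `rel_influence` (sums to 100), `n_obs`.
#' @export
abt_importance <- function(X, y, seed = 1, n_trees = 1000,
                           learning_rate = 0.01, max_depth = 3) {
  if (n_trees < 1) stop("n_trees must be a positive integer")
  d <- .importance_prepare(X, y)
  mm <- stats::model.matrix(~ ., data = d$X)[, -1, drop = FALSE]
  map <- attr(stats::model.matrix(~ ., data = d$X), "assign")[-1]
  term_names <- names(d$X)
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(mm, label = d$y)
  booster <- xgboost::xgb.train(
    params = list(eta = learning_rate, max_depth = max_depth,
                  objective = "reg:squarederror", nthread = 1),
    data = dtrain, nrounds = n_trees, verbose = 0)
  # split-gain importance aggregated from the tree dump
  dump <- as.data.frame(xgboost::xgb.model.dt.tree(model = booster))
  splits <- dump[dump$Feature != "Leaf", c("Feature", "Gain")]
  gain <- stats::setNames(rep(0, ncol(mm)), colnames(mm))
  if (nrow(splits)) {
    agg <- tapply(splits$Gain, splits$Feature, sum)
    gain[names(agg)] <- agg
  }
  by_term <- vapply(seq_along(term_names),
                    function(i) sum(gain[map == i]), 0)
  total <- sum(by_term)
  rel <- if (total > 0) 100 * by_term / total else rep(0, length(by_term))
  if (total == 0) warning("boosted ensemble made no splits; influence all 0")
  out <- data.frame(predictor = term_names, rel_influence = rel,
                    n_obs = d$n)
  out <- out[order(-out$rel_influence), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("importance_result", "data.frame")
  out
}

#' Weight-aware random-forest importance via bootstrapped preselection
#'
#' Incorporates meta-analytic weights into the forest by drawing bootstrap
#' samples with probability proportional to the weights, refitting the
#' forest on each, and averaging the %IncMSE importances over the
#' replicates. With equal weights this converges to the plain forest's
#' ranking.
#'
#' @inheritParams rf_importance
#' @param weights Positive observation weights (e.g. `1/(v + tau^2)`).
#' @param n_boot Number of weighted bootstrap replicates (1 is valid but
#'   flagged low-confidence).
#' @return Data frame (`importance_result`) with `predictor`, `inc_mse`
#'   (bootstrap mean), `n_obs`, `n_boot`.
#' @export
weighted_rf_importance <- function(X, y, weights, n_boot = 50, seed = 1,
                                   ntree = 500, mtry = NULL) {
  stopifnot(all(weights > 0), length(weights) == length(y))
  X <- as.data.frame(X)
  ok <- stats::complete.cases(X) & !is.na(y)
  d <- .importance_prepare(X[ok, , drop = FALSE], y[ok])
  weights <- weights[ok]
  if (max(weights) / sum(weights) > 0.99) {
    warning("degenerate weights: one observation carries > 99% of the mass")
  }
  if (n_boot < 2) warning("n_boot = 1: single-replicate importance is valid ",
                          "but low-confidence")
  mtry <- mtry %||% max(1, ceiling(ncol(d$X) / 3))
  set.seed(seed)
  acc <- NULL
  for (b in seq_len(n_boot)) {
    idx <- sample(d$n, d$n, replace = TRUE, prob = weights / sum(weights))
    rf <- randomForest::randomForest(d$X[idx, , drop = FALSE], d$y[idx],
                                     ntree = ntree, mtry = mtry,
                                     importance = TRUE)
    imp <- randomForest::importance(rf, type = 1, scale = TRUE)[, 1]
    acc <- if (is.null(acc)) imp else acc + imp
  }
  avg <- acc / n_boot
  out <- data.frame(predictor = names(avg), inc_mse = unname(avg),
                    n_obs = d$n, n_boot = n_boot)
  out <- out[order(-out$inc_mse), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("importance_result", "data.frame")
  out
}

#' Moderator-importance table across parameters
#'
#' Runs the three importance methods for each parameter's effect sizes
#' against the standard moderator set (continuous and categorical forms
#' both entered) and stacks the results in long format: one row per
#' parameter x predictor x method.
#'
#' @param effects Effect-size data frame.
#' @param predictors Moderator columns to enter.
#' @param by Parameter column.
#' @param min_n Parameters with fewer complete observations are skipped.
#' @param weights Optional weights (defaults to `1/(variance + tau2)` with
#'   `tau2` estimated per parameter) for the weighted forest.
#' @param methods Which of `"rf"`, `"abt"`, `"wrf"` to run.
#' @param seed,ntree,n_trees,n_boot Passed through to the methods.
#' @return Long data frame with columns `parameter`, `predictor`, `method`,
#'   `value`, `n_obs`.
#' @export
moderator_importance <- function(effects,
                                 predictors = c("ecosystem", "plastic_type",
                                                "general_type",
                                                "amount_g_per_kg",
                                                "amount_class", "size_um",
                                                "size_class",
                                                "incubation_days",
                                                "time_class",
                                                "microbial_group"),
                                 by = "parameter_name", min_n = 30,
                                 weights = NULL, methods = c("rf", "abt",
                                                             "wrf"),
                                 seed = 1, ntree = 500, n_trees = 500,
                                 n_boot = 20) {
  predictors <- intersect(predictors, names(effects))
  rows <- list()
  for (p in unique(effects[[by]])) {
    sub <- effects[effects[[by]] == p, , drop = FALSE]
    X <- sub[, predictors, drop = FALSE]
    ok <- stats::complete.cases(X) & !is.na(sub$lnrr)
    if (sum(ok) < min_n) next
    y <- sub$lnrr
    if ("rf" %in% methods) {
      r <- rf_importance(X, y, n_perm = 0, seed = seed, ntree = ntree)
      rows[[length(rows) + 1L]] <-
        data.frame(parameter = p, predictor = r$predictor, method = "rf",
                   value = r$inc_mse, n_obs = r$n_obs)
    }
    if ("abt" %in% methods) {
      r <- abt_importance(X, y, seed = seed, n_trees = n_trees)
      rows[[length(rows) + 1L]] <-
        data.frame(parameter = p, predictor = r$predictor, method = "abt",
                   value = r$rel_influence, n_obs = r$n_obs)
    }
    if ("wrf" %in% methods) {
      w <- weights
      if (is.null(w)) {
        t2 <- estimate_tau2(y[ok], sub$variance[ok])
        w <- 1 / (sub$variance + t2)
      }
      r <- weighted_rf_importance(X, y, w, n_boot = n_boot, seed = seed,
                                  ntree = ntree)
      rows[[length(rows) + 1L]] <-
        data.frame(parameter = p, predictor = r$predictor, method = "wrf",
                   value = r$inc_mse, n_obs = r$n_obs)
    }
  }
  if (!length(rows)) {
    return(data.frame(parameter = character(), predictor = character(),
                      method = character(), value = numeric(),
                      n_obs = integer()))
  }
  do.call(rbind, rows)
}
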