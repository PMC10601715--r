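# restricted log-likelihood of the random/mixed-effects model
# y_i ~ N(X beta, v_i + tau2); X defaults to an intercept column
.reml_ll <- function(tau2, y, v, X) {
  w <- 1 / (v + tau2)
  XtW <- t(X * w)
  XtWX <- XtW %*% X
  beta <- solve(XtWX, XtW %*% y)
  r <- y - X %*% beta
  -0.5 * (sum(log(v + tau2)) + determinant(XtWX, logarithm = TRUE)$modulus +
            sum(w * r^2))
}

.reml_tau2 <- function(y, v, X = matrix(1, length(y), 1L)) {
  upper <- max(10 * stats::var(y), max(v), 0.1)
  opt <- stats::optimize(.reml_ll, c(0, upper), y = y, v = v, X = X,
                         maximum = TRUE, tol = 1e-10)
  # the optimum may sit on the tau2 = 0 boundary
  if (.reml_ll(0, y, v, X) >= opt$objective) 0 else max(0, opt$maximum)
}

#' Between-observation heterogeneity variance
#'
#' Estimates `tau^2`, the variance of true effects over and above sampling
#' error, by restricted maximum likelihood (`"REML"`, default) or the
#' closed-form DerSimonian-Laird moment estimator (`"DL"`), both truncated
#' at zero.
#'
#' @param effects Numeric vector of effect sizes.
#' @param variances Sampling variances (> 0), same length.
#' @param method `"REML"` or `"DL"`.
#' @return Non-negative scalar `tau^2`. With fewer than two effects, 0 with
#'   a warning.
#' @export
estimate_tau2 <- function(effects, variances, method = c("REML", "DL")) {
  method <- match.arg(method)
  k <- length(effects)
  stopifnot(length(variances) == k, all(variances > 0))
  if (k < 2) {
    warning("tau^2 is not estimable from fewer than 2 effects; returning 0")
    return(0)
  }
  if (method == "DL") {
    w <- 1 / variances
    mu <- sum(w * effects) / sum(w)
    Q <- sum(w * (effects - mu)^2)
    denom <- sum(w) - sum(w^2) / sum(w)
    if (denom <= 0) return(0)
    return(max(0, (Q - (k - 1)) / denom))
  }
  .reml_tau2(effects, variances)
}

#' Pool effect sizes with inverse-variance random-effects weights
#'
#' Weights are `w_i = 1 / (v_i + tau^2)`; the pooled mean is the weighted
#' average, its standard error `1 / sqrt(sum w)`, and the confidence
#' interval uses the normal quantile (a t quantile on `k - 1` df via
#' `ci_dist = "t"`). An effect is declared significant when the interval
#' excludes zero. With `tau^2 = 0` this is exactly fixed-effects
#' inverse-variance pooling.
#'
#' @param effects Effect sizes.
#' @param variances Sampling variances (> 0).
#' @param tau2 Heterogeneity variance; estimated by `method` when `NULL`.
#' @param method Passed to [estimate_tau2()] when `tau2` is `NULL`.
#' @param level Confidence level.
#' @param ci_dist `"z"` (default) or `"t"`.
#' @return A `pooled_estimate`: list with `k`, `mean_effect`, `se`,
#'   `ci_low`, `ci_high`, `tau2`, `Q_total`, `p`, `significant`, `weights`.
#' @export
pool_effects <- function(effects, variances, tau2 = NULL,
                         method = c("REML", "DL"), level = 0.95,
                         ci_dist = c("z", "t")) {
  method <- match.arg(method); ci_dist <- match.arg(ci_dist)
  k <- length(effects)
  stopifnot(k >= 1, length(variances) == k, all(variances > 0))
  if (is.null(tau2)) {
    tau2 <- if (k >= 2) estimate_tau2(effects, variances, method) else 0
  }
  w <- 1 / (variances + tau2)
  mu <- sum(w * effects) / sum(w)
  se <- 1 / sqrt(sum(w))
  crit <- if (ci_dist == "z") stats::qnorm(1 - (1 - level) / 2)
          else stats::qt(1 - (1 - level) / 2, df = max(k - 1, 1))
  wf <- 1 / variances
  muf <- sum(wf * effects) / sum(wf)
  Q <- sum(wf * (effects - muf)^2)
  out <- list(k = k, mean_effect = mu, se = se,
              ci_low = mu - crit * se, ci_high = mu + crit * se,
              tau2 = tau2, Q_total = Q,
              p = 2 * stats::pnorm(-abs(mu / se)),
              significant = (mu - crit * se) > 0 | (mu + crit * se) < 0,
              level = level, weights = w)
  class(out) <- "pooled_estimate"
  out
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf(
    "Pooled effect (k = %d): %.4f [%.4f, %.4f] (%.0f%% CI), tau^2 = %.4f%s\n",
    x$k, x$mean_effect, x$ci_low, x$ci_high, 100 * x$level, x$tau2,
    if (x$significant) " *" else ""))
  invisible(x)
}

#' Categorical mixed-effects subgroup analysis with Qm
#'
#' Fits the weighted categorical moderator model: a common residual
#' `tau^2` is estimated (REML on the moderator model, or DL from the
#' residual heterogeneity), weights `1/(v + tau^2)` are formed, and the
#' weighted sum of squares about the grand mean is decomposed into
#' within-level heterogeneity and the between-group statistic
#' `Qm = Q_total - sum(Q_within)`, referred to a chi-square with
#' `(levels - 1)` degrees of freedom. Levels with too few observations
#' (not more than `min_n`) are excluded and listed.
#'
#' @param effects Effect sizes.
#' @param variances Sampling variances.
#' @param groups Factor/character vector of subgroup labels.
#' @param min_n A level is included only when it has strictly more than
#'   `min_n` observations.
#' @param method `tau^2` estimator, `"REML"` or `"DL"`.
#' @param tau2 Optional fixed residual `tau^2` (skips estimation).
#' @return A `subgroup_result`: per-level [pool_effects()] estimates,
#'   `Qm`, `df`, `p_qm`, `Q_total`, `Q_within`, `tau2`, `excluded_levels`.
#' @export
subgroup_qm <- function(effects, variances, groups, min_n = 5,
                        method = c("REML", "DL"), tau2 = NULL) {
  method <- match.arg(method)
  keep0 <- !is.na(groups)
  effects <- effects[keep0]; variances <- variances[keep0]
  groups <- as.character(groups[keep0])
  counts <- table(groups)
  included <- names(counts)[counts > min_n]
  excluded <- setdiff(names(counts), included)
  if (length(included) < 2) {
    stop("subgroup analysis undefined: fewer than 2 levels with more than ",
         min_n, " observations (excluded: ",
         paste(excluded, collapse = ", "), ")")
  }
  keep <- groups %in% included
  y <- effects[keep]; v <- variances[keep]; g <- factor(groups[keep])
  X <- stats::model.matrix(~ 0 + g)
  if (is.null(tau2)) {
    tau2 <- if (method == "REML") {
      .reml_tau2(y, v, X)
    } else {
      # DL on the residual Q of the fixed-effects moderator model
      w <- 1 / v
      Qe <- sum(vapply(levels(g), function(l) {
        i <- g == l
        mu <- sum(w[i] * y[i]) / sum(w[i])
        sum(w[i] * (y[i] - mu)^2)
      }, 0))
      C <- sum(w) - sum(vapply(levels(g), function(l) {
        i <- g == l
        sum(w[i]^2) / sum(w[i])
      }, 0))
      if (C <= 0) 0 else max(0, (Qe - (length(y) - nlevels(g))) / C)
    }
  }
  w <- 1 / (v + tau2)
  grand <- sum(w * y) / sum(w)
  per_level <- lapply(levels(g), function(l) {
    i <- g == l
    pool_effects(y[i], v[i], tau2 = tau2)
  })
  names(per_level) <- levels(g)
  Qw <- sum(vapply(levels(g), function(l) {
    i <- g == l
    mu <- sum(w[i] * y[i]) / sum(w[i])
    sum(w[i] * (y[i] - mu)^2)
  }, 0))
  Qt <- sum(w * (y - grand)^2)
  Qm <- Qt - Qw
  df <- nlevels(g) - 1L
  out <- list(levels = per_level, Qm = Qm, df = df,
              p_qm = stats::pchisq(Qm, df, lower.tail = FALSE),
              Q_total = Qt, Q_within = Qw, tau2 = tau2,
              excluded_levels = excluded, k = length(y))
  class(out) <- "subgroup_result"
  out
}

#' @export
print.subgroup_result <- function(x, ...) {
  cat(sprintf("Subgroup heterogeneity: Qm = %.3f, df = %d, p = %.4g (k = %d)\n",
              x$Qm, x$df, x$p_qm, x$k))
  for (l in names(x$levels)) {
    e <- x$levels[[l]]
    cat(sprintf("  %-12s k = %3d  %.4f [%.4f, %.4f]%s\n", l, e$k,
                e$mean_effect, e$ci_low, e$ci_high,
                if (e$significant) " *" else ""))
  }
  if (length(x$excluded_levels)) {
    cat("  excluded (too few observations):",
        paste(x$excluded_levels, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-parameter forest table
#'
#' Pools each parameter's effect sizes and returns one row per parameter:
#' the content of a forest plot. Optionally adds a pooled `functionality`
#' row synthesised from the functional indicator subset.
#'
#' @param effects Effect-size data frame (needs `lnrr`, `variance` and the
#'   `by` column).
#' @param by Grouping column, default `"parameter_name"`.
#' @param method `tau^2` estimator.
#' @param min_k Parameters with fewer observations are dropped.
#' @param functionality Add the synthesised functionality row?
#' @param indicators Functional indicator list.
#' @param p_adjust Multiple-testing adjustment for the per-parameter
#'   p-values (default `"none"`, matching the raw-p reporting convention;
#'   e.g. `"BH"` for Benjamini-Hochberg).
#' @return Data frame with parameter, k, mean, CI, tau2, p, significant.
#' @export
meta_table <- function(effects, by = "parameter_name",
                       method = c("REML", "DL"), min_k = 3,
                       functionality = TRUE,
                       indicators = default_functionality_indicators(),
                       p_adjust = "none") {
  method <- match.arg(method)
  groups <- split(effects, effects[[by]])
  groups <- groups[vapply(groups, nrow, 0L) >= min_k]
  if (functionality) {
    fun <- suppressWarnings(aggregate_functionality(effects, indicators))
    if (nrow(fun) >= min_k) groups <- c(groups, list(functionality = fun))
  }
  rows <- lapply(names(groups), function(nm) {
    p <- pool_effects(groups[[nm]]$lnrr, groups[[nm]]$variance,
                      method = method)
    data.frame(parameter = nm, k = p$k, mean_effect = p$mean_effect,
               se = p$se, ci_low = p$ci_low, ci_high = p$ci_high,
               tau2 = p$tau2, p = p$p, significant = p$significant)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = p_adjust)
  out[order(out$parameter), , drop = FALSE]
}
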