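#' Egger regression test for funnel-plot asymmetry
#'
#' Regresses the standard normal deviate of each effect (`effect / se`) on
#' its precision (`1 / se`); the intercept estimates small-study asymmetry
#' and is zero for a funnel symmetric about the pooled effect. The
#' two-sided p-value uses the t distribution on `k - 2` df.
#'
#' @param effects Effect sizes.
#' @param variances Sampling variances (> 0). At least 3 effects are
#'   required; 10 or more are recommended for any power.
#' @return A `bias_result`: `egger_intercept`, `egger_se`, `egger_p`,
#'   `slope`, `k`.
#' @export
egger_test <- function(effects, variances) {
  k <- length(effects)
  stopifnot(length(variances) == k, all(variances > 0))
  if (k < 3) stop("Egger regression needs at least 3 effects")
  se <- sqrt(variances)
  fit <- stats::lm(I(effects / se) ~ I(1 / se))
  sm <- summary(fit)$coefficients
  out <- list(egger_intercept = unname(sm[1, 1]),
              egger_se = unname(sm[1, 2]),
              egger_p = unname(sm[1, 4]),
              slope = unname(sm[2, 1]), k = k)
  class(out) <- "bias_result"
  out
}

#' @export
print.bias_result <- function(x, ...) {
  cat(sprintf("Egger test (k = %d): intercept %.4f (se %.4f), p = %.4g\n",
              x$k, x$egger_intercept, x$egger_se, x$egger_p))
  invisible(x)
}

#' Rosenthal fail-safe number
#'
#' The smallest number of hypothetical zero-effect studies whose addition
#' would push the Stouffer combined z-test of the pooled effect above
#' `alpha` (two-sided). Zero when the combined test is already
#' non-significant. Closed form: with `S = sum(z_i)`, the fail-safe number
#' is `ceiling(S^2 / z_crit^2 - k)`.
#'
#' @param effects Effect sizes.
#' @param variances Sampling variances (> 0).
#' @param alpha Significance threshold.
#' @return Non-negative integer.
#' @export
failsafe_n <- function(effects, variances, alpha = 0.05) {
  k <- length(effects)
  stopifnot(k >= 1, length(variances) == k, all(variances > 0))
  z <- effects / sqrt(variances)
  S <- sum(z)
  zcrit <- stats::qnorm(1 - alpha / 2)
  if (abs(S) / sqrt(k) <= zcrit) return(0L)
  as.integer(ceiling(S^2 / zcrit^2 - k))
}

#' Per-parameter publication-bias table
#'
#' Egger asymmetry and fail-safe number for each parameter with at least
#' `min_k` effect sizes.
#'
#' @param effects Effect-size data frame (`lnrr`, `variance`, `by` column).
#' @param by Grouping column.
#' @param min_k Minimum effects per parameter.
#' @param alpha Passed to [failsafe_n()].
#' @return Data frame with one row per parameter.
#' @export
publication_bias_table <- function(effects, by = "parameter_name",
                                   min_k = 3, alpha = 0.05) {
  groups <- split(effects, effects[[by]])
  groups <- groups[vapply(groups, nrow, 0L) >= min_k]
  rows <- lapply(names(groups), function(nm) {
    g <- groups[[nm]]
    e <- egger_test(g$lnrr, g$variance)
    data.frame(parameter = nm, k = e$k,
               egger_intercept = e$egger_intercept,
               egger_se = e$egger_se, egger_p = e$egger_p,
               failsafe_n = failsafe_n(g$lnrr, g$variance, alpha))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(parameter = character(), k = integer(),
                      egger_intercept = numeric(), egger_se = numeric(),
                      egger_p = numeric(), failsafe_n = integer())
  }
  out
}
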