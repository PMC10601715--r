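# all cascade candidates are fitted with weights normalised to sum to n so
# their (weighted) Gaussian log-likelihoods, hence AICs, are comparable
.dose_token <- function(x, y) c(length(x), sum(x), sum(y))

.new_dose_fit <- function(kind, x, y, weights, fit, extra = list()) {
  out <- c(list(model_kind = kind, n = length(x), fit = fit,
                x_range = range(x), token = .dose_token(x, y),
                weights = weights),
           extra)
  class(out) <- "dose_fit"
  out
}

#' @export
print.dose_fit <- function(x, ...) {
  cat(sprintf("%s fit (n = %d): AIC = %.2f, r2 = %.3f, p = %.3g\n",
              x$model_kind, x$n, x$aic, x$r2, x$p_model))
  if (!is.null(x$breakpoint) && !is.na(x$breakpoint)) {
    cat(sprintf("  breakpoint c = %.4f (se %.4f); slopes %.5f -> %.5f\n",
                x$breakpoint, x$breakpoint_se, x$beta1, x$beta1 + x$beta2))
  }
  invisible(x)
}

#' Linear dose-response fit (ordinary or weighted least squares)
#'
#' Unweighted OLS treats every observation equally; with meta-analytic
#' weights (`1/(v + tau^2)`) it becomes a weighted meta-regression. AIC is
#' computed from the (weighted) Gaussian log-likelihood with weights
#' normalised to sum to `n`.
#'
#' @param x Predictor (dose: amount, size or time).
#' @param y Response (effect sizes).
#' @param weights Optional positive weights.
#' @return A `dose_fit` with coefficients, `aic`, `r2`, `p_model`,
#'   `residual_se` and a `predict_fn`.
#' @export
fit_linear <- function(x, y, weights = NULL) {
  n <- length(x)
  stopifnot(n >= 3, length(y) == n)
  if (length(unique(x)) < 2) stop("constant predictor: rank-deficient fit")
  kind <- if (is.null(weights)) "ols" else "wls"
  w <- if (is.null(weights)) rep(1, n) else normalize_weights(weights)
  fit <- stats::lm(y ~ x, weights = w)
  sm <- summary(fit)
  pf <- if (nrow(sm$coefficients) > 1) sm$coefficients[2, 4] else NA_real_
  b <- coef(fit)
  .new_dose_fit(kind, x, y, w, fit, list(
    beta0 = unname(b[1]), beta1 = unname(b[2]), beta2 = NA_real_,
    breakpoint = NA_real_, breakpoint_se = NA_real_,
    residual_se = sm$sigma, aic = stats::AIC(fit),
    r2 = sm$r.squared, p_model = pf,
    predict_fn = function(newx) unname(b[1] + b[2] * newx)))
}

#' Penalised-spline smooth dose-response fit
#'
#' A generalized additive model `y ~ s(x)` (thin-plate spline, smoothness
#' chosen by GCV) describing nonlinear dose-response patterns; AIC accounts
#' for the effective degrees of freedom of the smooth.
#'
#' @inheritParams fit_linear
#' @param k Spline basis dimension; shrunk with a warning when `n` is small.
#' @return A `dose_fit`.
#' @export
fit_gam <- function(x, y, weights = NULL, k = 10) {
  n <- length(x)
  stopifnot(n >= 10, length(y) == n)
  nx <- length(unique(x))
  if (nx < k + 1) {
    k <- max(3, nx - 1)
    warning("few distinct predictor values: spline basis reduced to k = ", k)
  }
  w <- if (is.null(weights)) rep(1, n) else normalize_weights(weights)
  dat <- data.frame(x = x, y = y)
  fit <- mgcv::gam(y ~ s(x, k = k), data = dat, weights = w,
                   method = "GCV.Cp")
  sm <- summary(fit)
  .new_dose_fit("gam", x, y, w, fit, list(
    beta0 = unname(coef(fit)[1]), beta1 = NA_real_, beta2 = NA_real_,
    breakpoint = NA_real_, breakpoint_se = NA_real_,
    residual_se = sqrt(fit$sig2), aic = stats::AIC(fit),
    r2 = sm$r.sq, p_model = unname(sm$s.table[1, "p-value"]),
    edf = sum(fit$edf),
    predict_fn = function(newx) {
      as.numeric(predict(fit, newdata = data.frame(x = newx)))
    }))
}

#' Select between the linear fit and the smooth by the 2-unit AIC rule
#'
#' The smooth (GAM) is preferred only when its AIC undercuts the ordinary
#' linear fit's by at least 2 units; ties and smaller gaps go to the linear
#' fit (parsimony). A broken-stick threshold search is warranted only when
#' the nonlinear model wins.
#'
#' @param linear_fit,gam_fit `dose_fit` objects on identical data.
#' @return The selected `dose_fit`, with attribute `"gam_selected"`.
#' @export
select_model <- function(linear_fit, gam_fit) {
  if (!isTRUE(all.equal(linear_fit$token, gam_fit$token))) {
    stop("candidate fits were not computed on identical data")
  }
  gam_wins <- gam_fit$aic <= linear_fit$aic - 2
  out <- if (gam_wins) gam_fit else linear_fit
  attr(out, "gam_selected") <- gam_wins
  out
}

# weighted RSS of the one-breakpoint model at fixed c
.seg_rss <- function(cc, x, y, w) {
  f <- stats::lm.wfit(cbind(1, x, pmax(x - cc, 0)), y, w)
  sum(w * f$residuals^2)
}

#' Grid-search broken-stick fit (shipped oracle)
#'
#' Profiles the breakpoint over a dense grid of candidate values inside the
#' predictor range, refitting the two-slope model at each, and returns the
#' candidate minimising the weighted residual sum of squares. Slow but
#' global; it is the reference the iterative estimator is checked against,
#' and its fallback.
#'
#' @inheritParams fit_linear
#' @param n_grid Number of candidate breakpoints.
#' @param interior Quantile pair bounding the candidate range.
#' @return List with `breakpoint` and `rss`.
#' @export
fit_segmented_grid <- function(x, y, weights = NULL, n_grid = 500,
                               interior = c(0.02, 0.98)) {
  w <- if (is.null(weights)) rep(1, length(x)) else normalize_weights(weights)
  lim <- stats::quantile(x, interior, names = FALSE)
  cs <- seq(lim[1], lim[2], length.out = n_grid)
  rss <- vapply(cs, .seg_rss, 0, x = x, y = y, w = w)
  list(breakpoint = cs[which.min(rss)], rss = min(rss))
}

#' Broken-stick (segmented) dose-response fit
#'
#' Fits `Y = b0 + b1 X + b2 (X - c) * 1[X > c] + e`: two joined straight
#' lines whose slope changes from `b1` to `b1 + b2` at the threshold `c`
#' ("infection point"), with the mean response continuous at `c`. `c` is
#' estimated by iterative linearization (Muggeo's method) from `c_init`,
#' refining until the breakpoint update falls below `tol`; if the iteration
#' cycles, diverges, or lands in a worse optimum than the dense grid
#' profile ([fit_segmented_grid()]), the grid optimum is adopted and
#' polished. The breakpoint standard error comes from the final
#' linearization. When no interior breakpoint improves on the straight
#' line, the linear fit is returned (breakpoint `NA`) with a warning.
#'
#' @inheritParams fit_linear
#' @param c_init Starting breakpoint, default the sample median.
#' @param tol Convergence tolerance on `c`.
#' @param max_iter Maximum Muggeo iterations.
#' @param n_grid Grid size for the profile check/fallback.
#' @return A `dose_fit` with `beta0`, `beta1`, `beta2`, `breakpoint`,
#'   `breakpoint_se`; AIC counts the breakpoint as one extra parameter.
#' @export
fit_segmented <- function(x, y, weights = NULL, c_init = stats::median(x),
                          tol = 1e-8, max_iter = 50, n_grid = 500) {
  n <- length(x)
  stopifnot(n >= 8, length(y) == n)
  w <- if (is.null(weights)) rep(1, n) else normalize_weights(weights)
  lim <- stats::quantile(x, c(0.02, 0.98), names = FALSE)
  if (!any(x < c_init) || !any(x > c_init)) c_init <- mean(lim)

  muggeo <- function(c0) {
    c_cur <- c0
    se <- NA_real_
    for (i in seq_len(max_iter)) {
      U <- pmax(x - c_cur, 0)
      V <- -as.numeric(x > c_cur)
      f <- tryCatch(stats::lm(y ~ x + U + V, weights = w),
                    error = function(e) NULL)
      if (is.null(f)) return(NULL)
      b <- coef(f)
      if (anyNA(b) || abs(b["U"]) < 1e-12) return(NULL)
      c_new <- c_cur + b["V"] / b["U"]
      c_new <- min(max(c_new, lim[1]), lim[2])
      sm <- tryCatch(summary(f)$coefficients, error = function(e) NULL)
      if (!is.null(sm) && "V" %in% rownames(sm)) {
        se <- sm["V", "Std. Error"] / abs(b["U"])
      }
      if (abs(c_new - c_cur) < tol) {
        return(list(breakpoint = unname(c_new), se = unname(se),
                    rss = .seg_rss(unname(c_new), x, y, w)))
      }
      c_cur <- c_new
    }
    NULL # did not converge within max_iter
  }

  sol <- muggeo(c_init)
  grid <- fit_segmented_grid(x, y, weights = w, n_grid = n_grid)
  grid_step <- diff(lim) / (n_grid - 1)
  if (is.null(sol) || grid$rss < sol$rss - 1e-12) {
    polished <- muggeo(grid$breakpoint)
    sol <- if (!is.null(polished) && polished$rss <= grid$rss + 1e-12) {
      polished
    } else {
      list(breakpoint = grid$breakpoint, se = NA_real_, rss = grid$rss)
    }
  }

  if (is.na(sol$se)) {
    # one linearization at the final breakpoint gives the delta-method se
    U <- pmax(x - sol$breakpoint, 0)
    V <- -as.numeric(x > sol$breakpoint)
    sm <- tryCatch(summary(stats::lm(y ~ x + U + V,
                                     weights = w))$coefficients,
                   error = function(e) NULL)
    if (!is.null(sm) && all(c("U", "V") %in% rownames(sm))) {
      sol$se <- sm["V", "Std. Error"] / abs(sm["U", "Estimate"])
    }
  }

  lin <- fit_linear(x, y, weights = w)
  rss_lin <- sum(w * stats::residuals(lin$fit)^2)
  interior_ok <- sol$breakpoint > min(x) + grid_step / 2 &&
    sol$breakpoint < max(x) - grid_step / 2
  if (!interior_ok || sol$rss >= rss_lin - 1e-12) {
    warning("no interior breakpoint improves on the linear fit; ",
            "returning the linear fit (breakpoint = NA)")
    return(lin)
  }

  cc <- sol$breakpoint
  U <- pmax(x - cc, 0)
  fit <- stats::lm(y ~ x + U, weights = w)
  sm <- summary(fit)
  b <- coef(fit)
  pf <- stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                  lower.tail = FALSE)
  .new_dose_fit("segmented", x, y, w, fit, list(
    beta0 = unname(b[1]), beta1 = unname(b[2]), beta2 = unname(b[3]),
    breakpoint = cc, breakpoint_se = sol$se,
    residual_se = sm$sigma,
    aic = stats::AIC(fit) + 2,  # the estimated breakpoint is a parameter
    r2 = sm$r.squared, p_model = unname(pf),
    predict_fn = function(newx) {
      unname(b[1] + b[2] * newx + b[3] * pmax(newx - cc, 0))
    }))
}

#' Smallest sign-change threshold of a fitted dose-response curve
#'
#' Scans the fitted mean response over `x_range` on a dense grid and
#' returns the smallest predictor value where it changes sign, refined by
#' bisection; `NA` when the prediction never changes sign. For a
#' functionality dose-response this is the dose/size at which the effect
#' turns from positive to negative.
#'
#' @param fit A `dose_fit`.
#' @param x_range Numeric length-2 search interval; defaults to the fitted
#'   range.
#' @param n_grid Scan resolution.
#' @return Scalar root or `NA`.
#' @export
zero_crossing <- function(fit, x_range = fit$x_range, n_grid = 1000) {
  f <- fit$predict_fn
  xs <- seq(x_range[1], x_range[2], length.out = n_grid)
  ys <- f(xs)
  exact <- which(ys == 0)
  flip <- which(ys[-1] * ys[-n_grid] < 0)
  first_exact <- if (length(exact)) exact[1] else Inf
  first_flip <- if (length(flip)) flip[1] else Inf
  if (is.infinite(first_exact) && is.infinite(first_flip)) return(NA_real_)
  if (first_exact < first_flip) return(xs[first_exact])
  i <- first_flip
  stats::uniroot(function(z) f(z), c(xs[i], xs[i + 1]), tol = 1e-10)$root
}

#' Full dose-response model cascade
#'
#' Runs the model-selection cascade on one predictor/response pair:
#' unweighted OLS, weighted meta-regression (when weights are given), and
#' the penalised smooth; the smooth is retained only if it beats the OLS
#' AIC by 2 units ([select_model()]), and only then is the broken-stick
#' threshold model fitted and its breakpoint and sign-change threshold
#' reported.
#'
#' @inheritParams fit_linear
#' @return List with elements `ols`, `wls` (or `NULL`), `gam`,
#'   `segmented` (or `NULL`), `selected` (a model-kind string),
#'   `breakpoint`, `zero_crossing`.
#' @export
fit_dose_response <- function(x, y, weights = NULL) {
  ols <- fit_linear(x, y)
  wls <- if (!is.null(weights)) fit_linear(x, y, weights) else NULL
  gam <- fit_gam(x, y, weights)
  chosen <- select_model(ols, gam)
  seg <- NULL
  selected <- if (!is.null(wls)) "wls" else "ols"
  bp <- NA_real_
  zc <- NA_real_
  if (attr(chosen, "gam_selected")) {
    selected <- "gam"
    seg <- withCallingHandlers(
      fit_segmented(x, y, weights),
      warning = function(w) invokeRestart("muffleWarning"))
    if (seg$model_kind == "segmented") {
      selected <- "segmented"
      bp <- seg$breakpoint
      zc <- zero_crossing(seg)
    } else {
      seg <- NULL
      zc <- zero_crossing(gam)
    }
  } else {
    zc <- zero_crossing(if (!is.null(wls)) wls else ols)
  }
  list(ols = ols, wls = wls, gam = gam, segmented = seg,
       selected = selected, breakpoint = bp, zero_crossing = zc)
}
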