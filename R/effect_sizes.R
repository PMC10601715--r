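#' Log response ratio
#'
#' The effect size for a control-versus-treatment comparison of a positive
#' quantity: `lnRR = ln(x_t) - ln(x_c)`. It is symmetric around zero
#' (swapping the groups flips the sign) and independent of measurement
#' units.
#'
#' @param x_t Treatment mean(s), strictly positive.
#' @param x_c Control mean(s), strictly positive.
#' @return Numeric vector of log response ratios.
#' @export
lnrr <- function(x_t, x_c) {
  if (any(!is.finite(x_t) | x_t <= 0) || any(!is.finite(x_c) | x_c <= 0)) {
    stop("lnRR is undefined for non-positive means")
  }
  log(x_t) - log(x_c)
}

#' Sampling variance of the log response ratio
#'
#' `v = s_t^2 / (n_t * x_t^2) + s_c^2 / (n_c * x_c^2)`, the delta-method
#' variance from the two group means. Strictly decreasing in both replicate
#' counts; zero only when both SDs are zero. Missing SDs must be imputed
#' (see [impute_missing_sd()]) before this is called.
#'
#' @param sd_t,sd_c Group standard deviations (>= 0).
#' @param n_t,n_c Replicate counts (>= 1).
#' @param x_t,x_c Group means (non-zero).
#' @return Numeric vector of variances.
#' @export
lnrr_variance <- function(sd_t, n_t, x_t, sd_c, n_c, x_c) {
  if (any(is.na(sd_t)) || any(is.na(sd_c))) {
    stop("missing SD: run impute_missing_sd() before computing variances")
  }
  stopifnot(all(sd_t >= 0), all(sd_c >= 0),
            all(n_t >= 1), all(n_c >= 1),
            all(x_t != 0), all(x_c != 0))
  sd_t^2 / (n_t * x_t^2) + sd_c^2 / (n_c * x_c^2)
}

#' Impute missing standard deviations from pooled coefficients of variation
#'
#' For each group (control or treatment) lacking an SD, the SD is
#' approximated as the reported group mean times an average coefficient of
#' variation (CV = SD / mean). The averaging pool is all complete groups
#' reporting the same parameter; when that pool holds fewer than `min_pool`
#' CVs it falls back to the dataset-wide pool. Imputed groups are flagged in
#' logical columns `sd_control_imputed` / `sd_treatment_imputed`.
#'
#' @param obs Observation data frame.
#' @param min_pool Minimum per-parameter pool size before falling back to
#'   the dataset-wide pool.
#' @return `obs` with SDs filled and imputation flags added.
#' @export
impute_missing_sd <- function(obs, min_pool = 3) {
  cv_of <- function(s, m) ifelse(!is.na(s) & !is.na(m) & m > 0, s / m, NA_real_)
  cvs <- c(cv_of(obs$sd_control, obs$mean_control),
           cv_of(obs$sd_treatment, obs$mean_treatment))
  par <- rep(obs$parameter_name, 2L)
  pool_all <- cvs[!is.na(cvs)]
  obs$sd_control_imputed <- FALSE
  obs$sd_treatment_imputed <- FALSE
  need <- is.na(obs$sd_control) | is.na(obs$sd_treatment)
  if (!any(need)) return(obs)
  if (!length(pool_all)) {
    stop("no complete observations to form a CV imputation pool; ",
         "drop the SD-less records instead")
  }
  mean_cv_for <- function(p) {
    pool <- cvs[!is.na(cvs) & par == p]
    if (length(pool) < min_pool) pool <- pool_all
    mean(pool)
  }
  for (i in which(need)) {
    cv <- mean_cv_for(obs$parameter_name[i])
    if (is.na(obs$sd_control[i])) {
      obs$sd_control[i] <- cv * obs$mean_control[i]
      obs$sd_control_imputed[i] <- TRUE
    }
    if (is.na(obs$sd_treatment[i])) {
      obs$sd_treatment[i] <- cv * obs$mean_treatment[i]
      obs$sd_treatment_imputed[i] <- TRUE
    }
  }
  obs
}

#' Compute observation-level effect sizes
#'
#' Adds `lnrr`, `variance` and `sd_imputed` columns to a validated
#' observation table. Missing SDs are imputed first (CV method); rows whose
#' means are not strictly positive are excluded -- the ratio is undefined
#' for them -- and reported in the `"excluded"` attribute (row number plus
#' reason) and via a message, never silently dropped.
#'
#' @param obs Observation data frame.
#' @param impute Impute missing SDs before computing variances?
#' @param min_pool Passed to [impute_missing_sd()].
#' @return Effect-size data frame (excluded rows removed), with attribute
#'   `"excluded"`.
#' @export
compute_effect_sizes <- function(obs, impute = TRUE, min_pool = 3) {
  if (impute && any(is.na(obs$sd_control) | is.na(obs$sd_treatment))) {
    obs <- impute_missing_sd(obs, min_pool = min_pool)
  }
  if (is.null(obs$sd_control_imputed)) obs$sd_control_imputed <- FALSE
  if (is.null(obs$sd_treatment_imputed)) obs$sd_treatment_imputed <- FALSE
  bad_mean <- !(obs$mean_control > 0 & obs$mean_treatment > 0)
  bad_sd <- is.na(obs$sd_control) | is.na(obs$sd_treatment)
  excluded <- data.frame(
    row = which(bad_mean | bad_sd),
    reason = ifelse(bad_mean[bad_mean | bad_sd],
                    "non-positive mean: lnRR undefined", "missing SD"))
  if (nrow(excluded)) {
    message(nrow(excluded), " observation(s) excluded from effect sizes (",
            paste(unique(excluded$reason), collapse = "; "), ")")
  }
  keep <- obs[!(bad_mean | bad_sd), , drop = FALSE]
  keep$lnrr <- lnrr(keep$mean_treatment, keep$mean_control)
  keep$variance <- lnrr_variance(keep$sd_treatment, keep$n_treatment,
                                 keep$mean_treatment,
                                 keep$sd_control, keep$n_control,
                                 keep$mean_control)
  keep$sd_imputed <- keep$sd_control_imputed | keep$sd_treatment_imputed
  attr(keep, "excluded") <- excluded
  keep
}

#' Mean pairwise ordination distances within and between groups
#'
#' From 2-D ordination coordinates (the first two axes of a PCA/PCoA/NMDS
#' plot), computes `Dc` and `Dt`, the mean Euclidean distance over all
#' unordered within-group pairs of the control and treatment clouds, and
#' `Db`, the mean distance over all control x treatment pairs.
#'
#' @param control,treatment Two-column numeric matrices of coordinates,
#'   at least two rows each.
#' @return List with elements `Dc`, `Dt`, `Db`.
#' @export
ordination_distances <- function(control, treatment) {
  control <- as.matrix(control); treatment <- as.matrix(treatment)
  if (nrow(control) < 2 || nrow(treatment) < 2) {
    stop("need at least 2 points per group for within-group distances")
  }
  if (ncol(control) != 2 || ncol(treatment) != 2) {
    stop("coordinates must have exactly two ordination axes")
  }
  nc <- nrow(control)
  full <- as.matrix(stats::dist(rbind(control, treatment)))
  between <- full[seq_len(nc), nc + seq_len(nrow(treatment)), drop = FALSE]
  list(Dc = mean(stats::dist(control)),
       Dt = mean(stats::dist(treatment)),
       Db = mean(between))
}

#' Beta-diversity and community-structure response ratios
#'
#' `lnRRb = ln(Dt / Dc)` compares within-group dispersion (beta-diversity)
#' between treatment and control; `lnRRs = ln(Db / (Dc + Dt))` measures the
#' separation of the two clouds relative to their combined within-group
#' dispersion (community-structure shift). Both are invariant to a joint
#' rescaling of all coordinates.
#'
#' @param Dc,Dt,Db Mean within-control, within-treatment and between-group
#'   distances, all strictly positive (see [ordination_distances()]).
#' @return List with elements `lnrr_beta` and `lnrr_structure`.
#' @export
lnrr_beta_structure <- function(Dc, Dt, Db) {
  if (any(c(Dc, Dt, Db) <= 0) || any(!is.finite(c(Dc, Dt, Db)))) {
    stop("ordination response ratios undefined for zero distances")
  }
  list(lnrr_beta = log(Dt) - log(Dc),
       lnrr_structure = log(Db) - log(Dc + Dt))
}

#' Default functional indicator set
#'
#' Microbial parameters treated as components of soil functionality:
#' hydrolytic activity (FDA), soil respiration, carbon-, nitrogen- and
#' phosphorus-acquisition enzymes, and oxidative decomposition enzymes.
#' User-overridable wherever it is consumed.
#'
#' @return Character vector of parameter names.
#' @export
default_functionality_indicators <- function() {
  c("fda", "soil_respiration", "c_acq", "n_acq", "p_acq", "ox")
}

#' Tag the functionality subset of an effect-size table
#'
#' Returns the effect sizes whose `parameter_name` is in `indicators`, with
#' `parameter_group` set to `"functionality"` so they pool as one synthetic
#' parameter downstream. Indicator directions are pooled as-is (no sign
#' harmonisation): an overall functionality gain can coexist with a decline
#' in an individual indicator. The input table is not modified.
#'
#' @param effects Effect-size data frame.
#' @param indicators Functional parameter names;
#'   defaults to [default_functionality_indicators()].
#' @return The tagged subset (possibly empty, with a warning).
#' @export
aggregate_functionality <- function(effects,
                                    indicators =
                                      default_functionality_indicators()) {
  sub <- effects[effects$parameter_name %in% indicators, , drop = FALSE]
  if (!nrow(sub)) {
    warning("no observations match the functionality indicator list")
    return(sub)
  }
  sub$parameter_group <- "functionality"
  sub
}
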