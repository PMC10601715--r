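#' Configuration for the synthetic meta-dataset generator
#'
#' Defaults emulate a literature-survey meta-dataset of control-versus-
#' plastic comparisons: about 48 studies contributing ~15 observations each
#' (~710 comparisons); positive lognormal group means; heteroscedastic SDs
#' from a common coefficient of variation; replicate counts of 3-6; a
#' fraction of SDs missing; moderator-dependent true effects, including a
#' planted broken-stick (hormetic) amount-functionality dose response with
#' a positive pre-threshold slope and a declining-but-positive plateau
#' beyond it. Parameter base effects mirror the directions typical of soil
#' plastic-residue experiments (biomass and SOC depressed, functional
#' activities mostly stimulated, C-acquisition inhibited).
#'
#' @param n_studies,obs_per_study Number of studies and observations each.
#' @param tau2_true Between-observation (study-level) heterogeneity
#'   variance on the lnRR scale.
#' @param cv_true Within-group coefficient of variation of replicate
#'   measurements.
#' @param missing_sd_fraction Fraction of group SD cells blanked.
#' @param n_range Replicate-count range (inclusive).
#' @param base_effects Named vector of per-parameter true lnRRs.
#' @param parameter_groups Named vector mapping parameter to its group.
#' @param parameter_probs Sampling mix over parameters.
#' @param dose `NULL`, or `list(breakpoint, slope_pre, slope_post)` for the
#'   planted amount-functionality broken stick (slopes per g/kg).
#' @param type_effects Named list: parameter -> named vector of additive
#'   plastic-type effects.
#' @param amount_dist `"lognormal"` (survey-like) or `"uniform"`
#'   (designed dose gradient).
#' @param amount_range,size_range_um,time_range_days Moderator ranges
#'   (amount g/kg; size log-uniform in um; time uniform in days).
#' @param amount_meanlog,amount_sdlog Lognormal amount parameters.
#' @param control_meanlog,control_sdlog Lognormal control-mean parameters.
#' @param ecosystem_probs,type_probs,group_probs Categorical moderator
#'   distributions.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(
    n_studies = 48, obs_per_study = 15,
    tau2_true = 0.04, cv_true = 0.15, missing_sd_fraction = 0.1,
    n_range = c(3, 6),
    base_effects = c(richness = -0.02, shannon = 0, biomass = -0.07,
                     soc = -0.05, tn = -0.03, ph = -0.005,
                     soil_respiration = 0.05, fda = 0.05, c_acq = -0.06,
                     n_acq = 0.02, p_acq = 0.08, ox = 0.05),
    parameter_groups = c(richness = "alpha_diversity",
                         shannon = "alpha_diversity",
                         biomass = "biomass", soc = "soil_property",
                         tn = "soil_property", ph = "soil_property",
                         soil_respiration = "functionality",
                         fda = "functionality", c_acq = "functionality",
                         n_acq = "functionality", p_acq = "functionality",
                         ox = "functionality"),
    parameter_probs = c(richness = 0.10, shannon = 0.09, biomass = 0.09,
                        soc = 0.06, tn = 0.05, ph = 0.05,
                        soil_respiration = 0.10, fda = 0.05, c_acq = 0.11,
                        n_acq = 0.13, p_acq = 0.08, ox = 0.09),
    dose = list(breakpoint = 40, slope_pre = 0.004, slope_post = -0.001),
    type_effects = list(richness = c(PE = -0.07, PP = 0.17)),
    amount_dist = c("lognormal", "uniform"),
    amount_range = c(0.1, 100), amount_meanlog = log(10), amount_sdlog = 1,
    size_range_um = c(0.1, 30000), time_range_days = c(1, 365),
    control_meanlog = log(10), control_sdlog = 0.5,
    ecosystem_probs = c(cropland = 0.5, bare = 0.2, grassland = 0.2,
                        forest = 0.1),
    type_probs = c(PE = 0.30, PP = 0.15, PS = 0.12, PVC = 0.10, PET = 0.10,
                   PLA = 0.12, PCL = 0.11),
    group_probs = c(bacteria = 0.45, fungi = 0.3, `whole community` = 0.25)) {
  amount_dist <- match.arg(amount_dist)
  stopifnot(n_studies >= 1, obs_per_study >= 1, tau2_true >= 0,
            cv_true > 0, missing_sd_fraction >= 0, missing_sd_fraction < 1,
            all(n_range >= 1),
            setequal(names(base_effects), names(parameter_groups)),
            setequal(names(base_effects), names(parameter_probs)))
  # lognormal means never reach 0, so generated ratios are always defined
  cfg <- as.list(environment())
  class(cfg) <- "synthetic_config"
  cfg
}

#' Designed dose-gradient configuration for breakpoint recovery
#'
#' A controlled-experiment variant of [synthetic_config()] used to test
#' whether the broken-stick estimator recovers a planted threshold: only
#' functionality parameters, amounts uniform over the dose range (so both
#' limbs of the stick are well covered), low assay noise (CV 0.05),
#' negligible extra heterogeneity, and no missing SDs. 400 observations by
#' default.
#'
#' @param n_obs Total observations (spread over `n_obs / 10` studies).
#' @param ... Overrides passed to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
dose_gradient_config <- function(n_obs = 400, ...) {
  fun_pars <- c("soil_respiration", "fda", "c_acq", "n_acq", "p_acq", "ox")
  base <- stats::setNames(rep(0, length(fun_pars)), fun_pars)
  synthetic_config(
    n_studies = max(1L, round(n_obs / 10)), obs_per_study = 10,
    tau2_true = 1e-4, cv_true = 0.05, missing_sd_fraction = 0,
    base_effects = base,
    parameter_groups = stats::setNames(rep("functionality",
                                           length(fun_pars)), fun_pars),
    parameter_probs = stats::setNames(rep(1 / length(fun_pars),
                                          length(fun_pars)), fun_pars),
    amount_dist = "uniform", ...)
}

.draw_amount <- function(n, cfg) {
  if (cfg$amount_dist == "uniform") {
    stats::runif(n, cfg$amount_range[1], cfg$amount_range[2])
  } else {
    a <- stats::rlnorm(n, cfg$amount_meanlog, cfg$amount_sdlog)
    pmin(pmax(a, cfg$amount_range[1]), cfg$amount_range[2])
  }
}

.broken_stick <- function(x, dose) {
  slope_post_minus_pre <- dose$slope_post - dose$slope_pre
  dose$slope_pre * x + slope_post_minus_pre * pmax(x - dose$breakpoint, 0)
}

#' Generate a synthetic meta-dataset with known truths
#'
#' Draws a full observation table (one row per control-versus-plastic
#' comparison) from the generative model described in
#' [synthetic_config()]: study-level random effects of variance
#' `tau2_true`; a true lnRR per observation composed of the parameter base
#' effect, moderator terms (the planted broken-stick in amount for
#' functionality parameters, plastic-type shifts) and the study effect;
#' lognormal replicate measurements with coefficient of variation
#' `cv_true` in both groups, whose sample means/SDs become the reported
#' values; and exactly `floor(missing_sd_fraction * 2n)` group SD cells
#' blanked. Fully reproducible from `seed`.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer RNG seed.
#' @return List with `observations` (a validated, moderator-classified
#'   observation data frame) and `truth` (a `synthetic_truth` list
#'   recording every planted parameter).
#' @export
generate_meta_dataset <- function(config = synthetic_config(), seed = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  cfg <- config
  n <- cfg$n_studies * cfg$obs_per_study
  study <- rep(sprintf("S%03d", seq_len(cfg$n_studies)),
               each = cfg$obs_per_study)
  study_re <- rep(stats::rnorm(cfg$n_studies, 0, sqrt(cfg$tau2_true)),
                  each = cfg$obs_per_study)
  pars <- sample(names(cfg$parameter_probs), n, replace = TRUE,
                 prob = cfg$parameter_probs)
  amount <- .draw_amount(n, cfg)
  size <- exp(stats::runif(n, log(cfg$size_range_um[1]),
                           log(cfg$size_range_um[2])))
  days <- stats::runif(n, cfg$time_range_days[1], cfg$time_range_days[2])
  eco <- sample(names(cfg$ecosystem_probs), n, TRUE, cfg$ecosystem_probs)
  ptype <- sample(names(cfg$type_probs), n, TRUE, cfg$type_probs)
  mgroup <- sample(names(cfg$group_probs), n, TRUE, cfg$group_probs)

  mu <- unname(cfg$base_effects[pars]) + study_re
  if (!is.null(cfg$dose)) {
    is_fun <- cfg$parameter_groups[pars] == "functionality"
    mu[is_fun] <- mu[is_fun] + .broken_stick(amount[is_fun], cfg$dose)
  }
  for (p in names(cfg$type_effects)) {
    eff <- cfg$type_effects[[p]]
    hit <- pars == p & ptype %in% names(eff)
    mu[hit] <- mu[hit] + unname(eff[ptype[hit]])
  }

  nc <- sample(cfg$n_range[1]:cfg$n_range[2], n, replace = TRUE)
  nt <- sample(cfg$n_range[1]:cfg$n_range[2], n, replace = TRUE)
  m_c <- stats::rlnorm(n, cfg$control_meanlog, cfg$control_sdlog)
  m_t <- m_c * exp(mu)
  sdlog <- sqrt(log(1 + cfg$cv_true^2))
  draw_group <- function(m, k) {
    reps <- stats::rlnorm(k, log(m) - sdlog^2 / 2, sdlog)
    c(mean(reps), stats::sd(reps))
  }
  ctrl <- vapply(seq_len(n), function(i) draw_group(m_c[i], nc[i]),
                 numeric(2))
  trt <- vapply(seq_len(n), function(i) draw_group(m_t[i], nt[i]),
                numeric(2))

  obs <- data.frame(
    study_id = study, parameter_name = pars,
    parameter_group = unname(cfg$parameter_groups[pars]),
    mean_control = ctrl[1, ], mean_treatment = trt[1, ],
    sd_control = ctrl[2, ], sd_treatment = trt[2, ],
    n_control = nc, n_treatment = nt,
    plastic_type = ptype, amount_g_per_kg = amount, size_um = size,
    incubation_days = days, ecosystem = eco, microbial_group = mgroup,
    stringsAsFactors = FALSE)

  n_blank <- floor(cfg$missing_sd_fraction * 2L * n)
  if (n_blank > 0) {
    slots <- sample(2L * n, n_blank)
    ctrl_slots <- slots[slots <= n]
    trt_slots <- slots[slots > n] - n
    obs$sd_control[ctrl_slots] <- NA_real_
    obs$sd_treatment[trt_slots] <- NA_real_
  }
  obs <- classify_moderators(obs)

  truth <- list(
    true_effect_by_parameter = cfg$base_effects,
    tau2_true = cfg$tau2_true,
    breakpoint_true = if (is.null(cfg$dose)) NA_real_ else cfg$dose$breakpoint,
    slope_pre = if (is.null(cfg$dose)) NA_real_ else cfg$dose$slope_pre,
    slope_post = if (is.null(cfg$dose)) NA_real_ else cfg$dose$slope_post,
    cv_true = cfg$cv_true,
    missing_sd_fraction = cfg$missing_sd_fraction,
    n_sd_blanked = as.integer(max(n_blank, 0)),
    seed = seed)
  class(truth) <- "synthetic_truth"
  list(observations = obs, truth = truth)
}

#' Generate 2-D ordination point clouds for two groups
#'
#' Control points are drawn from a bivariate normal centred at the origin
#' with isotropic spread `spread_c`; treatment points likewise at
#' `(separation, 0)` with spread `spread_t`. The expected mean pairwise
#' within-group distance is `spread * sqrt(pi)`, so the expected
#' beta-diversity response ratio is `ln(spread_t / spread_c)`, and the
#' structure ratio grows with `separation`.
#'
#' @param n_control,n_treatment Points per group (>= 2).
#' @param separation Distance between the group centres.
#' @param spread_c,spread_t Positive group spreads (SD per axis).
#' @param seed RNG seed.
#' @return List with matrices `control` and `treatment`.
#' @export
generate_ordination <- function(n_control, n_treatment, separation = 0,
                                spread_c = 1, spread_t = 1, seed = 1) {
  stopifnot(n_control >= 2, n_treatment >= 2)
  if (spread_c <= 0 || spread_t <= 0) stop("spreads must be positive")
  set.seed(seed)
  control <- matrix(stats::rnorm(2 * n_control, 0, spread_c),
                    ncol = 2)
  treatment <- cbind(stats::rnorm(n_treatment, separation, spread_t),
                     stats::rnorm(n_treatment, 0, spread_t))
  list(control = control, treatment = treatment)
}
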