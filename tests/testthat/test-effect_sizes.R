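test_that("lnRR identities hold", {
  expect_equal(lnrr(1, 1), 0)
  expect_equal(lnrr(exp(1), 1), 1)
  set.seed(1)
  for (i in 1:20) {
    a <- runif(1, 0.01, 50); b <- runif(1, 0.01, 50)
    expect_equal(lnrr(a, a), 0)
    expect_equal(lnrr(a, b), -lnrr(b, a))
  }
  expect_error(lnrr(0, 1), "non-positive")
  expect_error(lnrr(2, -1), "non-positive")
})

test_that("lnRR variance matches its closed form and scaling properties", {
  expect_equal(lnrr_variance(1, 4, 2, 1, 4, 2), 0.125)
  expect_equal(lnrr_variance(0, 5, 3, 0, 5, 3), 0)
  v1 <- lnrr_variance(1.3, 3, 2.1, 0.8, 4, 1.9)
  v2 <- lnrr_variance(1.3, 6, 2.1, 0.8, 8, 1.9)
  expect_equal(v2, v1 / 2)
  set.seed(2)
  for (i in 1:20) {
    v <- lnrr_variance(runif(1), sample(1:9, 1), runif(1, .1, 5),
                       runif(1), sample(1:9, 1), runif(1, .1, 5))
    expect_gte(v, 0)
  }
  expect_error(lnrr_variance(NA, 4, 2, 1, 4, 2), "impute_missing_sd")
})

test_that("a {0.1, 0.3} CV pool imputes sd 1.0 for a mean of 5", {
  obs <- make_obs(2,
                  mean_control = c(10, 5), sd_control = c(1, NA),
                  mean_treatment = c(10, 5), sd_treatment = c(3, NA))
  out <- impute_missing_sd(obs)
  expect_equal(out$sd_control[2], 0.2 * 5)
  expect_equal(out$sd_treatment[2], 0.2 * 5)
  expect_true(out$sd_control_imputed[2] && out$sd_treatment_imputed[2])
})

test_that("CV imputation uses the per-parameter pool and flags records", {
  obs <- make_obs(3,
                  mean_control = c(10, 10, 5),
                  sd_control = c(1, 3, NA),       # CVs 0.1 and 0.3
                  mean_treatment = c(10, 10, 8),
                  sd_treatment = c(1, 3, 1))      # CVs 0.1 and 0.3
  out <- impute_missing_sd(obs)
  # pooled mean CV = mean(0.1, 0.3, 0.1, 0.3, 1/8) restricted to biomass...
  # all rows share the parameter, pool = {.1,.3,.1,.3,.125}; imputed = cv*5
  expect_equal(out$sd_control[3], mean(c(.1, .3, .1, .3, .125)) * 5)
  expect_true(out$sd_control_imputed[3])
  expect_false(any(out$sd_control_imputed[1:2]))
})

test_that("imputation falls back to the dataset-wide pool for thin parameters", {
  obs <- make_obs(3,
                  parameter_name = c("biomass", "biomass", "shannon"),
                  mean_control = c(10, 10, 4), sd_control = c(1, 3, NA),
                  mean_treatment = c(10, 10, 4), sd_treatment = c(2, 2, 0.4))
  out <- impute_missing_sd(obs, min_pool = 3)
  # shannon pool has a single CV (0.1) < min_pool -> dataset-wide pool
  pool <- c(.1, .3, .2, .2, .1)
  expect_equal(out$sd_control[3], mean(pool) * 4)
})

test_that("imputation is a no-op without missing SDs and errors on empty pools", {
  obs <- make_obs(2)
  out <- impute_missing_sd(obs)
  expect_equal(out$sd_control, obs$sd_control)
  expect_false(any(out$sd_control_imputed, out$sd_treatment_imputed))
  all_missing <- make_obs(2, sd_control = NA_real_, sd_treatment = NA_real_)
  expect_error(impute_missing_sd(all_missing), "pool")
})

test_that("constant CV pools impute sd = cv * mean exactly", {
  obs <- make_obs(3, mean_control = c(10, 20, 6), sd_control = c(1.5, 3, NA),
                  mean_treatment = c(10, 20, 12),
                  sd_treatment = c(1.5, 3, 1.8))
  out <- impute_missing_sd(obs)
  expect_equal(out$sd_control[3], 0.15 * 6)
})

test_that("ordination distances match the hand example and brute force", {
  d <- ordination_distances(rbind(c(0, 0), c(0, 2)),
                            rbind(c(3, 0), c(3, 2)))
  expect_equal(d$Dc, 2)
  expect_equal(d$Dt, 2)
  expect_equal(d$Db, mean(c(3, sqrt(13), sqrt(13), 3)))
  set.seed(3)
  for (i in 1:15) {
    a <- matrix(rnorm(2 * sample(2:30, 1)), ncol = 2)
    b <- matrix(rnorm(2 * sample(2:30, 1), 1), ncol = 2)
    got <- ordination_distances(a, b)
    want <- brute_force_distances(a, b)
    expect_equal(got$Dc, want$Dc, tolerance = 1e-10)
    expect_equal(got$Dt, want$Dt, tolerance = 1e-10)
    expect_equal(got$Db, want$Db, tolerance = 1e-10)
  }
})

test_that("degenerate ordination clouds behave", {
  a <- rbind(c(1, 1), c(1, 1), c(1, 1))
  d <- ordination_distances(a, a)
  expect_equal(unlist(d), c(Dc = 0, Dt = 0, Db = 0))
  b <- matrix(rnorm(10), ncol = 2)
  d2 <- ordination_distances(b, b)
  expect_equal(d2$Dt, d2$Dc)
  expect_gte(d2$Db, 0)
  expect_error(ordination_distances(b[1, , drop = FALSE], b), "2 points")
})

test_that("beta/structure response ratios match their definitions", {
  r <- lnrr_beta_structure(1, 2, 2)
  expect_equal(r$lnrr_beta, log(2))
  expect_equal(r$lnrr_structure, log(2 / 3))
  bal <- lnrr_beta_structure(1, 1, 2)
  expect_equal(bal$lnrr_beta, 0)
  expect_equal(bal$lnrr_structure, 0)
  expect_equal(lnrr_beta_structure(2, 5, 3)$lnrr_beta,
               -lnrr_beta_structure(5, 2, 3)$lnrr_beta)
  expect_error(lnrr_beta_structure(0, 1, 1), "zero distances")
})

test_that("joint coordinate rescaling leaves both ordination ratios unchanged", {
  set.seed(4)
  for (i in 1:10) {
    a <- matrix(rnorm(20), ncol = 2)
    b <- matrix(rnorm(16, 1), ncol = 2)
    k <- runif(1, 0.1, 40)
    d1 <- ordination_distances(a, b)
    d2 <- ordination_distances(k * a, k * b)
    r1 <- lnrr_beta_structure(d1$Dc, d1$Dt, d1$Db)
    r2 <- lnrr_beta_structure(d2$Dc, d2$Dt, d2$Db)
    expect_equal(r1$lnrr_beta, r2$lnrr_beta, tolerance = 1e-10)
    expect_equal(r1$lnrr_structure, r2$lnrr_structure, tolerance = 1e-10)
  }
})

test_that("functionality tagging filters without altering inputs", {
  eff <- make_obs(5, parameter_name = c("soil_respiration", "fda", "fda",
                                        "shannon", "biomass"))
  eff$lnrr <- 1:5; eff$variance <- 0.01
  sub <- aggregate_functionality(eff, c("soil_respiration", "fda"))
  expect_equal(nrow(sub), 3)
  expect_true(all(sub$parameter_group == "functionality"))
  expect_equal(eff$parameter_group, rep("biomass", 5))  # input untouched
  expect_warning(none <- aggregate_functionality(eff, character(0)),
                 "no observations")
  expect_equal(nrow(none), 0)
})

test_that("effect-size computation excludes undefined ratios with reasons", {
  obs <- make_obs(3, mean_treatment = c(12, -1, 15))
  expect_message(eff <- compute_effect_sizes(obs), "excluded")
  expect_equal(nrow(eff), 2)
  excl <- attr(eff, "excluded")
  expect_equal(excl$row, 2L)
  expect_match(excl$reason, "non-positive")
  expect_equal(eff$lnrr, log(c(12, 15) / 10))
  expect_equal(eff$variance[1],
               lnrr_variance(1.2, 4, 12, 1, 4, 10))
})
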