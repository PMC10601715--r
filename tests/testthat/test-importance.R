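test_that("a planted continuous driver is top-ranked by forest and booster", {
  d <- planted_signal_data(n = 200, seed = 31)
  rf <- suppressMessages(rf_importance(d$X, d$y, n_perm = 0, seed = 1,
                                       ntree = 300))
  expect_identical(rf$predictor[1], "amount")
  abt <- suppressMessages(abt_importance(d$X, d$y, seed = 1, n_trees = 300,
                                         learning_rate = 0.05))
  expect_identical(abt$predictor[1], "amount")
})

test_that("importance tables are bit-identical under a fixed seed", {
  d <- planted_signal_data(n = 120, seed = 32)
  a <- suppressMessages(rf_importance(d$X, d$y, n_perm = 0, seed = 9,
                                      ntree = 150))
  b <- suppressMessages(rf_importance(d$X, d$y, n_perm = 0, seed = 9,
                                      ntree = 150))
  expect_identical(a, b)
  x1 <- suppressMessages(abt_importance(d$X, d$y, seed = 9, n_trees = 100))
  x2 <- suppressMessages(abt_importance(d$X, d$y, seed = 9, n_trees = 100))
  expect_identical(x1, x2)
})

test_that("relative influence is normalised to 100 and errors on bad input", {
  d <- planted_signal_data(n = 150, seed = 33)
  abt <- suppressMessages(abt_importance(d$X, d$y, n_trees = 150))
  expect_equal(sum(abt$rel_influence), 100, tolerance = 1e-6)
  one <- suppressMessages(
    abt_importance(d$X["amount"], d$y, n_trees = 100))
  expect_equal(one$rel_influence, 100, tolerance = 1e-9)
  expect_error(abt_importance(d$X, d$y, n_trees = 0), "positive")
  expect_error(suppressMessages(rf_importance(d$X, rep(1, 150), n_perm = 0)),
               "constant")
})

test_that("null permutation p-values stay near nominal per predictor", {
  set.seed(34)
  hits <- 0; total <- 0
  for (r in 1:8) {
    d <- planted_signal_data(n = 120, seed = 100 + r)
    y <- rnorm(120)  # independent of every predictor
    imp <- suppressMessages(rf_importance(d$X, y, n_perm = 39,
                                          seed = r, ntree = 60))
    hits <- hits + sum(imp$p_perm <= 0.05)
    total <- total + nrow(imp)
  }
  expect_lte(hits / total, 0.15)
})

test_that("a duplicated predictor column is tolerated", {
  d <- planted_signal_data(n = 120, seed = 35)
  X2 <- d$X
  X2$amount_copy <- X2$amount
  rf <- suppressMessages(rf_importance(X2, d$y, n_perm = 0, ntree = 150))
  expect_setequal(rf$predictor, c(names(d$X), "amount_copy"))
  # the duplicated signal still dominates jointly
  expect_true("amount" %in% rf$predictor[1:2] ||
                "amount_copy" %in% rf$predictor[1:2])
})

test_that("the weighted forest matches the plain one under equal weights", {
  d <- planted_signal_data(n = 200, seed = 36)
  rf <- suppressMessages(rf_importance(d$X, d$y, n_perm = 0, seed = 2,
                                       ntree = 200))
  wrf <- suppressMessages(
    weighted_rf_importance(d$X, d$y, weights = rep(1, 200), n_boot = 10,
                           seed = 2, ntree = 150))
  expect_identical(wrf$predictor[1], rf$predictor[1])
})

test_that("weight pathologies are flagged", {
  d <- planted_signal_data(n = 100, seed = 37)
  w <- rep(1e-6, 100); w[1] <- 1
  suppressWarnings(expect_warning(suppressMessages(
    weighted_rf_importance(d$X, d$y, w, n_boot = 2, ntree = 50)),
    "99%"))
  suppressWarnings(expect_warning(suppressMessages(
    weighted_rf_importance(d$X, d$y, rep(1, 100), n_boot = 1, ntree = 50)),
    "low-confidence"))
})

test_that("weighting can rescue a signal carried by high-weight rows", {
  set.seed(38)
  n <- 240
  X <- data.frame(amount = runif(n, 0, 100),
                  size = exp(runif(n, log(0.1), log(30000))),
                  time = runif(n, 1, 365))
  hi <- seq_len(n) <= 80  # precise studies carry the dose signal
  y <- ifelse(hi, 0.03 * X$amount, 0) + rnorm(n, 0, ifelse(hi, 0.1, 1.5))
  w <- ifelse(hi, 100, 0.1)
  wrf <- suppressMessages(
    weighted_rf_importance(X, y, w, n_boot = 10, seed = 3, ntree = 200))
  expect_identical(wrf$predictor[1], "amount")
})

test_that("the long-format importance table stacks methods per parameter", {
  gen <- generate_meta_dataset(synthetic_config(n_studies = 10,
                                                obs_per_study = 12), seed = 4)
  eff <- suppressMessages(compute_effect_sizes(gen$observations))
  tab <- suppressMessages(
    moderator_importance(eff, by = "parameter_group", min_n = 40,
                         ntree = 100, n_trees = 100, n_boot = 3))
  expect_true(all(c("parameter", "predictor", "method", "value") %in%
                    names(tab)))
  expect_setequal(unique(tab$method), c("rf", "abt", "wrf"))
  for (p in unique(tab$parameter)) {
    abt_sum <- sum(tab$value[tab$parameter == p & tab$method == "abt"])
    expect_equal(abt_sum, 100, tolerance = 1e-6)
  }
})
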