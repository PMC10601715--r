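# small observation-table builder with sensible defaults
make_obs <- function(n = 1, ...) {
  base <- data.frame(
    study_id = sprintf("S%02d", seq_len(n)),
    parameter_name = "biomass",
    parameter_group = "biomass",
    mean_control = 10, mean_treatment = 12,
    sd_control = 1, sd_treatment = 1.2,
    n_control = 4L, n_treatment = 4L,
    plastic_type = "PE", general_type = "aliphatic",
    amount_g_per_kg = 5, amount_class = "low",
    size_um = 100, size_class = "micro",
    incubation_days = 30, time_class = "long",
    ecosystem = "cropland", microbial_group = "bacteria",
    stringsAsFactors = FALSE)
  overrides <- list(...)
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  base
}

# independent all-pairs oracle for the ordination distances
brute_force_distances <- function(control, treatment) {
  pair_mean <- function(a, b) {
    tot <- 0; cnt <- 0
    for (i in seq_len(nrow(a))) {
      for (j in seq_len(nrow(b))) {
        tot <- tot + sqrt(sum((a[i, ] - b[j, ])^2)); cnt <- cnt + 1
      }
    }
    tot / cnt
  }
  within_mean <- function(a) {
    tot <- 0; cnt <- 0
    for (i in seq_len(nrow(a) - 1)) {
      for (j in (i + 1):nrow(a)) {
        tot <- tot + sqrt(sum((a[i, ] - a[j, ])^2)); cnt <- cnt + 1
      }
    }
    tot / cnt
  }
  list(Dc = within_mean(control), Dt = within_mean(treatment),
       Db = pair_mean(control, treatment))
}

# moderator table with one planted continuous driver ("amount")
planted_signal_data <- function(n = 200, seed = 1, sd_noise = 0.2) {
  set.seed(seed)
  X <- data.frame(
    amount = runif(n, 0, 100),
    size = exp(runif(n, log(0.1), log(30000))),
    time = runif(n, 1, 365),
    ecosystem = factor(sample(c("bare", "cropland", "grassland", "forest"),
                              n, TRUE)))
  y <- 0.02 * X$amount + rnorm(n, 0, sd_noise)
  list(X = X, y = y)
}
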