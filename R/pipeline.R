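#' Default pipeline configuration
#'
#' Returns the full configuration list consumed by [run_pipeline()], with
#' every field at its default. Supply overrides as arguments, or pass a
#' YAML/JSON file path to [run_pipeline()] whose entries override these
#' defaults.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1,
    input = NULL,            # observations CSV/TSV; NULL -> synthetic
    schema = NULL,           # column-name map for foreign tables
    synthetic = list(),      # overrides for synthetic_config()
    method = "REML",         # tau^2 estimator: REML or DL
    weighted = TRUE,         # meta-analytic weights in dose/importance fits
    collapse_degradable = FALSE,
    min_k = 3,               # min effects per pooled parameter
    min_n_subgroup = 5,      # levels need strictly more observations
    indicators = default_functionality_indicators(),
    subgroup_moderators = c("ecosystem", "general_type", "plastic_type",
                            "amount_class", "size_class", "time_class"),
    dose_responses = c("functionality", "biomass", "richness", "shannon"),
    dose_predictors = c("amount_g_per_kg", "size_um", "incubation_days"),
    dose_min_n = 30,
    importance_min_n = 30,
    importance_ntree = 300,
    importance_n_trees = 300,
    importance_n_boot = 10,
    stages = c("meta", "subgroups", "dose", "importance", "bias"))
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  cfg
}

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    stopifnot(file.exists(config))
    loaded <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("yaml package needed to read YAML configs")
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
    config <- do.call(pipeline_config, loaded)
  } else if (is.list(config)) {
    config <- do.call(pipeline_config, config)
  } else {
    stop("config must be a list or a path to a YAML/JSON file")
  }
  config
}

.config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, force = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

.dose_subset <- function(effects, response, indicators) {
  if (response == "functionality") {
    suppressWarnings(aggregate_functionality(effects, indicators))
  } else if (response %in% effects$parameter_name) {
    effects[effects$parameter_name == response, , drop = FALSE]
  } else {
    effects[effects$parameter_group == response, , drop = FALSE]
  }
}

#' Run the full meta-analytic pipeline
#'
#' Orchestrates all stages on one dataset: read (or generate) and validate
#' observations; merge richness metrics and classify moderators; impute
#' missing SDs and compute effect sizes; pool per parameter (forest
#' table); categorical subgroup analyses with Qm; the dose-response model
#' cascade with breakpoints and sign-change thresholds; moderator
#' importance by three tree-ensemble methods; and publication-bias
#' screening. All tables are written as TSV under `output_dir` along with
#' a machine-readable `report.json`; any stage failure aborts with a
#' stage-tagged error.
#'
#' @param config A list of overrides (see [pipeline_config()]) or a path
#'   to a YAML/JSON configuration file.
#' @param output_dir Directory for output tables and the run report.
#' @return The run report (list), invisibly. The report's bookkeeping
#'   invariant is `analyzed + excluded = read` at the effect-size stage.
#' @export
run_pipeline <- function(config = list(), output_dir = tempfile("plastmeta_")) {
  cfg <- .load_config(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config_hash = .config_hash(cfg), seed = cfg$seed,
                 stages = list(), tables = list())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    report$stages[[name]] <<- list(seconds = proc.time()[["elapsed"]] - t0)
    out
  }

  obs <- t_stage("read", {
    if (!is.null(cfg$input)) {
      report$input_digest <- unname(tools::md5sum(cfg$input))
      read_observations(cfg$input, schema = cfg$schema)
    } else {
      gen <- generate_meta_dataset(do.call(synthetic_config, cfg$synthetic),
                                   seed = cfg$seed)
      report$truth <- unclass(gen$truth)
      gen$observations
    }
  })
  report$n_read <- nrow(obs)

  effects <- t_stage("effects", {
    obs <- merge_richness(obs)
    obs <- classify_moderators(obs,
                               collapse_degradable = cfg$collapse_degradable)
    compute_effect_sizes(obs)
  })
  excl <- attr(effects, "excluded")
  report$n_excluded <- nrow(excl)
  report$n_analyzed <- nrow(effects)
  report$exclusion_reasons <- as.list(table(excl$reason))
  stopifnot(report$n_analyzed + report$n_excluded == report$n_read)
  eff_path <- file.path(output_dir, "effects.tsv")
  write_observations(effects, eff_path)
  report$tables$effects <- eff_path

  if ("meta" %in% cfg$stages) {
    forest <- t_stage("meta", {
      meta_table(effects, method = cfg$method, min_k = cfg$min_k,
                 indicators = cfg$indicators)
    })
    p <- file.path(output_dir, "forest.tsv")
    write_observations(forest, p)
    report$tables$forest <- p
  }

  if ("subgroups" %in% cfg$stages) {
    subgroups <- t_stage("subgroups", {
      rows <- list()
      for (mod in intersect(cfg$subgroup_moderators, names(effects))) {
        for (par in unique(effects$parameter_name)) {
          sub <- effects[effects$parameter_name == par, , drop = FALSE]
          res <- tryCatch(
            subgroup_qm(sub$lnrr, sub$variance, sub[[mod]],
                        min_n = cfg$min_n_subgroup, method = cfg$method),
            error = function(e) NULL)
          if (is.null(res)) next
          for (lev in names(res$levels)) {
            e <- res$levels[[lev]]
            rows[[length(rows) + 1L]] <- data.frame(
              parameter = par, moderator = mod, level = lev, k = e$k,
              mean_effect = e$mean_effect, ci_low = e$ci_low,
              ci_high = e$ci_high, significant = e$significant,
              Qm = res$Qm, df = res$df, p_qm = res$p_qm)
          }
        }
      }
      if (length(rows)) do.call(rbind, rows) else data.frame()
    })
    p <- file.path(output_dir, "subgroups.tsv")
    write_observations(subgroups, p)
    report$tables$subgroups <- p
  }

  if ("dose" %in% cfg$stages) {
    dose <- t_stage("dose", {
      rows <- list()
      for (resp in cfg$dose_responses) {
        sub <- .dose_subset(effects, resp, cfg$indicators)
        for (pred in cfg$dose_predictors) {
          ok <- !is.na(sub[[pred]]) & !is.na(sub$lnrr)
          if (sum(ok) < cfg$dose_min_n) next
          x <- sub[[pred]][ok]; y <- sub$lnrr[ok]
          w <- NULL
          if (cfg$weighted) {
            t2 <- estimate_tau2(y, sub$variance[ok], method = cfg$method)
            w <- 1 / (sub$variance[ok] + t2)
          }
          fits <- suppressWarnings(fit_dose_response(x, y, w))
          final <- switch(fits$selected, segmented = fits$segmented,
                          gam = fits$gam,
                          wls = fits$wls, ols = fits$ols)
          rows[[length(rows) + 1L]] <- data.frame(
            response = resp, predictor = pred, selected = fits$selected,
            aic_ols = fits$ols$aic,
            aic_wls = if (is.null(fits$wls)) NA_real_ else fits$wls$aic,
            aic_gam = fits$gam$aic,
            aic_segmented = if (is.null(fits$segmented)) NA_real_
                            else fits$segmented$aic,
            beta0 = final$beta0, beta1 = final$beta1, beta2 = final$beta2,
            breakpoint = fits$breakpoint,
            breakpoint_se = if (is.null(fits$segmented)) NA_real_
                            else fits$segmented$breakpoint_se,
            zero_crossing = fits$zero_crossing,
            r2 = final$r2, p_model = final$p_model, n = final$n)
        }
      }
      if (length(rows)) do.call(rbind, rows) else data.frame()
    })
    p <- file.path(output_dir, "dose_models.tsv")
    write_observations(dose, p)
    report$tables$dose_models <- p
  }

  if ("importance" %in% cfg$stages) {
    imp <- t_stage("importance", {
      suppressMessages(moderator_importance(
        effects, min_n = cfg$importance_min_n, seed = cfg$seed,
        ntree = cfg$importance_ntree, n_trees = cfg$importance_n_trees,
        n_boot = cfg$importance_n_boot))
    })
    p <- file.path(output_dir, "importance.tsv")
    write_observations(imp, p)
    report$tables$importance <- p
  }

  if ("bias" %in% cfg$stages) {
    bias <- t_stage("bias", publication_bias_table(effects,
                                                   min_k = cfg$min_k))
    p <- file.path(output_dir, "bias.tsv")
    write_observations(bias, p)
    report$tables$bias <- p
  }

  jsonlite::write_json(report, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, force = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(report)
}
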