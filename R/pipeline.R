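#' Validate a pipeline configuration
#'
#' Reads a YAML configuration (or takes a list), fills in the published
#' defaults and validates every field, collecting all violations into a
#' single error. An empty configuration is valid and yields the default
#' pipeline: 50 counties over 2008--2020, training years 2008--2018, test
#' years 2019--2020, 200 epochs, learning rate 1e-4, dropout 0.2, SVR with
#' C = 100 and gamma = 0.1, RFR with 200 trees and minimum leaf size 4.
#'
#' @param config Path to a YAML file, or a (possibly partial) configuration
#'   list.
#' @return Validated configuration list of class `soyield_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  stopifnot(is.list(config))
  defaults <- list(
    seed = 1L,
    simulate = list(n_counties = 50L, years = 2008:2020, noise_var = 1,
                    drought_year = NULL),
    split = list(train_years = 2008:2018, test_years = 2019:2020),
    model = list(name = "GCBA", conv_channels = 256L, gru_hidden = 512L,
                 gru_layers = 3L, dropout = 0.2),
    train = list(epochs = 200L, lr = 1e-4, batch_size = 64L, delta = 1),
    svr = list(cost = 100, gamma = 0.1, cv_folds = 5),
    rfr = list(n_estimators = 200L, min_samples_leaf = 4L, cv_folds = 5),
    tune = list(n_pop = 30L, iterations = 50L, epochs = 20L),
    importance = list(n_samples = 128L, method = "shapley")
  )
  cfg <- utils::modifyList(defaults, config)

  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed: single integer")
  chk(cfg$simulate$n_counties >= 2, "simulate.n_counties: must be >= 2")
  chk(length(cfg$simulate$years) >= 1 && !anyNA(cfg$simulate$years),
      "simulate.years: nonempty integer years")
  chk(cfg$simulate$noise_var > 0, "simulate.noise_var: must be positive")
  chk(cfg$train$lr > 0, "train.lr: must be positive")
  chk(cfg$train$epochs >= 1, "train.epochs: must be >= 1")
  chk(cfg$train$batch_size >= 1, "train.batch_size: must be >= 1")
  chk(cfg$model$dropout >= 0 && cfg$model$dropout < 1,
      "model.dropout: must be in [0, 1)")
  chk(cfg$model$name %in% c("GCBA", "SVR", "RFR", "CNN", "GRU", "CNN-GRU"),
      "model.name: unknown model")
  chk(cfg$svr$cost > 0, "svr.cost: must be positive")
  chk(cfg$svr$gamma > 0, "svr.gamma: must be positive")
  chk(cfg$rfr$n_estimators >= 1, "rfr.n_estimators: must be >= 1")
  chk(!length(intersect(cfg$split$train_years, cfg$split$test_years)),
      "split: train and test years overlap")
  chk(cfg$importance$n_samples >= 1, "importance.n_samples: must be >= 1")
  if (length(problems)) {
    stop("invalid configuration:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  class(cfg) <- c("soyield_config", "list")
  cfg
}

config_model_builder <- function(cfg) {
  name <- cfg$model$name
  function(k) {
    gc <- gcba_config(in_variables = k,
                      conv_channels = cfg$model$conv_channels,
                      gru_hidden = cfg$model$gru_hidden,
                      gru_layers = cfg$model$gru_layers,
                      dropout = cfg$model$dropout,
                      seed = cfg$seed)
    if (name == "GCBA") build_gcba(gc) else
      build_baseline(name, gc,
                     svr = cfg$svr[c("cost", "gamma")],
                     rfr = cfg$rfr)
  }
}

config_train_control <- function(cfg) {
  train_control(lr = cfg$train$lr, epochs = cfg$train$epochs,
                batch_size = cfg$train$batch_size, delta = cfg$train$delta,
                seed = cfg$seed)
}

write_manifest <- function(out_dir, stage, cfg, artifacts) {
  digest <- vapply(artifacts, function(p) unname(tools::md5sum(p)), "")
  manifest <- list(
    stage = stage,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    config = unclass(cfg),
    artifacts = as.list(stats::setNames(digest, basename(artifacts)))
  )
  path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  path
}

#' Run one pipeline stage
#'
#' Stages communicate through the canonical CSV formats in `out_dir`, each
#' stage writing a JSON run manifest with the configuration snapshot, seed
#' and MD5 digests of its artifacts, so a run can be reproduced and checked
#' byte for byte.
#'
#' * `simulate`: generate `features.csv` and `yields.csv`.
#' * `prep`: quality-filter yields (`yields_filtered.csv`,
#'   `filter_report.json`) and fit/store the training-year scaler
#'   (`scaler.yaml`).
#' * `tune`: GOA search over learning rate, dropout, batch size and
#'   convolution channels, minimizing validation RMSE with the last training
#'   year held out; writes `tuned.yaml`.
#' * `train`: fit the configured model on the training years
#'   (`train_history.csv`).
#' * `evaluate`: metrics per test year (`eval_report.csv`, per-county
#'   `predictions.csv`).
#' * `ablate`: the six-combination variable-group ablation
#'   (`ablation.csv`).
#' * `importance`: per-variable sampled-Shapley scores
#'   (`importance.csv`).
#'
#' @param stage Stage name.
#' @param config Configuration (path, list or validated object).
#' @param out_dir Artifact directory, created if missing.
#' @return Invisibly, a list of produced artifact paths (and for
#'   `evaluate`/`ablate`, the report data frame as `"report"` attribute
#'   holder entry `report`).
#' @export
run_stage <- function(stage = c("simulate", "prep", "tune", "train",
                                "evaluate", "ablate", "importance"),
                      config = list(), out_dir = ".") {
  stage <- match.arg(stage)
  cfg <- if (inherits(config, "soyield_config")) config else
    validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(out_dir, f)

  load_data <- function() {
    list(panel = read_feature_panel(path("features.csv")),
         yields = read_yield_table(path("yields_filtered.csv")))
  }

  arts <- switch(stage,
    simulate = {
      gc <- generator_config(n_counties = cfg$simulate$n_counties,
                             years = cfg$simulate$years,
                             noise_var = cfg$simulate$noise_var,
                             drought_year = cfg$simulate$drought_year,
                             seed = cfg$seed)
      d <- generate_dataset(gc)
      write_feature_panel(d$panel, path("features.csv"))
      write_yield_table(d$yields, path("yields.csv"))
      c(path("features.csv"), path("yields.csv"))
    },
    prep = {
      yields <- read_yield_table(path("yields.csv"))
      fr <- filter_yields(yields)
      write_yield_table(fr$yields, path("yields_filtered.csv"))
      jsonlite::write_json(unclass(fr$report), path("filter_report.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      panel <- read_feature_panel(path("features.csv"))
      scaler <- fit_scaler(panel, cfg$split$train_years)
      yaml::write_yaml(lapply(unclass(scaler), as.list), path("scaler.yaml"))
      c(path("yields_filtered.csv"), path("filter_report.json"),
        path("scaler.yaml"))
    },
    tune = {
      dat <- load_data()
      val_year <- max(cfg$split$train_years)
      fit_years <- setdiff(cfg$split$train_years, val_year)
      objective <- function(par) {
        res <- evaluate_combo(
          dat$panel, dat$yields,
          function(k) build_gcba(gcba_config(
            in_variables = k, conv_channels = as.integer(par[4]),
            dropout = par[2], gru_hidden = cfg$model$gru_hidden,
            gru_layers = cfg$model$gru_layers, seed = cfg$seed)),
          control = train_control(lr = par[1],
                                  batch_size = as.integer(par[3]),
                                  epochs = cfg$tune$epochs,
                                  seed = cfg$seed),
          train_years = fit_years, test_years = val_year)
        mean(res$metrics$rmse)
      }
      gcfg <- goa_config(gcba_search_space(), n_pop = cfg$tune$n_pop,
                         iterations = cfg$tune$iterations, seed = cfg$seed)
      best <- goa_optimize(objective, gcfg, log_file = path("tune_log.csv"))
      tuned <- list(lr = best$par[1], dropout = best$par[2],
                    batch_size = as.integer(best$par[3]),
                    conv_channels = as.integer(best$par[4]),
                    val_rmse = best$value)
      yaml::write_yaml(tuned, path("tuned.yaml"))
      c(path("tuned.yaml"), path("tune_log.csv"))
    },
    train = {
      dat <- load_data()
      if (file.exists(path("tuned.yaml"))) {
        tuned <- yaml::read_yaml(path("tuned.yaml"))
        cfg$train$lr <- tuned$lr
        cfg$train$batch_size <- tuned$batch_size
        cfg$model$dropout <- tuned$dropout
        cfg$model$conv_channels <- tuned$conv_channels
      }
      res <- evaluate_combo(dat$panel, dat$yields, config_model_builder(cfg),
                            control = config_train_control(cfg),
                            train_years = cfg$split$train_years,
                            test_years = cfg$split$test_years)
      if (!is.null(res$model$history)) {
        utils::write.csv(data.frame(epoch = seq_along(res$model$history),
                                    loss = res$model$history),
                         path("train_history.csv"), row.names = FALSE)
      } else {
        utils::write.csv(data.frame(epoch = integer(0), loss = numeric(0)),
                         path("train_history.csv"), row.names = FALSE)
      }
      utils::write.csv(res$metrics, path("eval_report.csv"),
                       row.names = FALSE)
      utils::write.csv(res$predictions, path("predictions.csv"),
                       row.names = FALSE)
      c(path("train_history.csv"), path("eval_report.csv"),
        path("predictions.csv"))
    },
    evaluate = {
      if (!file.exists(path("eval_report.csv"))) {
        run_stage("train", cfg, out_dir)
      }
      rep <- utils::read.csv(path("eval_report.csv"))
      jsonlite::write_json(rep, path("eval_report.json"), pretty = TRUE,
                           digits = NA)
      c(path("eval_report.csv"), path("eval_report.json"))
    },
    ablate = {
      dat <- load_data()
      rep <- run_ablation(dat$panel, dat$yields, config_model_builder(cfg),
                          control = config_train_control(cfg),
                          train_years = cfg$split$train_years,
                          test_years = cfg$split$test_years)
      utils::write.csv(rep, path("ablation.csv"), row.names = FALSE)
      path("ablation.csv")
    },
    importance = {
      dat <- load_data()
      res <- evaluate_combo(dat$panel, dat$yields, config_model_builder(cfg),
                            control = config_train_control(cfg),
                            train_years = cfg$split$train_years,
                            test_years = cfg$split$test_years)
      scaled <- apply_scaler(dat$panel, res$scaler)
      ai <- assemble_inputs(scaled, dat$yields)
      imp <- feature_importance(res$model, ai$x,
                                n_samples = cfg$importance$n_samples,
                                seed = cfg$seed,
                                method = cfg$importance$method, y = ai$y)
      utils::write.csv(imp, path("importance.csv"), row.names = FALSE)
      path("importance.csv")
    }
  )
  manifest <- write_manifest(out_dir, stage, cfg, arts)
  invisible(c(arts, manifest))
}
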