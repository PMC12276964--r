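# End-to-end workbench: a config-driven pipeline over the package modules,
# with on-disk artifacts per stage so runs are reproducible and resumable.
# Stages: generate-maps -> simulate -> genotypes (sample + synthesize) ->
# train -> predict -> evaluate -> bootstrap.

default_run_config <- function() {
  list(
    seed = 1L,
    width = 10L,
    output_dir = "demomap_run",
    priors = list(sigma = c(0.73, 3.08), k = c(4, 40)),
    max_segments = 2L,
    sim = list(cycles = 300L, burn_in = 100L, sigma_m = 1, sigma_c = 1, L = 4,
               genome_length = 1e8, recomb_rate = 1e-8),
    n_sims = list(train = 12L, test = 3L),
    sampling = list(mode = "uniform", n = 20L),
    genotypes = list(m_target = 250L, phased = FALSE),
    augment_draws = 2L,
    model = list(features = 48L, conv_channels = c(16L, 32L), pool = 10L,
                 min_len = 64L, loc_hidden = 48L, comb_hidden = 48L,
                 f_hidden = 48L),
    train = list(batch_size = 10L, learning_rate = 1e-3,
                 validation_fraction = 0.2, plateau_halve = 5L,
                 plateau_stop = 12L, max_epochs = 20L),
    predict = list(replicates = 10L, k_init = 80L, k_extract = 80L),
    bootstrap = list(B = 0L))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load a workbench run configuration
#'
#' Reads a YAML or JSON config and merges it over the built-in defaults.
#' Unknown top-level keys raise an error.
#'
#' @param path Config file (`.yaml`/`.yml`/`.json`), or `NULL` for defaults.
#' @param overrides Named list applied after the file.
#' @return Run configuration list.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  user <- list()
  if (!is.null(path)) {
    user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("the yaml package is required for YAML configs", call. = FALSE)
      }
      yaml::read_yaml(path)
    }
  }
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- merge_config(cfg, user)
  merge_config(cfg, overrides)
}

wb_paths <- function(config) {
  root <- config$output_dir
  list(root = root,
       maps = file.path(root, "maps"),
       sims = file.path(root, "sims"),
       data = file.path(root, "datasets"),
       model = file.path(root, "model"),
       pred = file.path(root, "predictions"))
}

wb_priors <- function(config) {
  list(sigma = map_prior(config$priors$sigma[1], config$priors$sigma[2],
                         "dispersal"),
       k = map_prior(config$priors$k[1], config$priors$k[2], "density"))
}

wb_params <- function(config) {
  s <- config$sim
  sim_params(sigma_m = s$sigma_m, sigma_c = s$sigma_c, L = s$L,
             n_cycles = s$cycles, burn_in = s$burn_in,
             genome_length = s$genome_length, recomb_rate = s$recomb_rate)
}

wb_log <- function(config, stage, extra = list()) {
  p <- wb_paths(config)
  dir.create(p$root, recursive = TRUE, showWarnings = FALSE)
  entry <- c(list(stage = stage, time = format(Sys.time()),
                  seed = config$seed,
                  config_hash = sprintf("%08x",
                    sum(utf8ToInt(paste(deparse(config), collapse = ""))))),
             extra)
  log_path <- file.path(p$root, "run_log.json")
  log <- if (file.exists(log_path)) {
    jsonlite::read_json(log_path, simplifyVector = FALSE)
  } else list()
  log[[length(log) + 1L]] <- entry
  jsonlite::write_json(log, log_path, auto_unbox = TRUE, digits = NA)
  invisible(entry)
}

#' Workbench stage: generate demographic maps
#'
#' Draws the configured number of training and test maps and writes them as
#' CSV grids under `<output_dir>/maps`.
#'
#' @param config A [load_run_config()] result.
#' @return Invisible list of the drawn maps.
#' @export
wb_generate_maps <- function(config) {
  p <- wb_paths(config)
  dir.create(p$maps, recursive = TRUE, showWarnings = FALSE)
  pri <- wb_priors(config)
  set.seed(config$seed)
  roles <- c(rep("train", config$n_sims$train), rep("test", config$n_sims$test))
  maps <- lapply(seq_along(roles), function(i) {
    m <- draw_demographic_map(pri$sigma, pri$k, config$width,
                              config$max_segments)
    write_demographic_map(m, file.path(p$maps, sprintf("%s_%03d", roles[i], i)),
                          seed = config$seed)
    m
  })
  names(maps) <- sprintf("%s_%03d", roles, seq_along(roles))
  wb_log(config, "generate-maps", list(n_maps = length(maps)))
  invisible(maps)
}

wb_read_maps <- function(config) {
  p <- wb_paths(config)
  prefixes <- sort(unique(sub("_(dispersal|density|mask)\\.csv(\\.json)?$", "",
                              list.files(p$maps, full.names = TRUE))))
  maps <- lapply(prefixes, read_demographic_map)
  names(maps) <- basename(prefixes)
  maps
}

#' Workbench stage: forward simulations
#'
#' Runs the simulator on every generated map (ancestry recorded) and stores
#' results under `<output_dir>/sims`.
#'
#' @param config A [load_run_config()] result.
#' @return Invisible list of `sim_result`s.
#' @export
wb_simulate <- function(config) {
  p <- wb_paths(config)
  dir.create(p$sims, recursive = TRUE, showWarnings = FALSE)
  maps <- wb_read_maps(config)
  params <- wb_params(config)
  sims <- lapply(seq_along(maps), function(i) {
    set.seed(config$seed + 100L + i)
    s <- run_simulation(maps[[i]], params, record_ancestry = TRUE,
                        record_realized = FALSE)
    saveRDS(s, file.path(p$sims, paste0(names(maps)[i], ".rds")))
    s
  })
  names(sims) <- names(maps)
  wb_log(config, "simulate",
         list(final_sizes = vapply(sims, function(s) nrow(s$population), 0)))
  invisible(sims)
}

wb_read_sims <- function(config) {
  p <- wb_paths(config)
  files <- sort(list.files(p$sims, pattern = "\\.rds$", full.names = TRUE))
  sims <- lapply(files, readRDS)
  names(sims) <- sub("\\.rds$", "", basename(files))
  sims
}

#' Workbench stage: sampling and genotype synthesis
#'
#' Draws sample sets for every simulation (training simulations get
#' `augment_draws` sets each, test simulations one) and synthesizes
#' genotype datasets; locations CSVs are written alongside.
#'
#' @param config A [load_run_config()] result.
#' @return Invisible named list of per-simulation dataset lists.
#' @export
wb_genotypes <- function(config) {
  p <- wb_paths(config)
  dir.create(p$data, recursive = TRUE, showWarnings = FALSE)
  sims <- wb_read_sims(config)
  scheme <- do.call(sampling_scheme, config$sampling)
  gcfg <- genotype_config(config$genotypes$m_target,
                          phased = isTRUE(config$genotypes$phased))
  out <- lapply(seq_along(sims), function(i) {
    sim <- sims[[i]]
    nm <- names(sims)[i]
    draws <- if (grepl("^train", nm)) config$augment_draws else 1L
    set.seed(config$seed + 500L + i)
    sets <- replicate(draws, draw_sample(sim$population, scheme,
                                         config$width)$id, simplify = FALSE)
    ds <- synthesize_genotypes(sim, sets, gcfg,
                               seed = config$seed + 500L + i)
    for (d in seq_along(ds)) {
      write_locations_csv(ds[[d]]$locations,
                          file.path(p$data, sprintf("%s_draw%d_locations.csv",
                                                    nm, d)))
    }
    saveRDS(ds, file.path(p$data, paste0(nm, ".rds")))
    ds
  })
  names(out) <- names(sims)
  wb_log(config, "genotypes", list(n_datasets = sum(lengths(out))))
  invisible(out)
}

#' Workbench stage: model training
#'
#' Fits the target transform on the training maps, assembles training
#' datasets, trains the network, and stores the fitted model, transform and
#' history under `<output_dir>/model`.
#'
#' @param config A [load_run_config()] result.
#' @return Invisible list with `model`, `transform`, `history`.
#' @export
wb_train <- function(config) {
  p <- wb_paths(config)
  dir.create(p$model, recursive = TRUE, showWarnings = FALSE)
  maps <- wb_read_maps(config)
  data <- lapply(sort(list.files(p$data, pattern = "\\.rds$",
                                 full.names = TRUE)), readRDS)
  names(data) <- sub("\\.rds$", "",
                     sort(list.files(p$data, pattern = "\\.rds$")))
  train_names <- grep("^train", names(data), value = TRUE)
  tfm <- fit_target_transform(maps[train_names])
  tds <- unlist(lapply(train_names, function(nm) {
    tgt <- map_to_array(maps[[nm]])
    lapply(data[[nm]], prepare_training_dataset, target = tgt,
           transform = tfm, width = config$width,
           k_init = config$predict$k_init,
           k_extract = config$predict$k_extract,
           mask = maps[[nm]]$habitat_mask)
  }), recursive = FALSE)
  set.seed(config$seed + 900L)
  model <- build_model(config$genotypes$m_target,
                       do.call(model_config, config$model))
  tc <- do.call(train_config, config$train)
  fit <- train(model, tds, tc)
  saveRDS(list(model = fit$model, transform = tfm), file.path(p$model, "model.rds"))
  utils::write.csv(fit$history, file.path(p$model, "history.csv"),
                   row.names = FALSE)
  wb_log(config, "train", list(epochs = nrow(fit$history),
                               best_val = min(fit$history$val_loss)))
  invisible(list(model = fit$model, transform = tfm, history = fit$history))
}

#' Workbench stage: prediction on test datasets
#'
#' Ensemble prediction for every test dataset; maps are written as CSV
#' grids under `<output_dir>/predictions`.
#'
#' @param config A [load_run_config()] result.
#' @return Invisible named list of `map_estimate`s.
#' @export
wb_predict <- function(config) {
  p <- wb_paths(config)
  dir.create(p$pred, recursive = TRUE, showWarnings = FALSE)
  fitted <- readRDS(file.path(p$model, "model.rds"))
  pri <- wb_priors(config)
  test_files <- sort(list.files(p$data, pattern = "^test.*\\.rds$",
                                full.names = TRUE))
  set.seed(config$seed + 1300L)
  ests <- lapply(test_files, function(f) {
    ds <- readRDS(f)[[1L]]
    est <- ensemble_predict(fitted$model, ds, config$width, fitted$transform,
                            R = config$predict$replicates,
                            k_init = config$predict$k_init)
    nm <- sub("\\.rds$", "", basename(f))
    em <- array_to_map(est$point, sigma_prior = pri$sigma, k_prior = pri$k)
    write_demographic_map(em, file.path(p$pred, nm))
    est
  })
  names(ests) <- sub("\\.rds$", "", basename(test_files))
  wb_log(config, "predict", list(n_test = length(ests)))
  invisible(ests)
}

#' Workbench stage: evaluation
#'
#' MRAE and r-squared of every test prediction against its simulation input
#' map; a JSON report is written to `<output_dir>/metrics.json`.
#'
#' @param config A [load_run_config()] result.
#' @return Invisible list of per-dataset metrics plus the mean.
#' @export
wb_evaluate <- function(config) {
  p <- wb_paths(config)
  maps <- wb_read_maps(config)
  test_names <- grep("^test", names(maps), value = TRUE)
  per <- lapply(test_names, function(nm) {
    est <- read_demographic_map(file.path(p$pred, nm))
    truth <- maps[[nm]]
    if (truth$width != est$width) {
      stop("map width mismatch between prediction and truth", call. = FALSE)
    }
    metrics_report(map_to_array(truth), map_to_array(est),
                   mask = truth$habitat_mask)
  })
  names(per) <- test_names
  mean_of <- function(field) mean(vapply(per, `[[`, 0, field))
  report <- list(per_dataset = per,
                 mean = list(mrae_dispersal = mean_of("mrae_dispersal"),
                             mrae_density = mean_of("mrae_density")))
  jsonlite::write_json(report, file.path(p$root, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  wb_log(config, "evaluate", report$mean)
  invisible(report)
}

#' Run the full workbench pipeline
#'
#' Executes generate-maps, simulate, genotypes, train, predict, and
#' evaluate in order under one root seed.
#'
#' @param config A [load_run_config()] result.
#' @return Invisible evaluation report.
#' @export
run_end_to_end <- function(config) {
  wb_generate_maps(config)
  wb_simulate(config)
  wb_genotypes(config)
  wb_train(config)
  wb_predict(config)
  invisible(wb_evaluate(config))
}
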