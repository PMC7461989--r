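#' Read a pipeline run configuration from YAML
#'
#' A run configuration ties the pipeline stages together: the phantom
#' cohort, the network architecture, the training settings, the evaluation
#' criteria/modes, and the run directory. Every stage seed defaults to the
#' global `seed` unless set explicitly in its own section.
#'
#' Top-level YAML keys: `seed`, `out_dir`, and optional `phantom`,
#' `network`, `training`, `evaluation` sections whose fields mirror
#' [phantom_config()], [network_spec()], [training_config()] and
#' [evaluate_case()] arguments one-to-one.
#'
#' @param path YAML file path.
#' @return An object of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such config file: '%s'", path),
                               call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop(sprintf("failed to parse YAML config '%s': %s", path,
                 conditionMessage(e)), call. = FALSE)
  })
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  seed <- as.integer(raw$seed %||% 1L)
  out_dir <- raw$out_dir %||% "run"

  ph <- raw$phantom %||% list()
  if (is.null(ph$seed)) ph$seed <- seed
  # vectors come back as lists from YAML; flatten numeric fields
  ph <- lapply(ph, function(x) if (is.list(x)) unlist(x) else x)
  if (!is.null(ph$split)) {
    ph$split <- stats::setNames(as.numeric(ph$split),
                                names(ph$split) %||% c("train", "val", "test"))
  }
  phantom <- do.call(phantom_config, ph)

  nw <- raw$network %||% list()
  nw <- lapply(nw, function(x) if (is.list(x)) unlist(x) else x)
  network <- do.call(network_spec, nw)

  tr <- raw$training %||% list()
  if (is.null(tr$seed)) tr$seed <- seed
  if (!is.null(tr$weights)) {
    tr$weights <- do.call(loss_weights, as.list(unlist(tr$weights)))
  }
  training <- do.call(training_config, tr)

  ev <- raw$evaluation %||% list()
  criteria <- if (is.null(ev$criteria)) default_gamma_criteria() else {
    lapply(ev$criteria, function(cr) {
      gamma_criteria(as.numeric(cr$delta_suv_pct), as.numeric(cr$delta_d_mm))
    })
  }
  modes <- ev$modes %||% c("2D", "3D")

  structure(list(seed = seed, out_dir = out_dir, phantom = phantom,
                 network = network, training = training,
                 evaluation = list(criteria = criteria,
                                   modes = unlist(modes))),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_paths <- function(cfg) {
  list(cohort = file.path(cfg$out_dir, "cohort"),
       checkpoints = file.path(cfg$out_dir, "checkpoints"),
       reports = file.path(cfg$out_dir, "reports"),
       logs = file.path(cfg$out_dir, "logs"))
}

log_line <- function(cfg, ...) {
  dir.create(run_paths(cfg)$logs, recursive = TRUE, showWarnings = FALSE)
  msg <- sprintf(...)
  cat(msg, "\n", sep = "", file = file.path(run_paths(cfg)$logs, "run.log"),
      append = TRUE)
  message(msg)
}

#' Pipeline stage: simulate the phantom cohort
#'
#' Generates the configured cohort under `<out_dir>/cohort` and logs the
#' split sizes.
#'
#' @param config_path YAML run configuration, see [read_run_config()].
#' @param overwrite overwrite an existing cohort directory.
#' @return Invisibly, the `phantom_cohort`.
#' @export
cmd_simulate <- function(config_path, overwrite = FALSE) {
  cfg <- read_run_config(config_path)
  paths <- run_paths(cfg)
  cohort <- generate_cohort(cfg$phantom, out_dir = paths$cohort,
                            overwrite = overwrite)
  log_line(cfg, "simulate: %d cases (train %d / val %d / test %d) -> %s [seed %d]",
           cfg$phantom$n_cases, length(cohort_split(cohort, "train")),
           length(cohort_split(cohort, "val")),
           length(cohort_split(cohort, "test")), paths$cohort, cfg$phantom$seed)
  invisible(cohort)
}

#' Pipeline stage: train the network
#'
#' Loads the simulated cohort, trains with [train_model()], writes the
#' checkpoint (with the network spec and channel mode embedded) and a CSV
#' loss log.
#'
#' @param config_path YAML run configuration.
#' @param no_dose train the dose-ablated 2-channel variant.
#' @return Invisibly, the checkpoint path.
#' @export
cmd_train <- function(config_path, no_dose = FALSE) {
  cfg <- read_run_config(config_path)
  paths <- run_paths(cfg)
  if (!dir.exists(paths$cohort)) {
    stop(sprintf("no cohort under '%s'; run cmd_simulate() first", paths$cohort),
         call. = FALSE)
  }
  cohort <- load_cohort(paths$cohort)
  spec <- cfg$network
  tcfg <- cfg$training
  if (no_dose) {
    tcfg$use_dose <- FALSE
    spec$input_channels <- 2L
  }
  trained <- train_model(cohort, spec, tcfg)
  dir.create(paths$checkpoints, recursive = TRUE, showWarnings = FALSE)
  tag <- if (no_dose) "nodose" else "dose"
  ckpt <- file.path(paths$checkpoints, sprintf("model_%s.rds", tag))
  saveRDS(trained, ckpt)
  dir.create(paths$logs, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(trained$log,
                   file.path(paths$logs, sprintf("training_log_%s.csv", tag)),
                   row.names = FALSE)
  log_line(cfg, "train[%s]: %d epochs, %d channels, final train loss %.5f, best val %.5f -> %s",
           tag, tcfg$epochs, spec$input_channels,
           trained$log$train_loss[nrow(trained$log)], min(trained$log$val_loss),
           ckpt)
  invisible(ckpt)
}

#' Pipeline stage: predict intra-treatment PET volumes
#'
#' Writes one predicted NIfTI volume per case of the chosen split.
#'
#' @param config_path YAML run configuration.
#' @param checkpoint checkpoint path from [cmd_train()].
#' @param split cohort split to predict.
#' @return Invisibly, the written paths.
#' @export
cmd_predict <- function(config_path, checkpoint, split = "test") {
  cfg <- read_run_config(config_path)
  paths <- run_paths(cfg)
  trained <- load_checkpoint(checkpoint)
  cohort <- load_cohort(paths$cohort)
  ids <- cohort_split(cohort, split)
  if (length(ids) == 0) stop(sprintf("split '%s' has no cases", split),
                             call. = FALSE)
  out <- character()
  for (id in ids) {
    pred <- predict_case(trained, cohort$cases[[id]])
    p <- file.path(paths$cohort, id, "pet_intra_pred.nii.gz")
    write_volume(pred, p)
    out <- c(out, p)
  }
  log_line(cfg, "predict: %d volumes written for split '%s'", length(out), split)
  invisible(out)
}

load_checkpoint <- function(checkpoint) {
  if (!file.exists(checkpoint)) {
    stop(sprintf("no such checkpoint: '%s'", checkpoint), call. = FALSE)
  }
  trained <- readRDS(checkpoint)
  if (!inherits(trained, "trained_model")) {
    stop(sprintf("'%s' is not a trained model checkpoint", checkpoint),
         call. = FALSE)
  }
  trained
}

#' Pipeline stage: evaluate predictions against ground truth
#'
#' Predicts and evaluates every case of the chosen split, writes per-case
#' and split-averaged mean-SUV and gamma pass-rate tables, and — when both a
#' with-dose and a without-dose checkpoint are supplied — a combined
#' comparison table (criteria x ROI x with/without dose).
#'
#' @param config_path YAML run configuration.
#' @param checkpoint with-dose checkpoint path.
#' @param checkpoint_nodose optional dose-ablated checkpoint path.
#' @param split cohort split to evaluate.
#' @param weighting pass-rate averaging across cases, see
#'   [average_evaluations()].
#' @return Invisibly, a list with `evals`, `averaged` and (optionally)
#'   `comparison`.
#' @export
cmd_evaluate <- function(config_path, checkpoint, checkpoint_nodose = NULL,
                         split = "test", weighting = "case") {
  cfg <- read_run_config(config_path)
  paths <- run_paths(cfg)
  cohort <- load_cohort(paths$cohort)
  ids <- cohort_split(cohort, split)
  if (length(ids) == 0) stop(sprintf("split '%s' has no cases", split),
                             call. = FALSE)

  evaluate_with <- function(trained) {
    evals <- lapply(ids, function(id) {
      cs <- cohort$cases[[id]]
      pred <- predict_case(trained, cs)
      evaluate_case(pred, cs$pet_intra_truth, cs$rois,
                    criteria = cfg$evaluation$criteria,
                    modes = cfg$evaluation$modes)
    })
    names(evals) <- ids
    evals
  }

  trained <- load_checkpoint(checkpoint)
  evals <- evaluate_with(trained)
  nvox <- vapply(ids, function(id) sum(cohort$cases[[id]]$rois$body$values), 0)
  averaged <- average_evaluations(evals, body_voxels = nvox,
                                  weighting = weighting)
  dir.create(paths$reports, recursive = TRUE, showWarnings = FALSE)
  write_evaluation_reports(averaged, paths$reports)
  for (id in ids) {
    utils::write.csv(evals[[id]]$gamma_table,
                     file.path(paths$reports, sprintf("gamma_%s.csv", id)),
                     row.names = FALSE)
  }

  comparison <- NULL
  if (!is.null(checkpoint_nodose)) {
    trained_nd <- load_checkpoint(checkpoint_nodose)
    evals_nd <- evaluate_with(trained_nd)
    averaged_nd <- average_evaluations(evals_nd, body_voxels = nvox,
                                       weighting = weighting)
    g <- averaged$gamma; gn <- averaged_nd$gamma
    comparison <- tibble::tibble(
      mode = g$mode, criteria = g$criteria,
      body_with_dose = g$pass_body, body_without_dose = gn$pass_body,
      ctv_with_dose = g$pass_ctv, ctv_without_dose = gn$pass_ctv,
      gtv_with_dose = g$pass_gtv, gtv_without_dose = gn$pass_gtv)
    utils::write.csv(comparison,
                     file.path(paths$reports, "dose_ablation_comparison.csv"),
                     row.names = FALSE)
  }
  log_line(cfg, "evaluate: %d cases of split '%s'%s", length(ids), split,
           if (is.null(comparison)) "" else " (with dose-ablation comparison)")
  invisible(list(evals = evals, averaged = averaged, comparison = comparison))
}
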