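#' Region-prioritizing loss weights
#'
#' The training loss multiplies squared errors inside the clinical target
#' volume by `w_ctv` and inside the gross tumor volume by `w_gtv`, on top of
#' the unweighted term over the rest of the body. The defaults 3.0 / 6.0 are
#' the empirically chosen prioritization of the method.
#'
#' @param w_ctv,w_gtv nonnegative penalty factors.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(w_ctv = 3.0, w_gtv = 6.0) {
  if (w_ctv < 0 || w_gtv < 0) stop("loss weights must be >= 0", call. = FALSE)
  structure(list(w_ctv = w_ctv, w_gtv = w_gtv), class = "loss_weights")
}

#' ROI-weighted modified mean square error for one slice
#'
#' The training objective is a sum of three squared-error terms over the
#' region indicators of one axial slice:
#' \deqn{L = \sum 1_{non} (p-g)^2 + w_{CTV} \sum 1_{CTV} (p-g)^2
#'           + w_{GTV} \sum 1_{GTV} (p-g)^2}
#' where `non` is BODY minus CTV. The indicators are taken literally: GTV
#' voxels lie inside the CTV indicator too, so they accrue the CTV-weighted
#' term plus the GTV-weighted term (effective weight `w_ctv + w_gtv`).
#' Setting `exclusive = TRUE` switches to mutually exclusive regions
#' (GTV-only weight `w_gtv`, CTV-minus-GTV weight `w_ctv`).
#'
#' @param pred,truth numeric matrices (one slice each), same shape.
#' @param gtv,ctv,non binary indicator matrices of the same shape; `non`
#'   must be the body-minus-CTV indicator.
#' @param weights a [loss_weights()].
#' @param exclusive use mutually exclusive region semantics instead of the
#'   literal overlapping indicators.
#' @return Nonnegative scalar; 0 iff `pred == truth` on the union of the
#'   three regions.
#' @export
mmse_loss <- function(pred, truth, gtv, ctv, non, weights = loss_weights(),
                      exclusive = FALSE) {
  if (!all(dim(pred) == dim(truth)) || !all(dim(pred) == dim(gtv)) ||
      !all(dim(pred) == dim(ctv)) || !all(dim(pred) == dim(non))) {
    stop("all arrays passed to mmse_loss must share one shape", call. = FALSE)
  }
  for (m in list(gtv, ctv, non)) {
    if (!all(m %in% c(0, 1))) stop("masks must be binary 0/1", call. = FALSE)
  }
  stopifnot(inherits(weights, "loss_weights"))
  sq <- (pred - truth)^2
  if (exclusive) {
    sum(non * sq) + weights$w_ctv * sum(ctv * (1 - gtv) * sq) +
      weights$w_gtv * sum(gtv * sq)
  } else {
    sum(non * sq) + weights$w_ctv * sum(ctv * sq) + weights$w_gtv * sum(gtv * sq)
  }
}

# per-voxel effective weight implied by the three-term objective
mmse_weight_map <- function(gtv, ctv, non, weights, exclusive = FALSE) {
  if (exclusive) {
    non + weights$w_ctv * ctv * (1 - gtv) + weights$w_gtv * gtv
  } else {
    non + weights$w_ctv * ctv + weights$w_gtv * gtv
  }
}

#' Training configuration
#'
#' @param epochs number of passes over the training slices (default 50).
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size slices per gradient step (default 8).
#' @param seed integer; fixes weight initialization and slice shuffling, so
#'   a run is reproducible from (cohort, spec, config).
#' @param use_dose include the dose channel (`FALSE` = ablation mode).
#' @param weights a [loss_weights()].
#' @param exclusive_rois mutually exclusive region semantics in the loss,
#'   see [mmse_loss()].
#' @param adam_beta1,adam_beta2,adam_eps Adam moment decay rates and
#'   numerical floor (standard defaults).
#' @return An object of class `training_config`.
#' @export
training_config <- function(epochs = 50, learning_rate = 1e-3, batch_size = 8,
                            seed = 42, use_dose = TRUE,
                            weights = loss_weights(), exclusive_rois = FALSE,
                            adam_beta1 = 0.9, adam_beta2 = 0.999,
                            adam_eps = 1e-8) {
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  if (batch_size < 1) stop("batch_size must be >= 1", call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 use_dose = isTRUE(use_dose), weights = weights,
                 exclusive_rois = isTRUE(exclusive_rois),
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps),
            class = "training_config")
}

# build the per-slice training samples of one case: input tensors, targets in
# normalized units, and loss weight maps. Only axial slices intersecting the
# BODY contour are used; empty slices would dilute the objective.
case_samples <- function(case, cfg, dose_scale) {
  nc <- normalize_case(case, dose_scale)
  pet_scale <- nc$records$pet$scale
  body <- case$rois$body$values
  slices <- which(apply(body, 3, sum) > 0)
  non <- non_target_mask(case$rois)$values
  lapply(slices, function(k) {
    list(x = assemble_input(nc, k, use_dose = cfg$use_dose),
         y = case$pet_intra_truth$values[, , k] / pet_scale,
         w = mmse_weight_map(case$rois$gtv$values[, , k],
                             case$rois$ctv$values[, , k],
                             non[, , k], cfg$weights, cfg$exclusive_rois))
  })
}

stack_batch <- function(samples, idx) {
  d <- dim(samples[[idx[1]]]$x)
  B <- length(idx)
  x <- array(0, c(d[1], d[2], d[3], B))
  y <- array(0, c(d[1], d[2], B))
  w <- array(0, c(d[1], d[2], B))
  for (b in seq_along(idx)) {
    s <- samples[[idx[b]]]
    x[, , , b] <- s$x; y[, , b] <- s$y; w[, , b] <- s$w
  }
  list(x = x, y = y, w = w)
}

# mean over slices of the per-slice weighted sum-of-squares
batch_loss <- function(pred, y, w) {
  sum(w * (pred - y)^2) / dim(pred)[3]
}

adam_init <- function(model) {
  list(m_W = lapply(model$W, function(w) w * 0),
       v_W = lapply(model$W, function(w) w * 0),
       m_b = lapply(model$b, function(b) b * 0),
       v_b = lapply(model$b, function(b) b * 0),
       t = 0L)
}

adam_step <- function(model, grads, state, cfg) {
  state$t <- state$t + 1L
  b1 <- cfg$adam_beta1; b2 <- cfg$adam_beta2
  corr1 <- 1 - b1^state$t; corr2 <- 1 - b2^state$t
  for (l in seq_along(model$W)) {
    state$m_W[[l]] <- b1 * state$m_W[[l]] + (1 - b1) * grads$dW[[l]]
    state$v_W[[l]] <- b2 * state$v_W[[l]] + (1 - b2) * grads$dW[[l]]^2
    model$W[[l]] <- model$W[[l]] - cfg$learning_rate *
      (state$m_W[[l]] / corr1) / (sqrt(state$v_W[[l]] / corr2) + cfg$adam_eps)
    state$m_b[[l]] <- b1 * state$m_b[[l]] + (1 - b1) * grads$db[[l]]
    state$v_b[[l]] <- b2 * state$v_b[[l]] + (1 - b2) * grads$db[[l]]^2
    model$b[[l]] <- model$b[[l]] - cfg$learning_rate *
      (state$m_b[[l]] / corr1) / (sqrt(state$v_b[[l]] / corr2) + cfg$adam_eps)
  }
  list(model = model, state = state)
}

#' Train the prediction network on a phantom cohort
#'
#' Runs the seeded training loop: He initialization, slice shuffling,
#' mini-batch Adam steps on the ROI-weighted loss, per-epoch training and
#' validation losses, and best-validation checkpoint retention. The run is
#' fully reproducible from `(cohort, spec, config)` including the seed.
#'
#' @param cohort a `phantom_cohort` with nonempty train and val splits.
#' @param spec a [network_spec()]; its `input_channels` must match
#'   `config$use_dose` (3 with dose, 2 without).
#' @param config a [training_config()].
#' @param verbose print per-epoch losses.
#' @return An object of class `trained_model`: the best-validation `model`,
#'   the final-epoch `final_model`, the `spec`, `config`, `dose_scale`, and
#'   a tibble `log` with columns epoch / train_loss / val_loss.
#' @export
train_model <- function(cohort, spec, config, verbose = FALSE) {
  stopifnot(inherits(cohort, "phantom_cohort"), inherits(spec, "network_spec"),
            inherits(config, "training_config"))
  expected_channels <- if (config$use_dose) 3L else 2L
  if (spec$input_channels != expected_channels) {
    stop(sprintf("spec has %d input channels but use_dose=%s requires %d",
                 spec$input_channels, config$use_dose, expected_channels),
         call. = FALSE)
  }
  train_ids <- cohort_split(cohort, "train")
  val_ids <- cohort_split(cohort, "val")
  if (length(train_ids) == 0 || length(val_ids) == 0) {
    stop("cohort must have nonempty train and val splits", call. = FALSE)
  }
  dose_scale <- as.numeric(cohort$manifest$delivered_dose_gy)

  train_samples <- do.call(c, lapply(cohort$cases[train_ids], case_samples,
                                     cfg = config, dose_scale = dose_scale))
  val_samples <- do.call(c, lapply(cohort$cases[val_ids], case_samples,
                                   cfg = config, dose_scale = dose_scale))

  set.seed(config$seed)
  model <- build_network(spec)
  state <- adam_init(model)

  eval_loss <- function(samples) {
    n <- length(samples)
    tot <- 0
    i <- 1L
    while (i <= n) {
      idx <- i:min(i + config$batch_size - 1L, n)
      bt <- stack_batch(samples, idx)
      pred <- network_forward(model, bt$x)
      tot <- tot + sum(bt$w * (pred - bt$y)^2)
      i <- i + config$batch_size
    }
    tot / n
  }

  n_train <- length(train_samples)
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric())
  best_val <- Inf
  best_model <- model
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n_train)
    epoch_tot <- 0
    i <- 1L
    batch_no <- 0L
    while (i <= n_train) {
      idx <- ord[i:min(i + config$batch_size - 1L, n_train)]
      batch_no <- batch_no + 1L
      bt <- stack_batch(train_samples, idx)
      fw <- network_forward(model, bt$x, keep_cache = TRUE)
      B <- dim(bt$y)[3]
      loss <- batch_loss(fw$pred, bt$y, bt$w)
      if (!is.finite(loss)) {
        stop(sprintf("non-finite training loss at epoch %d, batch %d",
                     epoch, batch_no), call. = FALSE)
      }
      epoch_tot <- epoch_tot + loss * B
      dpred <- (2 / B) * bt$w * (fw$pred - bt$y)
      grads <- network_backward(model, fw$cache, fw$pred, dpred)
      upd <- adam_step(model, grads, state, config)
      model <- upd$model; state <- upd$state
      i <- i + config$batch_size
    }
    train_loss <- epoch_tot / n_train
    val_loss <- eval_loss(val_samples)
    if (val_loss < best_val) {
      best_val <- val_loss
      best_model <- model
    }
    log <- rbind(log, data.frame(epoch = epoch, train_loss = train_loss,
                                 val_loss = val_loss))
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                      train_loss, val_loss))
    }
  }
  structure(list(model = best_model, final_model = model, spec = spec,
                 config = config, dose_scale = dose_scale,
                 log = tibble::as_tibble(log)),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %d epochs, %s channels, best val loss %.5f\n",
              max(x$log$epoch), if (x$config$use_dose) "PET+CT+dose" else "PET+CT",
              min(x$log$val_loss)))
  invisible(x)
}

#' Predict the intra-treatment PET volume of one case
#'
#' Assembles normalized input slices, runs the trained network on every
#' axial slice, and restores the output to SUV units using the case's PET
#' normalization record. The prediction lives on the case grid and is
#' nonnegative when the network's final activation is ReLU.
#'
#' @param trained a `trained_model` from [train_model()].
#' @param case a `phantom_case` (or compatible list of input volumes).
#' @param use_best use the best-validation weights (default) rather than the
#'   final-epoch weights.
#' @return A PET [volume()] in SUV.
#' @export
predict_case <- function(trained, case, use_best = TRUE) {
  stopifnot(inherits(trained, "trained_model"))
  model <- if (use_best) trained$model else trained$final_model
  cfg <- trained$config
  nc <- normalize_case(case, trained$dose_scale)
  d <- dim(nc$pet$values)
  nchan <- if (cfg$use_dose) 3L else 2L
  pred_norm <- array(0, d)
  # slices are processed in small batches to bound the im2col working set
  chunk <- 4L
  k <- 1L
  while (k <= d[3]) {
    ks <- k:min(k + chunk - 1L, d[3])
    xs <- lapply(ks, function(kk) assemble_input(nc, kk, cfg$use_dose))
    x <- array(unlist(xs, use.names = FALSE), c(d[1], d[2], nchan, length(ks)))
    pred_norm[, , ks] <- network_forward(model, x)
    k <- k + chunk
  }
  pred <- volume(pred_norm, case$pet_pre$spacing,
                 case$pet_pre$origin, "PET")
  restore_volume(pred, nc$records$pet)
}
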