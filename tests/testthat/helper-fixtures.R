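# Shared fixture builders. Everything is generated in code under fixed
# seeds; nothing is read from disk except through the package's own I/O.

random_volume <- function(dims = c(8, 8, 4), spacing = c(2, 2, 2),
                          range = c(1, 5), modality = "PET", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  volume(array(runif(prod(dims), range[1], range[2]), dims),
         spacing = spacing, modality = modality)
}

full_body_mask <- function(dims = c(8, 8, 4), spacing = c(2, 2, 2)) {
  volume(array(1, dims), spacing = spacing, modality = "MASK")
}

# small, fast phantom configuration for unit tests (not the study-scale
# configuration used by the acceptance tests)
tiny_phantom_config <- function(..., n_cases = 4, noise_sd_suv = 0,
                                split = c(train = 0.5, val = 0.25, test = 0.25)) {
  phantom_config(grid_shape = c(24, 24, 12), spacing_mm = c(2, 2, 2),
                 n_cases = n_cases, tumor_radius_range_mm = c(4, 6),
                 ctv_margin_mm = 3, noise_sd_suv = noise_sd_suv,
                 split = split, ...)
}

tiny_network_spec <- function(input_channels = 3) {
  network_spec(n_conv_layers = 4, filters_per_layer = c(6, 8, 6, 1),
               input_channels = input_channels)
}

# independent naive evaluation of the three-term weighted loss, summed voxel
# by voxel with explicit loops
naive_mmse <- function(pred, truth, gtv, ctv, non, w_ctv, w_gtv) {
  acc <- 0
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      d2 <- (pred[i, j] - truth[i, j])^2
      if (non[i, j] == 1) acc <- acc + d2
      if (ctv[i, j] == 1) acc <- acc + w_ctv * d2
      if (gtv[i, j] == 1) acc <- acc + w_gtv * d2
    }
  }
  acc
}

# exhaustive between-class-variance search over every split of the sorted
# unique values; independent oracle for otsu_threshold()
naive_otsu <- function(x) {
  u <- sort(unique(x))
  best_t <- NA_real_
  best_v <- -Inf
  for (k in seq_len(length(u) - 1)) {
    lo <- x[x <= u[k]]; hi <- x[x > u[k]]
    v <- (length(lo) / length(x)) * (length(hi) / length(x)) *
      (mean(lo) - mean(hi))^2
    if (v > best_v + 1e-15) {
      best_v <- v
      best_t <- (u[k] + u[k + 1]) / 2
    }
  }
  best_t
}
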