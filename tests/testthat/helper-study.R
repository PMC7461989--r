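# The desk-scale study configuration: the conditions under which the
# package's end-to-end claims (response recovery, ablation direction) are
# exercised. Mirrors the configuration described in the methods vignette.

study_phantom_config <- function(seed) {
  phantom_config(grid_shape = c(64, 64, 32), spacing_mm = c(2, 2, 2),
                 n_cases = 10, noise_sd_suv = 0,
                 response_alpha_per_gy = c(0.05, 0.05),
                 tumor_radius_range_mm = c(8, 14), ctv_margin_mm = 6,
                 delivered_dose_gy = 20,
                 split = c(train = 0.6, val = 0.2, test = 0.2), seed = seed)
}

ablation_phantom_config <- function(seed) {
  phantom_config(grid_shape = c(48, 48, 24), spacing_mm = c(2, 2, 2),
                 n_cases = 10, noise_sd_suv = 0,
                 response_alpha_per_gy = c(0.15, 0.15),
                 tumor_radius_range_mm = c(7, 11), ctv_margin_mm = 5,
                 delivered_dose_gy = 20, dose_heterogeneity = 0.3,
                 split = c(train = 0.6, val = 0.2, test = 0.2), seed = seed)
}

study_network_spec <- function(input_channels = 3) {
  network_spec(filters_per_layer = c(8, 16, 16, 16, 16, 16, 8, 1),
               input_channels = input_channels)
}

study_training_config <- function(seed, use_dose = TRUE) {
  training_config(epochs = 50, learning_rate = 2e-3, batch_size = 8,
                  seed = seed, use_dose = use_dose)
}
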