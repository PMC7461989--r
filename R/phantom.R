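#' Configuration of the digital phantom cohort generator
#'
#' Describes a family of synthetic "patients" that emulate the co-registered
#' inputs of the prediction pipeline: a pre-treatment PET with a tumor
#' hotspot, a two-level CT, a planned dose distribution that is uniform
#' inside the CTV with a smooth exterior falloff, nested GTV/CTV/BODY masks,
#' and a ground-truth intra-treatment PET produced by a known analytic
#' dose-response ([apply_response()]). Because the response parameters are
#' recorded per case, training and evaluation can be validated end-to-end
#' against a recoverable ground truth.
#'
#' @param grid_shape integer length-3, voxels per axis (slice axis last).
#' @param spacing_mm numeric length-3, voxel size in mm.
#' @param n_cases number of cases in the cohort.
#' @param background_suv SUV of normal tissue inside the BODY contour.
#' @param tumor_suv_range `[min, max]` peak SUV of the tumor hotspot.
#' @param tumor_radius_range_mm `[min, max]` GTV sphere radius in mm.
#' @param ctv_margin_mm isotropic expansion of the GTV into the CTV, mm.
#' @param delivered_dose_gy plateau dose inside the CTV in Gy; default 20,
#'   the dose delivered at the intra-treatment scan time point.
#' @param dose_falloff_mm exponential penumbra length scale outside the CTV.
#' @param response_alpha_per_gy `[min, max]` range of the per-case SUV decay
#'   rate (per Gy) of the analytic response model.
#' @param noise_sd_suv standard deviation of additive Gaussian SUV noise
#'   (clipped at zero); 0 disables all noise, including CT noise.
#' @param dose_heterogeneity amplitude of an optional smooth multiplicative
#'   perturbation of the dose field (0 = perfectly uniform plateau). Useful
#'   for ablation studies where the dose channel must carry information not
#'   inferable from anatomy.
#' @param split named fractions `c(train=, val=, test=)` summing to 1.
#' @param seed integer seed; the whole cohort is a pure function of the
#'   configuration including this seed.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(64, 64, 32),
                           spacing_mm = c(2, 2, 2),
                           n_cases = 10,
                           background_suv = 1,
                           tumor_suv_range = c(3, 10),
                           tumor_radius_range_mm = c(8, 16),
                           ctv_margin_mm = 6,
                           delivered_dose_gy = 20,
                           dose_falloff_mm = 8,
                           response_alpha_per_gy = c(0.02, 0.08),
                           noise_sd_suv = 0.05,
                           dose_heterogeneity = 0,
                           split = c(train = 0.6, val = 0.2, test = 0.2),
                           seed = 1) {
  cfg <- list(grid_shape = as.integer(grid_shape), spacing_mm = as.numeric(spacing_mm),
              n_cases = as.integer(n_cases), background_suv = background_suv,
              tumor_suv_range = tumor_suv_range,
              tumor_radius_range_mm = tumor_radius_range_mm,
              ctv_margin_mm = ctv_margin_mm, delivered_dose_gy = delivered_dose_gy,
              dose_falloff_mm = dose_falloff_mm,
              response_alpha_per_gy = response_alpha_per_gy,
              noise_sd_suv = noise_sd_suv, dose_heterogeneity = dose_heterogeneity,
              split = split, seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  stopifnot(length(cfg$grid_shape) == 3, length(cfg$spacing_mm) == 3)
  if (any(cfg$grid_shape <= 0) || any(cfg$spacing_mm <= 0)) {
    stop("grid_shape and spacing_mm must be positive", call. = FALSE)
  }
  ranges <- list(tumor_suv_range = cfg$tumor_suv_range,
                 tumor_radius_range_mm = cfg$tumor_radius_range_mm,
                 response_alpha_per_gy = cfg$response_alpha_per_gy)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || r[1] > r[2]) {
      stop(sprintf("%s must be c(min, max) with min <= max", nm), call. = FALSE)
    }
  }
  for (nm in c("background_suv", "ctv_margin_mm", "delivered_dose_gy",
               "dose_falloff_mm", "noise_sd_suv", "dose_heterogeneity")) {
    if (cfg[[nm]] < 0) stop(sprintf("%s must be >= 0", nm), call. = FALSE)
  }
  if (cfg$response_alpha_per_gy[1] < 0) {
    stop("response_alpha_per_gy must be >= 0", call. = FALSE)
  }
  if (abs(sum(cfg$split) - 1) > 1e-8 ||
      !all(c("train", "val", "test") %in% names(cfg$split))) {
    stop("split must be named fractions train/val/test summing to 1", call. = FALSE)
  }
  semi <- body_semi_axes(cfg)
  if (cfg$tumor_radius_range_mm[2] + cfg$ctv_margin_mm >= min(semi)) {
    stop(sprintf(paste0("geometry does not fit: max GTV radius + CTV margin (%.1f mm) ",
                        "must be smaller than the smallest BODY semi-axis (%.1f mm)"),
                 cfg$tumor_radius_range_mm[2] + cfg$ctv_margin_mm, min(semi)),
         call. = FALSE)
  }
  invisible(cfg)
}

# BODY ellipsoid semi-axes in mm: fills most of the grid on every axis
body_semi_axes <- function(cfg) {
  0.45 * cfg$grid_shape * cfg$spacing_mm
}

#' Analytic dose-response parameters of one phantom case
#'
#' The ground-truth mapping from pre-treatment SUV and dose to
#' intra-treatment SUV, see [apply_response()].
#'
#' @param alpha_per_gy SUV decay rate per Gy, >= 0.
#' @param background_suv background (floor) SUV, >= 0.
#' @return An object of class `response_params`.
#' @export
response_params <- function(alpha_per_gy, background_suv) {
  if (alpha_per_gy < 0 || background_suv < 0) {
    stop("alpha_per_gy and background_suv must be >= 0", call. = FALSE)
  }
  structure(list(alpha_per_gy = alpha_per_gy, background_suv = background_suv),
            class = "response_params")
}

#' Apply the analytic dose-response model
#'
#' The above-background SUV excess decays exponentially with local dose:
#' for voxels with `SUV_pre > background`,
#' `SUV_post = background + (SUV_pre - background) * exp(-alpha * D)`;
#' voxels at or below background (including air outside the BODY) are left
#' unchanged. With `alpha = 0` the map is the identity, and as the dose grows
#' every above-background voxel decays towards the background floor.
#'
#' @param pet_pre pre-treatment PET [volume()] in SUV.
#' @param dose dose [volume()] in Gy, on the same grid.
#' @param params [response_params()].
#' @return The intra-treatment PET [volume()] (SUV, nonnegative).
#' @export
apply_response <- function(pet_pre, dose, params) {
  stopifnot(is_volume(pet_pre), is_volume(dose),
            inherits(params, "response_params"))
  stopifnot_same_grid(pet_pre, dose, what = "pet_pre and dose")
  if (any(dose$values < 0)) stop("dose must be >= 0 everywhere", call. = FALSE)
  bg <- params$background_suv
  excess <- pmax(pet_pre$values - bg, 0)
  decayed <- excess * exp(-params$alpha_per_gy * dose$values)
  post <- pet_pre$values - excess + decayed
  volume(pmax(post, 0), pet_pre$spacing, pet_pre$origin, "PET")
}

# smooth low-frequency random field in [-1, 1] (sum of 3 random-phase
# sinusoids along world coordinates), used by the dose heterogeneity knob
smooth_random_field <- function(cfg, coords) {
  f <- 0
  for (h in 1:3) {
    k <- stats::runif(3, -1, 1)
    k <- k / sqrt(sum(k^2)) * stats::runif(1, 0.5, 1.5) /
      (2 * min(cfg$grid_shape * cfg$spacing_mm))
    phase <- stats::runif(1, 0, 2 * pi)
    f <- f + sin(2 * pi * (coords$x * k[1] + coords$y * k[2] + coords$z * k[3]) + phase)
  }
  f / 3
}

#' Generate one phantom case
#'
#' Builds one synthetic patient deterministically from the configuration and
#' the case index. The BODY is an ellipsoid filling most of the grid; the
#' GTV is a sphere at a randomized interior location whose CTV expansion
#' still fits inside the BODY; the pre-treatment PET is background plus a
#' spherical-Gaussian hotspot peaking in the GTV; the CT is a two-level HU
#' map (air/soft tissue); the dose is the plateau value inside the CTV with
#' exponential falloff outside; and the ground-truth intra-treatment PET is
#' [apply_response()] of the pre-PET with independent noise.
#'
#' @param config a [phantom_config()].
#' @param case_index 0-based case index, `< n_cases`.
#' @return An object of class `phantom_case` with elements `pet_pre`, `ct`,
#'   `dose`, `rois`, `pet_intra_truth`, `params`, `case_id`.
#' @export
generate_case <- function(config, case_index) {
  validate_phantom_config(config)
  if (case_index < 0 || case_index >= config$n_cases) {
    stop(sprintf("case_index must be in [0, %d)", config$n_cases), call. = FALSE)
  }
  case_seed <- as.integer((config$seed %% 100000L) * 10000L + case_index)
  set.seed(case_seed)

  shp <- config$grid_shape; sp <- config$spacing_mm
  centre <- (shp - 1) / 2 * sp
  semi <- body_semi_axes(config)

  cx <- (seq_len(shp[1]) - 1) * sp[1]
  cy <- (seq_len(shp[2]) - 1) * sp[2]
  cz <- (seq_len(shp[3]) - 1) * sp[3]
  X <- array(rep(cx, times = shp[2] * shp[3]), shp)
  Y <- array(rep(rep(cy, each = shp[1]), times = shp[3]), shp)
  Z <- array(rep(cz, each = shp[1] * shp[2]), shp)

  body <- ((X - centre[1]) / semi[1])^2 + ((Y - centre[2]) / semi[2])^2 +
    ((Z - centre[3]) / semi[3])^2 <= 1

  r <- stats::runif(1, config$tumor_radius_range_mm[1], config$tumor_radius_range_mm[2])
  peak <- stats::runif(1, config$tumor_suv_range[1], config$tumor_suv_range[2])
  alpha <- stats::runif(1, config$response_alpha_per_gy[1], config$response_alpha_per_gy[2])

  # tumor centre: uniform inside the BODY ellipsoid shrunk so GTV + margin fits
  shrink <- (semi - (r + config$ctv_margin_mm)) / semi
  if (any(shrink <= 0)) {
    stop("GTV radius + CTV margin too large for the BODY ellipsoid", call. = FALSE)
  }
  repeat {
    u <- stats::runif(3, -1, 1)
    if (sum(u^2) <= 1) break
  }
  tc <- centre + u * semi * shrink

  d <- sqrt((X - tc[1])^2 + (Y - tc[2])^2 + (Z - tc[3])^2)
  gtv <- d <= r
  ctv <- (d <= r + config$ctv_margin_mm) & body
  if (!any(gtv) || sum(ctv) <= sum(gtv) || sum(body) <= sum(ctv)) {
    stop("degenerate mask geometry (grid too coarse for the sampled radii)",
         call. = FALSE)
  }

  noisy <- config$noise_sd_suv > 0
  bg <- config$background_suv
  # hotspot: Gaussian excess, decayed to 10% of peak at the GTV boundary
  sigma <- r / sqrt(2 * log(10))
  pet <- ifelse(body, bg, 0) + (peak - bg) * exp(-d^2 / (2 * sigma^2)) * body
  if (noisy) pet <- pet + stats::rnorm(length(pet), 0, config$noise_sd_suv)
  pet <- array(pmax(pet, 0), shp)

  ct <- ifelse(body, 40, -1000)
  if (noisy) ct <- ct + stats::rnorm(length(ct), 0, 15)
  ct <- array(ct, shp)

  dist_out <- pmax(d - (r + config$ctv_margin_mm), 0)
  dose <- config$delivered_dose_gy * exp(-dist_out / config$dose_falloff_mm)
  if (config$dose_heterogeneity > 0) {
    f <- smooth_random_field(config, list(x = X, y = Y, z = Z))
    dose <- dose * (1 + config$dose_heterogeneity * f)
  }
  dose <- array(pmax(dose, 0), shp)

  mk <- function(v, mod) volume(v, sp, c(0, 0, 0), mod)
  pet_pre <- mk(pet, "PET")
  dose_vol <- mk(dose, "DOSE")
  params <- response_params(alpha, bg)

  intra <- apply_response(pet_pre, dose_vol, params)$values
  if (noisy) intra <- intra + stats::rnorm(length(intra), 0, config$noise_sd_suv)
  intra <- array(pmax(intra, 0), shp)

  structure(
    list(pet_pre = pet_pre,
         ct = mk(ct, "CT"),
         dose = dose_vol,
         rois = roi_set(mk(gtv * 1, "MASK"), mk(ctv * 1, "MASK"), mk(body * 1, "MASK")),
         pet_intra_truth = mk(intra, "PET"),
         params = params,
         case_id = sprintf("case_%03d", case_index)),
    class = "phantom_case"
  )
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> %s  alpha=%.4f/Gy  peak pre-SUV=%.2f\n",
              x$case_id, x$params$alpha_per_gy, max(x$pet_pre$values)))
  print(x$rois)
  invisible(x)
}

#' Generate a phantom cohort with a train/validation/test split
#'
#' Generates `n_cases` cases (see [generate_case()]) and a seeded disjoint
#' split. When `out_dir` is given the cohort is written to disk in the
#' canonical layout: one directory per case holding `pet_pre.nii.gz`,
#' `ct.nii.gz`, `dose.nii.gz`, `pet_intra.nii.gz`, `mask_gtv.nii.gz`,
#' `mask_ctv.nii.gz`, `mask_body.nii.gz`, plus a `manifest.json` recording
#' per-case response parameters and the split. Two runs with the same
#' configuration produce byte-identical manifests.
#'
#' @param config a [phantom_config()].
#' @param out_dir optional output directory; `NULL` keeps the cohort in
#'   memory only.
#' @param overwrite overwrite an existing non-empty `out_dir`? Refused by
#'   default.
#' @return An object of class `phantom_cohort`: list of `cases`, the
#'   `manifest`, and `dir` (or `NULL`).
#' @export
generate_cohort <- function(config, out_dir = NULL, overwrite = FALSE) {
  validate_phantom_config(config)
  if (config$n_cases < 1) stop("n_cases must be >= 1", call. = FALSE)

  n <- config$n_cases
  n_train <- round(n * config$split[["train"]])
  n_val <- round(n * config$split[["val"]])
  n_test <- n - n_train - n_val
  if (n_test < 0) stop("split fractions produce a negative test count", call. = FALSE)

  set.seed(config$seed)
  perm <- sample.int(n)  # shuffled 1-based positions
  split_of <- character(n)
  split_of[perm[seq_len(n_train)]] <- "train"
  if (n_val > 0) split_of[perm[n_train + seq_len(n_val)]] <- "val"
  if (n_test > 0) split_of[perm[n_train + n_val + seq_len(n_test)]] <- "test"
  names(split_of) <- sprintf("case_%03d", 0:(n - 1))

  cases <- lapply(0:(n - 1), function(i) generate_case(config, i))
  names(cases) <- vapply(cases, `[[`, "", "case_id")

  manifest <- list(
    seed = config$seed,
    n_cases = n,
    grid_shape = config$grid_shape,
    spacing_mm = config$spacing_mm,
    delivered_dose_gy = config$delivered_dose_gy,
    cases = lapply(names(cases), function(id) {
      list(case_id = id, split = split_of[[id]],
           alpha_per_gy = cases[[id]]$params$alpha_per_gy,
           background_suv = cases[[id]]$params$background_suv)
    })
  )

  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite) {
      stop(sprintf("output directory '%s' exists and is non-empty; use overwrite = TRUE",
                   out_dir), call. = FALSE)
    }
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(cases)) {
      cdir <- file.path(out_dir, id)
      dir.create(cdir, showWarnings = FALSE)
      cs <- cases[[id]]
      write_volume(cs$pet_pre, file.path(cdir, "pet_pre.nii.gz"))
      write_volume(cs$ct, file.path(cdir, "ct.nii.gz"))
      write_volume(cs$dose, file.path(cdir, "dose.nii.gz"))
      write_volume(cs$pet_intra_truth, file.path(cdir, "pet_intra.nii.gz"))
      write_volume(cs$rois$gtv, file.path(cdir, "mask_gtv.nii.gz"))
      write_volume(cs$rois$ctv, file.path(cdir, "mask_ctv.nii.gz"))
      write_volume(cs$rois$body, file.path(cdir, "mask_body.nii.gz"))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(list(cases = cases, manifest = manifest, dir = out_dir),
            class = "phantom_cohort")
}

#' Load a phantom cohort from its on-disk layout
#'
#' @param dir directory written by [generate_cohort()].
#' @return A `phantom_cohort`.
#' @export
load_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) {
    stop(sprintf("no manifest.json under '%s'", dir), call. = FALSE)
  }
  manifest <- jsonlite::read_json(mpath, simplifyVector = FALSE)
  cases <- lapply(manifest$cases, function(m) {
    cdir <- file.path(dir, m$case_id)
    structure(
      list(pet_pre = read_volume(file.path(cdir, "pet_pre.nii.gz"), "PET"),
           ct = read_volume(file.path(cdir, "ct.nii.gz"), "CT"),
           dose = read_volume(file.path(cdir, "dose.nii.gz"), "DOSE"),
           rois = roi_set(read_volume(file.path(cdir, "mask_gtv.nii.gz"), "MASK"),
                          read_volume(file.path(cdir, "mask_ctv.nii.gz"), "MASK"),
                          read_volume(file.path(cdir, "mask_body.nii.gz"), "MASK")),
           pet_intra_truth = read_volume(file.path(cdir, "pet_intra.nii.gz"), "PET"),
           params = response_params(as.numeric(m$alpha_per_gy),
                                    as.numeric(m$background_suv)),
           case_id = m$case_id),
      class = "phantom_case"
    )
  })
  names(cases) <- vapply(manifest$cases, `[[`, "", "case_id")
  structure(list(cases = cases, manifest = manifest, dir = dir),
            class = "phantom_cohort")
}

#' Case ids belonging to one split of a cohort
#'
#' @param cohort a `phantom_cohort`.
#' @param split `"train"`, `"val"` or `"test"`.
#' @return Character vector of case ids.
#' @export
cohort_split <- function(cohort, split = c("train", "val", "test")) {
  split <- match.arg(split)
  ids <- vapply(cohort$manifest$cases, `[[`, "", "case_id")
  sp <- vapply(cohort$manifest$cases, `[[`, "", "split")
  ids[sp == split]
}
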