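#' Mean SUV over a mask
#'
#' Arithmetic mean of the volume's values over the support of a binary mask
#' on the same grid.
#'
#' @param vol a [volume()].
#' @param mask a MASK [volume()] on the same grid, nonempty.
#' @return Scalar mean.
#' @export
mean_suv <- function(vol, mask) {
  stopifnot(is_volume(vol), is_volume(mask))
  if (mask$modality != "MASK") stop("'mask' must be a MASK volume", call. = FALSE)
  stopifnot_same_grid(vol, mask, what = "volume and mask")
  sel <- mask$values > 0
  if (!any(sel)) stop("mask is empty", call. = FALSE)
  mean(vol$values[sel])
}

#' Otsu threshold of a set of intensities
#'
#' Exhaustively evaluates every split of the sorted unique values (the
#' empirical histogram) and returns the threshold maximizing the
#' between-class variance `w0 * w1 * (mu0 - mu1)^2`. The returned threshold
#' is the midpoint between the optimal split's neighbouring values, so it
#' separates the two classes strictly. Ties are broken towards the lowest
#' threshold.
#'
#' @param x numeric vector with at least two distinct values.
#' @return Scalar threshold.
#' @export
otsu_threshold <- function(x) {
  u <- sort(unique(x))
  if (length(u) < 2) {
    stop("Otsu threshold undefined: intensities are constant", call. = FALSE)
  }
  cnt <- tabulate(match(x, u))
  n <- length(x)
  csum <- cumsum(cnt)
  cval <- cumsum(cnt * u)
  total <- cval[length(u)]
  k <- seq_len(length(u) - 1)      # split after the k-th unique value
  w0 <- csum[k] / n
  w1 <- 1 - w0
  mu0 <- cval[k] / csum[k]
  mu1 <- (total - cval[k]) / (n - csum[k])
  sigma_b <- w0 * w1 * (mu0 - mu1)^2
  best <- which.max(sigma_b)       # which.max returns the first (lowest) tie
  (u[best] + u[best + 1]) / 2
}

#' High-uptake subregion of the GTV by Otsu's method
#'
#' Thresholds the GTV-restricted intensities with [otsu_threshold()] and
#' returns the mask of GTV voxels strictly above the threshold — the
#' high-uptake subregion conventionally used to delimit the metabolically
#' most active part of the tumor.
#'
#' @param vol PET [volume()].
#' @param gtv GTV MASK [volume()] on the same grid.
#' @return A MASK [volume()] (subset of the GTV, nonempty) with the applied
#'   threshold attached as attribute `"threshold"`.
#' @export
otsu_high_uptake <- function(vol, gtv) {
  stopifnot(is_volume(vol), is_volume(gtv))
  if (gtv$modality != "MASK") stop("'gtv' must be a MASK volume", call. = FALSE)
  stopifnot_same_grid(vol, gtv, what = "volume and GTV mask")
  sel <- gtv$values > 0
  if (!any(sel)) stop("GTV mask is empty", call. = FALSE)
  thr <- otsu_threshold(vol$values[sel])
  m <- (gtv$values > 0 & vol$values > thr) * 1
  out <- volume(m, vol$spacing, vol$origin, "MASK")
  attr(out, "threshold") <- thr
  out
}

#' Region mean-SUV report for a predicted volume against its ground truth
#'
#' Mean SUV inside the GTV, the CTV, and the Otsu high-uptake subregion of
#' the GTV, for both the predicted and the ground-truth volume. The
#' high-uptake region is recomputed per volume (each volume gets its own
#' Otsu threshold, both of which are recorded).
#'
#' If a volume is constant inside the GTV (e.g. an untrained network
#' predicting a flat map), its Otsu threshold is undefined and the
#' corresponding high-uptake entries are reported as `NA` rather than
#' aborting the evaluation.
#'
#' @param pred,truth PET [volume()]s on the same grid.
#' @param rois an [roi_set()].
#' @return An object of class `suv_report`: a tibble with columns `region`
#'   (`GTV`, `CTV`, `high_uptake`), `predicted`, `truth`, plus attributes
#'   `otsu_threshold_pred` and `otsu_threshold_truth`.
#' @export
suv_report <- function(pred, truth, rois) {
  high_mean <- function(vol) {
    hu <- tryCatch(otsu_high_uptake(vol, rois$gtv), error = function(e) NULL)
    if (is.null(hu)) list(mean = NA_real_, threshold = NA_real_)
    else list(mean = mean_suv(vol, hu), threshold = attr(hu, "threshold"))
  }
  hp <- high_mean(pred)
  ht <- high_mean(truth)
  tab <- tibble::tibble(
    region = c("GTV", "CTV", "high_uptake"),
    predicted = c(mean_suv(pred, rois$gtv), mean_suv(pred, rois$ctv), hp$mean),
    truth = c(mean_suv(truth, rois$gtv), mean_suv(truth, rois$ctv), ht$mean)
  )
  attr(tab, "otsu_threshold_pred") <- hp$threshold
  attr(tab, "otsu_threshold_truth") <- ht$threshold
  class(tab) <- c("suv_report", class(tab))
  tab
}

#' Full evaluation of one predicted case
#'
#' Runs the standard evaluation suite: the region mean-SUV report
#' ([suv_report()]) and a gamma analysis ([gamma_map()]) for every
#' combination of the given criteria and modes, reporting pass rates in the
#' whole-body / CTV / GTV column order.
#'
#' @param pred predicted PET [volume()].
#' @param truth ground-truth intra-treatment PET [volume()].
#' @param rois an [roi_set()] on the same grid.
#' @param criteria list of [gamma_criteria()]; defaults to the standard
#'   \{5,10\}% x \{5,10\} mm sweep.
#' @param modes character subset of `c("2D", "3D")`.
#' @param normalization gamma SUV-tolerance basis, see [gamma_map()].
#' @return An object of class `case_evaluation`: `suv` (the report),
#'   `gamma` (list of `gamma_result`), and `gamma_table` (tibble with
#'   columns mode, criteria, pass_body, pass_ctv, pass_gtv).
#' @export
evaluate_case <- function(pred, truth, rois,
                          criteria = default_gamma_criteria(),
                          modes = c("2D", "3D"),
                          normalization = c("global", "local")) {
  normalization <- match.arg(normalization)
  modes <- match.arg(modes, c("2D", "3D"), several.ok = TRUE)
  stopifnot_same_grid(pred, truth, rois$body, what = "evaluation inputs")

  suv <- suv_report(pred, truth, rois)
  gamma <- list()
  rows <- list()
  for (mode in modes) {
    for (crit in criteria) {
      res <- gamma_map(truth, pred, rois$body, crit, mode = mode,
                       rois = rois, normalization = normalization)
      key <- sprintf("%s %s", mode, criteria_label(crit))
      gamma[[key]] <- res
      rows[[key]] <- tibble::tibble(
        mode = mode, criteria = criteria_label(crit),
        delta_suv_pct = crit$delta_suv_pct, delta_d_mm = crit$delta_d_mm,
        pass_body = res$pass_rate_body, pass_ctv = res$pass_rate_ctv,
        pass_gtv = res$pass_rate_gtv)
    }
  }
  structure(list(suv = suv, gamma = gamma,
                 gamma_table = do.call(rbind, unname(rows))),
            class = "case_evaluation")
}

#' @export
print.case_evaluation <- function(x, ...) {
  cat("<case_evaluation>\nMean SUV:\n")
  print(as.data.frame(x$suv))
  cat("Gamma pass rates (%):\n")
  print(as.data.frame(x$gamma_table))
  invisible(x)
}

#' Average evaluations over the cases of a split
#'
#' Case-level averaging: every case contributes equally, matching how
#' multi-patient results are conventionally reported. Voxel-pooled
#' averaging is available via `weighting = "voxel"` (pass rates weighted by
#' each case's body voxel count).
#'
#' @param evals list of `case_evaluation` objects.
#' @param body_voxels integer vector of body voxel counts per case (only
#'   needed for voxel weighting).
#' @param weighting `"case"` (default) or `"voxel"`.
#' @return List with tibbles `suv` (mean over cases per region) and `gamma`
#'   (mean pass rates per mode x criteria).
#' @export
average_evaluations <- function(evals, body_voxels = NULL,
                                weighting = c("case", "voxel")) {
  weighting <- match.arg(weighting)
  stopifnot(length(evals) >= 1)
  wts <- if (weighting == "case") rep(1, length(evals)) else {
    stopifnot(length(body_voxels) == length(evals))
    body_voxels
  }
  wts <- wts / sum(wts)

  suv0 <- evals[[1]]$suv
  pred <- Reduce(`+`, Map(function(e, w) w * e$suv$predicted, evals, wts))
  tru <- Reduce(`+`, Map(function(e, w) w * e$suv$truth, evals, wts))
  suv <- tibble::tibble(region = suv0$region, predicted = pred, truth = tru)

  g0 <- evals[[1]]$gamma_table
  gb <- Reduce(`+`, Map(function(e, w) w * e$gamma_table$pass_body, evals, wts))
  gc_ <- Reduce(`+`, Map(function(e, w) w * e$gamma_table$pass_ctv, evals, wts))
  gg <- Reduce(`+`, Map(function(e, w) w * e$gamma_table$pass_gtv, evals, wts))
  gamma <- tibble::tibble(mode = g0$mode, criteria = g0$criteria,
                          pass_body = gb, pass_ctv = gc_, pass_gtv = gg)
  list(suv = suv, gamma = gamma)
}

#' Write evaluation reports to CSV and JSON
#'
#' Writes the mean-SUV table, one pass-rate table per gamma mode (rows =
#' criteria, columns = whole body / CTV region / GTV region), and a JSON
#' bundle of everything.
#'
#' @param averaged result of [average_evaluations()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_evaluation_reports <- function(averaged, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  p <- file.path(dir, "mean_suv.csv")
  utils::write.csv(averaged$suv, p, row.names = FALSE)
  paths <- c(paths, p)
  for (mode in unique(averaged$gamma$mode)) {
    sub <- averaged$gamma[averaged$gamma$mode == mode,
                          c("criteria", "pass_body", "pass_ctv", "pass_gtv")]
    names(sub) <- c("criteria", "whole_body_pct", "ctv_region_pct", "gtv_region_pct")
    p <- file.path(dir, sprintf("gamma_pass_rates_%s.csv", tolower(mode)))
    utils::write.csv(sub, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "evaluation.json")
  jsonlite::write_json(list(mean_suv = averaged$suv, gamma = averaged$gamma),
                       p, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}
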