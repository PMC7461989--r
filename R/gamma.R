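#' Gamma test acceptance criteria
#'
#' A gamma criterion pairs an SUV tolerance (as a percentage of the
#' normalization value, by default the ground-truth volume's maximum SUV)
#' with a distance-to-agreement (DTA) tolerance in millimetres. The standard
#' sweep evaluated by [evaluate_case()] is \{5, 10\}% x \{5, 10\} mm.
#'
#' @param delta_suv_pct SUV tolerance in percent, > 0.
#' @param delta_d_mm DTA tolerance in mm, > 0.
#' @return An object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(delta_suv_pct, delta_d_mm) {
  if (delta_suv_pct <= 0 || delta_d_mm <= 0) {
    stop("gamma criteria must be positive", call. = FALSE)
  }
  structure(list(delta_suv_pct = delta_suv_pct, delta_d_mm = delta_d_mm),
            class = "gamma_criteria")
}

#' The four standard criteria combinations
#'
#' @return List of [gamma_criteria()]: 5%/5mm, 10%/5mm, 5%/10mm, 10%/10mm.
#' @export
default_gamma_criteria <- function() {
  list(gamma_criteria(5, 5), gamma_criteria(10, 5),
       gamma_criteria(5, 10), gamma_criteria(10, 10))
}

criteria_label <- function(crit) {
  sprintf("%g%%/%g mm", crit$delta_suv_pct, crit$delta_d_mm)
}

# integer voxel shifts whose physical length is within delta_d_mm;
# 2D mode restricts the search to the axial plane (third axis fixed)
gamma_shift_table <- function(spacing, delta_d_mm, mode) {
  rng <- lapply(1:3, function(ax) {
    m <- floor(delta_d_mm / spacing[ax])
    if (mode == "2D" && ax == 3L) 0L else seq.int(-m, m)
  })
  g <- expand.grid(si = rng[[1]], sj = rng[[2]], sk = rng[[3]])
  dist2 <- (g$si * spacing[1])^2 + (g$sj * spacing[2])^2 + (g$sk * spacing[3])^2
  keep <- dist2 <= delta_d_mm^2
  list(shifts = as.matrix(g[keep, , drop = FALSE]),
       dist_term = dist2[keep] / delta_d_mm^2)
}

gamma_result_new <- function(gamma_vals, reference, body, crit, mode, rois,
                             cap, normalization) {
  b <- body$values > 0
  rate <- function(mask) 100 * mean(gamma_vals[mask & b] <= 1)
  # built directly: gamma maps carry NA outside the body contour, which the
  # volume() validator (finite values) intentionally refuses elsewhere
  map_vol <- structure(list(values = gamma_vals, spacing = reference$spacing,
                            origin = reference$origin, modality = "PET"),
                       class = "volume")
  res <- list(
    gamma_map = map_vol,
    pass_rate_body = rate(b),
    pass_rate_ctv = if (!is.null(rois)) rate(rois$ctv$values > 0) else NA_real_,
    pass_rate_gtv = if (!is.null(rois)) rate(rois$gtv$values > 0) else NA_real_,
    criteria = crit, mode = mode, cap = cap, normalization = normalization
  )
  class(res) <- "gamma_result"
  res
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %s %s: pass body %.1f%% | CTV %s | GTV %s\n",
              x$mode, criteria_label(x$criteria), x$pass_rate_body,
              ifelse(is.na(x$pass_rate_ctv), "-", sprintf("%.1f%%", x$pass_rate_ctv)),
              ifelse(is.na(x$pass_rate_gtv), "-", sprintf("%.1f%%", x$pass_rate_gtv))))
  invisible(x)
}

gamma_check_inputs <- function(reference, evaluated, body) {
  stopifnot(is_volume(reference), is_volume(evaluated), is_volume(body))
  stopifnot_same_grid(reference, evaluated, body, what = "gamma inputs")
  if (!any(body$values > 0)) stop("body mask is empty", call. = FALSE)
}

gamma_delta_abs <- function(reference, crit, normalization) {
  ref_max <- max(reference$values)
  if (ref_max <= 0) stop("reference volume has no positive values", call. = FALSE)
  if (normalization == "global") crit$delta_suv_pct / 100 * ref_max else NULL
}

#' Per-voxel SUV gamma analysis between a prediction and its ground truth
#'
#' For every reference voxel inside the body mask, the gamma index is the
#' minimum over evaluated-volume voxels within the DTA radius of
#' \deqn{\gamma(r) = \min_e \sqrt{\left(\frac{SUV_e - SUV_r}{\Delta SUV_t}\right)^2
#'   + \left(\frac{\|e - r\|}{\Delta d_t}\right)^2}}
#' A voxel passes when `gamma <= 1`. The SUV tolerance is
#' `delta_suv_pct`% of the global reference maximum (`normalization =
#' "global"`, the convention of gamma analysis; `"local"` uses each
#' reference voxel's own value). Candidate positions are evaluated-volume
#' voxel centres within `delta_d_mm`; positions farther away cannot pass
#' regardless of intensity, so the search radius equals the DTA tolerance.
#' Gamma values are reported capped at `cap` (pass/fail is unaffected).
#'
#' In `"2D"` mode the search is restricted to the reference voxel's own
#' axial slice; `"3D"` searches the full neighbourhood, so per-voxel
#' `gamma_3D <= gamma_2D` always holds.
#'
#' @param reference ground-truth PET [volume()].
#' @param evaluated predicted PET [volume()] on the same grid.
#' @param body BODY mask [volume()]; gamma is computed only inside it.
#' @param crit a [gamma_criteria()].
#' @param mode `"3D"` or `"2D"`.
#' @param rois optional [roi_set()] to also report CTV/GTV pass rates.
#' @param normalization `"global"` (default) or `"local"`.
#' @param cap reporting ceiling for the gamma map (default 10).
#' @return A `gamma_result`: the gamma map (NA outside the body), pass rates
#'   in percent per ROI, and the criteria/mode used.
#' @export
gamma_map <- function(reference, evaluated, body, crit,
                      mode = c("3D", "2D"), rois = NULL,
                      normalization = c("global", "local"), cap = 10) {
  mode <- match.arg(mode)
  normalization <- match.arg(normalization)
  stopifnot(inherits(crit, "gamma_criteria"))
  gamma_check_inputs(reference, evaluated, body)

  d <- dim(reference$values)
  st <- gamma_shift_table(reference$spacing, crit$delta_d_mm, mode)
  dsuv_abs <- gamma_delta_abs(reference, crit, normalization)
  ref <- reference$values
  ev <- evaluated$values
  denom <- if (normalization == "global") dsuv_abs else {
    pmax(crit$delta_suv_pct / 100 * ref, .Machine$double.eps)
  }

  g2 <- array(Inf, d)
  for (s in seq_len(nrow(st$shifts))) {
    si <- st$shifts[s, 1]; sj <- st$shifts[s, 2]; sk <- st$shifts[s, 3]
    if (max(1, 1 - si) > min(d[1], d[1] - si) ||
        max(1, 1 - sj) > min(d[2], d[2] - sj) ||
        max(1, 1 - sk) > min(d[3], d[3] - sk)) next  # shift exceeds extent
    ri <- max(1, 1 - si):min(d[1], d[1] - si)
    rj <- max(1, 1 - sj):min(d[2], d[2] - sj)
    rk <- max(1, 1 - sk):min(d[3], d[3] - sk)
    dd <- if (normalization == "global") {
      (ev[ri + si, rj + sj, rk + sk, drop = FALSE] -
         ref[ri, rj, rk, drop = FALSE]) / denom
    } else {
      (ev[ri + si, rj + sj, rk + sk, drop = FALSE] -
         ref[ri, rj, rk, drop = FALSE]) / denom[ri, rj, rk, drop = FALSE]
    }
    cand <- dd^2 + st$dist_term[s]
    g2[ri, rj, rk] <- pmin(g2[ri, rj, rk, drop = FALSE], cand)
  }
  gamma_vals <- pmin(sqrt(g2), cap)
  gamma_vals[body$values <= 0] <- NA_real_
  gamma_result_new(gamma_vals, reference, body, crit, mode, rois, cap,
                   normalization)
}

#' Exhaustive reference implementation of the gamma analysis
#'
#' Identical contract to [gamma_map()], but computed by a plain per-voxel
#' loop over every candidate within the search radius, with no vectorized
#' shift enumeration. It exists as an independent oracle for validating the
#' optimized path and is only sensible on small volumes.
#'
#' @inheritParams gamma_map
#' @return A `gamma_result`.
#' @export
gamma_brute_force <- function(reference, evaluated, body, crit,
                              mode = c("3D", "2D"), rois = NULL,
                              normalization = c("global", "local"), cap = 10) {
  mode <- match.arg(mode)
  normalization <- match.arg(normalization)
  stopifnot(inherits(crit, "gamma_criteria"))
  gamma_check_inputs(reference, evaluated, body)
  dsuv_abs <- if (normalization == "global") {
    gamma_delta_abs(reference, crit, normalization)
  } else -1  # signals per-voxel normalization to the C++ loop
  gamma_vals <- gamma_brute_cpp(reference$values, evaluated$values,
                                reference$spacing, dsuv_abs,
                                crit$delta_suv_pct, crit$delta_d_mm,
                                mode == "2D", cap)
  gamma_vals[body$values <= 0] <- NA_real_
  gamma_result_new(gamma_vals, reference, body, crit, mode, rois, cap,
                   normalization)
}
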