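#' Volumetric scalar field with grid geometry
#'
#' A `volume` is a 3D scalar array together with its voxel spacing, origin and
#' a modality tag. It is the common currency of the package: PET volumes carry
#' standardized uptake values (SUV), CT volumes Hounsfield units (HU), dose
#' volumes absorbed dose in Gy, and mask volumes binary 0/1 indicators.
#'
#' Voxel indices are 1-based in R; the world position of voxel `(i, j, k)` is
#' `origin + (c(i, j, k) - 1) * spacing`, all in millimetres. The slice
#' (axial) axis is the third array dimension.
#'
#' @param values numeric 3D array of voxel values; must be finite.
#' @param spacing numeric length-3, voxel size per axis in mm; all > 0.
#' @param origin numeric length-3, world position (mm) of the first voxel.
#' @param modality one of `"PET"`, `"CT"`, `"DOSE"`, `"MASK"`. MASK volumes
#'   may only contain the values 0 and 1.
#'
#' @return An object of class `volume`.
#' @export
#' @examples
#' v <- volume(array(1, c(4, 4, 2)), spacing = c(2, 2, 2), modality = "PET")
#' v
volume <- function(values, spacing, origin = c(0, 0, 0),
                   modality = c("PET", "CT", "DOSE", "MASK")) {
  modality <- match.arg(modality)
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("'values' must be a 3D array", call. = FALSE)
  }
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) {
    stop("volume values must all be finite", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("'spacing' must be 3 positive finite numbers (mm)", call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("'origin' must be 3 finite numbers (mm)", call. = FALSE)
  }
  if (modality == "MASK" && !all(values %in% c(0, 1))) {
    stop("MASK volume may only contain values 0 and 1", call. = FALSE)
  }
  structure(
    list(values = values, spacing = spacing, origin = origin,
         modality = modality),
    class = "volume"
  )
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume> %s  %d x %d x %d voxels  spacing %.3g x %.3g x %.3g mm\n",
              x$modality, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.3g, %.3g, %.3g) mm  value range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$values)

is_volume <- function(x) inherits(x, "volume")

#' Test whether two volumes share the same grid
#'
#' Compares array dimensions, spacing and origin (within `tol` mm).
#'
#' @param a,b `volume` objects.
#' @param tol absolute tolerance in mm for spacing/origin comparison.
#' @return Logical scalar.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stopifnot_same_grid <- function(..., what = "volumes") {
  vols <- list(...)
  ref <- vols[[1L]]
  for (v in vols[-1L]) {
    if (!same_grid(ref, v)) {
      stop(sprintf("%s must share the same grid (shape, spacing, origin)",
                   what), call. = FALSE)
    }
  }
  invisible(TRUE)
}

# world coordinates (mm) of every voxel centre along one axis
axis_coords <- function(vol, axis) {
  n <- dim(vol$values)[axis]
  vol$origin[axis] + (seq_len(n) - 1) * vol$spacing[axis]
}

#' Set of nested radiotherapy region-of-interest masks
#'
#' Bundles the three binary masks used throughout training and evaluation:
#' the gross tumor volume (GTV), the clinical target volume (CTV, the GTV
#' plus a margin for microscopic spread) and the BODY contour. The masks must
#' live on one common grid and be strictly nested: GTV < CTV < BODY, each
#' nonempty. The "non-target" region used by the weighted loss is BODY minus
#' CTV, see [non_target_mask()].
#'
#' @param gtv,ctv,body `volume` objects with modality `"MASK"`.
#' @return An object of class `roi_set` with elements `gtv`, `ctv`, `body`.
#' @export
roi_set <- function(gtv, ctv, body) {
  for (m in list(gtv, ctv, body)) {
    if (!is_volume(m) || m$modality != "MASK") {
      stop("roi_set components must be MASK volumes", call. = FALSE)
    }
  }
  stopifnot_same_grid(gtv, ctv, body, what = "ROI masks")
  g <- gtv$values > 0; c_ <- ctv$values > 0; b <- body$values > 0
  if (!any(g)) stop("GTV mask is empty", call. = FALSE)
  if (any(g & !c_)) stop("GTV must be a subset of CTV", call. = FALSE)
  if (any(c_ & !b)) stop("CTV must be a subset of BODY", call. = FALSE)
  if (sum(c_) <= sum(g)) stop("CTV must be a strict superset of GTV", call. = FALSE)
  if (sum(b) <= sum(c_)) stop("BODY must be a strict superset of CTV", call. = FALSE)
  structure(list(gtv = gtv, ctv = ctv, body = body), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> GTV %d | CTV %d | BODY %d voxels\n",
              sum(x$gtv$values), sum(x$ctv$values), sum(x$body$values)))
  invisible(x)
}

#' Non-target mask: BODY minus CTV
#'
#' The complement region of the weighted loss: voxels inside the BODY contour
#' that are not part of the clinical target volume.
#'
#' @param rois an [roi_set()].
#' @return A MASK `volume`.
#' @export
non_target_mask <- function(rois) {
  v <- rois$body$values * (1 - rois$ctv$values)
  volume(v, rois$body$spacing, rois$body$origin, "MASK")
}
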