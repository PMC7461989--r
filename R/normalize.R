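#' Normalize a volume into the [0,1] range
#'
#' Network inputs (PET, CT, dose) are mapped into `[0,1]` before training;
#' predictions are mapped back to SUV with [restore_volume()] using the
#' record returned here. The normalized value is `(x - offset) / scale`,
#' clamped to `[0,1]` only for the windowed CT scheme.
#'
#' Default schemes per modality:
#' \describe{
#'   \item{PET}{`"volume_max"`: divide by the volume's maximum SUV, so the
#'     record is per-volume and restoration is exact.}
#'   \item{DOSE}{`"fixed_scale"`: divide by a plan-level reference dose
#'     (`scale`, e.g. the delivered dose in Gy) so dose keeps its meaning
#'     across cases; `scale` must be supplied.}
#'   \item{CT}{`"window"`: fixed affine window \[-1000, 2000\] HU; values
#'     outside the window are clipped, so restoration is exact only inside
#'     the window.}
#' }
#'
#' @param vol a [volume()] (not a MASK).
#' @param scheme override the default scheme for the modality; one of
#'   `"volume_max"`, `"fixed_scale"`, `"window"`.
#' @param scale,offset scheme parameters where applicable. `fixed_scale`
#'   requires `scale > 0`; `window` defaults to offset -1000, scale 3000.
#' @return A list with elements `volume` (normalized) and `record`
#'   (a `normalization_record` capturing modality, scheme, scale, offset).
#' @export
normalize_volume <- function(vol, scheme = NULL, scale = NULL, offset = NULL) {
  stopifnot(is_volume(vol))
  if (vol$modality == "MASK") {
    stop("MASK volumes are not normalized", call. = FALSE)
  }
  if (is.null(scheme)) {
    scheme <- switch(vol$modality,
                     PET = "volume_max", DOSE = "fixed_scale", CT = "window")
  }
  scheme <- match.arg(scheme, c("volume_max", "fixed_scale", "window"))
  clip <- FALSE
  if (scheme == "volume_max") {
    mx <- max(vol$values)
    if (mx <= 0) {
      stop(sprintf("%s volume is all-zero: per-volume max scaling is undefined",
                   vol$modality), call. = FALSE)
    }
    scale <- mx; offset <- 0
  } else if (scheme == "fixed_scale") {
    if (is.null(scale) || !is.finite(scale) || scale <= 0) {
      stop("scheme 'fixed_scale' requires a positive 'scale' (reference dose in Gy)",
           call. = FALSE)
    }
    offset <- 0
  } else { # window
    if (is.null(offset)) offset <- -1000
    if (is.null(scale)) scale <- 3000
    clip <- TRUE
  }
  x <- (vol$values - offset) / scale
  if (clip) x <- pmin(pmax(x, 0), 1)
  rec <- structure(
    list(modality = vol$modality, scheme = scheme,
         scale = as.numeric(scale), offset = as.numeric(offset)),
    class = "normalization_record"
  )
  list(volume = volume(x, vol$spacing, vol$origin, vol$modality), record = rec)
}

#' Restore a normalized volume to its original intensity range
#'
#' Exact inverse of [normalize_volume()] (for windowed CT, exact for values
#' inside the window). The record's modality must match the volume's.
#'
#' @param vol normalized [volume()].
#' @param record the `normalization_record` produced when normalizing.
#' @return A [volume()] in original units.
#' @export
restore_volume <- function(vol, record) {
  stopifnot(is_volume(vol))
  if (!inherits(record, "normalization_record")) {
    stop("'record' must be a normalization_record", call. = FALSE)
  }
  if (record$modality != vol$modality) {
    stop(sprintf("normalization record is for %s but volume is %s",
                 record$modality, vol$modality), call. = FALSE)
  }
  volume(vol$values * record$scale + record$offset,
         vol$spacing, vol$origin, vol$modality)
}

#' @export
print.normalization_record <- function(x, ...) {
  cat(sprintf("<normalization_record> %s scheme=%s scale=%g offset=%g\n",
              x$modality, x$scheme, x$scale, x$offset))
  invisible(x)
}

#' Write/read a normalization record JSON sidecar
#'
#' @param record a `normalization_record`.
#' @param path JSON file path.
#' @return `read_normalization_record()` returns the record;
#'   `write_normalization_record()` returns `path` invisibly.
#' @export
write_normalization_record <- function(record, path) {
  jsonlite::write_json(unclass(record), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_normalization_record
#' @export
read_normalization_record <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(modality = x$modality, scheme = x$scheme,
                 scale = as.numeric(x$scale), offset = as.numeric(x$offset)),
            class = "normalization_record")
}
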