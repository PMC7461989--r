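#' Read a volume from a NIfTI file
#'
#' Reads a 3D NIfTI image (`.nii` or `.nii.gz`) into a [volume()]. Voxel
#' spacing is taken from the header `pixdim` and the origin from the
#' translation column of the stored affine. Only axis-aligned volumes with a
#' positive diagonal affine are supported; anything else is rejected rather
#' than silently reoriented.
#'
#' @param path file path to a NIfTI image with a 3D payload.
#' @param modality modality tag to attach, see [volume()]. Files read as
#'   `"MASK"` must contain only the values 0 and 1.
#' @return A [volume()].
#' @export
read_volume <- function(path, modality = c("PET", "CT", "DOSE", "MASK")) {
  modality <- match.arg(modality)
  if (!file.exists(path)) {
    stop(sprintf("no such file: '%s'", path), call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    stop(sprintf("'%s': expected a 3D payload, got %d dimensions",
                 path, length(d)), call. = FALSE)
  }
  vals <- array(as.numeric(img), dim = d)
  if (!all(is.finite(vals))) {
    stop(sprintf("'%s': volume contains non-finite values", path),
         call. = FALSE)
  }
  spacing <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img, useQuaternionFirst = FALSE)
  rot <- xf[1:3, 1:3]
  if (any(abs(rot - diag(diag(rot))) > 1e-4) || any(diag(rot) <= 0)) {
    stop(sprintf("'%s': only axis-aligned volumes with a positive diagonal affine are supported",
                 path), call. = FALSE)
  }
  origin <- xf[1:3, 4]
  tryCatch(
    volume(vals, spacing = spacing, origin = origin, modality = modality),
    error = function(e) {
      stop(sprintf("'%s': %s", path, conditionMessage(e)), call. = FALSE)
    }
  )
}

#' Write a volume to a NIfTI file
#'
#' Writes the values with a diagonal affine encoding spacing and origin, so
#' that [read_volume()] round-trips values and geometry exactly (64-bit float
#' payload).
#'
#' @param vol a [volume()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_volume(vol))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  m <- diag(4)
  m[1, 1] <- vol$spacing[1]; m[2, 2] <- vol$spacing[2]; m[3, 3] <- vol$spacing[3]
  m[1:3, 4] <- vol$origin
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Resample a volume onto the grid of a reference volume
#'
#' Maps every voxel centre of the reference grid into the source volume's
#' continuous index space and interpolates. PET and dose volumes are
#' typically resampled onto the CT grid before network input assembly; masks
#' must use nearest-neighbour interpolation so they stay binary.
#'
#' Positions outside the source extent are filled with 0 for PET, dose and
#' mask volumes and with -1000 HU (air) for CT.
#'
#' @param vol source [volume()].
#' @param reference [volume()] whose grid defines the output geometry.
#' @param mode `"linear"` (trilinear) or `"nearest"`. Linear interpolation on
#'   a MASK volume is an error.
#' @return A [volume()] on the reference grid, keeping `vol`'s modality.
#' @export
resample_to_grid <- function(vol, reference, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  stopifnot(is_volume(vol), is_volume(reference))
  if (vol$modality == "MASK" && mode == "linear") {
    stop("MASK volumes must be resampled with mode = 'nearest'", call. = FALSE)
  }
  fill <- if (vol$modality == "CT") -1000 else 0

  dr <- dim(reference$values)
  # continuous (1-based) source index of each reference voxel centre, per axis
  src_idx <- lapply(1:3, function(ax) {
    w <- axis_coords(reference, ax)
    (w - vol$origin[ax]) / vol$spacing[ax] + 1
  })
  gx <- array(rep(src_idx[[1]], times = dr[2] * dr[3]), dr)
  gy <- array(rep(rep(src_idx[[2]], each = dr[1]), times = dr[3]), dr)
  gz <- array(rep(src_idx[[3]], each = dr[1] * dr[2]), dr)

  ds <- dim(vol$values)
  out <- if (mode == "nearest") {
    ix <- round(gx); iy <- round(gy); iz <- round(gz)
    inside <- ix >= 1 & ix <= ds[1] & iy >= 1 & iy <= ds[2] & iz >= 1 & iz <= ds[3]
    res <- array(fill, dr)
    lin <- (ix[inside] - 1) + (iy[inside] - 1) * ds[1] + (iz[inside] - 1) * ds[1] * ds[2] + 1
    res[inside] <- vol$values[lin]
    res
  } else {
    x0 <- floor(gx); y0 <- floor(gy); z0 <- floor(gz)
    fx <- gx - x0; fy <- gy - y0; fz <- gz - z0
    inside <- x0 >= 1 & x0 + 1 <= ds[1] & y0 >= 1 & y0 + 1 <= ds[2] &
      z0 >= 1 & z0 + 1 <= ds[3]
    # exactly on the far face: pull back one cell so the corner gather stays valid
    atx <- gx == ds[1]; aty <- gy == ds[2]; atz <- gz == ds[3]
    x0[atx] <- x0[atx] - 1; fx[atx] <- 1
    y0[aty] <- y0[aty] - 1; fy[aty] <- 1
    z0[atz] <- z0[atz] - 1; fz[atz] <- 1
    inside <- inside | ((atx | aty | atz) &
      x0 >= 1 & x0 + 1 <= ds[1] & y0 >= 1 & y0 + 1 <= ds[2] & z0 >= 1 & z0 + 1 <= ds[3])
    res <- array(fill, dr)
    if (any(inside)) {
      x0i <- x0[inside]; y0i <- y0[inside]; z0i <- z0[inside]
      fxi <- fx[inside]; fyi <- fy[inside]; fzi <- fz[inside]
      corner <- function(dx, dy, dz) {
        lin <- (x0i + dx - 1) + (y0i + dy - 1) * ds[1] +
          (z0i + dz - 1) * ds[1] * ds[2] + 1
        vol$values[lin]
      }
      wx0 <- 1 - fxi; wy0 <- 1 - fyi; wz0 <- 1 - fzi
      acc <- corner(0, 0, 0) * wx0 * wy0 * wz0 +
        corner(1, 0, 0) * fxi * wy0 * wz0 +
        corner(0, 1, 0) * wx0 * fyi * wz0 +
        corner(1, 1, 0) * fxi * fyi * wz0 +
        corner(0, 0, 1) * wx0 * wy0 * fzi +
        corner(1, 0, 1) * fxi * wy0 * fzi +
        corner(0, 1, 1) * wx0 * fyi * fzi +
        corner(1, 1, 1) * fxi * fyi * fzi
      res[inside] <- acc
    }
    res
  }
  volume(out, reference$spacing, reference$origin, vol$modality)
}
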