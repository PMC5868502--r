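#' Construct a scalar volume
#'
#' A 3-D grid of scalar values — CT attenuation (HU) or the voxelwise
#' metabolic rate of glucose — with voxel spacing and a modality label. The
#' first two array axes span the coronal plane; the third axis (by default)
#' is the projection axis.
#'
#' @param data 3-D numeric array.
#' @param spacing_mm Voxel spacing per axis (mm), all positive.
#' @param modality Label, e.g. `"CT"` or `"MRgluc"`.
#' @param id Source identifier carried into projections.
#'
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(data, spacing_mm = c(1, 1, 1), modality = "MRgluc",
                          id = "volume") {
  if (!is.array(data) || length(dim(data)) != 3L || length(data) == 0L) {
    stop("'data' must be a non-empty 3-D array")
  }
  if (any(!is.finite(data))) stop("volume values must all be finite")
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0)) {
    stop("'spacing_mm' must be three positive values")
  }
  structure(list(data = data, spacing_mm = spacing_mm, modality = modality,
                 id = id),
            class = "scalar_volume")
}

#' Maximum intensity projection
#'
#' Projects a scalar volume along the projection axis: each output pixel is
#' exactly the maximum of the voxel values along the perpendicular
#' point-line, `out(x, y) = max_z vol(x, y, z)`.
#'
#' @param volume A [scalar_volume()] (or bare 3-D array).
#' @param axis Array axis to project along (default 3).
#'
#' @return An object of class `mip_image`: list with `data` (2-D matrix),
#'   `modality`, `source_id`.
#' @examples
#' v <- array(0, c(5, 5, 4)); v[2, 3, 2] <- 7
#' mip(v)$data[2, 3]
#' @export
mip <- function(volume, axis = 3L) {
  if (inherits(volume, "scalar_volume")) {
    arr <- volume$data; modality <- volume$modality; id <- volume$id
  } else {
    arr <- volume; modality <- NA_character_; id <- NA_character_
  }
  stopifnot(is.array(arr), length(dim(arr)) == 3L)
  perm <- c(setdiff(1:3, axis), axis)
  arr <- aperm(arr, perm)
  d <- dim(arr)
  out <- arr[, , 1L]
  for (z in seq_len(d[3])[-1L]) out <- pmax(out, arr[, , z])
  structure(list(data = out, modality = modality, source_id = id),
            class = "mip_image")
}

#' MIP hotspot within an ROI
#'
#' Identical selection rule to [hotspot_statistic()], applied to a maximum
#' intensity projection: the greatest `frac` (default 10%) of values within
#' the ROI are selected (`k = ceiling(frac * N)`, ties at the cutoff broken
#' by raster-scan order) and their median returned along with the binary
#' hotspot mask.
#'
#' @param mip_img A `mip_image` (or numeric matrix).
#' @param roi A `roi_mask` or logical matrix within the image.
#' @param frac Fraction of ROI pixels in the hotspot.
#'
#' @return List with `mask` (logical matrix) and `median` (scalar).
#' @export
mip_hotspot <- function(mip_img, roi, frac = 0.1) {
  img <- if (inherits(mip_img, "mip_image")) mip_img$data else mip_img
  mask <- roi_mask_matrix(roi)
  if (!all(dim(mask) == dim(img))) stop("ROI dimensions must match the MIP")
  if (!any(mask)) stop("empty ROI")
  list(mask = hotspot_mask(img, mask, frac = frac),
       median = hotspot_statistic(img, mask, frac = frac))
}

#' Composite rendering of CT and glucose-uptake projections
#'
#' Grayscale CT underlay with a color-mapped glucose overlay blended at
#' opacity `alpha`. Both projections are min-max normalized independently;
#' the overlay uses a black-red-yellow-white "hot" ramp. Deterministic.
#'
#' @param ct_mip,gluc_mip `mip_image` objects (or matrices) of equal
#'   dimensions.
#' @param alpha Overlay opacity in \[0, 1\].
#' @return An `h x w x 3` RGB array in \[0, 1\].
#' @export
composite_mip <- function(ct_mip, gluc_mip, alpha = 0.5) {
  ct <- if (inherits(ct_mip, "mip_image")) ct_mip$data else ct_mip
  gl <- if (inherits(gluc_mip, "mip_image")) gluc_mip$data else gluc_mip
  if (!all(dim(ct) == dim(gl))) stop("projections must share dimensions")
  if (alpha < 0 || alpha > 1) stop("'alpha' must be in [0, 1]")
  norm01 <- function(m) {
    r <- range(m)
    if (diff(r) == 0) matrix(0, nrow(m), ncol(m)) else (m - r[1]) / diff(r)
  }
  g <- norm01(ct)
  u <- norm01(gl)
  # hot ramp: black -> red -> yellow -> white
  hr <- pmin(3 * u, 1)
  hg <- pmin(pmax(3 * u - 1, 0), 1)
  hb <- pmin(pmax(3 * u - 2, 0), 1)
  out <- array(0, c(nrow(ct), ncol(ct), 3))
  out[, , 1] <- (1 - alpha) * g + alpha * hr
  out[, , 2] <- (1 - alpha) * g + alpha * hg
  out[, , 3] <- (1 - alpha) * g + alpha * hb
  out
}

#' Read / write scalar volumes as NIfTI
#'
#' @param path `.nii` or `.nii.gz` path.
#' @param modality,id Labels attached to the volume on read.
#' @return [read_volume()]: a [scalar_volume()].
#' @export
read_volume <- function(path, modality = "MRgluc", id = basename(path)) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  scalar_volume(arr, spacing_mm = RNifti::pixdim(img)[1:3],
                modality = modality, id = id)
}

#' @rdname read_volume
#' @param volume A [scalar_volume()].
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a MIP as 16-bit PNG with a JSON value scale
#'
#' The projection is linearly rescaled to the 16-bit range; the scale
#' (`value_min`, `value_max`) is recorded in a JSON sidecar so values can be
#' recovered.
#'
#' @param mip_img A `mip_image`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mip <- function(mip_img, path) {
  img <- mip_img$data
  r <- range(img)
  scaled <- if (diff(r) == 0) matrix(0, nrow(img), ncol(img)) else
    round((img - r[1]) / diff(r) * 65535)
  write_png_gray16(scaled, path)
  sidecar <- sub("\\.png$", ".json", path)
  jsonlite::write_json(list(value_min = r[1], value_max = r[2],
                            modality = mip_img$modality,
                            source_id = mip_img$source_id),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
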