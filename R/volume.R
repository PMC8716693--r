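# Volumetric containers and spatial preprocessing.
#
# A `volume_image` is a plain 3D numeric array plus per-axis voxel
# spacing in mm and a physical origin (the position of the centre of
# voxel [1,1,1]). A `binary_mask` is a `volume_image` whose values are
# exactly {0,1}. Physical coordinates follow the voxel-centre
# convention: voxel i (0-based) sits at origin + i * spacing.

#' Construct a volumetric image
#'
#' @param data 3D numeric array of intensities (finite values).
#' @param spacing numeric length-3, voxel size in mm per axis (> 0).
#' @param origin numeric length-3, physical position (mm) of the centre
#'   of the first voxel.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    ratbex_error("ratbex_not_3d", "`data` must be a 3D array")
  if (any(dim(data) < 1L))
    ratbex_error("ratbex_bad_geometry", "every dimension must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    ratbex_error("ratbex_bad_geometry", "spacing must be 3 positive values (mm)")
  if (!all(is.finite(data)))
    ratbex_error("ratbex_bad_intensity", "intensities must be finite")
  structure(list(data = data, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "volume_image")
}

#' Construct a binary mask
#'
#' @inheritParams volume_image
#' @return An object of class `binary_mask` (also a `volume_image`).
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  v <- volume_image(data, spacing, origin)
  if (!all(v$data %in% c(0, 1)))
    ratbex_error("ratbex_not_binary", "mask values must be exactly 0 or 1")
  class(v) <- c("binary_mask", "volume_image")
  v
}

is_binary_mask <- function(x) inherits(x, "binary_mask")

#' @export
print.volume_image <- function(x, ...) {
  kind <- if (is_binary_mask(x)) "binary_mask" else "volume_image"
  cat(sprintf("<%s> %s voxels @ %s mm\n", kind,
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Read a 3D NIfTI volume
#'
#' Reads a NIfTI-1 file (`.nii` or `.nii.gz`) into a [volume_image()],
#' taking voxel spacing from the header `pixdim` and the origin from the
#' stored affine. The image is never reoriented.
#'
#' @param path path to a NIfTI-1 file.
#' @param mask logical; if `TRUE` the file is validated and returned as
#'   a [binary_mask()].
#' @return A `volume_image` (or `binary_mask` when `mask = TRUE`).
#' @export
read_volume <- function(path, mask = FALSE) {
  if (!file.exists(path))
    ratbex_error("ratbex_missing_file", sprintf("file not found: %s", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    ratbex_error("ratbex_corrupt_nifti",
                                 sprintf("cannot read NIfTI file %s: %s",
                                         path, conditionMessage(e))))
  arr <- array(as.numeric(img), dim(img))
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    ratbex_error("ratbex_not_3d",
                 sprintf("not a 3D volume: %s has rank %d", path,
                         length(dim(arr))))
  spacing <- RNifti::pixdim(img)[1:3]
  origin <- tryCatch(as.numeric(RNifti::xform(img)[1:3, 4]),
                     error = function(e) c(0, 0, 0))
  if (mask) binary_mask(arr, spacing, origin)
  else volume_image(arr, spacing, origin)
}

#' Write a volume or mask to NIfTI
#'
#' Masks are stored with an integer datatype, images as 32-bit float.
#'
#' @param v a [volume_image()] or [binary_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "volume_image"))
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  dt <- if (is_binary_mask(v)) "uint8" else "float"
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Nearest-neighbour resampling to a target voxel spacing
#'
#' Output grid size per axis is `round(size * spacing / target)`; each
#' output voxel takes the value of the input voxel whose centre is
#' nearest in physical space. Binary masks stay binary because values
#' are copied, never interpolated.
#'
#' @param v a [volume_image()] or [binary_mask()].
#' @param target_spacing numeric length-3 target voxel size in mm.
#' @return Resampled object of the same class as `v`.
#' @export
resample_nn <- function(v, target_spacing) {
  stopifnot(inherits(v, "volume_image"))
  ts <- as.numeric(target_spacing)
  if (length(ts) == 1L) ts <- rep(ts, 3L)
  if (length(ts) != 3L || any(!is.finite(ts)) || any(ts <= 0))
    ratbex_error("ratbex_bad_geometry", "target spacing must be 3 positive values")
  out_size <- as.integer(floor(dim(v$data) * v$spacing / ts + 0.5))
  resample_nn_to(v, ts, out_size)
}

# Resample to an explicit target geometry (spacing + grid size). Used
# internally to restore a mask to the exact native grid of a raw image.
resample_nn_to <- function(v, target_spacing, out_size) {
  out_size <- as.integer(out_size)
  if (any(out_size < 1L))
    ratbex_error("ratbex_degenerate_grid",
                 "resampling target produces an empty grid")
  in_size <- dim(v$data)
  idx <- lapply(1:3, function(ax) {
    # physical coord of output voxel j (0-based): j * ts; nearest input
    # voxel: floor(coord / spacing + 0.5), clamped to the grid.
    j <- seq_len(out_size[ax]) - 1
    i <- floor(j * target_spacing[ax] / v$spacing[ax] + 0.5)
    pmin(pmax(i, 0), in_size[ax] - 1) + 1L
  })
  out <- v$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  dim(out) <- out_size
  if (is_binary_mask(v)) binary_mask(out, target_spacing, v$origin)
  else volume_image(out, target_spacing, v$origin)
}

#' Min-max intensity normalisation
#'
#' Linearly maps intensities to `[0, 1]`. Constant images cannot be
#' normalised and raise an error.
#'
#' @param v a [volume_image()].
#' @return A `volume_image` with intensities in `[0, 1]`.
#' @export
normalize_intensity <- function(v) {
  stopifnot(inherits(v, "volume_image"))
  r <- range(v$data)
  if (r[1] == r[2])
    ratbex_error("ratbex_constant_image",
                 "cannot normalise a constant image (max == min)")
  volume_image((v$data - r[1]) / (r[2] - r[1]), v$spacing, v$origin)
}

#' Threshold a probability map into a binary mask
#'
#' A voxel is labelled 1 iff its probability is strictly greater than
#' `threshold`; geometry is preserved.
#'
#' @param prob a [volume_image()] with values in `[0, 1]`.
#' @param threshold scalar in `[0, 1)`.
#' @return A [binary_mask()].
#' @export
binarize <- function(prob, threshold = 0.5) {
  stopifnot(inherits(prob, "volume_image"))
  if (length(threshold) != 1L || !is.finite(threshold) ||
      threshold < 0 || threshold >= 1)
    ratbex_error("ratbex_bad_threshold", "threshold must lie in [0, 1)")
  if (min(prob$data) < 0 || max(prob$data) > 1)
    ratbex_error("ratbex_bad_intensity", "probabilities must lie in [0, 1]")
  binary_mask(array(as.numeric(prob$data > threshold), dim(prob$data)),
              prob$spacing, prob$origin)
}
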