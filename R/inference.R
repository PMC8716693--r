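# Whole-volume prediction: overlapped patch tiling with probability
# averaging, and the full raw-resolution brain-extraction pipeline.

#' Plan a sliding-window patch grid
#'
#' Per axis the offsets are `0, stride, 2*stride, ...` plus a final
#' clamped offset `size - patch` so the tiles cover every voxel without
#' leaving the volume; the full grid is the Cartesian product across
#' axes in lexicographic order.
#'
#' @param volume_shape integer grid size per axis.
#' @param patch_shape integer patch size per axis (<= volume_shape).
#' @param stride integer step per axis (>= 1); a scalar is recycled.
#' @return An object of class `patch_grid` with 0-based `offsets` (one
#'   row per patch).
#' @export
plan_patch_grid <- function(volume_shape, patch_shape, stride) {
  volume_shape <- as.integer(volume_shape)
  patch_shape <- as.integer(patch_shape)
  nd <- length(patch_shape)
  stride <- as.integer(stride)
  if (length(stride) == 1L) stride <- rep(stride, nd)
  if (any(stride < 1L))
    ratbex_error("ratbex_bad_config", "stride must be >= 1")
  if (length(volume_shape) < nd)
    ratbex_error("ratbex_shape_mismatch", "volume rank below patch rank")
  vs <- volume_shape[seq_len(nd)]
  if (any(vs < patch_shape))
    ratbex_error("ratbex_volume_too_small",
                 "volume smaller than patch; resample to a finer grid first")
  axes <- lapply(seq_len(nd), function(ax) {
    off <- seq.int(0L, vs[ax] - patch_shape[ax], by = stride[ax])
    tail_off <- vs[ax] - patch_shape[ax]
    if (off[length(off)] != tail_off) off <- c(off, tail_off)
    off
  })
  grid <- as.matrix(do.call(expand.grid, rev(axes)))[, rev(seq_len(nd)),
                                                     drop = FALSE]
  dimnames(grid) <- NULL
  structure(list(volume_shape = volume_shape, patch_shape = patch_shape,
                 stride = stride, offsets = grid),
            class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("<patch_grid> %d patches of %s over %s (stride %s)\n",
              nrow(x$offsets), paste(x$patch_shape, collapse = "x"),
              paste(x$volume_shape, collapse = "x"),
              paste(x$stride, collapse = "x")))
  invisible(x)
}

#' Predict a whole volume by overlap-averaged patch inference
#'
#' Every patch of the grid is pushed through the network; each voxel's
#' probability is the arithmetic mean of the predictions of all patches
#' covering it (running sum divided by coverage count).
#'
#' For a 2D model the grid is applied slice-by-slice along the third
#' axis.
#'
#' @param model a [build_unet()] (or trained) model.
#' @param v a normalised [volume_image()].
#' @param grid a [plan_patch_grid()] for `dim(v$data)`; default uses a
#'   stride of a quarter patch.
#' @param batch_size patches evaluated per network call.
#' @return A probability [volume_image()] with values in `[0, 1]`.
#' @export
predict_volume <- function(model, v, grid = NULL,
                           batch_size = 16L) {
  stopifnot(inherits(model, "unet_model"), inherits(v, "volume_image"))
  ps <- model$config$patch_shape
  nd <- model$config$dimensionality
  if (is.null(grid))
    grid <- plan_patch_grid(dim(v$data), ps, pmax(ps %/% 4L, 1L))
  if (!identical(as.integer(grid$volume_shape[seq_len(nd)]),
                 as.integer(dim(v$data)[seq_len(nd)])) ||
      !identical(as.integer(grid$patch_shape), as.integer(ps)))
    ratbex_error("ratbex_shape_mismatch",
                 "grid was not planned for this volume/model")
  sz <- dim(v$data)
  acc <- array(0, sz)
  cnt <- array(0, sz)
  offs <- grid$offsets
  slices <- if (nd == 3L) 1L else seq_len(sz[3])
  for (sl in slices) {
    for (start in seq.int(1L, nrow(offs), by = batch_size)) {
      rows <- start:min(start + batch_size - 1L, nrow(offs))
      patches <- lapply(rows, function(r) {
        o <- offs[r, ]
        if (nd == 3L)
          v$data[o[1] + seq_len(ps[1]), o[2] + seq_len(ps[2]),
                 o[3] + seq_len(ps[3])]
        else
          v$data[o[1] + seq_len(ps[1]), o[2] + seq_len(ps[2]), sl]
      })
      X <- matrix(unlist(lapply(patches, as.numeric)), nrow = 1)
      prob <- unet_forward_mat(model, X, length(rows), training = FALSE)
      pn <- prod(ps)
      for (k in seq_along(rows)) {
        o <- offs[rows[k], ]
        pk <- prob[(k - 1) * pn + seq_len(pn)]
        if (nd == 3L) {
          ix <- o[1] + seq_len(ps[1]); iy <- o[2] + seq_len(ps[2])
          iz <- o[3] + seq_len(ps[3])
          acc[ix, iy, iz] <- acc[ix, iy, iz] + pk
          cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
        } else {
          ix <- o[1] + seq_len(ps[1]); iy <- o[2] + seq_len(ps[2])
          acc[ix, iy, sl] <- acc[ix, iy, sl] + pk
          cnt[ix, iy, sl] <- cnt[ix, iy, sl] + 1
        }
      }
    }
  }
  if (any(cnt == 0))
    ratbex_error("ratbex_coverage_gap", "patch grid left voxels uncovered")
  volume_image(acc / cnt, v$spacing, v$origin)
}

#' Extract the brain from a raw volume
#'
#' The full pipeline: min-max normalisation, nearest-neighbour
#' resampling to the working spacing (0.2 mm isotropic by default),
#' overlap-averaged sliding-window prediction, thresholding at the
#' working resolution, and nearest-neighbour resampling of the binary
#' mask back onto the exact native grid. If the resampled volume is
#' smaller than the patch along any axis, the working spacing is
#' halved until the patch fits.
#'
#' @param model a trained model.
#' @param raw the raw [volume_image()] (any spacing).
#' @param working_spacing isotropic working voxel size in mm.
#' @param stride inference stride (default: quarter patch).
#' @param threshold binarisation threshold in `[0, 1)`.
#' @param batch_size patches per network call.
#' @return A [binary_mask()] on the native grid of `raw`.
#' @export
extract_brain <- function(model, raw, working_spacing = c(0.2, 0.2, 0.2),
                          stride = NULL, threshold = 0.5, batch_size = 16L) {
  stopifnot(inherits(model, "unet_model"), inherits(raw, "volume_image"))
  ps <- model$config$patch_shape
  nd <- model$config$dimensionality
  ws <- as.numeric(working_spacing)
  if (length(ws) == 1L) ws <- rep(ws, 3L)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      ratbex_error("ratbex_stage_failure",
                   sprintf("[%s] %s", what, conditionMessage(e)))
    })
  }
  norm <- stage("normalize", normalize_intensity(raw))
  work <- stage("resample", {
    w <- resample_nn(norm, ws)
    check_axes <- if (nd == 3L) 1:3 else 1:2
    while (any(dim(w$data)[check_axes] < ps)) {
      ws <- ws / 2
      w <- resample_nn(norm, ws)
    }
    w
  })
  stride <- stride %||% pmax(ps %/% 4L, 1L)
  prob <- stage("predict", {
    grid <- plan_patch_grid(dim(work$data), ps, stride)
    predict_volume(model, work, grid, batch_size)
  })
  mask_work <- stage("binarize", binarize(prob, threshold))
  stage("restore-resolution",
        resample_nn_to(mask_work, raw$spacing, dim(raw$data)))
}
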