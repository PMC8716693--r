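# Segmentation evaluation metrics.
#
# Conventions: A is the ground-truth (manually delineated) voxel set,
# B the predicted voxel set. Overlap scores are unitless fractions;
# distances are physical mm. The Hausdorff distance is evaluated
# in-plane (per slice along the acquisition axis) and the worst slice
# is reported.

#' Voxelwise confusion counts between two masks
#'
#' @param truth,pred [binary_mask()]s sharing geometry.
#' @return A list of class `confusion_counts` with fields `TP`, `FP`,
#'   `FN`, `TN`.
#' @export
confusion <- function(truth, pred) {
  stopifnot(is_binary_mask(truth), is_binary_mask(pred))
  if (!same_geometry(truth, pred))
    ratbex_error("ratbex_geometry_mismatch",
                 "truth and prediction must share grid size and spacing")
  a <- truth$data > 0.5
  b <- pred$data > 0.5
  tp <- sum(a & b)
  structure(list(TP = tp, FP = sum(b) - tp, FN = sum(a) - tp,
                 TN = sum(!a & !b)),
            class = "confusion_counts")
}

#' Overlap metrics from confusion counts
#'
#' Dice = 2TP/(2TP+FP+FN), Jaccard = TP/(TP+FP+FN), PPV = TP/|B|,
#' SEN = TP/|A|. A metric whose denominator is zero is returned as `NA`
#' with the reason recorded in the `notes` element.
#'
#' @param counts a [confusion()] result.
#' @return A list with `dice`, `jaccard`, `ppv`, `sen` and `notes`.
#' @export
overlap_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN
  notes <- character()
  safe <- function(num, den, what) {
    if (den == 0) {
      notes <<- c(notes, sprintf("%s undefined: empty denominator", what))
      NA_real_
    } else num / den
  }
  list(dice = safe(2 * tp, 2 * tp + fp + fn, "dice"),
       jaccard = safe(tp, tp + fp + fn, "jaccard"),
       ppv = safe(tp, tp + fp, "ppv"),
       sen = safe(tp, tp + fn, "sen"),
       notes = notes)
}

# Physical-space (mm) coordinates of mask voxels. `axes` restricts to a
# subset of axes (e.g. in-plane).
mask_coords_mm <- function(mask, axes = 1:3) {
  idx <- which(mask$data > 0.5, arr.ind = TRUE)
  sweep(sweep((idx - 1)[, axes, drop = FALSE], 2, mask$spacing[axes], `*`),
        2, mask$origin[axes], `+`)
}

#' Centre-of-mass distance between two masks
#'
#' Euclidean distance in mm between the physical-space centroids of the
#' two voxel sets.
#'
#' @inheritParams confusion
#' @return Distance in mm.
#' @export
center_of_mass_distance <- function(truth, pred) {
  stopifnot(is_binary_mask(truth), is_binary_mask(pred))
  if (!same_geometry(truth, pred))
    ratbex_error("ratbex_geometry_mismatch", "masks must share geometry")
  if (sum(truth$data) == 0 || sum(pred$data) == 0)
    ratbex_error("ratbex_empty_mask",
                 "centre of mass is undefined for an empty mask")
  ca <- colMeans(mask_coords_mm(truth))
  cb <- colMeans(mask_coords_mm(pred))
  sqrt(sum((ca - cb)^2))
}

# Directed Hausdorff h(A,B) = max over a of min over b of d(a, b).
# Squared distances use explicit coordinate differences so identical
# points give exactly zero.
directed_hausdorff <- function(a, b) {
  d2 <- outer(a[, 1], b[, 1], `-`)^2
  for (k in seq_len(ncol(a))[-1])
    d2 <- d2 + outer(a[, k], b[, k], `-`)^2
  mins <- d2[cbind(seq_len(nrow(d2)), max.col(-d2, ties.method = "first"))]
  sqrt(max(mins))
}

#' Symmetric Hausdorff distance between two 2D point sets
#'
#' `max(h(A,B), h(B,A))` with `h` the directed max-min Euclidean
#' distance, computed in physical mm.
#'
#' @param a,b numeric matrices (points in rows, coordinates in mm).
#' @return Distance in mm.
#' @export
hausdorff_2d <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) == 0 || nrow(b) == 0)
    ratbex_error("ratbex_empty_mask", "Hausdorff undefined for empty point sets")
  max(directed_hausdorff(a, b), directed_hausdorff(b, a))
}

#' Worst-slice in-plane Hausdorff distance between two masks
#'
#' The 2D Hausdorff distance is evaluated on the voxel sets of each
#' slice perpendicular to `slice_axis`, and the maximum over slices is
#' returned. Slices where either mask is empty carry no matching
#' information and are skipped.
#'
#' @inheritParams confusion
#' @param slice_axis axis along which slices are taken (default 3, the
#'   stored through-plane axis).
#' @return Distance in mm.
#' @export
hausdorff_inplane_max <- function(truth, pred, slice_axis = 3L) {
  stopifnot(is_binary_mask(truth), is_binary_mask(pred))
  if (!same_geometry(truth, pred))
    ratbex_error("ratbex_geometry_mismatch", "masks must share geometry")
  inplane <- setdiff(1:3, slice_axis)
  n_slices <- dim(truth$data)[slice_axis]
  best <- -Inf
  for (s in seq_len(n_slices)) {
    sl <- function(m) {
      d <- switch(slice_axis,
                  m$data[s, , , drop = FALSE],
                  m$data[, s, , drop = FALSE],
                  m$data[, , s, drop = FALSE])
      idx <- which(array(d, dim(d)) > 0.5, arr.ind = TRUE)[, inplane, drop = FALSE]
      sweep(sweep(idx - 1, 2, m$spacing[inplane], `*`),
            2, m$origin[inplane], `+`)
    }
    pa <- sl(truth); pb <- sl(pred)
    if (nrow(pa) == 0 || nrow(pb) == 0) next
    best <- max(best, hausdorff_2d(pa, pb))
  }
  if (!is.finite(best))
    ratbex_error("ratbex_empty_mask",
                 "no slice where both masks are non-empty")
  best
}

#' Specify a spherical volume of interest
#'
#' @param center physical mm coordinates of the sphere centre.
#' @param diameter sphere diameter in mm (default 1).
#' @param role `"signal"` or `"background"`.
#' @return A list of class `voi_spec`.
#' @export
voi_spec <- function(center, diameter = 1, role = c("signal", "background")) {
  role <- match.arg(role)
  if (diameter <= 0) ratbex_error("ratbex_bad_spec", "diameter must be > 0")
  structure(list(center = as.numeric(center), diameter = diameter, role = role),
            class = "voi_spec")
}

voi_values <- function(v, voi) {
  r <- voi$diameter / 2
  lo <- voi$center - r; hi <- voi$center + r
  ext_lo <- v$origin - v$spacing / 2
  ext_hi <- v$origin + (dim(v$data) - 0.5) * v$spacing
  if (any(lo < ext_lo) || any(hi > ext_hi))
    ratbex_error("ratbex_voi_out_of_bounds", "VOI sphere exceeds the volume")
  ax <- lapply(1:3, function(k) v$origin[k] + (seq_len(dim(v$data)[k]) - 1) * v$spacing[k])
  d2 <- outer(outer((ax[[1]] - voi$center[1])^2,
                    (ax[[2]] - voi$center[2])^2, `+`),
              (ax[[3]] - voi$center[3])^2, `+`)
  v$data[d2 <= r^2]
}

#' Estimate image SNR from spherical VOIs
#'
#' SNR = mean intensity over the signal spheres divided by the standard
#' deviation of intensity over the background spheres (noise estimate).
#'
#' @param v a [volume_image()].
#' @param signal_vois,background_vois lists of [voi_spec()]s (typically
#'   two of each: bilateral signal spheres and two background spheres).
#' @return Unitless SNR.
#' @export
estimate_snr <- function(v, signal_vois, background_vois) {
  stopifnot(inherits(v, "volume_image"))
  if (inherits(signal_vois, "voi_spec")) signal_vois <- list(signal_vois)
  if (inherits(background_vois, "voi_spec")) background_vois <- list(background_vois)
  sig <- unlist(lapply(signal_vois, function(s) voi_values(v, s)))
  bg <- unlist(lapply(background_vois, function(s) voi_values(v, s)))
  s <- sd(bg)
  if (!is.finite(s) || s == 0)
    ratbex_error("ratbex_zero_background_sd",
                 "background VOIs have zero intensity variation")
  mean(sig) / s
}

#' Default SNR VOIs for a phantom volume
#'
#' Two 1 mm signal spheres placed bilaterally at the volume centre
#' (inside the brain, emulating striatal VOIs) and two 1 mm background
#' spheres near opposite corners, outside the head.
#'
#' @param v a [volume_image()] (or a `phantom_pair`).
#' @param diameter sphere diameter in mm.
#' @return List with elements `signal` and `background`.
#' @export
snr_vois <- function(v, diameter = 1) {
  if (inherits(v, "phantom_pair")) v <- v$image
  ctr <- v$origin + (dim(v$data) - 1) * v$spacing / 2
  off <- c(1.5, 0, 0)
  corner <- function(sgn) {
    xy <- if (sgn > 0) (dim(v$data)[1:2] - 1) * v$spacing[1:2] - 1 else c(1, 1)
    c(v$origin[1:2] + xy, ctr[3])
  }
  list(signal = list(voi_spec(ctr + off, diameter, "signal"),
                     voi_spec(ctr - off, diameter, "signal")),
       background = list(voi_spec(corner(-1), diameter, "background"),
                         voi_spec(corner(+1), diameter, "background")))
}

#' Full metric report for a mask pair
#'
#' @inheritParams confusion
#' @param slice_axis passed to [hausdorff_inplane_max()].
#' @return A one-row `data.frame` with columns `dice`, `jaccard`,
#'   `ppv`, `sen`, `cmd_mm`, `hausdorff_mm`.
#' @export
metric_report <- function(truth, pred, slice_axis = 3L) {
  om <- overlap_metrics(confusion(truth, pred))
  cmd <- tryCatch(center_of_mass_distance(truth, pred),
                  ratbex_empty_mask = function(e) NA_real_)
  hd <- tryCatch(hausdorff_inplane_max(truth, pred, slice_axis),
                 ratbex_empty_mask = function(e) NA_real_)
  data.frame(dice = om$dice, jaccard = om$jaccard, ppv = om$ppv,
             sen = om$sen, cmd_mm = cmd, hausdorff_mm = hd)
}
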