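# Evaluation metrics against hand-enumerable and brute-force oracles.

mk_mask <- function(idx_ones, dims, spacing = rep(0.2, 3)) {
  a <- array(0, dims)
  a[idx_ones] <- 1
  binary_mask(a, spacing)
}

test_that("confusion counts match hand-built grids", {
  # |A| = 4, |B| = 6, overlap 3 on a 4x4x1 grid
  truth <- mk_mask(c(1, 2, 3, 4), c(4, 4, 1))
  pred <- mk_mask(c(2, 3, 4, 5, 6, 7), c(4, 4, 1))
  cc <- confusion(truth, pred)
  expect_identical(cc[c("TP", "FP", "FN", "TN")],
                   list(TP = 3L, FP = 3L, FN = 1L, TN = 9L))
  om <- overlap_metrics(cc)
  expect_equal(om$dice, 0.6)
  expect_equal(om$jaccard, 3 / 7)
  expect_equal(om$ppv, 0.5)
  expect_equal(om$sen, 0.75)

  ident <- confusion(truth, truth)
  expect_identical(ident$FP + ident$FN, 0L)
  omi <- overlap_metrics(ident)
  expect_equal(unlist(omi[c("dice", "jaccard", "ppv", "sen")]),
               c(dice = 1, jaccard = 1, ppv = 1, sen = 1))

  disj <- overlap_metrics(confusion(mk_mask(1:2, c(4, 4, 1)),
                                    mk_mask(9:10, c(4, 4, 1))))
  expect_equal(unlist(disj[c("dice", "jaccard", "ppv", "sen")]),
               c(dice = 0, jaccard = 0, ppv = 0, sen = 0))

  empty <- overlap_metrics(confusion(mk_mask(integer(0), c(2, 2, 2)),
                                     mk_mask(1, c(2, 2, 2))))
  expect_true(is.na(empty$sen))
  expect_true(length(empty$notes) > 0)

  expect_error(confusion(mk_mask(1, c(2, 2, 2)), mk_mask(1, c(2, 2, 3))),
               class = "ratbex_geometry_mismatch")
})

test_that("centre-of-mass distance uses physical coordinates", {
  a <- mk_mask(cbind(2, 2, 1), c(10, 4, 2))
  b <- mk_mask(cbind(7, 2, 1), c(10, 4, 2))  # 5 voxels apart along x
  expect_equal(center_of_mass_distance(a, b), 1.0)
  expect_equal(center_of_mass_distance(a, a), 0)

  set.seed(3)
  core <- array(rbinom(6 * 6 * 6, 1, 0.5), c(6, 6, 6))
  big <- array(0, c(10, 10, 10)); big[1:6, 1:6, 1:6] <- core
  shifted <- array(0, c(10, 10, 10)); shifted[2:7, 3:8, 3:8] <- core
  expect_equal(center_of_mass_distance(
    binary_mask(big, rep(0.2, 3)), binary_mask(shifted, rep(0.2, 3))),
    sqrt(0.2^2 + 0.4^2 + 0.4^2))

  expect_error(center_of_mass_distance(mk_mask(integer(0), c(2, 2, 2)),
                                       mk_mask(1, c(2, 2, 2))),
               class = "ratbex_empty_mask")
})

brute_hausdorff <- function(a, b) {
  h <- function(p, q) {
    worst <- 0
    for (i in seq_len(nrow(p))) {
      best <- Inf
      for (j in seq_len(nrow(q)))
        best <- min(best, sqrt(sum((p[i, ] - q[j, ])^2)))
      worst <- max(worst, best)
    }
    worst
  }
  max(h(a, b), h(b, a))
}

test_that("hausdorff_2d matches the all-pairs brute-force oracle", {
  expect_equal(hausdorff_2d(matrix(c(0, 0), 1), matrix(c(3, 4), 1)), 5)
  a <- matrix(runif(10), 5)
  expect_equal(hausdorff_2d(a, a), 0)
  set.seed(77)
  for (k in 1:30) {
    a <- matrix(runif(2 * sample(2:50, 1), 0, 10), ncol = 2)
    b <- matrix(runif(2 * sample(2:50, 1), 0, 10), ncol = 2)
    expect_equal(hausdorff_2d(a, b), brute_hausdorff(a, b),
                 tolerance = 1e-12)
  }
  expect_error(hausdorff_2d(matrix(0, 0, 2), matrix(0, 1, 2)),
               class = "ratbex_empty_mask")
})

test_that("in-plane Hausdorff takes the worst slice and skips half-empty slices", {
  expect_equal(hausdorff_inplane_max(mk_mask(1:4, c(4, 4, 2)),
                                     mk_mask(1:4, c(4, 4, 2))), 0)
  # slice 1: single points 1 voxel apart (0.2 mm); slice 2: 15 voxels (3 mm)
  dims <- c(16, 4, 2)
  truth <- mk_mask(rbind(c(1, 1, 1), c(1, 1, 2)), dims)
  pred <- mk_mask(rbind(c(2, 1, 1), c(16, 1, 2)), dims)
  expect_equal(hausdorff_inplane_max(truth, pred), 3.0)
  # an empty-prediction slice is skipped, not infinite
  pred2 <- mk_mask(rbind(c(2, 1, 1)), dims)
  expect_equal(hausdorff_inplane_max(truth, pred2), 0.2)
  expect_error(hausdorff_inplane_max(truth, mk_mask(integer(0), dims)),
               class = "ratbex_empty_mask")
})

test_that("jaccard = dice/(2 - dice) and symmetry properties fuzz-hold", {
  set.seed(123)
  for (k in 1:40) {
    dims <- c(sample(3:8, 1), sample(3:8, 1), sample(2:5, 1))
    a <- binary_mask(array(rbinom(prod(dims), 1, runif(1, 0.2, 0.8)), dims),
                     rep(0.2, 3))
    b <- binary_mask(array(rbinom(prod(dims), 1, runif(1, 0.2, 0.8)), dims),
                     rep(0.2, 3))
    ab <- overlap_metrics(confusion(a, b))
    ba <- overlap_metrics(confusion(b, a))
    if (!is.na(ab$dice) && !is.na(ab$jaccard))
      expect_equal(ab$jaccard, ab$dice / (2 - ab$dice), tolerance = 1e-12)
    expect_equal(ab$dice, ba$dice, tolerance = 1e-12)
    expect_equal(ab$jaccard, ba$jaccard, tolerance = 1e-12)
    if (!is.na(ab$ppv)) expect_equal(ab$ppv, ba$sen, tolerance = 1e-12)
  }
})

test_that("distances scale linearly with voxel spacing", {
  set.seed(11)
  dims <- c(8, 8, 4)
  a_idx <- array(rbinom(prod(dims), 1, 0.4), dims)
  b_idx <- array(rbinom(prod(dims), 1, 0.4), dims)
  a1 <- binary_mask(a_idx, rep(0.2, 3)); b1 <- binary_mask(b_idx, rep(0.2, 3))
  a2 <- binary_mask(a_idx, rep(0.4, 3)); b2 <- binary_mask(b_idx, rep(0.4, 3))
  expect_equal(center_of_mass_distance(a2, b2),
               2 * center_of_mass_distance(a1, b1), tolerance = 1e-12)
  expect_equal(hausdorff_inplane_max(a2, b2),
               2 * hausdorff_inplane_max(a1, b1), tolerance = 1e-12)
})

test_that("SNR estimation recovers constructed signal-to-noise ratios", {
  dims <- c(32, 32, 32)
  spacing <- rep(0.2, 3)
  # deterministic +/- s background pattern, signal plateau at 26 * s
  s <- 0.03
  parity <- (outer(outer(1:dims[1], 1:dims[2], `+`), 1:dims[3], `+`)) %% 2
  vals <- array(s * ifelse(parity == 1, 1, -1), dims)
  ctr <- (dims - 1) * spacing / 2
  sig_idx <- ratbex:::ellipsoid_r2(
    ratbex:::centered_axes(dims, spacing), c(1.2, 1.2, 1.2)) <= 1
  vals[sig_idx] <- 26 * s
  v <- volume_image(vals, spacing)
  vois <- list(signal = list(voi_spec(ctr + c(0.5, 0, 0), 1, "signal"),
                             voi_spec(ctr - c(0.5, 0, 0), 1, "signal")),
               background = list(voi_spec(c(1, 1, ctr[3]), 1, "background"),
                                 voi_spec(c(5.4 - 1, 5.4 - 1, ctr[3]), 1,
                                          "background")))
  snr <- estimate_snr(v, vois$signal, vois$background)
  expect_equal(snr, 26, tolerance = 0.05)

  # Monte-Carlo: mean mu over background noise sd sigma
  set.seed(42)
  noise <- array(rnorm(prod(dims), 0, 0.02), dims)
  noise[sig_idx] <- noise[sig_idx] + 0.8
  v2 <- volume_image(noise, spacing)
  expect_equal(estimate_snr(v2, vois$signal, vois$background), 0.8 / 0.02,
               tolerance = 0.25)

  # doubling all intensities doubles signal and noise alike
  v3 <- volume_image(2 * vals, spacing)
  expect_equal(estimate_snr(v3, vois$signal, vois$background), snr,
               tolerance = 1e-9)
  # with the background noise held fixed, doubling the signal doubles SNR
  vals4 <- vals; vals4[sig_idx] <- 2 * vals[sig_idx]
  v4 <- volume_image(vals4, spacing)
  expect_equal(estimate_snr(v4, vois$signal, vois$background), 2 * snr,
               tolerance = 1e-9)

  expect_error(estimate_snr(v, vois$signal,
                            list(voi_spec(c(0, 0, 0), 1, "background"))),
               class = "ratbex_voi_out_of_bounds")
  flat <- volume_image(array(1, dims), spacing)
  expect_error(estimate_snr(flat, vois$signal, vois$background),
               class = "ratbex_zero_background_sd")
})

test_that("metric_report assembles all six metrics", {
  pair <- generate_phantom(tiny_phantom_spec(seed = 2))
  rep <- metric_report(pair$truth, pair$truth)
  expect_identical(names(rep),
                   c("dice", "jaccard", "ppv", "sen", "cmd_mm",
                     "hausdorff_mm"))
  expect_equal(unlist(rep), c(dice = 1, jaccard = 1, ppv = 1, sen = 1,
                              cmd_mm = 0, hausdorff_mm = 0))
})
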