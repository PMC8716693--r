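# Robustness harnesses: additive-noise sweep (SNR vs segmentation
# accuracy) and training-sample-size sweep (learning curve), both
# runnable at desk scale on phantom cohorts.

#' Default additive-noise variance ladder
#'
#' Ten levels from 5e-5 to 5e-4 in steps of 5e-5, on the normalised
#' intensity scale.
#' @return Numeric vector of variances.
#' @export
noise_variance_ladder <- function() seq(5e-5, 5e-4, by = 5e-5)

std_err <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_

#' Gaussian-noise robustness sweep
#'
#' For every variance level and test subject: add independent Gaussian
#' white noise to the normalised image, estimate SNR from the VOIs,
#' run brain extraction, and score Dice against the truth mask. Noise
#' draws are independent per image and per level, and the whole sweep
#' is deterministic given `seed`.
#'
#' @param model a trained model.
#' @param test_pairs list of `image`/`truth` pairs with normalised
#'   images (e.g. phantoms).
#' @param variances noise variance ladder; a leading 0 scores the clean
#'   images.
#' @param vois optional list as returned by [snr_vois()]; default is
#'   placed automatically per volume.
#' @param seed integer seed.
#' @param stride,threshold,batch_size passed to [extract_brain()].
#' @return A list of class `noise_sweep` with `per_subject` (one row
#'   per level x subject) and `summary` (per-level mean and standard
#'   error of SNR and Dice, SE across subjects).
#' @export
run_noise_sweep <- function(model, test_pairs,
                            variances = noise_variance_ladder(),
                            vois = NULL, seed = 1L, stride = NULL,
                            threshold = 0.5, batch_size = 16L) {
  if (length(test_pairs) == 0)
    ratbex_error("ratbex_empty_split", "test set must be non-empty")
  if (is.unsorted(variances))
    ratbex_error("ratbex_bad_config", "variance ladder must be increasing")
  rows <- list()
  for (li in seq_along(variances)) {
    v <- variances[li]
    for (si in seq_along(test_pairs)) {
      pr <- test_pairs[[si]]
      noisy <- add_gaussian_noise(pr$image, v,
                                  derive_seed(seed, li * 10000L + si))
      vv <- vois %||% snr_vois(noisy)
      snr <- estimate_snr(noisy, vv$signal, vv$background)
      pred <- extract_brain(model, noisy, working_spacing = pr$image$spacing,
                            stride = stride, threshold = threshold,
                            batch_size = batch_size)
      dice <- overlap_metrics(confusion(pr$truth, pred))$dice
      rows[[length(rows) + 1L]] <-
        data.frame(variance = v, subject = si, snr = snr, dice = dice)
    }
  }
  per_subject <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(per_subject, per_subject$variance),
    function(d) data.frame(variance = d$variance[1],
                           mean_snr = mean(d$snr), se_snr = std_err(d$snr),
                           mean_dice = mean(d$dice),
                           se_dice = std_err(d$dice))))
  summary <- summary[order(summary$variance), ]
  rownames(summary) <- NULL
  structure(list(per_subject = per_subject, summary = summary,
                 variances = variances, seed = seed),
            class = "noise_sweep")
}

#' Training-sample-size sweep (learning curve)
#'
#' For every combination of training-set size, validation-set size and
#' repeat: draw disjoint fit and validation subjects from the cohort
#' without replacement, train a fresh model from scratch, and score
#' mean whole-volume Dice on the held-out test set. Subject draws and
#' weight initialisations are deterministic given `seed`.
#'
#' @param cohort list of `image`/`truth` pairs to draw training data
#'   from (must not overlap the test set).
#' @param test_pairs held-out pairs used for the final Dice.
#' @param model_config a [unet_config()]; a fresh model is built per
#'   cell.
#' @param train_cfg a [train_config()].
#' @param train_ladder increasing training-set sizes.
#' @param val_sizes validation-set sizes.
#' @param repeats independent random selections per cell.
#' @param seed integer seed.
#' @param test_stride stride for test inference (default: the training
#'   validation stride).
#' @return A list of class `sample_size_sweep` with `results` (one row
#'   per n_train x n_val x repeat) and `summary` (per n_train x n_val
#'   mean and SE across repeats).
#' @export
run_sample_size_sweep <- function(cohort, test_pairs,
                                  model_config = unet_config_desk(),
                                  train_cfg = train_config(),
                                  train_ladder = c(2, 4, 6),
                                  val_sizes = 2, repeats = 2, seed = 1L,
                                  test_stride = NULL) {
  if (max(train_ladder) + max(val_sizes) > length(cohort))
    ratbex_error("ratbex_bad_config",
                 "cohort too small for the requested ladder + validation size")
  cid <- vapply(cohort, function(p) p$spec$subject_id %||% NA_integer_,
                1L)
  tid <- vapply(test_pairs, function(p) p$spec$subject_id %||% NA_integer_,
                1L)
  if (!all(is.na(cid)) && length(intersect(cid, tid)) > 0)
    ratbex_error("ratbex_leakage",
                 "cohort and test set share subjects")
  stride <- test_stride %||% train_cfg$val_stride %||% model_config$patch_shape
  rows <- list()
  cell <- 0L
  for (n_train in train_ladder) {
    for (n_val in val_sizes) {
      for (r in seq_len(repeats)) {
        cell <- cell + 1L
        cell_seed <- derive_seed(seed, cell)
        pick <- with_seed(cell_seed,
                          sample.int(length(cohort), n_train + n_val))
        fit <- cohort[pick[seq_len(n_train)]]
        val <- cohort[pick[n_train + seq_len(n_val)]]
        model <- build_unet(model_config, seed = derive_seed(cell_seed, 1L))
        cfg <- train_cfg
        cfg$seed <- derive_seed(cell_seed, 2L)
        fitres <- train_model(model, fit, val, cfg)
        test_dice <- validate_model(fitres$model, test_pairs, stride,
                                    train_cfg$threshold)$dice
        rows[[length(rows) + 1L]] <-
          data.frame(n_train = n_train, n_val = n_val, rep = r,
                     val_dice = fitres$best_val_dice, test_dice = test_dice)
      }
    }
  }
  results <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(
    split(results, interaction(results$n_train, results$n_val)),
    function(d) data.frame(n_train = d$n_train[1], n_val = d$n_val[1],
                           mean_test_dice = mean(d$test_dice),
                           se_test_dice = std_err(d$test_dice))))
  summary <- summary[order(summary$n_train, summary$n_val), ]
  rownames(summary) <- NULL
  structure(list(results = results, summary = summary, seed = seed),
            class = "sample_size_sweep")
}
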