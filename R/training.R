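# Dice-loss patch training: Adam, gradient-norm clipping, repeated
# 80/20 split protocol and best-validation model selection.

#' Training configuration
#'
#' Defaults follow the reference rodent protocol: Adam with initial
#' learning rate 1e-3, batch size 16, and all parameter gradients
#' clipped to a maximum global norm of 1.
#'
#' @param learning_rate Adam step size.
#' @param batch_size patches per optimisation step.
#' @param grad_clip_norm maximum global gradient norm.
#' @param patches_per_epoch random crops drawn per epoch (default
#'   `10 * number of fit subjects`).
#' @param max_epochs maximum training epochs.
#' @param early_stop_patience epochs without validation improvement
#'   before stopping.
#' @param loss_smooth soft-Dice smoothing constant.
#' @param val_stride stride for whole-volume validation inference
#'   (default: the patch shape, i.e. non-overlapping tiles, for speed).
#' @param threshold binarisation threshold for validation masks.
#' @param seed integer seed making the whole run reproducible.
#' @param verbose print per-epoch progress.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 16,
                         grad_clip_norm = 1, patches_per_epoch = NULL,
                         max_epochs = 15, early_stop_patience = 5,
                         loss_smooth = 1, val_stride = NULL,
                         threshold = 0.5, seed = 1L, verbose = FALSE) {
  if (learning_rate < 0 || batch_size < 1 || grad_clip_norm <= 0 ||
      max_epochs < 1 || early_stop_patience < 1 || loss_smooth <= 0)
    ratbex_error("ratbex_bad_config", "train_config values must be positive")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 grad_clip_norm = grad_clip_norm,
                 patches_per_epoch = patches_per_epoch,
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 loss_smooth = loss_smooth, val_stride = val_stride,
                 threshold = threshold, seed = seed, verbose = verbose),
            class = "train_config")
}

#' Repeated 80/20 train/validation/test split plan
#'
#' 20% of subjects (rounded up via `n - floor(0.8 n)`) are held out as
#' the test set, identical across repeats. The remaining pool is
#' re-partitioned `repeats` times into fit (`floor(0.8 * pool)`) and
#' validation subjects. With `n_subjects = 87` this yields the 18/55/14
#' test/fit/validation protocol.
#'
#' @param n_subjects cohort size (>= 5).
#' @param test_fraction held-out fraction (default 0.2).
#' @param val_fraction validation fraction of the training pool.
#' @param repeats number of fit/validation re-partitions.
#' @param seed integer seed.
#' @return An object of class `split_plan`: `test` indices plus a list
#'   `repeats` of `fit`/`val` index vectors.
#' @export
make_splits <- function(n_subjects, test_fraction = 0.2, val_fraction = 0.2,
                        repeats = 5, seed = 1L) {
  if (n_subjects < 5)
    ratbex_error("ratbex_bad_config", "need at least 5 subjects to split")
  pool_n <- floor((1 - test_fraction) * n_subjects)
  test_n <- n_subjects - pool_n
  fit_n <- floor((1 - val_fraction) * pool_n)
  val_n <- pool_n - fit_n
  if (min(pool_n, test_n, fit_n, val_n) < 1)
    ratbex_error("ratbex_empty_split", "split produces an empty subject list")
  with_seed(seed, {
    test <- sort(sample.int(n_subjects, test_n))
    pool <- setdiff(seq_len(n_subjects), test)
    reps <- lapply(seq_len(repeats), function(r) {
      fit <- sort(sample(pool, fit_n))
      list(fit = fit, val = sort(setdiff(pool, fit)))
    })
    structure(list(n_subjects = n_subjects, test = test, repeats = reps,
                   sizes = c(test = test_n, fit = fit_n, val = val_n)),
              class = "split_plan")
  })
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(pred * target) + smooth) / (sum(pred) + sum(target) +
#' smooth)`; lies in `[0, 1]` and is differentiable in `pred`.
#'
#' @param pred probabilities in `[0, 1]`.
#' @param target binary labels of the same shape.
#' @param smooth smoothing constant (> 0).
#' @return Scalar loss.
#' @export
dice_loss <- function(pred, target, smooth = 1) {
  if (!identical(dim(pred) %||% length(pred), dim(target) %||% length(target)))
    ratbex_error("ratbex_shape_mismatch", "pred and target shapes differ")
  1 - (2 * sum(pred * target) + smooth) / (sum(pred) + sum(target) + smooth)
}

#' Sample a random training patch
#'
#' The patch offset is uniform over all positions where the patch fits
#' entirely inside the volume; image and mask are cropped congruently.
#' For a 2D patch shape a random through-plane slice is drawn first.
#' Uses the ambient RNG stream.
#'
#' @param image a [volume_image()].
#' @param mask the paired [binary_mask()].
#' @param patch_shape integer patch size (length 2 or 3).
#' @return List with `image`, `mask` (arrays) and the 0-based `offset`.
#' @export
sample_random_patch <- function(image, mask, patch_shape) {
  sz <- dim(image$data)
  ps <- as.integer(patch_shape)
  if (length(ps) == 2L) {
    slice <- sample.int(sz[3], 1)
    if (any(sz[1:2] < ps))
      ratbex_error("ratbex_volume_too_small", "volume smaller than patch")
    off <- vapply(1:2, function(ax) sample.int(sz[ax] - ps[ax] + 1L, 1) - 1L, 1L)
    ix <- off[1] + seq_len(ps[1]); iy <- off[2] + seq_len(ps[2])
    return(list(image = image$data[ix, iy, slice],
                mask = mask$data[ix, iy, slice],
                offset = c(off, slice - 1L)))
  }
  if (any(sz < ps))
    ratbex_error("ratbex_volume_too_small", "volume smaller than patch")
  off <- vapply(1:3, function(ax) sample.int(sz[ax] - ps[ax] + 1L, 1) - 1L, 1L)
  ix <- off[1] + seq_len(ps[1]); iy <- off[2] + seq_len(ps[2])
  iz <- off[3] + seq_len(ps[3])
  list(image = image$data[ix, iy, iz], mask = mask$data[ix, iy, iz],
       offset = off)
}

# Scale gradients so the global L2 norm does not exceed max_norm.
clip_global_norm <- function(grads, max_norm) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), 0)))
  if (is.finite(gn) && gn > max_norm)
    grads <- lapply(grads, function(g) g * (max_norm / gn))
  attr(grads, "norm_before") <- gn
  attr(grads, "norm_after") <- min(gn, max_norm)
  grads
}

adam_init <- function(params)
  list(t = 0,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Per-sample soft-Dice loss and its gradient wrt the probabilities,
# averaged over the batch. p, t are 1 x (B*N) matrices.
dice_loss_batch <- function(p, t, B, smooth) {
  N <- length(p) / B
  pm <- matrix(p, N, B)
  tm <- matrix(t, N, B)
  num <- 2 * colSums(pm * tm) + smooth
  den <- colSums(pm) + colSums(tm) + smooth
  dp <- -(2 * sweep(tm, 2, den, `*`) - matrix(num, N, B, byrow = TRUE)) /
    matrix(den^2, N, B, byrow = TRUE) / B
  list(loss = mean(1 - num / den), dp = matrix(dp, nrow = 1))
}

#' Train a U-Net with Dice loss on random patches
#'
#' Adam optimisation at the configured learning rate with per-step
#' global gradient-norm clipping. Each epoch draws
#' `patches_per_epoch` random crops from the fit subjects, then scores
#' whole-volume Dice (and voxel accuracy) on the validation subjects
#' via sliding-window inference; the weights of the best validation
#' epoch are returned. Training stops early after
#' `early_stop_patience` epochs without improvement and aborts with a
#' diagnostic if the loss becomes non-finite.
#'
#' @param model a [build_unet()] model.
#' @param fit_pairs,val_pairs non-empty lists of `image`/`truth` pairs
#'   (e.g. [generate_phantom()] outputs) with normalised intensities.
#' @param cfg a [train_config()].
#' @return A list of class `unet_fit`: `model` (best-epoch weights),
#'   `log` (per-epoch data frame), `best_epoch`, `best_val_dice`.
#' @export
train_model <- function(model, fit_pairs, val_pairs, cfg = train_config()) {
  stopifnot(inherits(model, "unet_model"), inherits(cfg, "train_config"))
  if (length(fit_pairs) == 0 || length(val_pairs) == 0)
    ratbex_error("ratbex_empty_split", "fit and validation sets must be non-empty")
  ps <- model$config$patch_shape
  ppe <- cfg$patches_per_epoch %||% (10L * length(fit_pairs))
  steps <- max(1L, ceiling(ppe / cfg$batch_size))
  val_stride <- cfg$val_stride %||% ps
  N <- prod(ps)
  with_seed(cfg$seed, {
    opt <- adam_init(model$params)
    log <- data.frame(epoch = integer(), train_loss = numeric(),
                      val_dice = numeric(), val_accuracy = numeric(),
                      grad_norm_post_max = numeric())
    best <- list(dice = -Inf, params = model$params, stats = model$stats,
                 epoch = 0L)
    stall <- 0L
    for (epoch in seq_len(cfg$max_epochs)) {
      losses <- numeric(steps)
      post_norms <- numeric(steps)
      for (s in seq_len(steps)) {
        subj <- sample.int(length(fit_pairs), cfg$batch_size, replace = TRUE)
        crops <- lapply(subj, function(i)
          sample_random_patch(fit_pairs[[i]]$image, fit_pairs[[i]]$truth, ps))
        X <- matrix(unlist(lapply(crops, function(cr) as.numeric(cr$image))),
                    nrow = 1)
        Tg <- matrix(unlist(lapply(crops, function(cr) as.numeric(cr$mask))),
                     nrow = 1)
        fw <- unet_forward_mat(model, X, cfg$batch_size, training = TRUE,
                               collect_cache = TRUE)
        model$stats <- fw$stats
        lb <- dice_loss_batch(fw$prob, Tg, cfg$batch_size, cfg$loss_smooth)
        if (!is.finite(lb$loss))
          ratbex_error("ratbex_divergence", sprintf(
            "training diverged at epoch %d step %d (loss = %s)",
            epoch, s, format(lb$loss)))
        losses[s] <- lb$loss
        if (cfg$learning_rate > 0) {
          dz <- lb$dp * fw$prob * (1 - fw$prob)
          grads <- unet_backward_mat(model, fw$cache, dz, cfg$batch_size)
          grads <- clip_global_norm(grads, cfg$grad_clip_norm)
          post_norms[s] <- attr(grads, "norm_after")
          up <- adam_step(model$params, grads, opt, cfg$learning_rate)
          model$params <- up$params
          opt <- up$state
        }
      }
      val <- validate_model(model, val_pairs, val_stride, cfg$threshold)
      log <- rbind(log, data.frame(epoch = epoch,
                                   train_loss = mean(losses),
                                   val_dice = val$dice,
                                   val_accuracy = val$accuracy,
                                   grad_norm_post_max = max(post_norms)))
      if (cfg$verbose)
        message(sprintf("epoch %d: loss %.4f, val dice %.4f",
                        epoch, mean(losses), val$dice))
      if (val$dice > best$dice) {
        best <- list(dice = val$dice, params = model$params,
                     stats = model$stats, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$early_stop_patience) break
      }
    }
    model$params <- best$params
    model$stats <- best$stats
    structure(list(model = model, log = log, best_epoch = best$epoch,
                   best_val_dice = best$dice),
              class = "unet_fit")
  })
}

# Whole-volume validation: mean Dice and voxel accuracy over pairs.
validate_model <- function(model, pairs, stride, threshold) {
  scores <- vapply(pairs, function(pr) {
    grid <- plan_patch_grid(dim(pr$image$data), model$config$patch_shape,
                            stride)
    prob <- predict_volume(model, pr$image, grid)
    pred <- binarize(prob, threshold)
    d <- overlap_metrics(confusion(pr$truth, pred))$dice
    acc <- mean((pred$data > 0.5) == (pr$truth$data > 0.5))
    c(d, acc)
  }, numeric(2))
  list(dice = mean(scores[1, ]), accuracy = mean(scores[2, ]))
}

#' Select the best model across repeated trainings
#'
#' Returns the candidate with the highest mean validation score; ties
#' break toward the lowest index.
#'
#' @param candidates a list of [train_model()] results (`unet_fit`), or
#'   of lists with elements `model` and `score`.
#' @return The winning candidate's `unet_model`.
#' @export
select_best_model <- function(candidates) {
  if (length(candidates) == 0)
    ratbex_error("ratbex_empty_split", "no candidate models supplied")
  scores <- vapply(candidates, function(cd) {
    s <- if (inherits(cd, "unet_fit")) cd$best_val_dice else cd$score
    mean(as.numeric(s))
  }, 0)
  if (any(!is.finite(scores)))
    ratbex_error("ratbex_bad_config", "candidate scores must be finite")
  win <- candidates[[which.max(scores)]]
  if (inherits(win, "unet_fit")) win$model else win$model
}
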