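# Split protocol, Dice loss, patch sampling, optimisation contracts.

test_that("split sizes follow the 80/20 floor rules", {
  sp <- make_splits(87, seed = 1)
  expect_identical(sp$sizes, c(test = 18, fit = 55, val = 14))
  expect_identical(make_splits(10, seed = 2)$sizes,
                   c(test = 2, fit = 6, val = 2))

  # five repeats repartition the same pool; the test list never moves
  expect_length(sp$repeats, 5)
  pool <- setdiff(seq_len(87), sp$test)
  parts <- lapply(sp$repeats, function(r) {
    expect_length(intersect(r$fit, r$val), 0)
    expect_setequal(c(r$fit, r$val), pool)
    paste(r$fit, collapse = ",")
  })
  expect_gt(length(unique(unlist(parts))), 1)
  expect_identical(make_splits(87, seed = 1)$test, sp$test)
  expect_error(make_splits(4), class = "ratbex_bad_config")
})

test_that("dice loss matches its closed forms", {
  n <- 64
  target <- array(rbinom(n, 1, 0.5), c(4, 4, 4))
  expect_equal(dice_loss(target, target, smooth = 1),
               1 - (2 * sum(target) + 1) / (2 * sum(target) + 1))
  expect_equal(dice_loss(array(1, c(4, 4, 4)), array(0, c(4, 4, 4)),
                         smooth = 1),
               1 - 1 / (n + 1))
  half <- array(rep(c(1, 0), each = n / 2), c(4, 4, 4))
  expect_equal(dice_loss(array(0.5, c(4, 4, 4)), half, smooth = 1e-9), 0.5,
               tolerance = 1e-6)
  expect_error(dice_loss(array(1, c(2, 2, 2)), array(1, c(2, 2, 1))),
               class = "ratbex_shape_mismatch")
})

test_that("dice loss complements the metric-module Dice on binary input", {
  set.seed(8)
  for (k in 1:10) {
    dims <- c(4, 4, 4)
    a <- array(rbinom(64, 1, 0.5), dims)
    b <- array(rbinom(64, 1, 0.5), dims)
    d <- overlap_metrics(confusion(binary_mask(a, rep(1, 3)),
                                   binary_mask(b, rep(1, 3))))$dice
    expect_equal(dice_loss(b, a, smooth = 1e-12) + d, 1, tolerance = 1e-9)
  }
})

test_that("random patch offsets are uniform over feasible positions", {
  pair <- generate_phantom(tiny_phantom_spec(seed = 6))
  # volume exactly patch-sized: the single possible crop is returned
  ps <- dim(pair$image$data)
  set.seed(1)
  crop <- sample_random_patch(pair$image, pair$truth, ps)
  expect_identical(crop$offset, c(0L, 0L, 0L))
  expect_identical(crop$image, pair$image$data)
  expect_true(all(crop$mask %in% c(0, 1)))

  # chi-square uniformity over all offsets of an 8^3 patch in 12x12x10
  img <- volume_image(array(0, c(12, 12, 10)), rep(0.2, 3))
  msk <- binary_mask(array(0, c(12, 12, 10)), rep(0.2, 3))
  set.seed(99)
  draws <- t(replicate(10000, sample_random_patch(img, msk, c(8, 8, 8))$offset))
  cells <- table(factor(draws[, 1], levels = 0:4),
                 factor(draws[, 2], levels = 0:4),
                 factor(draws[, 3], levels = 0:2))
  chi <- sum((cells - 10000 / 75)^2 / (10000 / 75))
  expect_lt(chi, qchisq(0.99, df = 74))

  expect_error(sample_random_patch(img, msk, c(16, 16, 16)),
               class = "ratbex_volume_too_small")
})

test_that("clipped gradient norms never exceed the bound", {
  set.seed(4)
  g <- list(a = matrix(rnorm(20, 0, 10), 4), b = rnorm(5, 0, 10))
  cl <- ratbex:::clip_global_norm(g, 1)
  norm_after <- sqrt(sum(unlist(lapply(cl, function(x) sum(x * x)))))
  expect_lte(norm_after, 1 + 1e-6)
  # direction preserved
  expect_equal(cl$a / norm_after * attr(cl, "norm_before"), g$a,
               tolerance = 1e-9)
  small <- list(a = c(0.1, 0.1))
  expect_identical(ratbex:::clip_global_norm(small, 1)$a, small$a)
})

test_that("zero learning rate leaves the weights unchanged after an epoch", {
  pairs <- lapply(1:2, function(i)
    generate_phantom(tiny_phantom_spec(seed = i)))
  model <- build_unet(tiny_unet_config(), seed = 9)
  fit <- train_model(model, pairs, pairs,
                     tiny_train_config(learning_rate = 0, max_epochs = 1,
                                       early_stop_patience = 1))
  expect_identical(fit$model$params, model$params)
  expect_identical(nrow(fit$log), 1L)
})

test_that("training is run-to-run reproducible and improves the loss", {
  pairs <- lapply(1:3, function(i)
    generate_phantom(tiny_phantom_spec(seed = 10 + i)))
  model <- build_unet(tiny_unet_config(), seed = 13)
  cfg <- tiny_train_config(seed = 5, max_epochs = 3)
  f1 <- train_model(model, pairs[1:2], pairs[3], cfg)
  f2 <- train_model(model, pairs[1:2], pairs[3], cfg)
  expect_equal(f1$log$train_loss, f2$log$train_loss, tolerance = 1e-6)
  expect_identical(f1$model$params, f2$model$params)

  # bookkeeping: log bounded by max_epochs, clip instrumented
  expect_lte(nrow(f1$log), 3L)
  expect_true(all(f1$log$grad_norm_post_max <= 1 + 1e-6))
  expect_identical(f1$best_epoch,
                   f1$log$epoch[which.max(f1$log$val_dice)])
})

test_that("training errors are classed and informative", {
  pairs <- list(generate_phantom(tiny_phantom_spec(seed = 1)))
  model <- build_unet(tiny_unet_config(), seed = 1)
  expect_error(train_model(model, list(), pairs, tiny_train_config()),
               class = "ratbex_empty_split")
  # a non-finite loss (here: poisoned weights) aborts with a diagnostic
  poisoned <- model
  poisoned$params[["e1c1.W"]][1] <- NaN
  expect_error(train_model(poisoned, pairs, pairs, tiny_train_config()),
               class = "ratbex_divergence")
})

test_that("best-model selection takes the argmax with first-index ties", {
  mk <- function(score) list(model = structure(list(tag = score),
                                               class = "unet_model"),
                             score = score)
  cands <- list(mk(0.91), mk(0.95), mk(0.93))
  expect_identical(select_best_model(cands)$tag, 0.95)
  expect_identical(select_best_model(list(mk(0.9)))$tag, 0.9)
  tie <- list(mk(0.95), mk(0.95))
  expect_identical(select_best_model(tie), tie[[1]]$model)
  # vector scores are averaged
  multi <- list(mk(c(0.9, 0.92)), mk(c(0.96, 0.94)))
  expect_identical(select_best_model(multi)$tag, c(0.96, 0.94))
  expect_error(select_best_model(list()), class = "ratbex_empty_split")
})
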