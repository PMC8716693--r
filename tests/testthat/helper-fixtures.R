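# Fixtures are generated in code: tiny phantoms for fast unit tests and
# one memoized desk-scale training shared by the tests that need a
# competent model (training is the expensive step, so it runs once per
# session).

tiny_phantom_spec <- function(seed = 1L, noise_variance = 9e-4, ...) {
  args <- utils::modifyList(
    list(grid_size = c(24, 24, 16), brain_semi_axes = c(1.6, 1.4, 0.8),
         shell_thickness = c(0.2, 0.3), noise_variance = noise_variance,
         seed = seed),
    list(...))
  do.call(phantom_spec, args)
}

tiny_unet_config <- function() unet_config(3, c(8, 8, 8), c(4, 8))

tiny_train_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(batch_size = 4, max_epochs = 2, patches_per_epoch = 8, seed = seed),
    list(...))
  do.call(train_config, args)
}

.ratbex_test_cache <- new.env(parent = emptyenv())

# Desk-scale study conditions: 12 phantom subjects from the default
# cohort generator; 8 fit / 2 validation / 2 held-out test; the
# 4-level 16^3-patch 3D U-Net desk preset; reference optimiser settings
# (Adam 1e-3, batch 16, clip 1).
trained_desk_model <- function() {
  if (!is.null(.ratbex_test_cache$desk)) return(.ratbex_test_cache$desk)
  cohort <- generate_cohort(12, seed = 7)
  fit <- cohort[1:8]; val <- cohort[9:10]; test <- cohort[11:12]
  model <- build_unet(unet_config_desk(), seed = 11)
  fitres <- train_model(model, fit, val,
                        train_config(max_epochs = 10, seed = 3))
  .ratbex_test_cache$desk <- list(fit = fitres, train_pairs = fit,
                                  val_pairs = val, test_pairs = test)
  .ratbex_test_cache$desk
}
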