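# Configurable 2D/3D U-Net, implemented natively.
#
# Activations are matrices with one row per channel and one column per
# voxel, samples concatenated along columns (column-major spatial
# order). Convolutions (3^d kernels, stride 1, zero padding 1) are
# GEMMs against unfolded neighbourhoods (im2col); up-convolutions are
# kernel-2 stride-2 transposed convolutions; each conv is followed by
# batch normalisation and ReLU; a final 1x1(x1) convolution plus
# sigmoid yields per-voxel brain probabilities.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

#' U-Net architecture configuration
#'
#' The encoder has one block per entry of `level_channels` with 2^d max
#' pooling between blocks; the decoder mirrors it with transposed-conv
#' upsampling and channel-concatenation skip connections. The reference
#' rodent models are [unet_config_3d64()] (patch 64^3, channels
#' 32/64/96/128/256), [unet_config_3d16()] and [unet_config_2d64()].
#'
#' @param dimensionality 2 or 3.
#' @param patch_shape integer patch size per axis; every entry must be
#'   divisible by `2^(levels - 1)` and at least 2 at the bottleneck.
#' @param level_channels strictly increasing channel counts per level.
#' @param convs_per_block convolutions per block (default 2).
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(dimensionality = 3,
                        patch_shape = c(64, 64, 64),
                        level_channels = c(32, 64, 96, 128, 256),
                        convs_per_block = 2) {
  if (!dimensionality %in% c(2, 3))
    ratbex_error("ratbex_bad_config", "dimensionality must be 2 or 3")
  patch_shape <- as.integer(patch_shape)
  if (length(patch_shape) == 1L)
    patch_shape <- rep(patch_shape, dimensionality)
  if (length(patch_shape) != dimensionality)
    ratbex_error("ratbex_bad_config",
                 "patch_shape length must match dimensionality")
  L <- length(level_channels)
  if (L < 2)
    ratbex_error("ratbex_bad_config", "at least two levels are required")
  if (any(diff(level_channels) <= 0))
    ratbex_error("ratbex_bad_config",
                 "level_channels must be strictly increasing")
  div <- 2^(L - 1)
  if (any(patch_shape %% div != 0) || any(patch_shape %/% div < 2))
    ratbex_error("ratbex_bad_config", sprintf(
      "patch_shape must be divisible by %d with a bottleneck of at least 2 voxels per axis",
      div))
  if (convs_per_block < 1)
    ratbex_error("ratbex_bad_config", "convs_per_block must be >= 1")
  structure(list(dimensionality = as.integer(dimensionality),
                 patch_shape = patch_shape,
                 level_channels = as.integer(level_channels),
                 convs_per_block = as.integer(convs_per_block),
                 input_channels = 1L, output_channels = 1L),
            class = "unet_config")
}

#' @rdname unet_config
#' @export
unet_config_3d64 <- function() unet_config(3, c(64, 64, 64), c(32, 64, 96, 128, 256))

#' @rdname unet_config
#' @details `unet_config_3d16()` uses 4 levels (channels 32/64/96/128):
#'   a fifth pooling is impossible on a 16^3 patch.
#' @export
unet_config_3d16 <- function() unet_config(3, c(16, 16, 16), c(32, 64, 96, 128))

#' @rdname unet_config
#' @export
unet_config_2d64 <- function() unet_config(2, c(64, 64), c(32, 64, 96, 128, 256))

#' @rdname unet_config
#' @details `unet_config_desk()` is a reduced-width 4-level 16^3 model
#'   (channels 12/24/36/48) sized for single-CPU training on phantoms.
#' @export
unet_config_desk <- function() unet_config(3, c(16, 16, 16), c(12, 24, 36, 48))

kernel_taps <- function(cfg) 3L^cfg$dimensionality
up_taps <- function(cfg) 2L^cfg$dimensionality

# Channel widths entering/leaving each parameterised op, used by both
# the initialiser and the forward/backward passes.
unet_layout <- function(cfg) {
  L <- length(cfg$level_channels)
  ch <- cfg$level_channels
  enc_in <- c(cfg$input_channels, ch[-L])
  list(L = L, ch = ch, enc_in = enc_in, K = kernel_taps(cfg), K2 = up_taps(cfg))
}

#' Build a (randomly initialised) U-Net model
#'
#' Convolution weights use He-normal initialisation; batch-norm scales
#' start at 1, biases at 0. Deterministic given `seed`.
#'
#' @param config a [unet_config()].
#' @param seed integer seed for weight initialisation.
#' @return An object of class `unet_model` with elements `config`,
#'   `params`, `stats` (batch-norm running moments) and
#'   `parameter_count`.
#' @export
build_unet <- function(config, seed = 0L) {
  stopifnot(inherits(config, "unet_config"))
  ly <- unet_layout(config)
  P <- list(); S <- list()
  he <- function(nout, nin_taps)
    matrix(rnorm(nout * nin_taps, 0, sqrt(2 / nin_taps)), nout, nin_taps)
  add_conv_bn <- function(name, cin, cout) {
    P[[paste0(name, ".W")]] <<- he(cout, cin * ly$K)
    P[[paste0(name, ".b")]] <<- numeric(cout)
    P[[paste0(name, ".g")]] <<- rep(1, cout)
    P[[paste0(name, ".be")]] <<- numeric(cout)
    S[[paste0(name, ".rm")]] <<- numeric(cout)
    S[[paste0(name, ".rv")]] <<- rep(1, cout)
  }
  with_seed(seed, {
    for (l in seq_len(ly$L)) {
      cin <- ly$enc_in[l]
      for (j in seq_len(config$convs_per_block)) {
        add_conv_bn(sprintf("e%dc%d", l, j), cin, ly$ch[l])
        cin <- ly$ch[l]
      }
    }
    for (l in seq_len(ly$L - 1)) {
      P[[sprintf("u%d.W", l)]] <- he(ly$ch[l] * ly$K2, ly$ch[l + 1])
      P[[sprintf("u%d.b", l)]] <- numeric(ly$ch[l])
      cin <- 2L * ly$ch[l]
      for (j in seq_len(config$convs_per_block)) {
        add_conv_bn(sprintf("d%dc%d", l, j), cin, ly$ch[l])
        cin <- ly$ch[l]
      }
    }
    P[["h.W"]] <- he(1, ly$ch[1])
    P[["h.b"]] <- 0
  })
  structure(list(config = config, params = P, stats = S,
                 parameter_count = sum(vapply(P, length, 1L))),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<unet_model> %dD, patch %s, channels %s, %s parameters\n",
              cfg$dimensionality, paste(cfg$patch_shape, collapse = "x"),
              paste(cfg$level_channels, collapse = "/"),
              format(x$parameter_count, big.mark = ",")))
  invisible(x)
}

# --- forward / backward ----------------------------------------------------

conv_bn_relu_fw <- function(P, S, name, X, dims, B, training, cache_env) {
  col <- cpp_im2col(X, dims, B)
  z <- P[[paste0(name, ".W")]] %*% col + P[[paste0(name, ".b")]]
  if (training) {
    mu <- rowMeans(z)
    va <- rowMeans(z * z) - mu * mu
    va[va < 0] <- 0
    if (!is.null(cache_env)) {
      cache_env$new_stats[[paste0(name, ".rm")]] <-
        (1 - BN_MOMENTUM) * S[[paste0(name, ".rm")]] + BN_MOMENTUM * mu
      cache_env$new_stats[[paste0(name, ".rv")]] <-
        (1 - BN_MOMENTUM) * S[[paste0(name, ".rv")]] + BN_MOMENTUM * va
    }
  } else {
    mu <- S[[paste0(name, ".rm")]]
    va <- S[[paste0(name, ".rv")]]
  }
  inv <- 1 / sqrt(va + BN_EPS)
  xhat <- (z - mu) * inv
  y <- xhat * P[[paste0(name, ".g")]] + P[[paste0(name, ".be")]]
  out <- y * (y > 0)
  if (!is.null(cache_env))
    cache_env$cache[[name]] <- list(col = col, xhat = xhat, inv = inv,
                                    out = out, dims = dims)
  out
}

conv_bn_relu_bw <- function(P, name, dY, cache, B, grads) {
  cc <- cache[[name]]
  dy <- dY * (cc$out > 0)
  g <- P[[paste0(name, ".g")]]
  m <- ncol(dy)
  grads[[paste0(name, ".g")]] <- rowSums(dy * cc$xhat)
  grads[[paste0(name, ".be")]] <- rowSums(dy)
  dxhat <- dy * g
  dz <- (cc$inv / m) *
    (m * dxhat - rowSums(dxhat) - cc$xhat * rowSums(dxhat * cc$xhat))
  grads[[paste0(name, ".W")]] <- tcrossprod(dz, cc$col)
  grads[[paste0(name, ".b")]] <- rowSums(dz)
  dX <- cpp_col2im(crossprod(P[[paste0(name, ".W")]], dz), cc$dims, B)
  list(dX = dX, grads = grads)
}

# Core pass. X is a 1 x (B*N) matrix of normalised intensities; returns
# probabilities (1 x B*N). With collect_cache = TRUE also returns the
# per-op caches needed for the backward pass and updated BN running
# stats (when training).
unet_forward_mat <- function(model, X, B, training = FALSE,
                             collect_cache = FALSE) {
  cfg <- model$config
  ly <- unet_layout(cfg)
  P <- model$params; S <- model$stats
  env <- NULL
  if (collect_cache) {
    env <- new.env(parent = emptyenv())
    env$cache <- list(); env$new_stats <- S
  }
  dims <- cfg$patch_shape
  act <- X
  skips <- vector("list", ly$L - 1)
  pool_idx <- vector("list", ly$L - 1)
  pool_cols <- integer(ly$L - 1)
  for (l in seq_len(ly$L)) {
    for (j in seq_len(cfg$convs_per_block))
      act <- conv_bn_relu_fw(P, S, sprintf("e%dc%d", l, j), act, dims, B,
                             training, env)
    if (l < ly$L) {
      skips[[l]] <- act
      pool_cols[l] <- ncol(act)
      mp <- cpp_maxpool_fw(act, dims, B)
      act <- mp$y
      pool_idx[[l]] <- mp$idx
      dims <- dims %/% 2L
    }
  }
  up_in <- vector("list", ly$L - 1)
  up_dims <- vector("list", ly$L - 1)
  for (l in rev(seq_len(ly$L - 1))) {
    up_in[[l]] <- act
    up_dims[[l]] <- dims
    G <- P[[sprintf("u%d.W", l)]] %*% act
    act <- cpp_up2_scatter(G, dims, B, ly$ch[l]) + P[[sprintf("u%d.b", l)]]
    dims <- dims * 2L
    act <- rbind(act, skips[[l]])
    for (j in seq_len(cfg$convs_per_block))
      act <- conv_bn_relu_fw(P, S, sprintf("d%dc%d", l, j), act, dims, B,
                             training, env)
  }
  z <- P[["h.W"]] %*% act + P[["h.b"]]
  prob <- 1 / (1 + exp(-z))
  if (!collect_cache) return(prob)
  env$cache[["head"]] <- list(X = act)
  env$cache[["pool_idx"]] <- pool_idx
  env$cache[["pool_cols"]] <- pool_cols
  env$cache[["up_in"]] <- up_in
  env$cache[["up_dims"]] <- up_dims
  list(prob = prob, cache = env$cache,
       stats = if (training) env$new_stats else S)
}

# Backward pass from dL/dlogits (1 x B*N); returns a named gradient
# list congruent with model$params.
unet_backward_mat <- function(model, cache, dz, B) {
  cfg <- model$config
  ly <- unet_layout(cfg)
  P <- model$params
  grads <- list()
  grads[["h.W"]] <- tcrossprod(dz, cache[["head"]]$X)
  grads[["h.b"]] <- sum(dz)
  dact <- crossprod(P[["h.W"]], dz)
  dskip <- vector("list", ly$L - 1)
  # decoder, reverse of execution order (l = 1 .. L-1)
  for (l in seq_len(ly$L - 1)) {
    for (j in rev(seq_len(cfg$convs_per_block))) {
      r <- conv_bn_relu_bw(P, sprintf("d%dc%d", l, j), dact, cache, B, grads)
      grads <- r$grads
      dact <- r$dX
    }
    cl <- ly$ch[l]
    d_up <- dact[seq_len(cl), , drop = FALSE]
    dskip[[l]] <- dact[cl + seq_len(cl), , drop = FALSE]
    grads[[sprintf("u%d.b", l)]] <- rowSums(d_up)
    dG <- cpp_up2_gather(d_up, cache$up_dims[[l]], B, cl)
    grads[[sprintf("u%d.W", l)]] <- tcrossprod(dG, cache$up_in[[l]])
    dact <- crossprod(P[[sprintf("u%d.W", l)]], dG)
  }
  # encoder, deepest block first
  for (l in rev(seq_len(ly$L))) {
    if (l < ly$L)
      dact <- cpp_maxpool_bw(dact, cache$pool_idx[[l]], cache$pool_cols[l]) +
        dskip[[l]]
    for (j in rev(seq_len(cfg$convs_per_block))) {
      r <- conv_bn_relu_bw(P, sprintf("e%dc%d", l, j), dact, cache, B, grads)
      grads <- r$grads
      dact <- r$dX
    }
  }
  grads
}

# --- public batch interface ------------------------------------------------

# Accepts a single patch (array of patch_shape), a list of patches, or
# an array with one trailing batch dimension; returns X matrix + B.
pack_batch <- function(cfg, batch) {
  ps <- cfg$patch_shape
  as_one <- function(p) {
    p <- as.array(p)
    if (!identical(as.integer(dim(p)), ps))
      ratbex_error("ratbex_shape_mismatch", sprintf(
        "patch shape %s does not match config patch_shape %s",
        paste(dim(p), collapse = "x"), paste(ps, collapse = "x")))
    as.numeric(p)
  }
  if (is.list(batch)) {
    cols <- lapply(batch, as_one)
    return(list(X = matrix(unlist(cols), nrow = 1), B = length(cols)))
  }
  batch <- as.array(batch)
  nd <- length(dim(batch))
  if (nd == length(ps))
    return(list(X = matrix(as_one(batch), nrow = 1), B = 1L))
  if (nd == length(ps) + 1L &&
      identical(as.integer(dim(batch)[seq_along(ps)]), ps))
    return(list(X = matrix(as.numeric(batch), nrow = 1),
                B = dim(batch)[nd]))
  ratbex_error("ratbex_shape_mismatch",
               "batch must be patches of the configured patch shape")
}

#' Run the network on a batch of patches
#'
#' In evaluation mode (the default) batch-norm uses its running
#' moments, so the output is deterministic for a given input.
#'
#' @param model a [build_unet()] model.
#' @param batch a single patch array, a list of patch arrays, or an
#'   array with a trailing batch dimension; intensities are expected on
#'   the normalised `[0, 1]` scale.
#' @return Per-voxel probabilities in `[0, 1]` with the same spatial
#'   shape as the input: an array `patch_shape x B` (the trailing batch
#'   dimension is dropped for a single patch).
#' @export
unet_forward <- function(model, batch) {
  stopifnot(inherits(model, "unet_model"))
  pk <- pack_batch(model$config, batch)
  prob <- unet_forward_mat(model, pk$X, pk$B, training = FALSE)
  ps <- model$config$patch_shape
  if (pk$B == 1L) array(prob, ps) else array(prob, c(ps, pk$B))
}

#' Save / load a U-Net model
#'
#' The model (weights, batch-norm statistics, configuration) is written
#' with R's native serialisation; a plain-text `.cfg` sidecar makes the
#' checkpoint self-describing.
#'
#' @param model a `unet_model`.
#' @param path checkpoint path (e.g. `model.rds`).
#' @return `path` (invisibly) / the restored `unet_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "unet_model"))
  saveRDS(model, path)
  cfg <- model$config
  writeLines(c(sprintf("dimensionality=%d", cfg$dimensionality),
               sprintf("patch_shape=%s", paste(cfg$patch_shape, collapse = ",")),
               sprintf("level_channels=%s", paste(cfg$level_channels, collapse = ",")),
               sprintf("convs_per_block=%d", cfg$convs_per_block),
               sprintf("parameter_count=%d", model$parameter_count)),
             paste0(path, ".cfg"))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path))
    ratbex_error("ratbex_missing_file", sprintf("no checkpoint at %s", path))
  m <- readRDS(path)
  if (!inherits(m, "unet_model"))
    ratbex_error("ratbex_bad_checkpoint", "file does not contain a unet_model")
  m
}
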