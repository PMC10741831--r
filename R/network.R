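#' Network architecture configuration
#'
#' Describes the motion-simulation network: a four-level convolutional
#' encoder (two 3x3 convolutions + ReLU per level, channel count doubling,
#' 2x2 max pooling), a fully connected bottleneck producing the latent
#' vector, a two-layer one-to-many LSTM rolling the latent through the nine
#' subsequent phases, and a symmetric decoder with skip connections whose
#' 2-channel output is bounded by `max_disp * tanh(.)` to give per-phase
#' displacement fields.
#'
#' @param image_size integer length 1 or 2; input height/width, divisible
#'   by 16 (four pooling levels).
#' @param base_channels channel width of the first encoder level.
#' @param latent latent vector length (default 512).
#' @param max_disp displacement bound in pixels; default a quarter of the
#'   image height.
#' @param steps number of predicted phases (fixed 9).
#' @param lstm_layers recurrent depth (default 2).
#' @return An object of class `rms_config`.
#' @export
rms_config <- function(image_size = 64, base_channels = 8, latent = 512,
                       max_disp = NULL, steps = 9, lstm_layers = 2) {
  if (length(image_size) == 1) image_size <- c(image_size, image_size)
  image_size <- as.integer(image_size)
  if (any(image_size %% 16 != 0) || any(image_size < 32)) {
    abort("`image_size` must be >= 32 and divisible by 16 (four pooling levels).")
  }
  max_disp <- max_disp %||% (0.25 * image_size[1])
  structure(
    list(image_size = image_size, base_channels = as.integer(base_channels),
         latent = as.integer(latent), max_disp = max_disp,
         steps = as.integer(steps), lstm_layers = as.integer(lstm_layers),
         levels = 4L),
    class = "rms_config"
  )
}

# Channel width of encoder level l (1-based).
level_channels <- function(cfg, l) cfg$base_channels * 2L^(l - 1L)

#' Initialize network parameters
#'
#' @param cfg an [rms_config()].
#' @param seed integer seed for weight initialization.
#' @return Nested list of parameter arrays (class `rms_params`).
#' @export
rms_init_params <- function(cfg, seed = 1) {
  with_seed(seed, {
    enc <- lapply(1:cfg$levels, function(l) {
      cin <- if (l == 1) 1L else level_channels(cfg, l - 1)
      cl <- level_channels(cfg, l)
      list(conv1 = conv_init(cin, cl), conv2 = conv_init(cl, cl))
    })
    cb <- level_channels(cfg, cfg$levels)
    flat <- prod(cfg$image_size %/% 16L) * cb
    dec <- lapply(1:cfg$levels, function(l) {
      cl <- level_channels(cfg, l)
      cin <- if (l == cfg$levels) cb else level_channels(cfg, l + 1)
      list(
        up = tconv_init(cin, cl),
        conv1 = conv_init(2L * cl, cl),
        conv2 = conv_init(cl, cl)
      )
    })
    structure(
      list(
        enc = enc,
        fc_enc = fc_init(flat, cfg$latent),
        lstm = lstm_init(cfg$latent, cfg$lstm_layers),
        fc_dec = fc_init(cfg$latent, flat),
        dec = dec,
        head = conv1_init(cfg$base_channels, 2L)
      ),
      class = "rms_params"
    )
  })
}

#' Encode an end-of-inhale image to its latent vector
#'
#' Four down-sampling blocks (two 3x3 convolutions + ReLU, then 2x2 max
#' pooling with stride 2, channel count doubling per block); the bottleneck
#' is flattened through one fully connected layer into the latent vector.
#' Skip features (the pre-pooling activation of each level) are retained
#' for the decoder.
#'
#' @param params network parameters from [rms_init_params()].
#' @param cfg the matching [rms_config()].
#' @param p0 H x W matrix in \[0, 1\].
#' @return list with `x0` (latent vector), `skips` (4 feature arrays) and
#'   `cache` for backpropagation.
#' @export
rms_encode <- function(params, cfg, p0) {
  d <- dim(p0)
  if (any(d %% 16 != 0)) abort("input size must be divisible by 16")
  if (any(d != cfg$image_size)) abort("input size does not match the configuration")
  # center the input so first-level features carry both signs (all-positive
  # smooth images would otherwise silence most ReLU channels at init)
  x <- array(p0 - mean(p0), c(d, 1L))
  skips <- vector("list", cfg$levels)
  cache <- list(levels = vector("list", cfg$levels))
  for (l in 1:cfg$levels) {
    c1 <- conv_fwd(x, params$enc[[l]]$conv1)
    a1 <- relu_fwd(c1$y)
    c2 <- conv_fwd(a1, params$enc[[l]]$conv2)
    a2 <- relu_fwd(c2$y)
    skips[[l]] <- a2
    pl <- pool_fwd(a2)
    cache$levels[[l]] <- list(c1 = c1, a1 = a1, c2 = c2, a2 = a2, pool = pl)
    x <- pl$y
  }
  cache$bottom_dim <- dim(x)
  fc <- fc_fwd(as.numeric(x), params$fc_enc)
  cache$fc <- fc
  list(x0 = fc$y, skips = skips, cache = cache)
}

# Backward of the encoder. `dskips` are accumulated gradients on the skip
# features; `dx0` the gradient on the latent.
rms_encode_bwd <- function(params, cfg, dx0, dskips, cache) {
  grads <- list(enc = vector("list", cfg$levels))
  fcb <- fc_bwd(dx0, params$fc_enc, cache$fc)
  grads$fc_enc <- fcb$grads
  dx <- array(fcb$dx, cache$bottom_dim)
  for (l in cfg$levels:1) {
    lv <- cache$levels[[l]]
    da2 <- pool_bwd(dx, lv$pool) + dskips[[l]]
    dc2 <- relu_bwd(da2, lv$a2)
    b2 <- conv_bwd(dc2, params$enc[[l]]$conv2, lv$c2)
    dc1 <- relu_bwd(b2$dx, lv$a1)
    b1 <- conv_bwd(dc1, params$enc[[l]]$conv1, lv$c1)
    grads$enc[[l]] <- list(conv1 = b1$grads, conv2 = b2$grads)
    dx <- b1$dx
  }
  grads
}

#' Roll the latent vector through the respiratory cycle
#'
#' Autoregressive two-layer LSTM with zero-initialized state: the latent of
#' the input phase is the first input, and each emitted latent is fed back
#' until t = 9, yielding the nine subsequent phase latents.
#'
#' @param params network parameters.
#' @param x0 latent vector.
#' @param steps number of steps (default from the parameter shapes, 9).
#' @return list with `xs` (list of 9 latent vectors) and `cache`.
#' @export
rms_rollout <- function(params, x0, steps = 9) {
  out <- lstm_rollout_fwd(x0, params$lstm, steps)
  list(xs = out$xs, cache = out$caches)
}

#' Decode one phase latent into a displacement field
#'
#' Mirrors the encoder with four up-sampling blocks (2x2 transposed
#' convolution, skip concatenation, two 3x3 convolutions + ReLU); a final
#' 1x1 convolution with `max_disp * tanh` bounding yields the 2-channel
#' displacement field in pixels.
#'
#' @param params network parameters.
#' @param cfg the matching [rms_config()].
#' @param x_t latent vector for phase t.
#' @param skips skip features from [rms_encode()] of the same forward pass.
#' @return list with `dvf` (H x W x 2 array) and `cache`.
#' @export
rms_decode <- function(params, cfg, x_t, skips) {
  cb <- level_channels(cfg, cfg$levels)
  bottom <- c(cfg$image_size %/% 16L, cb)
  fc <- fc_fwd(x_t, params$fc_dec)
  a0 <- relu_fwd(array(fc$y, bottom))
  cache <- list(fc = fc, a0 = a0, bottom = bottom, levels = vector("list", cfg$levels))
  x <- a0
  for (l in cfg$levels:1) {
    if (!identical(dim(skips[[l]])[1:2], dim(x)[1:2] * 2L)) {
      abort("skip feature shape does not match the decoder level")
    }
    up <- tconv_fwd(x, params$dec[[l]]$up)
    au <- relu_fwd(up$y)
    cat_in <- abind2(au, skips[[l]])
    c1 <- conv_fwd(cat_in, params$dec[[l]]$conv1)
    a1 <- relu_fwd(c1$y)
    c2 <- conv_fwd(a1, params$dec[[l]]$conv2)
    a2 <- relu_fwd(c2$y)
    cache$levels[[l]] <- list(up = up, au = au, c1 = c1, a1 = a1,
                              c2 = c2, a2 = a2, n_up = dim(au)[3])
    x <- a2
  }
  hd <- conv1_fwd(x, params$head)
  th <- tanh(hd$y)
  cache$head <- hd
  cache$th <- th
  list(dvf = cfg$max_disp * th, cache = cache)
}

# Backward of one decode. Returns gradient on the latent, per-level skip
# gradients, and parameter gradients.
rms_decode_bwd <- function(params, cfg, ddvf, skips, cache) {
  dth <- cfg$max_disp * ddvf * (1 - cache$th^2)
  hb <- conv1_bwd(dth, params$head, cache$head)
  grads <- list(head = hb$grads, dec = vector("list", cfg$levels),
                fc_dec = NULL)
  dskips <- vector("list", cfg$levels)
  dx <- hb$dx
  for (l in 1:cfg$levels) {
    lv <- cache$levels[[l]]
    da2 <- relu_bwd(dx, lv$a2)
    b2 <- conv_bwd(da2, params$dec[[l]]$conv2, lv$c2)
    da1 <- relu_bwd(b2$dx, lv$a1)
    b1 <- conv_bwd(da1, params$dec[[l]]$conv1, lv$c1)
    n_up <- lv$n_up
    dcat <- b1$dx
    dau <- dcat[, , seq_len(n_up), drop = FALSE]
    dskips[[l]] <- dcat[, , n_up + seq_len(dim(dcat)[3] - n_up), drop = FALSE]
    dup <- relu_bwd(dau, lv$au)
    bu <- tconv_bwd(dup, params$dec[[l]]$up, lv$up)
    grads$dec[[l]] <- list(up = bu$grads, conv1 = b1$grads, conv2 = b2$grads)
    dx <- bu$dx
  }
  da0 <- relu_bwd(dx, cache$a0)
  fcb <- fc_bwd(as.numeric(da0), params$fc_dec, cache$fc)
  grads$fc_dec <- fcb$grads
  list(dx = fcb$dx, dskips = dskips, grads = grads)
}

# Concatenate two (H, W, C) arrays along channels.
abind2 <- function(a, b) {
  da <- dim(a)
  db <- dim(b)
  array(c(a, b), c(da[1], da[2], da[3] + db[3]))
}

#' Warp an image with a displacement field (spatial transformer)
#'
#' Each output pixel `(i, j)` samples the input at
#' `(i + u_y(i,j), j + u_x(i,j))` with bilinear (default) or
#' nearest-neighbour interpolation; out-of-bounds samples are border
#' clamped. Bilinear mode is differentiable with respect to both the image
#' and the field.
#'
#' @param image H x W numeric matrix.
#' @param dvf H x W x 2 array; slice 1 = column displacement `u_x`,
#'   slice 2 = row displacement `u_y` (pixels).
#' @param interp `"bilinear"` or `"nearest"` (use nearest for masks).
#' @return Warped H x W matrix.
#' @export
spatial_transform <- function(image, dvf, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  if (!all(is.finite(dvf))) abort("`dvf` contains non-finite values")
  d <- dim(dvf)
  if (length(d) != 3 || d[3] != 2 || !all(d[1:2] == dim(image))) {
    abort("`dvf` must be an (H, W, 2) array congruent with `image`")
  }
  cpp_warp_fwd(image, dvf, interp == "nearest")
}

# Warp an integer label mask (0/1/2) with nearest-neighbour sampling.
warp_mask <- function(mask, dvf) {
  out <- cpp_warp_fwd(mask + 0.0, dvf, TRUE)
  matrix(as.integer(round(out)), nrow(mask), ncol(mask))
}

#' Full forward pass: one EOI image to nine phases
#'
#' Composes [rms_encode()], [rms_rollout()], [rms_decode()] (nine decodes
#' reusing the single encoder's skip features) and [spatial_transform()].
#'
#' @param params network parameters.
#' @param cfg the matching [rms_config()].
#' @param p0 preprocessed input image (values in \[0, 1\], size divisible
#'   by 16).
#' @param keep_cache retain intermediate activations for a backward pass.
#' @return list with `dvfs` (9 fields), `preds` (9 warped images), `latents`
#'   and, if requested, `cache`.
#' @export
rms_forward <- function(params, cfg, p0, keep_cache = FALSE) {
  enc <- rms_encode(params, cfg, p0)
  ro <- rms_rollout(params, enc$x0, cfg$steps)
  dvfs <- vector("list", cfg$steps)
  preds <- vector("list", cfg$steps)
  dec_caches <- if (keep_cache) vector("list", cfg$steps) else NULL
  for (t in seq_len(cfg$steps)) {
    dc <- rms_decode(params, cfg, ro$xs[[t]], enc$skips)
    dvfs[[t]] <- dc$dvf
    preds[[t]] <- cpp_warp_fwd(p0, dc$dvf, FALSE)
    if (keep_cache) dec_caches[[t]] <- dc$cache
  }
  out <- list(dvfs = dvfs, preds = preds, latents = ro$xs, x0 = enc$x0)
  if (keep_cache) {
    out$cache <- list(enc = enc, rollout = ro, dec = dec_caches, p0 = p0)
  }
  out
}

# Backward pass of the full network. `dpreds` and `ddvfs` are gradients on
# the warped images and on the displacement fields. Returns the parameter
# gradient tree (same shape as `params`).
rms_backward <- function(params, cfg, fwd, dpreds, ddvfs) {
  cache <- fwd$cache
  if (is.null(cache)) abort("forward pass was run without `keep_cache = TRUE`")
  grads <- tree_zeros_like(unclass(params))
  dskips <- lapply(cache$enc$skips, function(s) s * 0)
  dxs <- vector("list", cfg$steps)
  for (t in seq_len(cfg$steps)) {
    du <- ddvfs[[t]]
    if (!is.null(dpreds[[t]])) {
      wb <- cpp_warp_bwd(cache$p0, fwd$dvfs[[t]], dpreds[[t]])
      du <- du + wb$du
    }
    db <- rms_decode_bwd(params, cfg, du, cache$enc$skips, cache$dec[[t]])
    grads$head <- tree_map2(grads$head, db$grads$head, `+`)
    grads$fc_dec <- tree_map2(grads$fc_dec, db$grads$fc_dec, `+`)
    for (l in 1:cfg$levels) {
      grads$dec[[l]] <- tree_map2(grads$dec[[l]], db$grads$dec[[l]], `+`)
      dskips[[l]] <- dskips[[l]] + db$dskips[[l]]
    }
    dxs[[t]] <- db$dx
  }
  rb <- lstm_rollout_bwd(dxs, params$lstm, cache$rollout$cache)
  grads$lstm <- rb$grads
  eb <- rms_encode_bwd(params, cfg, rb$dx0, dskips, cache$enc$cache)
  grads$enc <- eb$enc
  grads$fc_enc <- eb$fc_enc
  grads
}
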