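# Two-layer one-to-many LSTM over latent vectors, with manual
# backpropagation through time. The initial latent x0 is the first input;
# each step's top-layer hidden state is both the emitted latent x_t and the
# input of the next step, until t = 9. Hidden size equals the latent size.

lstm_layer_init <- function(n) {
  k <- 1 / sqrt(n)
  list(
    w_ih = matrix(runif(n * 4 * n, -k, k), n, 4 * n),
    w_hh = matrix(runif(n * 4 * n, -k, k), n, 4 * n),
    b = runif(4 * n, -k, k)
  )
}

lstm_init <- function(n, layers = 2) {
  lapply(seq_len(layers), function(i) lstm_layer_init(n))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# One LSTM cell step. x, h, c are length-n vectors (treated as 1 x n rows).
lstm_cell_fwd <- function(x, h, c, p) {
  n <- length(h)
  a <- as.numeric(matrix(x, 1) %*% p$w_ih + matrix(h, 1) %*% p$w_hh + p$b)
  i <- sigmoid(a[1:n])
  f <- sigmoid(a[n + 1:n])
  g <- tanh(a[2 * n + 1:n])
  o <- sigmoid(a[3 * n + 1:n])
  c_new <- f * c + i * g
  tau <- tanh(c_new)
  h_new <- o * tau
  list(h = h_new, c = c_new,
       cache = list(x = x, h_prev = h, c_prev = c,
                    i = i, f = f, g = g, o = o, tau = tau))
}

# Backward through one cell. Weight gradients are not formed here: the
# per-step gate deltas `da` are collected and turned into two GEMMs per
# layer at the end of BPTT (see lstm_rollout_bwd), which dominates the cost
# otherwise. `tw_ih` / `tw_hh` are pre-transposed weights.
lstm_cell_bwd <- function(dh, dc, tw_ih, tw_hh, cache) {
  dco <- dc + dh * cache$o * (1 - cache$tau^2)
  do_ <- dh * cache$tau
  di <- dco * cache$g
  dg <- dco * cache$i
  df <- dco * cache$c_prev
  dc_prev <- dco * cache$f
  da <- c(
    di * cache$i * (1 - cache$i),
    df * cache$f * (1 - cache$f),
    dg * (1 - cache$g^2),
    do_ * cache$o * (1 - cache$o)
  )
  dam <- matrix(da, 1)
  list(
    dx = as.numeric(dam %*% tw_ih),
    dh_prev = as.numeric(dam %*% tw_hh),
    dc_prev = dc_prev,
    da = da
  )
}

# Autoregressive rollout: 9 steps, zero-initialized states.
lstm_rollout_fwd <- function(x0, params, steps = 9) {
  n <- length(x0)
  n_layers <- length(params)
  h <- lapply(seq_len(n_layers), function(i) rep(0, n))
  cc <- lapply(seq_len(n_layers), function(i) rep(0, n))
  xs <- vector("list", steps)
  caches <- vector("list", steps)
  x_in <- x0
  for (t in seq_len(steps)) {
    step_cache <- vector("list", n_layers)
    inp <- x_in
    for (l in seq_len(n_layers)) {
      out <- lstm_cell_fwd(inp, h[[l]], cc[[l]], params[[l]])
      h[[l]] <- out$h
      cc[[l]] <- out$c
      step_cache[[l]] <- out$cache
      inp <- out$h
    }
    xs[[t]] <- inp
    caches[[t]] <- step_cache
    x_in <- inp
  }
  list(xs = xs, caches = caches)
}

# BPTT. `dxs` holds external gradients on each emitted latent x_1..x_9.
# The autoregressive feedback (x_t feeding step t+1) is handled by carrying
# the step-input gradient back onto the previous step's output.
lstm_rollout_bwd <- function(dxs, params, caches) {
  steps <- length(dxs)
  n_layers <- length(params)
  n <- length(dxs[[1]])
  tw_ih <- lapply(params, function(p) t(p$w_ih))
  tw_hh <- lapply(params, function(p) t(p$w_hh))
  das <- lapply(seq_len(n_layers), function(i) matrix(0, steps, 4 * n))
  dh <- lapply(seq_len(n_layers), function(i) rep(0, n))
  dc <- lapply(seq_len(n_layers), function(i) rep(0, n))
  dfeedback <- rep(0, n)
  dx0 <- rep(0, n)
  for (t in rev(seq_len(steps))) {
    d_into <- dxs[[t]] + dfeedback
    dh[[n_layers]] <- dh[[n_layers]] + d_into
    d_lower <- NULL
    for (l in rev(seq_len(n_layers))) {
      if (!is.null(d_lower)) dh[[l]] <- dh[[l]] + d_lower
      out <- lstm_cell_bwd(dh[[l]], dc[[l]], tw_ih[[l]], tw_hh[[l]],
                           caches[[t]][[l]])
      das[[l]][t, ] <- out$da
      dh[[l]] <- out$dh_prev
      dc[[l]] <- out$dc_prev
      d_lower <- out$dx
    }
    if (t > 1) dfeedback <- d_lower else dx0 <- d_lower
  }
  grads <- lapply(seq_len(n_layers), function(l) {
    xs <- do.call(rbind, lapply(caches, function(st) st[[l]]$x))
    hs <- do.call(rbind, lapply(caches, function(st) st[[l]]$h_prev))
    list(
      w_ih = crossprod(xs, das[[l]]),
      w_hh = crossprod(hs, das[[l]]),
      b = colSums(das[[l]])
    )
  })
  list(dx0 = dx0, grads = grads)
}
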