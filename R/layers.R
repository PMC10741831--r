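# Differentiable layer primitives. Each layer has `*_init` (parameters),
# `*_fwd` (returns output + cache), `*_bwd` (returns input gradient +
# parameter gradients). Compiled kernels do the heavy lifting; shapes follow
# the conventions in src/ops.cpp.

conv_init <- function(cin, cout) {
  list(
    w = matrix(rnorm(9 * cin * cout, sd = sqrt(2 / (9 * cin))), 9 * cin, cout),
    b = rep(0, cout)
  )
}

conv_fwd <- function(x, p) {
  y <- cpp_conv3_fwd(x, p$w, p$b)
  list(y = y, x = x)
}

conv_bwd <- function(dy, p, cache) {
  g <- cpp_conv3_bwd(cache$x, p$w, dy)
  list(dx = g$dx, grads = list(w = g$dw, b = as.numeric(g$db)))
}

relu_fwd <- function(x) {
  y <- x
  y[y < 0] <- 0
  y
}

relu_bwd <- function(dy, y) {
  dy * (y > 0)
}

pool_fwd <- function(x) {
  out <- cpp_maxpool2_fwd(x)
  list(y = out$y, idx = out$idx, h = dim(x)[1], w = dim(x)[2])
}

pool_bwd <- function(dy, cache) {
  cpp_maxpool2_bwd(dy, cache$idx, cache$h, cache$w)
}

tconv_init <- function(cin, cout) {
  list(
    w = array(rnorm(4 * cin * cout, sd = sqrt(2 / (4 * cin))), c(cin, cout, 4)),
    b = rep(0, cout)
  )
}

tconv_fwd <- function(x, p) {
  list(y = cpp_tconv2_fwd(x, p$w, p$b), x = x)
}

tconv_bwd <- function(dy, p, cache) {
  g <- cpp_tconv2_bwd(cache$x, p$w, dy)
  list(dx = g$dx, grads = list(w = g$dw, b = as.numeric(g$db)))
}

# 1x1 convolution (pointwise channel mix), used for the displacement head.
conv1_init <- function(cin, cout) {
  list(w = matrix(rnorm(cin * cout, sd = sqrt(1 / cin)), cin, cout),
       b = rep(0, cout))
}

conv1_fwd <- function(x, p) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3])
  ym <- xm %*% p$w
  ym <- sweep(ym, 2, p$b, "+")
  list(y = array(ym, c(d[1], d[2], ncol(p$w))), x = x)
}

conv1_bwd <- function(dy, p, cache) {
  d <- dim(cache$x)
  dym <- matrix(dy, d[1] * d[2], dim(dy)[3])
  xm <- matrix(cache$x, d[1] * d[2], d[3])
  list(
    dx = array(dym %*% t(p$w), d),
    grads = list(w = t(xm) %*% dym, b = colSums(dym))
  )
}

fc_init <- function(nin, nout) {
  list(w = matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout),
       b = rep(0, nout))
}

fc_fwd <- function(x, p) {
  list(y = as.numeric(x %*% p$w + p$b), x = x)
}

fc_bwd <- function(dy, p, cache) {
  dy <- as.numeric(dy)
  list(
    dx = as.numeric(p$w %*% dy),
    grads = list(w = outer(as.numeric(cache$x), dy), b = dy)
  )
}

# ---- parameter-tree helpers ------------------------------------------------

# Apply `f` elementwise across two parallel nested lists of numeric arrays.
tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- lapply(seq_along(a), function(i) tree_map2(a[[i]], b[[i]], f))
    names(out) <- names(a)
    out
  } else {
    f(a, b)
  }
}

tree_map <- function(a, f) {
  if (is.list(a)) {
    out <- lapply(a, tree_map, f = f)
    names(out) <- names(a)
    out
  } else {
    f(a)
  }
}

tree_zeros_like <- function(a) tree_map(a, function(x) x * 0)

# Flatten a parameter tree to a single numeric vector (for checks/hashing).
tree_unlist <- function(a) {
  if (is.list(a)) unlist(lapply(a, tree_unlist), use.names = FALSE) else as.numeric(a)
}
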