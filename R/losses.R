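# Training losses: displacement smoothness, image MSE, and local
# (windowed) normalized cross-correlation, plus their analytic gradients.

# Summed-area-table box filter: at each pixel, the sum of `m` over the
# centred (2r+1)^2 window, out-of-image contributions being zero.
box_sum <- function(m, r) {
  h <- nrow(m)
  w <- ncol(m)
  s <- apply(m, 2, cumsum)
  s <- t(apply(s, 1, cumsum))
  s <- rbind(0, cbind(0, s))
  i2 <- pmin(seq_len(h) + r, h) + 1
  i1 <- pmax(seq_len(h) - r, 1)
  j2 <- pmin(seq_len(w) + r, w) + 1
  j1 <- pmax(seq_len(w) - r, 1)
  s[i2, j2] - s[i1, j2] - s[i2, j1] + s[i1, j1]
}

#' Displacement-field smoothness penalty
#'
#' Forward finite differences of each displacement channel along rows and
#' columns (zero at the trailing edge), squared, summed over pixels, both
#' channels and all phases, divided by `2N` with `N` the number of pixels
#' per field.
#'
#' @param dvfs list of `(H, W, 2)` displacement arrays.
#' @return Non-negative scalar.
#' @export
smoothness_loss <- function(dvfs) {
  if (!is.list(dvfs)) dvfs <- list(dvfs)
  n <- prod(dim(dvfs[[1]])[1:2])
  total <- 0
  for (u in dvfs) {
    for (ch in 1:2) {
      d <- u[, , ch]
      dr <- rbind(diff(d), 0)
      dc <- cbind(t(diff(t(d))), 0)
      total <- total + sum(dr^2) + sum(dc^2)
    }
  }
  total / (2 * n)
}

# Gradient of smoothness_loss w.r.t. each field (list matching `dvfs`).
smoothness_loss_grad <- function(dvfs) {
  n <- prod(dim(dvfs[[1]])[1:2])
  lapply(dvfs, function(u) {
    g <- array(0, dim(u))
    for (ch in 1:2) {
      d <- u[, , ch]
      dr <- rbind(diff(d), 0)
      dc <- cbind(t(diff(t(d))), 0)
      g[, , ch] <- (rbind(0, dr[-nrow(dr), ]) - dr +
                      cbind(0, dc[, -ncol(dc)]) - dc) / n
    }
    g
  })
}

#' Mean-squared-error image loss
#'
#' Per-pixel mean of the squared difference, summed over the nine phases
#' (the per-pixel mean keeps loss weights resolution independent).
#'
#' @param pred,gt lists of congruent H x W matrices.
#' @return Non-negative scalar; zero iff the sequences are identical.
#' @export
mse_loss <- function(pred, gt) {
  check_pair(pred, gt)
  sum(vapply(seq_along(pred), function(t) mean((pred[[t]] - gt[[t]])^2),
             numeric(1)))
}

mse_loss_grad <- function(pred, gt) {
  n <- length(pred[[1]])
  lapply(seq_along(pred), function(t) 2 * (pred[[t]] - gt[[t]]) / n)
}

check_pair <- function(pred, gt) {
  if (!is.list(pred)) abort("`pred` must be a list of matrices")
  if (length(pred) != length(gt)) abort("`pred` and `gt` differ in length")
  ok <- all(vapply(seq_along(pred),
                   function(t) identical(dim(pred[[t]]), dim(gt[[t]])),
                   logical(1)))
  if (!ok) abort("`pred` and `gt` shapes differ")
  invisible(TRUE)
}

# Windowed NCC internals for one phase: returns per-pixel squared local
# correlation plus the quantities needed by the gradient. Windows are
# clipped at the image border, with per-pixel counts, so local statistics
# are exact (and positive affine maps give correlation 1 everywhere).
ncc_terms <- function(p, g, r, eps) {
  n_win <- box_sum(matrix(1, nrow(p), ncol(p)), r)
  sg <- box_sum(g, r)
  sp <- box_sum(p, r)
  cross <- box_sum(g * p, r) - sg * sp / n_win
  varg <- box_sum(g * g, r) - sg^2 / n_win
  varp <- box_sum(p * p, r) - sp^2 / n_win
  varg <- pmax(varg, 0)
  varp <- pmax(varp, 0)
  den <- varg * varp + eps
  list(cc = cross^2 / den, cross = cross, varg = varg, varp = varp,
       den = den, sg = sg, sp = sp, n_win = n_win)
}

#' Local normalized cross-correlation similarity
#'
#' For every pixel, means over a sliding square window are subtracted and
#' the squared local correlation
#' `(sum cov)^2 / (sum var_gt * sum var_pred + eps)` is computed; the value
#' is averaged over pixels and phases, so it lies in \[0, 1\] up to `eps`.
#' Higher is better (this is a similarity, subtracted in [total_loss()]).
#'
#' @param pred,gt lists of congruent H x W matrices.
#' @param window odd window size >= 3 (default 9).
#' @param eps denominator guard (default 1e-5).
#' @return Scalar in \[0, 1\] (up to `eps`).
#' @export
ncc_loss <- function(pred, gt, window = 9, eps = 1e-5) {
  check_pair(pred, gt)
  if (window %% 2 != 1 || window < 3) abort("`window` must be odd and >= 3")
  if (window > min(dim(pred[[1]]))) abort("`window` larger than the image")
  r <- (window - 1) %/% 2
  mean(vapply(seq_along(pred), function(t) {
    mean(ncc_terms(pred[[t]], gt[[t]], r, eps)$cc)
  }, numeric(1)))
}

# Gradient of ncc_loss w.r.t. `pred` (list matching pred).
ncc_loss_grad <- function(pred, gt, window = 9, eps = 1e-5) {
  r <- (window - 1) %/% 2
  n_pix <- length(pred[[1]])
  n_phase <- length(pred)
  lapply(seq_along(pred), function(t) {
    p <- pred[[t]]
    g <- gt[[t]]
    tm <- ncc_terms(p, g, r, eps)
    alpha <- 2 * tm$cross / tm$den
    ratio <- tm$cross^2 * tm$varg / tm$den^2
    beta <- -alpha * tm$sg / tm$n_win + 2 * ratio * tm$sp / tm$n_win
    gamma <- -2 * ratio
    (g * box_sum(alpha, r) + box_sum(beta, r) + p * box_sum(gamma, r)) /
      (n_pix * n_phase)
  })
}

#' Combined training loss
#'
#' `total = w_smooth * smooth + w_mse * mse - w_ncc * ncc`: the NCC term is
#' a similarity, so it enters with a negative sign under minimization.
#'
#' @param dvfs list of 9 displacement fields.
#' @param pred,gt lists of 9 predicted / target images.
#' @param weights named numeric: `smooth`, `mse`, `ncc` (defaults 1, 1, 1).
#' @param ncc_window window for [ncc_loss()].
#' @return A `loss_breakdown` list: `smooth`, `mse`, `ncc`, `total`.
#' @export
total_loss <- function(dvfs, pred, gt,
                       weights = c(smooth = 1, mse = 1, ncc = 1),
                       ncc_window = 9) {
  s <- smoothness_loss(dvfs)
  m <- mse_loss(pred, gt)
  n <- ncc_loss(pred, gt, window = ncc_window)
  structure(
    list(smooth = s, mse = m, ncc = n,
         total = weights[["smooth"]] * s + weights[["mse"]] * m -
           weights[["ncc"]] * n),
    class = "loss_breakdown"
  )
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("<loss> total %.5f  (smooth %.5f, mse %.5f, ncc %.4f)\n",
              x$total, x$smooth, x$mse, x$ncc))
  invisible(x)
}

# Gradients of total_loss w.r.t. fields and predicted images.
total_loss_grad <- function(dvfs, pred, gt,
                            weights = c(smooth = 1, mse = 1, ncc = 1),
                            ncc_window = 9) {
  dsm <- smoothness_loss_grad(dvfs)
  dm <- mse_loss_grad(pred, gt)
  dn <- ncc_loss_grad(pred, gt, window = ncc_window)
  list(
    ddvfs = lapply(dsm, function(g) weights[["smooth"]] * g),
    dpreds = lapply(seq_along(pred), function(t) {
      weights[["mse"]] * dm[[t]] - weights[["ncc"]] * dn[[t]]
    })
  )
}
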