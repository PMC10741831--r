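test_that("smoothness loss matches hand-computed finite differences", {
  # constant fields have zero gradient energy
  const_fields <- lapply(1:9, function(t) array(3.7, c(8, 8, 2)))
  expect_equal(smoothness_loss(const_fields), 0)

  # single 2x2 field, u_x = [[0,1],[0,1]] by column, u_y = 0:
  # row-direction diffs are 0, column-direction diffs are 1 at two pixels
  u <- array(0, c(2, 2, 2))
  u[, , 1] <- matrix(c(0, 0, 1, 1), 2, 2)
  expect_equal(smoothness_loss(list(u)), (1^2 + 1^2) / (2 * 4))

  # quadratic scaling
  fields <- lapply(1:3, function(t) random_smooth_dvf(8, 8))
  expect_equal(smoothness_loss(lapply(fields, function(u) 3 * u)),
               9 * smoothness_loss(fields))
})

test_that("mse loss follows the direct formula", {
  gt <- lapply(1:9, function(t) matrix(0.5, 1, 1))
  pred <- lapply(gt, function(m) m + 0.1)
  expect_equal(mse_loss(pred, gt), 9 * 0.01)
  expect_equal(mse_loss(gt, gt), 0)

  set.seed(4)
  a <- lapply(1:9, function(t) matrix(runif(64), 8, 8))
  b <- lapply(1:9, function(t) matrix(runif(64), 8, 8))
  oracle <- 0
  for (t in 1:9) {
    for (i in 1:8) for (j in 1:8) {
      oracle <- oracle + (a[[t]][i, j] - b[[t]][i, j])^2 / 64
    }
  }
  expect_equal(mse_loss(a, b), oracle, tolerance = 1e-7)
  expect_error(mse_loss(a, lapply(1:9, function(t) matrix(0, 4, 4))), "shape")
})

test_that("local NCC behaves as a correlation similarity", {
  set.seed(8)
  img <- lapply(1:9, function(t) matrix(runif(64 * 64), 64, 64))
  expect_equal(ncc_loss(img, img), 1, tolerance = 1e-3)
  # invariant to positive affine rescaling
  aff <- lapply(img, function(m) 2.5 * m + 0.3)
  expect_equal(ncc_loss(aff, img), 1, tolerance = 1e-3)
  # independent noise carries almost no local correlation
  case <- fixture_case()
  noise <- lapply(1:9, function(t) matrix(runif(64 * 64), 64, 64))
  expect_lt(ncc_loss(noise, case$images[2:10], window = 9), 0.2)
  expect_error(ncc_loss(img, img, window = 8), "odd")
  expect_error(ncc_loss(img, img, window = 129), "larger")
})

test_that("total loss combines components with the documented signs", {
  case <- fixture_case()
  gt <- case$images[2:10]
  dvfs <- case$gt_dvfs
  pred <- lapply(1:9, function(t) spatial_transform(case$images[[1]], dvfs[[t]]))
  lb <- total_loss(dvfs, pred, gt)
  expect_equal(lb$total, lb$smooth + lb$mse - lb$ncc)
  # weights select components
  lb_mse <- total_loss(dvfs, pred, gt, weights = c(smooth = 0, mse = 1, ncc = 0))
  expect_equal(lb_mse$total, lb$mse)
  # perfect prediction of a textured sequence with zero fields:
  # total = -ncc = -1 (best case)
  set.seed(9)
  tex <- lapply(1:9, function(t) matrix(runif(64 * 64), 64, 64))
  zero <- lapply(1:9, function(t) array(0, c(64, 64, 2)))
  lb0 <- total_loss(zero, tex, tex)
  expect_equal(lb0$smooth, 0)
  expect_equal(lb0$mse, 0)
  expect_equal(lb0$total, -lb0$ncc)
  expect_equal(lb0$ncc, 1, tolerance = 1e-3)
})

test_that("losses are permutation-equivariant over phases", {
  case <- fixture_case()
  gt <- case$images[2:10]
  pred <- lapply(1:9, function(t) spatial_transform(case$images[[1]], case$gt_dvfs[[t]]))
  perm <- c(3, 1, 9, 5, 4, 2, 8, 6, 7)
  expect_equal(mse_loss(pred[perm], gt[perm]), mse_loss(pred, gt))
  expect_equal(ncc_loss(pred[perm], gt[perm]), ncc_loss(pred, gt))
  expect_equal(smoothness_loss(case$gt_dvfs[perm]), smoothness_loss(case$gt_dvfs))
})

test_that("loss gradients match finite differences", {
  set.seed(5)
  h <- 12
  gt <- lapply(1:2, function(t) matrix(runif(h * h), h, h))
  pred <- lapply(1:2, function(t) matrix(runif(h * h), h, h))
  dvfs <- lapply(1:2, function(t) random_smooth_dvf(h, h, amp = 1))
  eps <- 1e-6

  g <- rmsim:::ncc_loss_grad(pred, gt, window = 5)
  for (k in 1:4) {
    i <- sample(h, 1); j <- sample(h, 1); t <- sample(2, 1)
    pp <- pred; pp[[t]][i, j] <- pp[[t]][i, j] + eps
    pm <- pred; pm[[t]][i, j] <- pm[[t]][i, j] - eps
    num <- (ncc_loss(pp, gt, window = 5) - ncc_loss(pm, gt, window = 5)) / (2 * eps)
    expect_equal(g[[t]][i, j], num, tolerance = 1e-4)
  }

  gs <- rmsim:::smoothness_loss_grad(dvfs)
  for (k in 1:4) {
    i <- sample(h, 1); j <- sample(h, 1); t <- sample(2, 1); ch <- sample(2, 1)
    up <- dvfs; up[[t]][i, j, ch] <- up[[t]][i, j, ch] + eps
    um <- dvfs; um[[t]][i, j, ch] <- um[[t]][i, j, ch] - eps
    num <- (smoothness_loss(up) - smoothness_loss(um)) / (2 * eps)
    expect_equal(gs[[t]][i, j, ch], num, tolerance = 1e-4)
  }
})

test_that("minimizing the loss over a free field solves a toy translation", {
  # 16x16 image with a bright blob shifted two pixels down; gradient descent
  # on the displacement alone must drive the image error toward zero
  g <- rmsim:::pixel_grid(16, 16)
  blob <- function(cy) exp(-((g$y - cy)^2 + (g$x - 7)^2) / 6)
  src <- blob(6)
  tgt <- blob(8)
  u <- list(array(0, c(16, 16, 2)))
  weights <- c(smooth = 0.05, mse = 1, ncc = 0)
  mse0 <- mse_loss(list(spatial_transform(src, u[[1]])), list(tgt))
  for (it in 1:300) {
    pred <- list(spatial_transform(src, u[[1]]))
    lg <- rmsim:::total_loss_grad(u, pred, list(tgt), weights, ncc_window = 5)
    wb <- rmsim:::cpp_warp_bwd(src, u[[1]], lg$dpreds[[1]])
    u[[1]] <- u[[1]] - 200 * (lg$ddvfs[[1]] + wb$du)
  }
  mse_final <- mse_loss(list(spatial_transform(src, u[[1]])), list(tgt))
  expect_lt(mse_final, mse0 / 20)
})
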