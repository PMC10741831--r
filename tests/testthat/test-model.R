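test_that("encoder produces the documented latent and skip shapes", {
  cfg <- rms_config(image_size = 64, base_channels = 16, latent = 512)
  params <- rms_init_params(cfg, 1)
  p0 <- matrix(runif(64 * 64), 64, 64)
  enc <- rms_encode(params, cfg, p0)
  expect_length(enc$x0, 512)
  expect_equal(vapply(enc$skips, function(s) dim(s)[1], numeric(1)),
               c(64, 32, 16, 8))
  expect_equal(vapply(enc$skips, function(s) dim(s)[3], numeric(1)),
               c(16, 32, 64, 128))
  # determinism with fixed weights
  enc2 <- rms_encode(params, cfg, p0)
  expect_identical(enc$x0, enc2$x0)
  # sizes not divisible by 16 are rejected
  expect_error(rms_config(image_size = 50), "divisible")
  expect_error(rms_encode(params, cfg, matrix(0, 48, 48)), "match")
})

test_that("latent rollout is a pure 9-step autoregression", {
  cfg <- tiny_config()
  params <- rms_init_params(cfg, 2)
  x0 <- rnorm(cfg$latent)
  ro <- rms_rollout(params, x0)
  expect_length(ro$xs, 9)
  expect_true(all(lengths(ro$xs) == cfg$latent))
  # pure function of weights and input
  ro2 <- rms_rollout(params, x0)
  expect_identical(ro$xs, ro2$xs)
  # different input, different sequence
  ro3 <- rms_rollout(params, x0 + 1)
  expect_false(identical(ro$xs[[1]], ro3$xs[[1]]))
})

test_that("decoder emits bounded displacement fields through the skips", {
  cfg <- tiny_config()
  params <- rms_init_params(cfg, 3)
  p0 <- matrix(runif(32 * 32), 32, 32)
  enc <- rms_encode(params, cfg, p0)
  dc <- rms_decode(params, cfg, enc$x0, enc$skips)
  expect_equal(dim(dc$dvf), c(32, 32, 2))
  expect_true(all(abs(dc$dvf) <= cfg$max_disp))
  # zero final layer gives the identity field
  params$head$w[] <- 0
  params$head$b[] <- 0
  dc0 <- rms_decode(params, cfg, enc$x0, enc$skips)
  expect_true(all(dc0$dvf == 0))
})

test_that("spatial transformer matches the brute-force sampling equation", {
  # identity warp
  img <- matrix(runif(256), 16, 16)
  zero <- array(0, c(16, 16, 2))
  expect_identical(spatial_transform(img, zero), img)

  # integer column shift with border clamping
  shift <- array(0, c(16, 16, 2))
  shift[, , 1] <- 3
  shifted <- spatial_transform(img, shift)
  expect_equal(shifted[, 1:13], img[, 4:16])
  expect_equal(shifted[, 14:16], img[, c(16, 16, 16)])

  # oracle equivalence on random smooth cases
  set.seed(21)
  for (k in 1:20) {
    im <- matrix(runif(256), 16, 16)
    u <- random_smooth_dvf(16, 16, amp = runif(1, 0.5, 3))
    expect_lt(max(abs(spatial_transform(im, u) - warp_oracle(im, u))), 1e-5)
  }
  expect_error(spatial_transform(img, zero + NA), "finite")
})

test_that("warping is linear in the image and binary for masks", {
  set.seed(31)
  u <- random_smooth_dvf(16, 16, amp = 2)
  i1 <- matrix(runif(256), 16, 16)
  i2 <- matrix(runif(256), 16, 16)
  lhs <- spatial_transform(2 * i1 + 3 * i2, u)
  rhs <- 2 * spatial_transform(i1, u) + 3 * spatial_transform(i2, u)
  expect_lt(max(abs(lhs - rhs)), 1e-6)

  mask <- matrix(as.numeric(matrix(runif(256), 16, 16) > 0.5), 16, 16)
  wm <- spatial_transform(mask, u, interp = "nearest")
  expect_true(all(wm %in% c(0, 1)))
})

test_that("the full forward pass composes the stages", {
  cfg <- tiny_config()
  params <- rms_init_params(cfg, 4)
  p0 <- fixture_case()$images[[1]]
  p0 <- rmsim:::resize_bilinear(p0, 32, 32)
  fwd <- rms_forward(params, cfg, p0)
  expect_length(fwd$dvfs, 9)
  expect_length(fwd$preds, 9)
  expect_true(all(vapply(fwd$preds, function(p) all(dim(p) == c(32, 32)),
                         logical(1))))
  # deterministic given fixed weights
  fwd2 <- rms_forward(params, cfg, p0)
  expect_identical(fwd$preds, fwd2$preds)
  # zeroed head: every prediction is the input
  params$head$w[] <- 0
  params$head$b[] <- 0
  fwd0 <- rms_forward(params, cfg, p0)
  for (t in 1:9) expect_equal(fwd0$preds[[t]], p0)
})

test_that("analytic parameter gradients agree with finite differences", {
  cfg <- tiny_config()
  params <- rms_init_params(cfg, 5)
  set.seed(6)
  p0 <- matrix(runif(32 * 32), 32, 32)
  gt <- lapply(1:9, function(t) matrix(runif(32 * 32), 32, 32))
  lossfn <- function(p) {
    fwd <- rms_forward(p, cfg, p0)
    total_loss(fwd$dvfs, fwd$preds, gt, ncc_window = 5)$total
  }
  fwd <- rms_forward(params, cfg, p0, keep_cache = TRUE)
  lg <- rmsim:::total_loss_grad(fwd$dvfs, fwd$preds, gt, ncc_window = 5)
  grads <- rmsim:::rms_backward(params, cfg, fwd, lg$dpreds, lg$ddvfs)
  eps <- 1e-5
  probe <- list(
    list(c("head", "w"), 2),
    list(list("lstm", 1L, "w_hh"), 11),
    list(list("dec", 2L, "conv1", "w"), 5),
    list(list("enc", 1L, "conv2", "w"), 3),
    list(c("fc_enc", "w"), 101)
  )
  get_leaf <- function(lst, path) Reduce(function(a, b) a[[b]], path, lst)
  set_leaf <- function(lst, path, v) {
    if (length(path) == 1) {
      lst[[path[[1]]]] <- v
      return(lst)
    }
    lst[[path[[1]]]] <- set_leaf(lst[[path[[1]]]], path[-1], v)
    lst
  }
  for (pr in probe) {
    leaf <- get_leaf(params, pr[[1]])
    i <- pr[[2]]
    lp <- leaf; lp[i] <- lp[i] + eps
    lm <- leaf; lm[i] <- lm[i] - eps
    num <- (lossfn(set_leaf(params, pr[[1]], lp)) -
              lossfn(set_leaf(params, pr[[1]], lm))) / (2 * eps)
    ana <- get_leaf(grads, pr[[1]])[i]
    expect_equal(ana, num, tolerance = 1e-3)
  }
})
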