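# Shared fixtures and independent oracles. Expensive objects are computed
# once per test session and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# A default-spec phantom case reused across test files.
fixture_case <- function(seed = 7) {
  cached(paste0("case_", seed), render_phantom_sequence(phantom_spec(), seed))
}

# Small 3D phantom for the preprocessing path.
fixture_volume_case <- function(seed = 3) {
  cached(paste0("vol_", seed), synth_volume_4d(phantom_spec(), seed))
}

# A tiny network configuration for fast model tests.
tiny_config <- function() {
  rms_config(image_size = 32, base_channels = 2, latent = 16)
}

# A small on-disk dataset shared by training tests.
fixture_dataset <- function(n_train = 2, n_test = 1) {
  key <- sprintf("ds_%d_%d", n_train, n_test)
  cached(key, {
    dir <- file.path(tempdir(), paste0("rmsim_", key))
    if (!dir.exists(dir)) {
      # 32 px frames keep the physical field of view by doubling the spacing
      build_phantom_dataset(dir, n_train, n_test,
                            spec = phantom_spec(image_size = c(32, 32),
                                                pixel_spacing_mm = 5),
                            seed = 11)
    }
    dir
  })
}

# ---- independent oracles ---------------------------------------------------

# Brute-force double-loop bilinear sampling (the spatial-transformer
# equation applied literally).
warp_oracle <- function(img, u) {
  h <- nrow(img)
  w <- ncol(img)
  out <- matrix(0, h, w)
  for (i in 1:h) {
    for (j in 1:w) {
      sr <- min(max(i - 1 + u[i, j, 2], 0), h - 1)
      sc <- min(max(j - 1 + u[i, j, 1], 0), w - 1)
      r0 <- max(min(floor(sr), h - 2), 0)
      c0 <- max(min(floor(sc), w - 2), 0)
      fr <- sr - r0
      fc <- sc - c0
      out[i, j] <- (1 - fr) * (1 - fc) * img[r0 + 1, c0 + 1] +
        fr * (1 - fc) * img[r0 + 2, c0 + 1] +
        (1 - fr) * fc * img[r0 + 1, c0 + 2] +
        fr * fc * img[r0 + 2, c0 + 2]
    }
  }
  out
}

# Per-pixel 2x2 determinant of the deformation Jacobian, loops and
# explicit finite differences only.
jacobian_oracle <- function(u) {
  h <- dim(u)[1]
  w <- dim(u)[2]
  d1 <- function(v, i) {
    if (i == 1) v[2] - v[1]
    else if (i == length(v)) v[i] - v[i - 1]
    else (v[i + 1] - v[i - 1]) / 2
  }
  det_j <- matrix(0, h, w)
  for (i in 1:h) {
    for (j in 1:w) {
      dux_dx <- d1(u[i, , 1], j)
      duy_dx <- d1(u[i, , 2], j)
      dux_dy <- d1(u[, j, 1], i)
      duy_dy <- d1(u[, j, 2], i)
      det_j[i, j] <- (1 + dux_dx) * (1 + duy_dy) - dux_dy * duy_dx
    }
  }
  det_j
}

# Per-ray voxel summation for parallel-beam projection along the depth
# axis (axis 3).
raycast_oracle <- function(volume, mask, step_mm = 1) {
  d <- dim(volume)
  out <- matrix(0, d[1], d[2])
  for (i in 1:d[1]) {
    for (j in 1:d[2]) {
      s <- 0
      for (k in 1:d[3]) {
        if (mask[i, j, k] > 0) {
          s <- s + max(0, (volume[i, j, k] + 1000) / 1000)
        }
      }
      out[i, j] <- s * step_mm
    }
  }
  out
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

random_smooth_dvf <- function(h, w, amp = 2) {
  g <- expand.grid(y = seq(0, 1, length.out = h), x = seq(0, 1, length.out = w))
  f <- function() {
    amp * matrix(sin(2 * pi * (runif(1) + runif(1, 0.5, 1.5) * g$x +
                                 runif(1, 0.5, 1.5) * g$y)), h, w)
  }
  u <- array(0, c(h, w, 2))
  u[, , 1] <- f()
  u[, , 2] <- f()
  u
}
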