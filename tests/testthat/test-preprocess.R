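test_that("threshold segmentation recovers the phantom's own lungs", {
  vol <- fixture_volume_case()
  seg <- segment_lungs(vol$volumes[[1]], threshold_hu = -400)
  expect_gt(jaccard(seg > 0, vol$lung_masks[[1]] > 0), 0.99)
  # left/right labels agree with the generator's
  expect_gt(jaccard(seg == 1, vol$lung_masks[[1]] == 1), 0.99)
  # degenerate inputs
  expect_error(segment_lungs(array(0, c(32, 32, 32))), "no lung")
  expect_error(segment_lungs(vol$volumes[[1]], threshold_hu = -2000), "no lung")
})

test_that("parallel ray casting is an exact masked line integral", {
  # uniform attenuation slab: covered pixels equal a * k exactly
  vol <- array(-1000, c(8, 8, 6))         # attenuation 0
  vol[3:5, 2:7, 2:4] <- 0                 # attenuation 1, 3 voxels thick
  mask <- array(1, dim(vol))
  drr <- ray_cast_drr(vol, mask, projection_geometry(step_mm = 1))
  expect_equal(drr[4, 3], 3)
  expect_equal(drr[1, 1], 0)

  # oracle equivalence on a phantom volume
  vcase <- fixture_volume_case()
  v <- vcase$volumes[[1]]
  m <- vcase$lung_masks[[1]]
  expect_lt(max(abs(ray_cast_drr(v, m) - raycast_oracle(v, m))), 1e-6)

  # all-zero attenuation projects to zero
  expect_true(all(ray_cast_drr(array(-1000, c(8, 8, 4)),
                               array(1, c(8, 8, 4))) == 0))
})

test_that("ray casting is linear in attenuation before normalization", {
  # HU adds are not linear, but attenuation is: compare via masks
  set.seed(2)
  a1 <- array(runif(8 * 8 * 5, 0, 500), c(8, 8, 5))
  a2 <- array(runif(8 * 8 * 5, 0, 500), c(8, 8, 5))
  m <- array(1, c(8, 8, 5))
  g <- projection_geometry()
  # (a + 1000 HU offsets cancel when comparing sums of attenuation maps)
  d1 <- ray_cast_drr(a1, m, g)
  d2 <- ray_cast_drr(a2, m, g)
  d12 <- ray_cast_drr(a1 + a2 + 1000, m, g)
  expect_lt(max(abs(d12 - (d1 + d2))), 1e-6)
})

test_that("bounding boxes cover the union of phases and clip at edges", {
  m <- matrix(0, 20, 20)
  m1 <- m; m1[6, 8] <- 1
  expect_equal(unname(lung_bounding_box(list(m1), 0)), c(5, 7, 6, 8))

  m2 <- m; m2[11:21 - 1, 3:5] <- 1   # rows 10..20 0-based 9..19
  m3 <- m; m3[16:20, 3:5] <- 1
  bb <- lung_bounding_box(list(m2, m3), 0)
  expect_equal(unname(bb[c(1, 3)]), c(9, 20))

  # margin clipped at the frame
  m4 <- m; m4[1, 20] <- 1
  bb4 <- lung_bounding_box(list(m4), 2)
  expect_equal(unname(bb4), c(0, 17, 3, 20))
  expect_error(lung_bounding_box(list(m)), "empty")

  # monotonicity: adding pixels never shrinks the box
  bb_union <- lung_bounding_box(list(m1, m2))
  expect_true(bb_union[1] <= lung_bounding_box(list(m1))[1])
  expect_true(bb_union[3] >= lung_bounding_box(list(m1))[3])
})

test_that("crop_and_normalize rescales into [0, 1] without moving structure", {
  img <- matrix(runif(64 * 64, 2, 7), 64, 64)
  out <- crop_and_normalize(img, c(0, 0, 64, 64), c(64, 64))
  expect_equal(range(out), c(0, 1))
  expect_equal(which.max(out), which.max(img))

  # constant image maps to zeros by convention
  expect_true(all(crop_and_normalize(matrix(5, 8, 8), c(0, 0, 8, 8), c(8, 8)) == 0))

  # 2x downscale equals the direct bilinear formula
  chk <- matrix(rep(c(0, 1), 16), 16, 16)
  small <- rmsim:::resize_bilinear(chk, 8, 8)
  oracle <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    sr <- (i - 1) * 15 / 7
    sc <- (j - 1) * 15 / 7
    r0 <- min(floor(sr), 14); c0 <- min(floor(sc), 14)
    fr <- sr - r0; fc <- sc - c0
    oracle[i, j] <- (1 - fr) * (1 - fc) * chk[r0 + 1, c0 + 1] +
      fr * (1 - fc) * chk[r0 + 2, c0 + 1] +
      (1 - fr) * fc * chk[r0 + 1, c0 + 2] +
      fr * fc * chk[r0 + 2, c0 + 2]
  }
  expect_lt(max(abs(small - oracle)), 1e-6)
  expect_error(crop_and_normalize(img, c(5, 5, 5, 9), c(8, 8)), "degenerate")
})

test_that("the full preprocessing chain yields a valid phase sequence", {
  vol <- fixture_volume_case()
  ps <- preprocess_case(vol$volumes, out_size = c(32, 32),
                        spacing_mm = vol$spacing_mm)
  expect_s3_class(ps, "phase_sequence")
  expect_length(ps$phases, 10)
  expect_true(all(vapply(ps$phases, function(p) all(dim(p) == c(32, 32)),
                         logical(1))))
  expect_true(all(vapply(ps$phases, function(p) min(p) >= 0 && max(p) <= 1,
                         logical(1))))
  expect_equal(ps$eoi_phase, 1L)

  # caller owns phase order: a shuffled input stays shuffled
  perm <- c(2, 1, 3:10)
  ps_perm <- preprocess_case(vol$volumes[perm], out_size = c(32, 32))
  expect_equal(ps_perm$phases[[1]], ps$phases[[2]])

  expect_error(preprocess_case(vol$volumes[1:9]), "10")

  # exhale shrinks the projected lung area
  g <- projection_geometry()
  area <- function(i) sum(rmsim:::project_mask(segment_lungs(vol$volumes[[i]]), g) > 0)
  expect_lt(area(6), area(1))
})

test_that("phantom volumes round-trip through NIfTI", {
  vol <- fixture_volume_case()
  path <- tempfile(fileext = ".nii.gz")
  write_volume_nifti(vol$volumes[[1]], path)
  back <- read_volume_nifti(path)
  expect_equal(dim(back), dim(vol$volumes[[1]]))
  expect_equal(back, vol$volumes[[1]], tolerance = 1e-6, ignore_attr = TRUE)
  unlink(path)
})

test_that("perspective projection approaches the parallel limit", {
  vol <- fixture_volume_case()
  v <- vol$volumes[[1]]
  m <- vol$lung_masks[[1]]
  par <- ray_cast_drr(v, m, projection_geometry())
  per <- ray_cast_drr(v, m, projection_geometry(mode = "perspective",
                                                source_distance_mm = 1e6))
  expect_lt(max(abs(par - per)) / max(par), 0.05)
  expect_error(ray_cast_drr(v, m, projection_geometry(mode = "perspective",
                                                      source_distance_mm = 10)),
               "exceed")
})
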