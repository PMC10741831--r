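test_that("anatomy synthesis is deterministic and anatomically labeled", {
  spec <- phantom_spec(nodule_count = 0, noise_sigma = 0)
  a1 <- synth_anatomy_2d(spec, 42)
  a2 <- synth_anatomy_2d(spec, 42)
  expect_identical(a1$image, a2$image)
  expect_identical(a1$mask, a2$mask)

  # two connected lung components, left centroid left of right centroid
  lab <- a1$mask
  expect_setequal(setdiff(unique(as.vector(lab)), 0L), c(1L, 2L))
  expect_lt(mean(col(lab)[lab == 1]), mean(col(lab)[lab == 2]))
  expect_true(all(a1$image >= 0 & a1$image <= 1))
})

test_that("small frames are rejected", {
  expect_error(phantom_spec(image_size = c(16, 16)), "32")
})

test_that("nodules add exactly the requested number of disc supports", {
  spec0 <- phantom_spec(nodule_count = 0, noise_sigma = 0)
  spec2 <- phantom_spec(nodule_count = 2, noise_sigma = 0)
  a0 <- synth_anatomy_2d(spec0, 5)
  a2 <- synth_anatomy_2d(spec2, 5)
  diff <- abs(a2$image - a0$image) > 1e-9
  lab <- rmsim:::label_components(diff)
  expect_equal(max(lab), 2)
  # discs sit inside lungs and are brighter than the lung field
  expect_true(all(a0$mask[diff] > 0))
  expect_true(all(a2$image[diff] >= a0$image[diff]))
})

test_that("cycle fields follow the sin^2 phase weighting", {
  spec <- phantom_spec()
  anatomy <- synth_anatomy_2d(spec, 9)
  dvfs <- synth_cycle_dvfs(spec, anatomy, 9)
  amp <- attr(dvfs, "amplitude_px")
  w <- sin(pi * (1:9) / 10)^2
  # phase ordering of the weights: start and end move least
  expect_lt(w[1], w[4])
  expect_lt(w[9], w[5])
  for (t in c(1, 5, 9)) {
    expect_equal(max(abs(dvfs[[t]][, , 2])), amp * w[t], tolerance = 0.05)
  }
  # vertical motion shrinks toward the apex
  u5 <- dvfs[[5]][, , 2]
  expect_lt(max(u5[5, ]), max(u5[60, ]))
})

test_that("zero amplitude freezes the cycle", {
  spec <- phantom_spec(diaphragm_amplitude_mm = 0)
  anatomy <- synth_anatomy_2d(spec, 2)
  dvfs <- synth_cycle_dvfs(spec, anatomy, 2)
  expect_true(all(vapply(dvfs, function(u) all(u == 0), logical(1))))
  case <- render_phantom_sequence(spec, 2)
  for (t in 2:10) {
    expect_identical(case$images[[t]], case$images[[1]])
    expect_equal(dice_score(case$masks[[1]], case$masks[[t]]), 1)
  }
})

test_that("warping the EOI frame with ground-truth fields reproduces each phase", {
  for (seed in c(1, 12, 33, 54, 75)) {
    case <- render_phantom_sequence(phantom_spec(), seed)
    for (t in c(1, 4, 5, 9)) {
      warped <- spatial_transform(case$images[[1]], case$gt_dvfs[[t]])
      expect_lt(max(abs(warped - case$images[[t + 1]])), 0.02)
    }
  }
})

test_that("phase masks keep two lungs and motion is a real learning problem", {
  d5 <- vapply(1:10, function(seed) {
    case <- render_phantom_sequence(phantom_spec(), seed)
    for (t in 1:10) {
      expect_equal(max(rmsim:::label_components(case$masks[[t]] > 0)), 2)
    }
    dice_score(case$masks[[1]], case$masks[[6]])
  }, numeric(1))
  # end-of-exhale overlap with the input frame is substantial but imperfect
  expect_true(all(d5 >= 0.85 & d5 <= 0.95))
})

test_that("diaphragm dome rises at end-of-exhale", {
  case <- fixture_case()
  dome_row <- function(mask) {
    cols <- which(colSums(mask) > 0)
    span <- range(cols)
    central <- cols[cols >= span[1] + 0.2 * diff(span) &
                      cols <= span[1] + 0.8 * diff(span)]
    min(vapply(central, function(j) max(which(mask[, j] > 0)), numeric(1)))
  }
  expect_lt(dome_row(case$masks[[6]] == 1), dome_row(case$masks[[1]] == 1))
  expect_lt(dome_row(case$masks[[6]] == 2), dome_row(case$masks[[1]] == 2))
})

test_that("3D phantom volumes behave like a breathing CT", {
  vol <- fixture_volume_case()
  expect_length(vol$volumes, 10)
  hu_lung <- vol$volumes[[1]][vol$lung_masks[[1]] > 0]
  expect_true(all(hu_lung > -950 & hu_lung < -650))
  # exhalation shrinks the lungs
  expect_lt(sum(vol$lung_masks[[6]] > 0), sum(vol$lung_masks[[1]] > 0))
  # determinism
  v2 <- synth_volume_4d(phantom_spec(), 3)
  expect_identical(v2$volumes[[5]], vol$volumes[[5]])
  # zero amplitude freezes the volume
  v0 <- synth_volume_4d(phantom_spec(diaphragm_amplitude_mm = 0), 4)
  expect_identical(v0$volumes[[1]], v0$volumes[[6]])
  expect_error(synth_volume_4d(phantom_spec(volume_size = c(16, 48, 48)), 1),
               "32")
})

test_that("dataset builder writes a reproducible split manifest", {
  dir1 <- file.path(tempdir(), "rmsim_ds_a")
  dir2 <- file.path(tempdir(), "rmsim_ds_b")
  unlink(c(dir1, dir2), recursive = TRUE)
  spec <- phantom_spec(image_size = c(32, 32), pixel_spacing_mm = 5)
  m1 <- build_phantom_dataset(dir1, n_train = 2, n_test = 1, spec = spec, seed = 5)
  expect_equal(nrow(m1), 3)
  expect_equal(sum(m1$split == "train"), 2)
  expect_false(anyDuplicated(m1$seed) > 0)
  expect_length(list.files(dir1, pattern = "^case_.*rds$"), 3)

  # refuses to overwrite without force
  expect_error(build_phantom_dataset(dir1, 2, 1, spec = spec, seed = 5),
               "force")

  # identical call gives a byte-identical manifest
  build_phantom_dataset(dir2, n_train = 2, n_test = 1, spec = spec, seed = 5)
  expect_identical(readLines(file.path(dir1, "manifest.json")),
                   readLines(file.path(dir2, "manifest.json")))

  man <- phantom_manifest(dir1)
  expect_s3_class(man, "tbl_df")
  case <- load_phantom_case(dir1, man$case_id[1])
  expect_s3_class(case, "phantom_case")
  unlink(c(dir1, dir2), recursive = TRUE)
})
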