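#' Specification of the synthetic thoracic phantom
#'
#' Defines the population a phantom cohort is drawn from: image geometry,
#' breathing amplitude and its per-case variability, the apex-to-base motion
#' gradient, lesion count and texture level. A ten-phase cycle is generated
#' per case, phase 0 being end-of-inhale (EOI) and maximal diaphragm
#' elevation occurring near mid-cycle (end-of-exhale).
#'
#' @param image_size integer length-2, rows x columns of the 2D images.
#' @param pixel_spacing_mm physical size of one pixel (mm).
#' @param diaphragm_amplitude_mm peak superior displacement of the diaphragm
#'   dome over the cycle, before per-case jitter (mm).
#' @param amplitude_jitter fractional per-case amplitude variability; the
#'   effective amplitude is scaled by `1 + amplitude_jitter * z` with
#'   `z` in \[-1, 1\], mostly tied to the case's diaphragm resting position so
#'   breathing depth is (partly) readable from the EOI frame.
#' @param apex_motion_fraction motion at the lung apex relative to the base,
#'   in \[0, 1\]. Displacement magnitude ramps quadratically from apex to base,
#'   so the motion gradient concentrates in the lower lung.
#' @param nodule_count number of bright nodule-like lesions per case.
#' @param noise_sigma standard deviation of the smooth intensity texture
#'   (deformed consistently across phases, on the \[0, 1\] scale).
#' @param volume_size integer length-3 `(H, W, D)` for 3D phantom volumes
#'   (`D` is the anterior-posterior depth).
#' @param n_phases number of respiratory phases; fixed at 10.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = c(64, 64),
                         pixel_spacing_mm = 2.5,
                         diaphragm_amplitude_mm = 20,
                         amplitude_jitter = 0.2,
                         apex_motion_fraction = 0.12,
                         nodule_count = 0,
                         noise_sigma = 0.03,
                         volume_size = c(48, 48, 32),
                         n_phases = 10) {
  image_size <- as.integer(image_size)
  if (length(image_size) != 2 || any(image_size < 32)) {
    abort("`image_size` must be two integers, each >= 32.")
  }
  if (n_phases != 10) abort("`n_phases` is fixed at 10 (p0..p9).")
  if (!is_scalar_number(pixel_spacing_mm) || pixel_spacing_mm <= 0) {
    abort("`pixel_spacing_mm` must be a positive number.")
  }
  if (diaphragm_amplitude_mm < 0) abort("`diaphragm_amplitude_mm` must be >= 0.")
  if (amplitude_jitter < 0) abort("`amplitude_jitter` must be >= 0.")
  if (apex_motion_fraction < 0 || apex_motion_fraction > 1) {
    abort("`apex_motion_fraction` must lie in [0, 1].")
  }
  if (nodule_count < 0) abort("`nodule_count` must be >= 0.")
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0.")
  if (diaphragm_amplitude_mm / pixel_spacing_mm >= 0.25 * image_size[1]) {
    abort("Amplitude too large: diaphragm motion must stay within a quarter of the frame height.")
  }
  volume_size <- as.integer(volume_size)
  if (length(volume_size) != 3) abort("`volume_size` must be length 3 (H, W, D).")
  structure(
    list(
      image_size = image_size,
      pixel_spacing_mm = pixel_spacing_mm,
      diaphragm_amplitude_mm = diaphragm_amplitude_mm,
      amplitude_jitter = amplitude_jitter,
      apex_motion_fraction = apex_motion_fraction,
      nodule_count = as.integer(nodule_count),
      noise_sigma = noise_sigma,
      volume_size = volume_size,
      n_phases = 10L
    ),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec> ", x$image_size[1], "x", x$image_size[2],
      " px @ ", x$pixel_spacing_mm, " mm, amplitude ",
      x$diaphragm_amplitude_mm, " mm (jitter ", x$amplitude_jitter,
      "), apex fraction ", x$apex_motion_fraction,
      ", nodules ", x$nodule_count, "\n", sep = "")
  invisible(x)
}

# Phase weights of the breathing cycle: zero at EOI (t = 0), maximal near
# mid-cycle, returning toward inhale by t = 9.
phase_weight <- function(t) sin(pi * t / 10)^2

# Draw one case's anatomical and motion parameters (RNG-consuming; call
# under with_seed). `depth_z` couples resting diaphragm position and
# breathing amplitude.
draw_case_params <- function(spec) {
  z <- runif(1, -1, 1)
  y_apex <- 0.10 + runif(1, -0.015, 0.015)
  y_base <- 0.72 + 0.04 * z + runif(1, -0.015, 0.015)
  dome_h <- 0.10 * (1 + 0.15 * runif(1, -1, 1))
  lung <- function(xc0) {
    list(
      xc = xc0 + runif(1, -0.015, 0.015),
      rx = 0.155 * (1 + 0.08 * runif(1, -1, 1)),
      y_apex = y_apex + runif(1, -0.01, 0.01),
      y_base = y_base,
      dome_h = dome_h * (1 + 0.1 * runif(1, -1, 1))
    )
  }
  left <- lung(0.28)
  right <- lung(0.72)
  k <- 30
  texture <- list(
    amp = rep(spec$noise_sigma * sqrt(2 / k), k),
    freq = runif(k, 0.02, 0.10),
    theta = runif(k, 0, pi),
    phase = runif(k, 0, 2 * pi)
  )
  nodules <- NULL
  if (spec$nodule_count > 0) {
    nodules <- lapply(seq_len(spec$nodule_count), function(i) {
      side <- if (i %% 2 == 1) right else left
      list(
        x = side$xc + runif(1, -0.5, 0.5) * side$rx,
        y = y_apex + runif(1, 0.25, 0.6) * (y_base - y_apex),
        radius_px = runif(1, 3.5, 5),
        amp = 0.2
      )
    })
  }
  list(
    depth_z = z, y_apex = y_apex, y_base = y_base,
    left = left, right = right,
    texture = texture, nodules = nodules,
    base_intensity = 0.86, intensity_gradient = 0.05, lung_drop = 0.5
  )
}

# Soft lung membership of one lung at (possibly fractional) pixel coords.
# Smooth edges keep bilinear interpolation error across phases small.
soft_lung <- function(lung, xp, yp, h, w) {
  xn <- (xp + 0.5) / w
  yn <- (yp + 0.5) / h
  yc <- (lung$y_apex + lung$y_base) / 2
  ry <- (lung$y_base - lung$y_apex) / 2 * 1.02
  e <- ((xn - lung$xc) / lung$rx)^2 + ((yn - yc) / ry)^2
  tt <- clamp((xn - lung$xc) / lung$rx, -1, 1)
  y_dia <- lung$y_base - lung$dome_h * (1 - tt^2)
  plogis((1 - e) / 0.25) * plogis((y_dia - yn) * h / 1.5)
}

# Analytic intensity of the EOI anatomy, evaluated at arbitrary fractional
# pixel coordinates; phases are rendered by evaluating this at displaced
# coordinates, so every phase image is exact (no resampling chain).
# Coordinates are clamped to the frame, matching the warper's border policy.
render_intensity <- function(par, xp, yp, h, w, with_nodules = TRUE) {
  xp <- clamp(xp, 0, w - 1)
  yp <- clamp(yp, 0, h - 1)
  yn <- (yp + 0.5) / h
  lungness <- soft_lung(par$left, xp, yp, h, w) +
    soft_lung(par$right, xp, yp, h, w)
  img <- par$base_intensity + par$intensity_gradient * yn -
    par$lung_drop * lungness
  tx <- par$texture
  for (k in seq_along(tx$amp)) {
    img <- img + tx$amp[k] * (0.4 + 0.6 * lungness) *
      cos(2 * pi * tx$freq[k] * (cos(tx$theta[k]) * xp + sin(tx$theta[k]) * yp) +
            tx$phase[k])
  }
  if (with_nodules && length(par$nodules)) {
    for (nd in par$nodules) {
      d2 <- (xp - nd$x * w)^2 + (yp - nd$y * h)^2
      s2 <- clamp(d2 / nd$radius_px^2, 0, 1)
      img <- img + nd$amp * (1 - s2)^3
    }
  }
  clamp(img, 0, 1)
}

# Binary left(1)/right(2) labels at integer pixel positions.
render_masks <- function(par, h, w) {
  g <- pixel_grid(h, w)
  m <- matrix(0L, h, w)
  m[soft_lung(par$left, g$x, g$y, h, w) > 0.5] <- 1L
  m[soft_lung(par$right, g$x, g$y, h, w) > 0.5] <- 2L
  m
}

#' Synthesize the end-of-inhale anatomy of one phantom case
#'
#' Renders a radiograph-like frame: bright soft-tissue background, two darker
#' lung fields shaped as half-ellipses with a convex inferior (diaphragm)
#' border, a mediastinal gap, smooth intensity texture, and optional bright
#' nodules. Deterministic for a fixed `(spec, seed)`.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed for the case.
#' @return A list with `image` (H x W matrix in \[0, 1\]), `mask`
#'   (integer matrix, 0 background / 1 left lung / 2 right lung), and
#'   `params` (the drawn case parameters).
#' @export
synth_anatomy_2d <- function(spec, seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$image_size[1]
  w <- spec$image_size[2]
  par <- with_seed(seed, draw_case_params(spec))
  g <- pixel_grid(h, w)
  image <- render_intensity(par, g$x, g$y, h, w)
  mask <- render_masks(par, h, w)
  lab <- label_components(mask > 0)
  if (max(lab) != 2) abort("anatomy rendering did not produce two lung components")
  list(image = image, mask = mask, params = par)
}

# Motion amplitude in pixels for one case: base amplitude scaled by jitter
# that is 80% tied to the anatomy's breathing-depth factor and 20%
# independent.
case_amplitude_px <- function(spec, params, extra_z) {
  amp <- spec$diaphragm_amplitude_mm / spec$pixel_spacing_mm
  amp * (1 + spec$amplitude_jitter * (0.8 * params$depth_z + 0.2 * extra_z))
}

# Vertical motion profile: apex_motion_fraction at/above the apex, ramping
# quadratically to 1 at the diaphragm base and staying 1 below it. The
# quadratic ramp concentrates the motion gradient in the lower lung.
motion_profile <- function(yp, y_apex_px, y_base_px, apex_fraction) {
  r <- clamp((yp - y_apex_px) / (y_base_px - y_apex_px), 0, 1)
  apex_fraction + (1 - apex_fraction) * r^2
}

#' Ground-truth displacement fields for one breathing cycle
#'
#' Produces the nine displacement fields mapping each target phase's pixel
#' coordinates back into the end-of-inhale frame (backward-warping
#' convention). Displacement at phase `t` scales with the cycle weight
#' `sin^2(pi * t / 10)`; vertical magnitude ramps from
#' `apex_motion_fraction` at the apex to 1 at the diaphragm, with a small
#' lateral contraction toward the mediastinum.
#'
#' @param spec a [phantom_spec()].
#' @param anatomy result of [synth_anatomy_2d()].
#' @param seed integer seed (drives the small anatomy-independent share of
#'   the amplitude jitter).
#' @return A list of 9 arrays `(H, W, 2)`; slice 1 is the column
#'   displacement `u_x`, slice 2 the row displacement `u_y`, pixel units.
#'   The effective per-case amplitude (pixels) is attached as attribute
#'   `amplitude_px`.
#' @export
synth_cycle_dvfs <- function(spec, anatomy, seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$image_size[1]
  w <- spec$image_size[2]
  par <- anatomy$params
  extra_z <- with_seed(seed, runif(1, -1, 1))
  amp_px <- case_amplitude_px(spec, par, extra_z)
  g <- pixel_grid(h, w)
  f <- motion_profile(g$y, par$y_apex * h, par$y_base * h,
                      spec$apex_motion_fraction)
  x_mid <- (par$left$xc + par$right$xc) / 2 * w
  lateral <- 0.15
  dvfs <- lapply(1:9, function(t) {
    a_t <- amp_px * phase_weight(t)
    u <- array(0, c(h, w, 2))
    u[, , 2] <- a_t * f
    u[, , 1] <- lateral * a_t / h * f * (g$x - x_mid)
    u
  })
  attr(dvfs, "amplitude_px") <- amp_px
  dvfs
}

#' Render a complete ten-phase phantom case
#'
#' Composes [synth_anatomy_2d()] and [synth_cycle_dvfs()]: phase images are
#' rendered analytically at displaced coordinates (so warping the EOI image
#' by the ground-truth field reproduces each phase up to bilinear
#' interpolation error), and phase masks are the EOI masks warped with
#' nearest-neighbour sampling.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer case seed.
#' @return An object of class `phantom_case`: `images` (list of 10
#'   matrices), `masks` (list of 10 integer label matrices),
#'   `gt_dvfs` (list of 9 `(H, W, 2)` arrays), `spacing_mm`,
#'   `amplitude_px`, `seed`, `spec`.
#' @export
render_phantom_sequence <- function(spec, seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$image_size[1]
  w <- spec$image_size[2]
  anatomy <- synth_anatomy_2d(spec, seed)
  dvfs <- synth_cycle_dvfs(spec, anatomy, seed + 500000L)
  g <- pixel_grid(h, w)
  images <- vector("list", 10)
  masks <- vector("list", 10)
  images[[1]] <- anatomy$image
  masks[[1]] <- anatomy$mask
  for (t in 1:9) {
    u <- dvfs[[t]]
    images[[t + 1]] <- render_intensity(anatomy$params,
                                        g$x + u[, , 1], g$y + u[, , 2], h, w)
    masks[[t + 1]] <- warp_mask(anatomy$mask, u)
    lab <- label_components(masks[[t + 1]] > 0)
    if (max(lab) != 2 || !all(1:2 %in% masks[[t + 1]])) {
      abort(sprintf("phase %d lost a lung component; amplitude too large", t))
    }
  }
  structure(
    list(
      images = images, masks = masks, gt_dvfs = dvfs,
      spacing_mm = spec$pixel_spacing_mm,
      amplitude_px = attr(dvfs, "amplitude_px"),
      seed = seed, spec = spec
    ),
    class = "phantom_case"
  )
}

#' @export
print.phantom_case <- function(x, ...) {
  cat("<phantom_case> seed ", x$seed, ": 10 phases of ",
      nrow(x$images[[1]]), "x", ncol(x$images[[1]]), " px @ ",
      x$spacing_mm, " mm, amplitude ",
      round(x$amplitude_px * x$spacing_mm, 1), " mm\n", sep = "")
  invisible(x)
}

# ---- 3D phantom ------------------------------------------------------------

# Analytic 3D anatomy in HU at (fractional) voxel coordinates, given in the
# EOI frame. Coordinates: y = row (superior->inferior), x = column
# (left->right), z = depth (anterior->posterior); arrays are (H, W, D).
volume_hu_at <- function(par, xp, yp, zp, h, w, d) {
  xn <- (xp + 0.5) / w
  yn <- (yp + 0.5) / h
  zn <- (zp + 0.5) / d
  body <- ((xn - 0.5) / 0.46)^2 + ((zn - 0.5) / 0.46)^2 <= 1
  hu <- ifelse(body, 0, -1000)
  lung_l <- lung_voxels(par$left, xn, yn, zn)
  lung_r <- lung_voxels(par$right, xn, yn, zn)
  noise <- 40 * sin(17 * xn + 23 * yn * zn + par$vol_phase) *
    cos(13 * zn + 19 * yn)
  hu[lung_l | lung_r] <- -800 + noise[lung_l | lung_r]
  spine <- ((xn - 0.5)^2 + (zn - 0.72)^2) <= 0.055^2 & yn > 0.05 & yn < 0.97
  hu[spine & body] <- 400
  hu
}

# Lung ellipsoids are slightly narrower in x and z than their 2D
# counterparts so a tissue margin of a few voxels always separates lung
# air from the air outside the body.
lung_voxels <- function(lung, xn, yn, zn) {
  yc <- (lung$y_apex + lung$y_base) / 2
  ry <- (lung$y_base - lung$y_apex) / 2 * 1.02
  e <- ((xn - lung$xc) / (0.92 * lung$rx))^2 + ((yn - yc) / ry)^2 +
    ((zn - 0.5) / 0.30)^2
  tt <- clamp((xn - lung$xc) / lung$rx, -1, 1)
  y_dia <- lung$y_base - lung$dome_h * (1 - tt^2)
  e <= 1 & yn <= y_dia
}

#' Synthesize a ten-phase 3D phantom (CT-like volumes)
#'
#' Small Hounsfield-valued volumes with two lung ellipsoids cut by a domed
#' diaphragm surface, a soft-tissue body cylinder, a spine rod, and air
#' outside the body. The same cycle weights as the 2D phantom raise the
#' diaphragm per phase, shrinking the lungs toward end-of-exhale.
#'
#' @param spec a [phantom_spec()]; `volume_size` gives `(H, W, D)`.
#' @param seed integer case seed.
#' @return A list with `volumes` and `lung_masks` (lists of 10 `(H, W, D)`
#'   arrays; masks labeled 0/1/2), `spacing_mm`, `seed`.
#' @export
synth_volume_4d <- function(spec, seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$volume_size
  if (any(dims < 32)) abort("`volume_size` must be >= 32 in every dimension.")
  h <- dims[1]; w <- dims[2]; d <- dims[3]
  par <- with_seed(seed, draw_case_params(spec))
  par$vol_phase <- with_seed(seed + 1L, runif(1, 0, 2 * pi))
  extra_z <- with_seed(seed + 500000L, runif(1, -1, 1))
  amp_vox <- case_amplitude_px(spec, par, extra_z) * spec$image_size[1] / h
  xp <- array(rep(seq_len(w) - 1, each = h, times = d), c(h, w, d))
  yp <- array(rep(seq_len(h) - 1, times = w * d), c(h, w, d))
  zp <- array(rep(seq_len(d) - 1, each = h * w), c(h, w, d))
  volumes <- vector("list", 10)
  masks <- vector("list", 10)
  for (t in 0:9) {
    a_t <- amp_vox * phase_weight(t)
    f <- motion_profile(yp, par$y_apex * h, par$y_base * h,
                        spec$apex_motion_fraction)
    ys <- yp + a_t * f
    xn <- (xp + 0.5) / w; yn <- (ys + 0.5) / h; zn <- (zp + 0.5) / d
    volumes[[t + 1]] <- volume_hu_at(par, xp, ys, zp, h, w, d)
    m <- array(0L, c(h, w, d))
    m[lung_voxels(par$left, xn, yn, zn)] <- 1L
    m[lung_voxels(par$right, xn, yn, zn)] <- 2L
    masks[[t + 1]] <- m
  }
  list(volumes = volumes, lung_masks = masks,
       spacing_mm = spec$pixel_spacing_mm, seed = seed)
}

# ---- dataset builder -------------------------------------------------------

#' Build a reproducible on-disk phantom cohort
#'
#' Renders `n_train + n_test` cases with disjoint per-case seeds derived from
#' `seed`, writes one `.rds` bundle per case plus a JSON manifest recording
#' case id, split, seed and a hash of the spec. Re-running with identical
#' arguments reproduces identical manifests.
#'
#' @param out_dir output directory (created; refuses to overwrite an
#'   existing dataset unless `force = TRUE`).
#' @param n_train,n_test number of training / test cases (>= 1).
#' @param spec a [phantom_spec()].
#' @param seed integer cohort seed.
#' @param mode `"2d"` (images + masks + ground-truth fields) or `"3d"`
#'   (volumes for the preprocessing path).
#' @param force overwrite an existing dataset directory.
#' @return The manifest as a tibble (invisibly also written to
#'   `manifest.json`).
#' @export
build_phantom_dataset <- function(out_dir, n_train = 40, n_test = 20,
                                  spec = phantom_spec(), seed = 1,
                                  mode = c("2d", "3d"), force = FALSE) {
  mode <- match.arg(mode)
  if (n_train < 1 || n_test < 1) abort("`n_train` and `n_test` must be >= 1.")
  if (dir.exists(out_dir) && file.exists(file.path(out_dir, "manifest.json"))) {
    if (!force) abort("dataset directory already exists; use `force = TRUE` to overwrite")
    unlink(out_dir, recursive = TRUE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n <- n_train + n_test
  case_seeds <- seed * 1000L + seq_len(n)
  spec_hash <- hash_object(unclass(spec))
  manifest <- tibble::tibble(
    case_id = sprintf("case_%03d", seq_len(n)),
    split = rep(c("train", "test"), c(n_train, n_test)),
    seed = as.integer(case_seeds),
    spec_hash = spec_hash,
    mode = mode
  )
  for (i in seq_len(n)) {
    case <- if (mode == "2d") {
      render_phantom_sequence(spec, case_seeds[i])
    } else {
      synth_volume_4d(spec, case_seeds[i])
    }
    saveRDS(case, file.path(out_dir, paste0(manifest$case_id[i], ".rds")),
            version = 2)
  }
  json <- jsonlite::toJSON(
    list(spec = unclass(spec), mode = mode, seed = seed,
         cases = manifest[c("case_id", "split", "seed", "spec_hash")]),
    auto_unbox = TRUE, digits = 12, pretty = TRUE
  )
  writeLines(as.character(json), file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

#' Read a phantom dataset manifest
#'
#' @param dir dataset directory created by [build_phantom_dataset()].
#' @return A tibble with one row per case (`case_id`, `split`, `seed`,
#'   `spec_hash`), with the spec and mode as attributes.
#' @export
phantom_manifest <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) abort(paste0("no manifest.json under ", dir))
  m <- jsonlite::fromJSON(path)
  out <- tibble::as_tibble(m$cases)
  attr(out, "spec") <- do.call(phantom_spec, m$spec[setdiff(names(m$spec), "n_phases")])
  attr(out, "mode") <- m$mode
  attr(out, "dir") <- dir
  out
}

#' Load one case from a phantom dataset
#'
#' @param dir dataset directory.
#' @param case_id case identifier as listed in the manifest.
#' @return The stored case object.
#' @export
load_phantom_case <- function(dir, case_id) {
  path <- file.path(dir, paste0(case_id, ".rds"))
  if (!file.exists(path)) abort(paste0("no such case: ", case_id))
  readRDS(path)
}
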