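# Preprocessing path: CT-like 4D volumes to model-ready phase sequences.
# Volumes are (H, W, D) arrays in Hounsfield units: H rows
# (superior->inferior), W columns (left->right), D depth slices
# (anterior->posterior).

#' Projection geometry for DRR generation
#'
#' @param mode `"parallel"` (axis-aligned rays; default) or
#'   `"perspective"` (point source, ray marching).
#' @param direction axis index the rays travel along (3 = anterior-
#'   posterior depth, the beam's-eye-view default).
#' @param source_distance_mm point-source distance (perspective only); must
#'   exceed the volume extent.
#' @param step_mm ray-march step (and thickness weight of one voxel along
#'   the ray in parallel mode).
#' @return A `projection_geometry` object.
#' @export
projection_geometry <- function(mode = c("parallel", "perspective"),
                                direction = 3, source_distance_mm = 1000,
                                step_mm = 1) {
  mode <- match.arg(mode)
  if (step_mm <= 0) abort("`step_mm` must be positive")
  if (!direction %in% 1:3) abort("`direction` must be 1, 2 or 3")
  structure(list(mode = mode, direction = as.integer(direction),
                 source_distance_mm = source_distance_mm, step_mm = step_mm),
            class = "projection_geometry")
}

#' Threshold-based lung segmentation of a CT-like volume
#'
#' Voxels below `threshold_hu` are candidate air; the components touching
#' the volume border (external air) are removed, and the two largest
#' remaining components are kept and labeled left (1) / right (2) by
#' centroid column.
#'
#' @param volume 3D numeric array in HU.
#' @param threshold_hu threshold separating lung parenchyma from soft
#'   tissue (default -400).
#' @return Integer array congruent with `volume` (0 / 1 / 2).
#' @export
segment_lungs <- function(volume, threshold_hu = -400) {
  if (!all(is.finite(volume))) abort("`volume` must be finite-valued")
  air <- volume < threshold_hu
  if (!any(air)) abort("no voxels below the threshold; no lung found")
  lab <- label_components(air)
  d <- dim(volume)
  border_labels <- unique(c(
    lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])]
  ))
  border_labels <- border_labels[border_labels > 0]
  interior <- air & !(lab %in% border_labels)
  dim(interior) <- d
  keep <- largest_components(interior, 2)
  if (is.null(keep)) abort("fewer than two lung components found")
  centroid_col <- function(k) mean(which(keep == k, arr.ind = TRUE)[, 2])
  out <- array(0L, d)
  if (centroid_col(1) <= centroid_col(2)) {
    out[keep == 1] <- 1L
    out[keep == 2] <- 2L
  } else {
    out[keep == 1] <- 2L
    out[keep == 2] <- 1L
  }
  out
}

# Map HU to a non-negative attenuation coefficient (water-relative affine
# scaling, clamped at air).
hu_to_attenuation <- function(hu) pmax(0, (hu + 1000) / 1000)

#' Ray-cast a digitally reconstructed radiograph
#'
#' Each output pixel is the line integral of attenuation (an affine map of
#' HU clamped at zero) along its ray, restricted to the masked voxels and
#' scaled by `step_mm`. Parallel mode integrates along the chosen axis;
#' perspective mode marches rays from a point source through the volume
#' with trilinear sampling.
#'
#' @param volume 3D HU array.
#' @param mask congruent mask; only voxels with `mask > 0` contribute
#'   (lungs-only projection). Use `array(1, dim(volume))` for a full-volume
#'   DRR.
#' @param geometry a [projection_geometry()].
#' @return 2D projection matrix (not yet normalized).
#' @export
ray_cast_drr <- function(volume, mask, geometry = projection_geometry()) {
  if (!identical(dim(volume), dim(mask))) abort("mask and volume must be congruent")
  att <- hu_to_attenuation(volume) * (mask > 0)
  if (geometry$mode == "parallel") {
    perm <- switch(geometry$direction, c(2, 3, 1), c(1, 3, 2), c(1, 2, 3))
    a <- aperm(att, perm)
    rowSums(a, dims = 2) * geometry$step_mm
  } else {
    ray_cast_perspective(att, geometry)
  }
}

# Point-source ray marching along the depth axis with trilinear sampling.
ray_cast_perspective <- function(att, geometry) {
  d <- dim(att)
  if (geometry$direction != 3) abort("perspective mode projects along axis 3")
  if (geometry$source_distance_mm <= d[3]) {
    abort("`source_distance_mm` must exceed the volume extent")
  }
  h <- d[1]; w <- d[2]; dep <- d[3]
  src_z <- -geometry$source_distance_mm + dep / 2
  out <- matrix(0, h, w)
  zs <- seq(0, dep - 1, by = geometry$step_mm)
  ci <- (h - 1) / 2
  cj <- (w - 1) / 2
  for (z in zs) {
    scale <- (z - src_z) / (dep - 1 - src_z)
    ri <- ci + (matrix(0:(h - 1), h, w) - ci) * scale
    rj <- cj + (matrix(0:(w - 1), h, w, byrow = TRUE) - cj) * scale
    out <- out + trilinear_slice(att, ri, rj, z)
  }
  out * geometry$step_mm
}

trilinear_slice <- function(att, ri, rj, z) {
  d <- dim(att)
  z0 <- min(max(floor(z), 0), d[3] - 2)
  fz <- z - z0
  s0 <- bilinear_at(att[, , z0 + 1], ri, rj)
  s1 <- bilinear_at(att[, , z0 + 2], ri, rj)
  (1 - fz) * s0 + fz * s1
}

bilinear_at <- function(m, ri, rj) {
  h <- nrow(m); w <- ncol(m)
  ri <- clamp(ri, 0, h - 1)
  rj <- clamp(rj, 0, w - 1)
  r0 <- pmin(floor(ri), h - 2); c0 <- pmin(floor(rj), w - 2)
  fr <- ri - r0; fc <- rj - c0
  idx <- function(a, b) m[cbind(as.vector(a + 1), as.vector(b + 1))]
  out <- (1 - fr) * (1 - fc) * idx(r0, c0) + fr * (1 - fc) * idx(r0 + 1, c0) +
    (1 - fr) * fc * idx(r0, c0 + 1) + fr * fc * idx(r0 + 1, c0 + 1)
  matrix(out, h, ncol(ri))
}

#' Shared lung bounding box across phases
#'
#' The minimal axis-aligned box containing the union of all projected lung
#' masks, expanded by `margin_px` and clipped to the image bounds. One box
#' per case keeps inter-phase pixel correspondence intact.
#'
#' @param projected_masks list of congruent binary matrices (one per
#'   phase).
#' @param margin_px margin in pixels.
#' @return Integer vector `(row0, col0, row1, col1)`, 0-based, half-open.
#' @export
lung_bounding_box <- function(projected_masks, margin_px = 0) {
  if (!is.list(projected_masks)) projected_masks <- list(projected_masks)
  u <- Reduce(`+`, lapply(projected_masks, function(m) (m > 0) * 1)) > 0
  if (!any(u)) abort("union of projected masks is empty")
  rows <- which(rowSums(u) > 0)
  cols <- which(colSums(u) > 0)
  h <- nrow(u); w <- ncol(u)
  c(
    row0 = max(min(rows) - 1 - margin_px, 0),
    col0 = max(min(cols) - 1 - margin_px, 0),
    row1 = min(max(rows) + margin_px, h),
    col1 = min(max(cols) + margin_px, w)
  )
}

#' Crop, resize and normalize a projection
#'
#' Crops the half-open 0-based `bbox`, bilinearly resizes to `out_size`,
#' and min-max normalizes into \[0, 1\] (a constant image maps to zeros).
#' Supplying `range` normalizes with shared case-level extremes instead of
#' the image's own.
#'
#' @param image 2D matrix.
#' @param bbox `(row0, col0, row1, col1)`, 0-based half-open.
#' @param out_size integer length-2 output size.
#' @param range optional `c(min, max)` for shared normalization.
#' @return Matrix of size `out_size` with values in \[0, 1\].
#' @export
crop_and_normalize <- function(image, bbox, out_size, range = NULL) {
  bbox <- as.integer(bbox)
  if (bbox[3] <= bbox[1] || bbox[4] <= bbox[2]) abort("degenerate bounding box")
  if (bbox[1] < 0 || bbox[2] < 0 || bbox[3] > nrow(image) || bbox[4] > ncol(image)) {
    abort("bounding box outside the image")
  }
  crop <- image[(bbox[1] + 1):bbox[3], (bbox[2] + 1):bbox[4], drop = FALSE]
  out <- resize_bilinear(crop, out_size[1], out_size[2])
  r <- range %||% base::range(out)
  if (r[2] <= r[1]) return(matrix(0, out_size[1], out_size[2]))
  clamp((out - r[1]) / (r[2] - r[1]), 0, 1)
}

# Nearest-neighbour crop + resize for label masks.
crop_resize_mask <- function(mask, bbox, out_size) {
  crop <- mask[(bbox[1] + 1):bbox[3], (bbox[2] + 1):bbox[4], drop = FALSE]
  h <- nrow(crop); w <- ncol(crop)
  ri <- round(seq(1, h, length.out = out_size[1]))
  ci <- round(seq(1, w, length.out = out_size[2]))
  crop[ri, ci, drop = FALSE]
}

# Project a labeled 3D mask along the geometry axis, keeping labels.
project_mask <- function(mask3d, geometry) {
  perm <- switch(geometry$direction, c(2, 3, 1), c(1, 3, 2), c(1, 2, 3))
  lab <- matrix(0L, dim(mask3d)[perm[1]], dim(mask3d)[perm[2]])
  for (k in 2:1) {
    hit <- rowSums(aperm(mask3d == k, perm), dims = 2) > 0
    lab[hit] <- k
  }
  lab
}

#' Preprocess a ten-phase volume sequence into a phase sequence
#'
#' Runs the full chain of the preprocessing path per phase: threshold lung
#' segmentation, lungs-only ray-cast DRR, one shared bounding box over the
#' union of the projected masks, cropping/resizing, and case-level min-max
#' normalization. Phase 0 is tagged as the end-of-inhale input.
#'
#' @param volumes list of exactly 10 congruent 3D HU arrays (p0..p9, in
#'   caller-supplied order).
#' @param threshold_hu segmentation threshold (default -400).
#' @param geometry a [projection_geometry()].
#' @param out_size output image size (default `c(64, 64)`).
#' @param spacing_mm voxel spacing of the volumes (mm).
#' @param margin_px bounding-box margin.
#' @return A `phase_sequence`: `phases` (10 matrices in \[0, 1\]),
#'   `lung_masks` (10 labeled matrices), `spacing_mm` (after resizing),
#'   `bbox`, `provenance`.
#' @export
preprocess_case <- function(volumes, threshold_hu = -400,
                            geometry = projection_geometry(),
                            out_size = c(64, 64), spacing_mm = 1,
                            margin_px = 2) {
  if (!is.list(volumes) || length(volumes) != 10) {
    abort("`volumes` must be a list of exactly 10 phase volumes")
  }
  segs <- lapply(volumes, segment_lungs, threshold_hu = threshold_hu)
  drrs <- lapply(seq_along(volumes), function(i) {
    ray_cast_drr(volumes[[i]], segs[[i]], geometry)
  })
  masks2d <- lapply(segs, project_mask, geometry = geometry)
  bbox <- lung_bounding_box(masks2d, margin_px)
  cropped <- lapply(drrs, function(d) {
    crop <- d[(bbox[1] + 1):bbox[3], (bbox[2] + 1):bbox[4], drop = FALSE]
    resize_bilinear(crop, out_size[1], out_size[2])
  })
  r <- range(unlist(lapply(cropped, base::range)))
  phases <- lapply(cropped, function(m) {
    if (r[2] <= r[1]) matrix(0, out_size[1], out_size[2])
    else (m - r[1]) / (r[2] - r[1])
  })
  masks_out <- lapply(masks2d, crop_resize_mask, bbox = bbox, out_size = out_size)
  scale <- mean(c((bbox[3] - bbox[1]) / out_size[1],
                  (bbox[4] - bbox[2]) / out_size[2]))
  structure(
    list(phases = phases, lung_masks = masks_out,
         spacing_mm = spacing_mm * scale, bbox = bbox,
         eoi_phase = 1L, provenance = "volumes"),
    class = "phase_sequence"
  )
}

#' @export
print.phase_sequence <- function(x, ...) {
  cat("<phase_sequence> 10 phases of ", nrow(x$phases[[1]]), "x",
      ncol(x$phases[[1]]), " px @ ", signif(x$spacing_mm, 3),
      " mm (bbox ", paste(x$bbox, collapse = ","), "); p0 = end-of-inhale\n",
      sep = "")
  invisible(x)
}

#' Read / write volumes as NIfTI
#'
#' Thin wrappers over the RNifti package (suggested dependency) for moving
#' phantom volumes in and out of standard imaging formats.
#'
#' @param volume 3D array (for writing).
#' @param path file path (`.nii` / `.nii.gz`).
#' @return `read_volume_nifti` returns a plain 3D array.
#' @export
write_volume_nifti <- function(volume, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("the RNifti package is required for NIfTI output")
  }
  RNifti::writeNifti(RNifti::asNifti(volume), path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("the RNifti package is required for NIfTI input")
  }
  arr <- RNifti::readNifti(path)
  array(as.numeric(arr), dim(arr))
}
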