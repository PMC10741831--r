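#' Jacobian-determinant ventilation map
#'
#' Central finite differences (one-sided at borders) of the displacement
#' components give the 2x2 Jacobian of the deformation
#' `x -> x + u(x)`; its determinant
#' `det J = (1 + du_x/dx)(1 + du_y/dy) - (du_x/dy)(du_y/dx)` measures local
#' area change (> 1 expansion, < 1 compression) and ventilation is defined
#' as `v = det J - 1`.
#'
#' @param dvf `(H, W, 2)` displacement array (pixels).
#' @return A `ventilation_map` list with `v` and `det_j` matrices.
#' @export
ventilation_map <- function(dvf) {
  if (!all(is.finite(dvf))) abort("`dvf` contains non-finite values")
  ux <- dvf[, , 1]
  uy <- dvf[, , 2]
  dx <- function(m) t(apply(m, 1, grad_1d)) # d/dcolumn
  dy <- function(m) apply(m, 2, grad_1d)    # d/drow
  det_j <- (1 + dx(ux)) * (1 + dy(uy)) - dy(ux) * dx(uy)
  structure(list(v = det_j - 1, det_j = det_j), class = "ventilation_map")
}

# Central differences with one-sided stencils at the ends.
grad_1d <- function(x) {
  n <- length(x)
  if (n < 2) return(rep(0, n))
  c(x[2] - x[1], if (n > 2) (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1])
}

#' Dice similarity coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` between two congruent binary masks.
#'
#' @param mask_a,mask_b logical/0-1 matrices (any nonzero value counts).
#' @return Value in \[0, 1\]; symmetric.
#' @export
dice_score <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) abort("masks must be congruent")
  a <- mask_a > 0
  b <- mask_b > 0
  sa <- sum(a)
  sb <- sum(b)
  if (sa + sb == 0) abort("both masks are empty")
  2 * sum(a & b) / (sa + sb)
}

#' Propagate the EOI lung masks through predicted fields
#'
#' Warps the left and right end-of-inhale lung labels with each predicted
#' displacement field using nearest-neighbour sampling, preserving labels.
#'
#' @param p0_mask integer H x W matrix (0 background, 1 left, 2 right).
#' @param dvfs list of 9 `(H, W, 2)` displacement arrays.
#' @return List of 9 labeled masks; phases whose warped mask lost a lung
#'   are flagged in attribute `empty_phases`.
#' @export
predict_phase_masks <- function(p0_mask, dvfs) {
  out <- lapply(dvfs, function(u) warp_mask(p0_mask, u))
  empty <- which(vapply(out, function(m) !all(1:2 %in% m), logical(1)))
  attr(out, "empty_phases") <- empty
  out
}

#' Apex-to-dome diaphragmatic length of one lung
#'
#' The apex row is the most superior mask row; the dome row is the most
#' superior point of the per-column inferior boundary, restricted to the
#' central 60% of the lung's column span (avoiding costophrenic angles and
#' the mediastinal border); the length is their row distance in mm.
#'
#' @param mask binary matrix of a single lung.
#' @param spacing_mm pixel spacing (mm).
#' @return Length in mm (> 0).
#' @export
diaphragm_length <- function(mask, spacing_mm = 1) {
  mask <- mask > 0
  cols <- which(colSums(mask) > 0)
  if (length(cols) < 3) abort("mask thinner than 3 columns")
  span <- range(cols)
  lo <- span[1] + 0.2 * (span[2] - span[1])
  hi <- span[1] + 0.8 * (span[2] - span[1])
  central <- cols[cols >= lo & cols <= hi]
  if (!length(central)) central <- cols
  apex_row <- min(which(rowSums(mask) > 0))
  dome_row <- min(vapply(central, function(j) max(which(mask[, j])), numeric(1)))
  (dome_row - apex_row) * spacing_mm
}

# Resize a displacement field to a new grid, rescaling the displacement
# values to the new pixel size.
resize_dvf <- function(dvf, out_h, out_w) {
  d <- dim(dvf)
  if (d[1] == out_h && d[2] == out_w) return(dvf)
  out <- array(0, c(out_h, out_w, 2))
  out[, , 1] <- resize_bilinear(dvf[, , 1], out_h, out_w) * (out_w / d[2])
  out[, , 2] <- resize_bilinear(dvf[, , 2], out_h, out_w) * (out_h / d[1])
  out
}

# Predicted fields for one case at the case's native resolution.
predict_case_dvfs <- function(model, case) {
  h <- nrow(case$images[[1]])
  w <- ncol(case$images[[1]])
  if (identical(model, "identity")) {
    return(lapply(1:9, function(t) array(0, c(h, w, 2))))
  }
  if (identical(model, "oracle")) {
    return(case$gt_dvfs)
  }
  stopifnot(inherits(model, "rms_checkpoint"))
  cfg <- model$net_config
  p0 <- case$images[[1]]
  if (!all(dim(p0) == cfg$image_size)) {
    p0 <- resize_bilinear(p0, cfg$image_size[1], cfg$image_size[2])
  }
  fwd <- rms_forward(model$params, cfg, p0)
  lapply(fwd$dvfs, resize_dvf, out_h = h, out_w = w)
}

# Mean |v| of predicted ventilation inside the upper / lower halves of the
# EOI lung mask (used for the regional ventilation trend).
ventilation_region_means <- function(dvf, mask) {
  v <- ventilation_map(dvf)$v
  inside <- mask > 0
  rows <- which(rowSums(inside) > 0)
  mid <- (min(rows) + max(rows)) / 2
  upper <- inside & (row(mask) <= mid)
  lower <- inside & (row(mask) > mid)
  c(upper = mean(abs(v[upper])), lower = mean(abs(v[lower])))
}

#' Evaluate a model on a phantom cohort
#'
#' Runs the forward pass from each test case's end-of-inhale image,
#' propagates the lung masks through the predicted fields, and reports
#' per-phase Dice (whole-lung), signed and absolute left/right
#' diaphragmatic-position errors in mm, and regional ventilation summaries.
#' `model = "identity"` scores the no-motion baseline and
#' `model = "oracle"` feeds the ground-truth fields through the same stack.
#'
#' @param model an `rms_checkpoint`, `"identity"`, or `"oracle"`.
#' @param dataset_dir phantom dataset directory (2D mode).
#' @param split `"test"` (default) or `"train"`.
#' @return An `rms_metrics` object: `per_case` (case x phase tibble),
#'   `per_phase` (mean +/- sd aggregates), and `summary` (overall mean
#'   Dice, minimum Dice, median absolute length error in mm).
#' @export
evaluate_model <- function(model, dataset_dir, split = "test") {
  man <- phantom_manifest(dataset_dir)
  ids <- man$case_id[man$split == split]
  if (!length(ids)) abort(paste0("no cases in split '", split, "'"))
  rows <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    case <- load_phantom_case(dataset_dir, ids[k])
    dvfs <- predict_case_dvfs(model, case)
    pred_masks <- predict_phase_masks(case$masks[[1]], dvfs)
    sp <- case$spacing_mm
    rows[[k]] <- dplyr::bind_rows(lapply(1:9, function(t) {
      gt <- case$masks[[t + 1]]
      pm <- pred_masks[[t]]
      lg <- diaphragm_length(gt == 1, sp)
      rg <- diaphragm_length(gt == 2, sp)
      lp <- diaphragm_length(pm == 1, sp)
      rp <- diaphragm_length(pm == 2, sp)
      vr <- ventilation_region_means(dvfs[[t]], case$masks[[1]])
      tibble::tibble(
        case_id = ids[k], phase = t,
        dice = dice_score(gt, pm),
        left_len_gt = lg, left_len_pred = lp,
        right_len_gt = rg, right_len_pred = rp,
        lle = lp - lg, rle = rp - rg,
        lle_abs = abs(lp - lg), rle_abs = abs(rp - rg),
        vent_upper = vr[["upper"]], vent_lower = vr[["lower"]]
      )
    }))
  }
  per_case <- dplyr::bind_rows(rows)
  per_phase <- per_case |>
    dplyr::group_by(.data$phase) |>
    dplyr::summarise(
      dice_mean = mean(.data$dice), dice_sd = sd(.data$dice),
      lle_mean = mean(.data$lle), lle_sd = sd(.data$lle),
      rle_mean = mean(.data$rle), rle_sd = sd(.data$rle),
      vent_upper = mean(.data$vent_upper),
      vent_lower = mean(.data$vent_lower),
      .groups = "drop"
    )
  summary <- list(
    n_cases = length(ids),
    mean_dice = mean(per_case$dice),
    min_dice = min(per_case$dice),
    median_abs_error_mm = median(c(per_case$lle_abs, per_case$rle_abs)),
    frac_error_lt_10mm = mean(c(per_case$lle_abs, per_case$rle_abs) < 10)
  )
  structure(list(per_case = per_case, per_phase = per_phase,
                 summary = summary, split = split),
            class = "rms_metrics")
}

#' @export
print.rms_metrics <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<rms_metrics> %d cases (%s split): mean Dice %.4f, min Dice %.4f, median |error| %.2f mm (%.0f%% < 10 mm)\n",
    s$n_cases, x$split, s$mean_dice, s$min_dice, s$median_abs_error_mm,
    100 * s$frac_error_lt_10mm))
  print(x$per_phase, n = 9)
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' @param metrics an `rms_metrics` object.
#' @param out_dir output directory; per-case CSV and a JSON summary are
#'   written.
#' @return `out_dir`, invisibly.
#' @export
write_metrics_report <- function(metrics, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(metrics$per_case, file.path(out_dir, "per_case.csv"),
                   row.names = FALSE)
  utils::write.csv(metrics$per_phase, file.path(out_dir, "per_phase.csv"),
                   row.names = FALSE)
  writeLines(as.character(jsonlite::toJSON(metrics$summary, auto_unbox = TRUE,
                                           digits = 10)),
             file.path(out_dir, "summary.json"))
  invisible(out_dir)
}
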