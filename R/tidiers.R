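# broom-style accessors for fitted objects and reports.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an evaluation report
#'
#' @param x an `rms_metrics` object.
#' @param ... unused.
#' @return The per-phase aggregate tibble (mean +/- sd Dice and signed
#'   left/right diaphragmatic-position errors per phase).
#' @export
tidy.rms_metrics <- function(x, ...) {
  x$per_phase
}

#' One-row summary of an evaluation report
#'
#' @param x an `rms_metrics` object.
#' @param ... unused.
#' @return Tibble with overall mean Dice, minimum Dice, median absolute
#'   diaphragmatic error (mm) and the fraction of errors below 10 mm.
#' @export
glance.rms_metrics <- function(x, ...) {
  tibble::as_tibble(x$summary)
}

#' Tidy a training checkpoint
#'
#' @param x an `rms_checkpoint`.
#' @param ... unused.
#' @return The per-epoch loss history tibble.
#' @export
tidy.rms_checkpoint <- function(x, ...) {
  x$history
}

#' One-row summary of a training checkpoint
#'
#' @param x an `rms_checkpoint`.
#' @param ... unused.
#' @return Tibble with epochs run, parameter count and final loss
#'   components.
#' @export
glance.rms_checkpoint <- function(x, ...) {
  n_par <- length(tree_unlist(unclass(x$params)))
  last <- if (nrow(x$history)) x$history[nrow(x$history), ] else
    tibble::tibble(smooth = NA_real_, mse = NA_real_, ncc = NA_real_,
                   total = NA_real_)
  tibble::tibble(
    epochs = x$last$epoch, n_parameters = n_par,
    final_smooth = last$smooth, final_mse = last$mse,
    final_ncc = last$ncc, final_total = last$total,
    best_val = x$last$best_val
  )
}
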