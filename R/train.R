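#' Training configuration
#'
#' Bundles every knob of a training run into one serializable object:
#' optimization (epochs, batch size, learning rate, Adam), loss weights and
#' NCC window, network size (image size, base channels, latent width,
#' displacement bound) and the run seed. Defaults are sized for CPU-scale
#' experiments on the packaged phantom cohort.
#'
#' @param epochs number of passes over the training split.
#' @param batch_size cases per gradient step (gradients averaged).
#' @param learning_rate Adam step size.
#' @param optimizer only `"adam"` is implemented.
#' @param seed integer seed controlling initialization and shuffling.
#' @param smooth_weight,mse_weight,ncc_weight loss weights. The smoothness
#'   default (1e-3) balances the per-pixel-mean MSE the way an equal-weight
#'   pixel-sum formulation would at 64 x 64; see the package vignette.
#' @param lr_decay multiplicative per-epoch learning-rate decay (1 = constant
#'   rate; useful for long memorization runs where late-stage Adam
#'   oscillation limits the attainable error).
#' @param ncc_window window of the local cross-correlation loss.
#' @param image_size network input size (square, divisible by 16).
#' @param base_channels encoder width at the first level.
#' @param latent latent vector length.
#' @param max_disp displacement bound in pixels (default `image_size / 4`).
#' @param val_every validation cadence in epochs.
#' @param device placement hint (informational; computation is CPU).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 30, batch_size = 2, learning_rate = 2e-3,
                         optimizer = "adam", seed = 42, lr_decay = 1,
                         smooth_weight = 1e-3, mse_weight = 1, ncc_weight = 1,
                         ncc_window = 9, image_size = 64, base_channels = 8,
                         latent = 512, max_disp = NULL, val_every = 3,
                         device = "cpu") {
  if (optimizer != "adam") abort("only the adam optimizer is implemented")
  num <- c(batch_size = batch_size, learning_rate = learning_rate,
           ncc_window = ncc_window, image_size = image_size,
           base_channels = base_channels, latent = latent,
           val_every = val_every)
  if (any(!is.finite(num)) || any(num <= 0)) {
    abort("all numeric training-config fields must be positive")
  }
  if (epochs < 0) abort("`epochs` must be >= 0")
  if (lr_decay <= 0 || lr_decay > 1) abort("`lr_decay` must lie in (0, 1]")
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate, optimizer = optimizer,
         seed = as.integer(seed), lr_decay = lr_decay,
         smooth_weight = smooth_weight, mse_weight = mse_weight,
         ncc_weight = ncc_weight, ncc_window = as.integer(ncc_window),
         image_size = as.integer(image_size),
         base_channels = as.integer(base_channels),
         latent = as.integer(latent), max_disp = max_disp,
         val_every = as.integer(val_every), device = device),
    class = "train_config"
  )
}

#' Read / write a training configuration as YAML
#'
#' @param path YAML file.
#' @return [train_config()] object (`read_train_config`), or the path
#'   invisibly (`write_train_config`).
#' @export
read_train_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(train_config, vals)
}

#' @rdname read_train_config
#' @param config a [train_config()].
#' @export
write_train_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

net_config_of <- function(config) {
  rms_config(image_size = config$image_size,
             base_channels = config$base_channels,
             latent = config$latent, max_disp = config$max_disp)
}

loss_weights_of <- function(config) {
  c(smooth = config$smooth_weight, mse = config$mse_weight,
    ncc = config$ncc_weight)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(state$m, state$v, function(m, v) {
    lr * (m / bc1) / (sqrt(v / bc2) + eps)
  })
  params <- tree_map2(params, upd, `-`)
  list(params = params, state = state)
}

# ---- data loading ----------------------------------------------------------

# Load a split of a 2D phantom dataset as model-ready pairs, resizing to the
# network input size if needed.
load_training_cases <- function(dir, split, image_size) {
  man <- phantom_manifest(dir)
  ids <- man$case_id[man$split == split]
  if (!length(ids)) abort(paste0("no cases in split '", split, "'"))
  lapply(ids, function(id) {
    case <- load_phantom_case(dir, id)
    imgs <- lapply(case$images, function(im) {
      if (all(dim(im) == image_size)) im else resize_bilinear(im, image_size[1], image_size[2])
    })
    list(case_id = id, p0 = imgs[[1]], targets = imgs[2:10])
  })
}

# ---- training loop ---------------------------------------------------------

case_loss_and_grads <- function(params, cfg, case, weights, ncc_window) {
  fwd <- rms_forward(params, cfg, case$p0, keep_cache = TRUE)
  loss <- total_loss(fwd$dvfs, fwd$preds, case$targets, weights, ncc_window)
  lg <- total_loss_grad(fwd$dvfs, fwd$preds, case$targets, weights, ncc_window)
  grads <- rms_backward(params, cfg, fwd, lg$dpreds, lg$ddvfs)
  list(loss = loss, grads = grads)
}

validation_loss <- function(params, cfg, cases, weights, ncc_window) {
  mean(vapply(cases, function(case) {
    fwd <- rms_forward(params, cfg, case$p0)
    total_loss(fwd$dvfs, fwd$preds, case$targets, weights, ncc_window)$total
  }, numeric(1)))
}

#' Train the motion-simulation network
#'
#' For every case the end-of-inhale image is the input and phases 1-9 are
#' the targets; the combined smoothness + MSE - NCC loss is minimized with
#' Adam. Fully reproducible given `(dataset, config)`: the seed controls
#' initialization and shuffling, and the returned checkpoint carries the
#' optimizer and RNG state so training can be resumed exactly.
#'
#' @param dataset_dir phantom dataset directory (2D mode).
#' @param config a [train_config()].
#' @param quiet suppress per-epoch progress lines.
#' @return An `rms_checkpoint`: best-by-validation parameters (`params`),
#'   network config, training config, per-epoch `history` tibble, and the
#'   exact end-of-run state (`last`) for [rms_resume()].
#' @export
rms_train <- function(dataset_dir, config = train_config(), quiet = TRUE) {
  cfg <- net_config_of(config)
  params <- rms_init_params(cfg, config$seed)
  state <- list(
    params = params, opt = adam_init(params),
    best_params = params, best_val = Inf, epoch = 0L,
    history = list()
  )
  set.seed(config$seed + 1L)
  state$rng <- get(".Random.seed", globalenv())
  run_training(state, dataset_dir, config, quiet)
}

#' Resume training from a checkpoint
#'
#' Restores parameters, optimizer state and RNG state, and continues until
#' `config$epochs`; resuming mid-run is exactly equivalent to an
#' uninterrupted run on the same data.
#'
#' @param checkpoint an `rms_checkpoint` from [rms_train()].
#' @param dataset_dir phantom dataset directory.
#' @param config a [train_config()]; its architecture must match the
#'   checkpoint (validated by hash).
#' @param quiet suppress progress lines.
#' @return An updated `rms_checkpoint`.
#' @export
rms_resume <- function(checkpoint, dataset_dir, config, quiet = TRUE) {
  stopifnot(inherits(checkpoint, "rms_checkpoint"))
  if (!identical(checkpoint$arch_hash, arch_hash_of(net_config_of(config)))) {
    abort("architecture mismatch: checkpoint was trained with a different network configuration")
  }
  if (checkpoint$last$epoch >= config$epochs) return(checkpoint)
  state <- list(
    params = checkpoint$last$params, opt = checkpoint$last$opt,
    best_params = checkpoint$params, best_val = checkpoint$last$best_val,
    epoch = checkpoint$last$epoch,
    history = lapply(seq_len(nrow(checkpoint$history)), function(i) {
      as.list(checkpoint$history[i, ])
    }),
    rng = checkpoint$last$rng
  )
  run_training(state, dataset_dir, config, quiet)
}

arch_hash_of <- function(cfg) hash_object(unclass(cfg))

run_training <- function(state, dataset_dir, config, quiet) {
  cfg <- net_config_of(config)
  weights <- loss_weights_of(config)
  train_cases <- load_training_cases(dataset_dir, "train", cfg$image_size)
  val_cases <- tryCatch(
    load_training_cases(dataset_dir, "test", cfg$image_size),
    error = function(e) NULL
  )
  assign(".Random.seed", state$rng, envir = globalenv())
  n <- length(train_cases)
  while (state$epoch < config$epochs) {
    state$epoch <- state$epoch + 1L
    order_idx <- sample.int(n)
    comp <- c(smooth = 0, mse = 0, ncc = 0, total = 0)
    b0 <- 1
    while (b0 <= n) {
      idx <- order_idx[b0:min(b0 + config$batch_size - 1L, n)]
      acc <- NULL
      for (i in idx) {
        cl <- case_loss_and_grads(state$params, cfg, train_cases[[i]],
                                  weights, config$ncc_window)
        if (!is.finite(cl$loss$total)) {
          abort(sprintf("non-finite loss at epoch %d (case %s): smooth=%g mse=%g ncc=%g",
                        state$epoch, train_cases[[i]]$case_id,
                        cl$loss$smooth, cl$loss$mse, cl$loss$ncc))
        }
        comp <- comp + c(cl$loss$smooth, cl$loss$mse, cl$loss$ncc, cl$loss$total)
        acc <- if (is.null(acc)) cl$grads else tree_map2(acc, cl$grads, `+`)
      }
      acc <- tree_map(acc, function(g) g / length(idx))
      lr <- config$learning_rate * (config$lr_decay %||% 1)^(state$epoch - 1)
      st <- adam_step(state$params, acc, state$opt, lr)
      state$params <- st$params
      state$opt <- st$state
      b0 <- b0 + config$batch_size
    }
    comp <- comp / n
    val <- NA_real_
    if (!is.null(val_cases) &&
        (state$epoch %% config$val_every == 0 || state$epoch == config$epochs)) {
      val <- validation_loss(state$params, cfg, val_cases, weights,
                             config$ncc_window)
      if (val < state$best_val) {
        state$best_val <- val
        state$best_params <- state$params
      }
    }
    state$history[[length(state$history) + 1]] <-
      list(epoch = state$epoch, smooth = comp[["smooth"]],
           mse = comp[["mse"]], ncc = comp[["ncc"]],
           total = comp[["total"]], val_total = val)
    if (!quiet) {
      message(sprintf("epoch %3d  total %.5f  mse %.5f  ncc %.4f  val %s",
                      state$epoch, comp[["total"]], comp[["mse"]],
                      comp[["ncc"]],
                      if (is.na(val)) "-" else sprintf("%.5f", val)))
    }
  }
  state$rng <- get(".Random.seed", globalenv())
  history <- if (length(state$history)) {
    dplyr::bind_rows(lapply(state$history, tibble::as_tibble))
  } else {
    tibble::tibble(epoch = integer(), smooth = numeric(), mse = numeric(),
                   ncc = numeric(), total = numeric(), val_total = numeric())
  }
  best <- if (is.finite(state$best_val)) state$best_params else state$params
  structure(
    list(
      params = best,
      net_config = cfg,
      train_config = config,
      arch_hash = arch_hash_of(cfg),
      config_hash = hash_object(unclass(config)),
      history = history,
      last = list(params = state$params, opt = state$opt, rng = state$rng,
                  epoch = state$epoch, best_val = state$best_val)
    ),
    class = "rms_checkpoint"
  )
}

#' @export
print.rms_checkpoint <- function(x, ...) {
  np <- length(tree_unlist(unclass(x$params)))
  cat("<rms_checkpoint> ", x$net_config$image_size[1], "x",
      x$net_config$image_size[2], " px, base ", x$net_config$base_channels,
      ", latent ", x$net_config$latent, "; ", np, " parameters; ",
      x$last$epoch, " epochs\n", sep = "")
  if (nrow(x$history)) {
    f <- x$history[nrow(x$history), ]
    cat(sprintf("  final loss: total %.5f (smooth %.5f, mse %.5f, ncc %.4f)\n",
                f$total, f$smooth, f$mse, f$ncc))
  }
  invisible(x)
}

#' Save / load a checkpoint
#'
#' The file bundles parameters with the architecture metadata needed to
#' rebuild the network; loading validates the architecture hash, and a
#' load-save round trip is idempotent.
#'
#' @param checkpoint an `rms_checkpoint`.
#' @param path file path (`.rds`).
#' @return `load_rms_checkpoint` returns the checkpoint.
#' @export
save_rms_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "rms_checkpoint"))
  saveRDS(checkpoint, path, version = 2)
  invisible(path)
}

#' @rdname save_rms_checkpoint
#' @export
load_rms_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  if (!inherits(ckpt, "rms_checkpoint")) abort("not an rms checkpoint file")
  if (!identical(ckpt$arch_hash, arch_hash_of(ckpt$net_config))) {
    abort("checkpoint architecture hash does not match its metadata")
  }
  ckpt
}
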