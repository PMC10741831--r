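# Small shared helpers: seeded evaluation, grids, resizing, components.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# 0-based pixel-coordinate grids: x = column index, y = row index.
pixel_grid <- function(h, w) {
  list(
    x = matrix(rep(seq_len(w) - 1, each = h), h, w),
    y = matrix(rep(seq_len(h) - 1, times = w), h, w)
  )
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Bilinear resize with corner alignment (used by crop_and_normalize).
resize_bilinear <- function(img, out_h, out_w) {
  h <- nrow(img)
  w <- ncol(img)
  sr <- if (out_h == 1) rep(0, out_h) else (seq_len(out_h) - 1) * (h - 1) / (out_h - 1)
  sc <- if (out_w == 1) rep(0, out_w) else (seq_len(out_w) - 1) * (w - 1) / (out_w - 1)
  r0 <- pmin(floor(sr), h - 2)
  c0 <- pmin(floor(sc), w - 2)
  r0[r0 < 0] <- 0
  c0[c0 < 0] <- 0
  fr <- sr - r0
  fc <- sc - c0
  a <- img[r0 + 1, c0 + 1, drop = FALSE]
  b <- img[r0 + 2, c0 + 1, drop = FALSE]
  cc <- img[r0 + 1, c0 + 2, drop = FALSE]
  d <- img[r0 + 2, c0 + 2, drop = FALSE]
  fr <- matrix(fr, out_h, out_w)
  fc <- matrix(fc, out_h, out_w, byrow = TRUE)
  (1 - fr) * (1 - fc) * a + fr * (1 - fc) * b + (1 - fr) * fc * cc + fr * fc * d
}

# Connected components of a logical 2D/3D array (4-/6-neighbourhood).
label_components <- function(mask) {
  dims <- dim(mask)
  if (is.null(dims)) abort("`mask` must be a matrix or 3D array.")
  cpp_label_components(as.logical(mask), as.integer(dims))
}

n_components <- function(mask) {
  max(label_components(mask))
}

# Keep the `k` largest components of a logical array.
largest_components <- function(mask, k) {
  lab <- label_components(mask)
  if (max(lab) < k) return(NULL)
  sizes <- tabulate(lab[lab > 0])
  keep <- order(sizes, decreasing = TRUE)[seq_len(k)]
  out <- array(0L, dim(mask))
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  out
}

# Stable content hash for manifests: md5 of a canonical JSON rendering.
hash_object <- function(x) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(txt), f)
  unname(tools::md5sum(f))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
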