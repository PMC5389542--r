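# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Integer translation of a matrix: content moves by +dy rows, +dx cols;
# vacated pixels take `fill`.
shift_matrix <- function(m, dy, dx, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dy
  src_c <- seq_len(nc) - dx
  ok_r <- src_r >= 1L & src_r <= nr
  ok_c <- src_c >= 1L & src_c <= nc
  if (any(ok_r) && any(ok_c))
    out[which(ok_r), which(ok_c)] <- m[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}

# Binary erosion with the 3x3 (8-connected) structuring element.
# Pixels outside the image count as background.
erode3x3 <- function(mask) {
  out <- mask
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    out <- out & shift_matrix(mask, dy, dx, fill = FALSE)
  }
  out
}

# Separable Gaussian blur with edge renormalization (kernel truncated at
# the image border and rescaled, so a flat image stays flat). sigma = 0 is
# the identity.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  blur1 <- function(m) {
    n <- nrow(m)
    acc <- matrix(0, nrow(m), ncol(m))
    wt <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) {
      d <- i - r - 1L
      acc <- acc + k[i] * shift_matrix(m, d, 0, fill = 0)
      wt <- wt + k[i] * shift_matrix(matrix(1, n, ncol(m)), d, 0, fill = 0)
    }
    acc / wt
  }
  t(blur1(t(blur1(img))))
}

# round-half-up (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

# raster (row-major) ordering index for (row, col) pairs
raster_rank <- function(row, col, ncol) (row - 1) * ncol + col

stop_if_not_matrix <- function(x, what = "image") {
  if (!is.matrix(x) || !is.numeric(x) && !is.logical(x))
    stop(sprintf("`%s` must be a numeric matrix", what), call. = FALSE)
}
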