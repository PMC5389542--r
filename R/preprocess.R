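# Image preparation: background subtraction, automatic thresholding,
# translational registration of channels.

#' Rolling-ball background subtraction
#'
#' Estimates the background as the grayscale opening of the image with a
#' spherical ("rolling ball") structuring element and subtracts it,
#' clipping at zero. Features narrower than the ball (cells) are preserved;
#' smooth background variation wider than the ball is removed. The default
#' radius of 50 px suits typical bacterial fields; it must comfortably
#' exceed the cell width.
#'
#' @param image Numeric matrix.
#' @param ball_radius Ball radius in pixels (>= 1, smaller than the image).
#' @return Background-subtracted matrix (the input is not modified).
#' @export
subtract_background <- function(image, ball_radius = 50) {
  stop_if_not_matrix(image)
  if (ball_radius < 1) stop("ball_radius must be >= 1")
  if (2 * ball_radius + 1 > min(dim(image)))
    stop(sprintf("ball_radius %g too large for a %dx%d image",
                 ball_radius, nrow(image), ncol(image)))
  bg <- .rolling_ball_bg(image, ball_radius)
  pmax(image - bg, 0)
}

#' ISODATA (iterative intermeans) automatic threshold
#'
#' Computes the classic iterative-intermeans threshold: starting from the
#' image mean, the threshold is repeatedly set to the midpoint of the mean
#' intensities below and above it until it stabilises. Pixels strictly
#' above the threshold form the foreground; with `dark_foreground = TRUE`
#' (e.g. phase-contrast images of bacteria, which are darker than the
#' background) pixels strictly below the threshold do.
#'
#' @param image Numeric matrix with at least two distinct values.
#' @param dark_foreground Logical; select pixels below the threshold
#'   instead of above it.
#' @return Logical mask of the same shape, with attributes `threshold` and
#'   `method` recording the provenance.
#' @export
threshold_isodata <- function(image, dark_foreground = FALSE) {
  stop_if_not_matrix(image)
  v <- as.numeric(image)
  if (length(unique(v)) < 2)
    stop("cannot threshold a constant image (only one intensity value)")
  t_cur <- mean(v)
  for (i in 1:200) {
    lo <- v[v <= t_cur]; hi <- v[v > t_cur]
    if (length(hi) == 0 || length(lo) == 0) { # walked off the histogram
      t_cur <- mean(range(v))
      next
    }
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t_cur) < 1e-9) break
    t_cur <- t_new
  }
  mask <- if (dark_foreground) image < t_cur else image > t_cur
  attr(mask, "threshold") <- t_cur
  attr(mask, "method") <- sprintf("isodata intermeans, dark_foreground=%s",
                                  dark_foreground)
  mask
}

#' Estimate the integer translation between two binary masks
#'
#' Exhaustive search over all integer shifts within `max_shift`: returns
#' the displacement `c(dy, dx)` of `mask_moving` relative to `mask_ref`,
#' i.e. the shift that, applied to `mask_ref`, maximizes the foreground
#' overlap count with `mask_moving`. Ties are broken by smallest
#' `|dy| + |dx|`, then smallest `dy`, then smallest `dx`. To align the
#' moving image back onto the reference, apply the *negated* offset with
#' [apply_offset()].
#'
#' @param mask_ref,mask_moving Logical masks of identical shape, each with
#'   at least one foreground pixel.
#' @param max_shift Maximum absolute shift searched in each axis.
#' @return Integer vector `c(dy, dx)` with attribute `overlap` (the
#'   maximal overlap count).
#' @export
estimate_offset <- function(mask_ref, mask_moving, max_shift = 10L) {
  if (!all(dim(mask_ref) == dim(mask_moving)))
    stop("masks must have identical shape")
  if (!any(mask_ref)) stop("reference mask is empty")
  if (!any(mask_moving)) stop("moving mask is empty")
  shifts <- expand.grid(dy = -max_shift:max_shift, dx = -max_shift:max_shift)
  score <- integer(nrow(shifts))
  for (i in seq_len(nrow(shifts))) {
    score[i] <- sum(shift_matrix(mask_ref, shifts$dy[i], shifts$dx[i],
                                 fill = FALSE) & mask_moving)
  }
  best <- max(score)
  cand <- shifts[score == best, , drop = FALSE]
  ord <- order(abs(cand$dy) + abs(cand$dx), cand$dy, cand$dx)
  pick <- cand[ord[1], ]
  structure(c(dy = as.integer(pick$dy), dx = as.integer(pick$dx)),
            overlap = best)
}

#' Apply an integer translation to an image
#'
#' Content moves by `+dy` rows and `+dx` columns; vacated pixels take
#' `fill`. The shape is preserved.
#'
#' @param image Numeric matrix.
#' @param offset Integer `c(dy, dx)`.
#' @param fill Fill value for vacated pixels (default 0).
#' @return Translated matrix.
#' @export
apply_offset <- function(image, offset, fill = 0) {
  stop_if_not_matrix(image)
  stopifnot(length(offset) == 2)
  shift_matrix(image, as.integer(offset[1]), as.integer(offset[2]), fill = fill)
}
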