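# Per-cell localization statistics: normalization, top-fraction pixel
# selection, observed/expected overlap, the threshold overlap score (TOS),
# the erosion-based membrane TOS, and signal-to-background exclusion.

#' Global normalization of a set of images
#'
#' Linearly rescales every image by the single (low, high) pair taken over
#' all images jointly, mapping the global range to `[0, 1]`. Used for
#' comparing absolute signal between strains.
#'
#' @param images Named or unnamed list of numeric matrices (>= 1).
#' @return List of rescaled matrices in `[0, 1]`.
#' @export
normalize_global <- function(images) {
  if (!is.list(images) || length(images) < 1) stop("need at least one image")
  lo <- min(vapply(images, min, 0))
  hi <- max(vapply(images, max, 0))
  if (hi == lo) stop("global high equals global low: cannot normalize")
  lapply(images, function(img) (img - lo) / (hi - lo))
}

#' Cellular normalization of per-cell pixel arrays
#'
#' Rescales each cell independently to `[0, 1]` using that cell's own
#' extremes, as used for per-cell heat maps. A constant cell cannot be
#' scaled: it is flagged and given heat 0.5 everywhere (visualization
#' only; such cells carry no ranking information).
#'
#' @param cell_arrays List of data.frames with a `value` column (e.g. from
#'   [cell_pixels()]).
#' @return The same list with an added `heat` column; attribute
#'   `constant_cells` lists the indices of flagged constant cells.
#' @export
normalize_cellular <- function(cell_arrays) {
  flagged <- integer(0)
  out <- lapply(seq_along(cell_arrays), function(i) {
    df <- cell_arrays[[i]]
    lo <- min(df$value); hi <- max(df$value)
    if (hi == lo) {
      df$heat <- rep(0.5, nrow(df))
      flagged <<- c(flagged, i)
    } else df$heat <- (df$value - lo) / (hi - lo)
    df
  })
  names(out) <- names(cell_arrays)
  attr(out, "constant_cells") <- flagged
  out
}

#' Select the top-F_T fraction of pixels in a cell
#'
#' Returns the `n_sel = max(1, round(F_T * n))` pixels of highest
#' intensity (round-half-up). Ties at the cutoff are broken by raster
#' order (smaller row first, then smaller column), so the selection is
#' deterministic.
#'
#' @param cell_df data.frame with columns `row`, `col`, `value`.
#' @param f_t Selected fraction in (0, 1); default 0.1 as set by the
#'   accompanying power calculation ([selected_fraction_power()]).
#' @return Object of class `threshold_selection`: list with `selected`
#'   (n_sel x 2 row/col matrix), `n_sel`, `n_cell_pixels`, `f_t`.
#' @export
select_top_fraction <- function(cell_df, f_t = 0.1) {
  if (!is.data.frame(cell_df) || nrow(cell_df) == 0)
    stop("cell_df must be a nonempty data.frame")
  if (!(f_t > 0 && f_t < 1)) stop("f_t must lie in (0, 1)")
  n <- nrow(cell_df)
  n_sel <- max(1L, as.integer(round_half_up(f_t * n)))
  ord <- order(-cell_df$value, cell_df$row, cell_df$col)
  sel <- as.matrix(cell_df[ord[seq_len(n_sel)], c("row", "col")])
  rownames(sel) <- NULL
  structure(list(selected = sel, n_sel = n_sel, n_cell_pixels = n,
                 f_t = f_t),
            class = "threshold_selection")
}

pixel_key <- function(m) paste(m[, 1], m[, 2], sep = ",")

#' Observed fractional overlap of two top-fraction selections
#'
#' The number of pixels common to the signal and reference selections,
#' divided by the size of the reference (DAPI) selection.
#'
#' @param sel_signal,sel_ref `threshold_selection` objects from the same
#'   cell (signal channel and reference/DAPI channel).
#' @return Fraction in `[0, 1]`.
#' @export
observed_overlap <- function(sel_signal, sel_ref) {
  stopifnot(inherits(sel_signal, "threshold_selection"),
            inherits(sel_ref, "threshold_selection"))
  if (sel_ref$n_sel == 0) stop("empty reference selection")
  sum(pixel_key(sel_signal$selected) %in% pixel_key(sel_ref$selected)) /
    sel_ref$n_sel
}

#' Threshold overlap score (TOS)
#'
#' Rescales the observed/expected overlap ratio to `[-1, 1]`:
#' 0 when observed equals expected; `observed/expected - 1` when observed
#' is below expected (reaching -1 at zero overlap); and
#' `(observed/expected - 1) / (1/expected - 1)` when above (reaching +1 at
#' complete overlap). Positive, zero and negative scores mean
#' colocalization, non-colocalization and anticolocalization with the
#' reference region, independent of how clustered the selections are.
#'
#' @param observed Observed overlap fraction(s) in `[0, 1]` (vectorized).
#' @param expected Expected overlap under the uniform null, in (0, 1); for
#'   whole-cell analysis this equals the selected fraction F_T.
#' @return Score(s) in `[-1, 1]`.
#' @export
tos <- function(observed, expected) {
  if (!(expected > 0 && expected < 1))
    stop("expected overlap must lie strictly inside (0, 1)")
  if (any(observed < 0 | observed > 1))
    stop("observed overlap must lie in [0, 1]")
  ratio <- observed / expected
  ifelse(observed == expected, 0,
         ifelse(observed < expected, ratio - 1,
                (ratio - 1) / (1 / expected - 1)))
}

#' Null expectation of the observed overlap
#'
#' Expected fractional overlap of the reference selection with a signal
#' whose selected pixels are a uniformly random subset of the cell,
#' independent of the reference: the overlap count is hypergeometric, and
#' its mean divided by the reference selection size equals `n_sel / n`.
#' For whole-cell analysis with `round(F_T * n) = F_T * n` this is F_T
#' exactly; the discrepancy for other cell sizes is at most one pixel's
#' worth and the convention used throughout is the stated F_T.
#'
#' @param n_pixels Number of pixels in the cell.
#' @param f_t Selected fraction.
#' @return The exact null expectation (computed from the hypergeometric
#'   law, not assumed).
#' @export
null_expected_overlap <- function(n_pixels, f_t = 0.1) {
  stopifnot(n_pixels >= 1, f_t > 0, f_t < 1)
  n_sel <- max(1L, as.integer(round_half_up(f_t * n_pixels)))
  k <- 0:n_sel
  # mean overlap count when n_sel of n pixels are marked and n_sel drawn
  sum(k * stats::dhyper(k, n_sel, n_pixels - n_sel, n_sel)) / n_sel
}

#' Partition a cell into edge, membrane and interior pixel layers
#'
#' Successive 3x3 erosions of the cell mask: the outermost layer
#' (`discarded_edge`) is dropped from membrane analysis because it mixes
#' intra- and extracellular signal and suffers the point-spread edge
#' effect; the next layer is the `membrane`; everything deeper is
#' `interior`. The three sets partition the cell. Cells too thin to retain
#' an interior after two erosions are excluded (returns `NULL` with a
#' message).
#'
#' @param pixels n x 2 (row, col) pixel matrix of one cell (or a
#'   `cell_roi`, whose `$pixels` is used).
#' @return List of class `membrane_layers` with `discarded_edge`,
#'   `membrane`, `interior` (row/col matrices), or `NULL` if degenerate.
#' @export
membrane_layers <- function(pixels) {
  if (inherits(pixels, "cell_roi")) pixels <- pixels$pixels
  r0 <- min(pixels[, 1]) - 2L; c0 <- min(pixels[, 2]) - 2L
  nr <- max(pixels[, 1]) - r0 + 3L; nc <- max(pixels[, 2]) - c0 + 3L
  m <- matrix(FALSE, nr, nc)
  m[cbind(pixels[, 1] - r0, pixels[, 2] - c0)] <- TRUE
  e1 <- erode3x3(m)
  e2 <- erode3x3(e1)
  if (!any(e2)) {
    message("cell excluded from membrane analysis: no interior after two erosions")
    return(NULL)
  }
  grab <- function(msk) {
    idx <- which(msk, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    cbind(row = idx[, 1] + r0, col = idx[, 2] + c0)
  }
  structure(list(discarded_edge = grab(m & !e1),
                 membrane = grab(e1 & !e2),
                 interior = grab(e2)),
            class = "membrane_layers")
}

#' Membrane threshold overlap score for one cell
#'
#' Ranks the cell's pixel intensities after discarding the outermost
#' (edge) layer, selects the top `f_t` fraction, and scores its overlap
#' with the membrane layer. The expected overlap under a uniform null is
#' the membrane layer's share of the eroded cell. With
#' `ranking = "whole"` the selection is instead taken over the whole cell
#' (both conventions are defensible readings of the procedure; the eroded
#' cell is the default because the edge layer is explicitly discarded).
#'
#' @param cell_df data.frame `row`, `col`, `value` for the whole cell.
#' @param layers A [membrane_layers()] result (or `NULL`).
#' @param f_t Selected fraction (default 0.1).
#' @param ranking `"eroded"` (default) or `"whole"`.
#' @return List with `observed`, `expected`, `tos`, or `NULL` if the cell
#'   was excluded from membrane analysis.
#' @export
membrane_tos <- function(cell_df, layers, f_t = 0.1,
                         ranking = c("eroded", "whole")) {
  if (is.null(layers)) return(NULL)
  ranking <- match.arg(ranking)
  stopifnot(inherits(layers, "membrane_layers"))
  key <- paste(cell_df$row, cell_df$col, sep = ",")
  domain_key <- if (ranking == "eroded")
    c(pixel_key(layers$membrane), pixel_key(layers$interior))
  else key
  df <- cell_df[key %in% domain_key, , drop = FALSE]
  sel <- select_top_fraction(df, f_t)
  mem_key <- pixel_key(layers$membrane)
  observed <- sum(pixel_key(sel$selected) %in% mem_key) / sel$n_sel
  expected <- length(mem_key) / nrow(df)
  list(observed = observed, expected = expected,
       tos = tos(observed, expected))
}

#' Per-cell signal-to-background ratios with inclusion flags
#'
#' Background is the mean intensity over unlabeled (non-cell) pixels of
#' the image; each cell's ratio is its mean in-cell intensity divided by
#' that background. Cells strictly below `cutoff` are flagged for
#' exclusion (equality is retained), mirroring the practice of dropping
#' cells with average signal-to-background below 1.2-fold (mRNA/Cy3
#' channel) or 1.3-fold (sRNA/Cy5 channel).
#'
#' @param image Intensity matrix.
#' @param count_mask Label matrix from [build_count_mask()].
#' @param cutoff Inclusion cutoff (default 1.3).
#' @return data.frame `cell_id`, `sb_ratio`, `included`.
#' @export
signal_to_background <- function(image, count_mask, cutoff = 1.3) {
  if (!all(dim(image) == dim(count_mask)))
    stop("image and count_mask shapes differ")
  bg_px <- image[count_mask == 0L]
  if (length(bg_px) == 0) stop("no unlabeled pixels: background undefined")
  bg <- mean(bg_px)
  if (bg <= 0) stop("background mean is not positive")
  ids <- sort(unique(count_mask[count_mask > 0L]))
  ratio <- vapply(ids, function(id) mean(image[count_mask == id]) / bg, 0)
  data.frame(cell_id = ids, sb_ratio = ratio, included = ratio >= cutoff)
}
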