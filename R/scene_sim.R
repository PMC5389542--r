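# Synthetic microscopy-scene generator.
#
# Scenes emulate fields of rod-shaped bacteria imaged in phase contrast
# (dark cells on a bright background), a DAPI channel marking the nucleoid,
# and an RNA FISH channel whose true localization mode is known. Because
# the ground-truth geometry is retained, every downstream stage
# (registration, segmentation, scoring) can be tested against truth.

LOCALIZATION_MODES <- c("uniform", "nucleoid_excluded", "nucleoid_enriched",
                        "membrane", "polar")

# Rasterize a spherocylinder: all pixel centers within width/2 of the
# centerline segment. Returns an n x 2 (row, col) integer matrix.
rasterize_spherocylinder <- function(center, theta, length, width,
                                     image_shape) {
  hl <- (length - width) / 2         # half-length of the straight part
  rad <- width / 2
  u <- c(cos(theta), sin(theta))     # axis direction in (row, col)
  half <- length / 2 + 1
  r0 <- max(1L, floor(center[1] - half)); r1 <- min(image_shape[1], ceiling(center[1] + half))
  c0 <- max(1L, floor(center[2] - half)); c1 <- min(image_shape[2], ceiling(center[2] + half))
  rr <- r0:r1; cc <- c0:c1
  gr <- matrix(rr, length(rr), length(cc)) - center[1]
  gc <- matrix(cc, length(rr), length(cc), byrow = TRUE) - center[2]
  proj <- gr * u[1] + gc * u[2]
  clamped <- pmin(pmax(proj, -hl), hl)
  dr <- gr - clamped * u[1]
  dc <- gc - clamped * u[2]
  inside <- (dr * dr + dc * dc) <= rad * rad
  idx <- which(inside, arr.ind = TRUE)        # column-major order
  pix <- cbind(row = rr[idx[, 1]], col = cc[idx[, 2]])
  proj_vals <- proj[inside]                   # same (column-major) order
  ord <- order(pix[, 1], pix[, 2])            # raster order
  out <- pix[ord, , drop = FALSE]
  attr(out, "proj") <- proj_vals[ord]
  attr(out, "hl") <- hl
  out
}

#' Generate ground-truth geometry for a synthetic scene
#'
#' Places `n_cells` non-overlapping spherocylindrical (rod-shaped) cells in
#' an image by rejection sampling. Each cell carries a nucleoid, an
#' axis-aligned scaled copy of the cell occupying `nucleoid_area_fraction`
#' of its area (literature estimates put the nucleoid at roughly 50-75% of
#' the cell volume), and two polar caps. All cells have true length/width
#' ratio above 2.01 so they survive the standard rod-shape filter.
#'
#' @param n_cells Number of cells to place (0 allowed).
#' @param cell_length_range,cell_width_range Tip-to-tip length and width
#'   ranges in pixels; lengths are resampled until length/width > 2.01.
#' @param nucleoid_area_fraction Target nucleoid/cell area fraction in (0,1).
#' @param image_shape `c(rows, cols)` of the scene in pixels.
#' @param seed Integer RNG seed; identical seed and parameters give a
#'   bitwise-identical scene.
#' @param gap Minimum pixel gap enforced between cells (default 2).
#' @param margin Pixels kept free along the image border (default 3).
#' @param max_tries Placement attempts before giving up.
#' @return An object of class `scene_truth`: list with `image_shape`,
#'   `cells` (per cell: `id`, `cell`, `nucleoid`, `poles` pixel matrices),
#'   label matrices `cell_labels`, `nucleoid_labels`, `pole_labels`, the
#'   requested `nucleoid_area_fraction`, `seed` and the generation params.
#' @export
make_geometry <- function(n_cells,
                          cell_length_range = c(40, 50),
                          cell_width_range = c(12, 15),
                          nucleoid_area_fraction = 0.6,
                          image_shape = c(512L, 512L),
                          seed = 1L,
                          gap = 2L,
                          margin = 3L,
                          max_tries = 200L * max(n_cells, 1L)) {
  stopifnot(n_cells >= 0, all(cell_length_range > 0), all(cell_width_range > 0),
            nucleoid_area_fraction > 0, nucleoid_area_fraction < 1,
            length(image_shape) == 2, all(image_shape >= 8))
  image_shape <- as.integer(image_shape)
  cell_labels <- matrix(0L, image_shape[1], image_shape[2])
  nucleoid_labels <- matrix(0L, image_shape[1], image_shape[2])
  pole_labels <- matrix(0L, image_shape[1], image_shape[2])
  cells <- vector("list", n_cells)
  with_seed(seed, {
    placed <- 0L
    tries <- 0L
    while (placed < n_cells) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop(sprintf(paste0("cell placement failed after %d tries: %d of %d ",
                            "cells placed; requested density too high for a ",
                            "%dx%d image"),
                     max_tries, placed, n_cells,
                     image_shape[1], image_shape[2]), call. = FALSE)
      }
      len <- stats::runif(1, cell_length_range[1], cell_length_range[2])
      wid <- stats::runif(1, cell_width_range[1], cell_width_range[2])
      if (len / wid <= 2.01) next
      theta <- stats::runif(1, 0, pi)
      half <- len / 2 + 1
      lo_r <- margin + half; hi_r <- image_shape[1] - margin - half
      lo_c <- margin + half; hi_c <- image_shape[2] - margin - half
      if (hi_r <= lo_r || hi_c <= lo_c)
        stop("image too small for requested cell size", call. = FALSE)
      center <- c(stats::runif(1, lo_r, hi_r), stats::runif(1, lo_c, hi_c))
      pix <- rasterize_spherocylinder(center, theta, len, wid, image_shape)
      if (nrow(pix) == 0) next
      # overlap check against existing cells, with a safety gap
      clash <- FALSE
      for (dy in -gap:gap) {
        for (dx in -gap:gap) {
          rs <- pix[, 1] + dy; cs <- pix[, 2] + dx
          ok <- rs >= 1 & rs <= image_shape[1] & cs >= 1 & cs <= image_shape[2]
          if (any(cell_labels[cbind(rs[ok], cs[ok])] != 0L)) { clash <- TRUE; break }
        }
        if (clash) break
      }
      if (clash) next
      placed <- placed + 1L
      id <- placed
      k <- sqrt(nucleoid_area_fraction)
      nuc <- rasterize_spherocylinder(center, theta, len * k, wid * k,
                                      image_shape)
      proj <- attr(pix, "proj")
      hl <- attr(pix, "hl")
      poles <- pix[abs(proj) > hl, , drop = FALSE]
      cell_labels[pix] <- id
      nucleoid_labels[nuc] <- id
      pole_labels[poles] <- id
      cells[[id]] <- list(id = id, cell = pix, nucleoid = nuc, poles = poles,
                          center = center, theta = theta,
                          length = len, width = wid)
    }
  })
  structure(list(image_shape = image_shape, cells = cells,
                 cell_labels = cell_labels,
                 nucleoid_labels = nucleoid_labels,
                 pole_labels = pole_labels,
                 nucleoid_area_fraction = nucleoid_area_fraction,
                 seed = as.integer(seed),
                 params = list(cell_length_range = cell_length_range,
                               cell_width_range = cell_width_range,
                               gap = gap, margin = margin)),
            class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> %d cells in %dx%d px, nucleoid fraction %.2f, seed %d\n",
              length(x$cells), x$image_shape[1], x$image_shape[2],
              x$nucleoid_area_fraction, x$seed))
  invisible(x)
}

#' Rendering parameters for synthetic channels
#'
#' Defaults describe a plausible EM-CCD fluorescence acquisition at
#' ~0.065 um/px: a 1 px Gaussian point-spread blur, a flat background of
#' 100 counts, Poisson shot noise on expected counts plus Gaussian read
#' noise (sd 5 counts), no inter-channel offset, 16-bit quantization.
#'
#' @param psf_sigma Gaussian PSF sigma in pixels (0 disables blur).
#' @param background_level Flat background intensity added to all channels.
#' @param poisson Apply Poisson shot noise to expected counts?
#' @param read_noise_sd Gaussian read-noise standard deviation (0 disables).
#' @param channel_offset Integer `c(dy, dx)` translation applied to the
#'   fluorescence channels (not the phase channel), emulating chromatic /
#'   stage offsets that registration must undo.
#' @param bit_depth Quantization bit depth (intensities clamped to
#'   `[0, 2^bit_depth - 1]`).
#' @return A list of class `render_params`.
#' @export
render_params <- function(psf_sigma = 1, background_level = 100,
                          poisson = TRUE, read_noise_sd = 5,
                          channel_offset = c(0L, 0L), bit_depth = 16L) {
  stopifnot(psf_sigma >= 0, background_level >= 0, read_noise_sd >= 0,
            length(channel_offset) == 2, bit_depth %in% c(8L, 16L))
  structure(list(psf_sigma = psf_sigma, background_level = background_level,
                 poisson = poisson, read_noise_sd = read_noise_sd,
                 channel_offset = as.integer(channel_offset),
                 bit_depth = as.integer(bit_depth)),
            class = "render_params")
}

#' Render the image channels of a synthetic scene
#'
#' Produces a phase-contrast cartoon (bright background, dark cells), a
#' DAPI channel with signal density on the nucleoid only, and an RNA
#' channel whose signal density follows `mode`:
#' `uniform` (whole cell), `nucleoid_excluded` (cell minus nucleoid),
#' `nucleoid_enriched` (nucleoid only), `membrane` (the one-pixel boundary
#' layer of the cell) or `polar` (the spherocylinder caps). Each density
#' map is blurred with the PSF, background and noise are added, the
#' fluorescence channels are shifted by `channel_offset`, and everything
#' is quantized to the configured bit depth.
#'
#' @param truth A `scene_truth` from [make_geometry()].
#' @param mode RNA localization mode (see above).
#' @param signal_level Peak signal density in counts (above background).
#' @param params A [render_params()] object.
#' @param seed Integer RNG seed for the noise draws.
#' @param phase_levels `c(cell, background)` intensities of the phase
#'   cartoon.
#' @return Named list of numeric matrices: `phase`, `dapi`, `rna`.
#' @export
render_channels <- function(truth, mode = "uniform", signal_level = 1000,
                            params = render_params(), seed = 1L,
                            phase_levels = c(8000, 30000)) {
  stopifnot(inherits(truth, "scene_truth"))
  mode <- match.arg(mode, LOCALIZATION_MODES)
  if (signal_level <= params$background_level && signal_level != 0)
    stop("signal_level must exceed background_level")
  shp <- truth$image_shape
  cell <- truth$cell_labels > 0L
  nuc <- truth$nucleoid_labels > 0L
  density_rna <- switch(mode,
    uniform = cell,
    nucleoid_excluded = cell & !nuc,
    nucleoid_enriched = nuc,
    membrane = cell & !erode3x3(cell),
    polar = truth$pole_labels > 0L)
  maxv <- 2^params$bit_depth - 1
  corrupt <- function(expected, is_fluor) {
    img <- gaussian_blur(expected, params$psf_sigma)
    img <- img + params$background_level
    if (params$poisson) img <- matrix(stats::rpois(length(img), lambda = img),
                                      nrow(img), ncol(img))
    if (params$read_noise_sd > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, params$read_noise_sd),
                          nrow(img), ncol(img))
    if (is_fluor && any(params$channel_offset != 0L))
      img <- shift_matrix(img, params$channel_offset[1],
                          params$channel_offset[2],
                          fill = params$background_level)
    img <- round(img)
    img[img < 0] <- 0
    img[img > maxv] <- maxv
    img
  }
  with_seed(seed, {
    phase <- matrix(phase_levels[2], shp[1], shp[2])
    phase[cell] <- phase_levels[1]
    # phase cartoon: blur + read noise only (not photon-limited), no offset
    phase <- gaussian_blur(phase, params$psf_sigma)
    if (params$read_noise_sd > 0)
      phase <- phase + matrix(stats::rnorm(length(phase), 0,
                                           params$read_noise_sd),
                              shp[1], shp[2])
    phase <- pmin(pmax(round(phase), 0), maxv)
    dapi <- corrupt(signal_level * nuc, is_fluor = TRUE)
    rna <- corrupt(signal_level * density_rna, is_fluor = TRUE)
    list(phase = phase, dapi = dapi, rna = rna)
  })
}

#' Write a rendered scene and its ground truth to disk
#'
#' One 16-bit grayscale TIFF per channel, the truth as label-image TIFFs
#' (integer cell ids) and a plain-text parameter record. The round trip
#' through [read_scene()] is lossless.
#'
#' @param truth A `scene_truth`.
#' @param images Named list of channel matrices (e.g. from
#'   [render_channels()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(truth, images, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)
  for (ch in names(images))
    write_tiff(images[[ch]], file.path(dir, paste0(ch, ".tif")), bits = 16L)
  write_tiff(truth$cell_labels, file.path(dir, "truth_cells.tif"), bits = 16L)
  write_tiff(truth$nucleoid_labels, file.path(dir, "truth_nucleoids.tif"),
             bits = 16L)
  write_tiff(truth$pole_labels, file.path(dir, "truth_poles.tif"), bits = 16L)
  rec <- c(sprintf("image_rows=%d", truth$image_shape[1]),
           sprintf("image_cols=%d", truth$image_shape[2]),
           sprintf("n_cells=%d", length(truth$cells)),
           sprintf("nucleoid_area_fraction=%.10g", truth$nucleoid_area_fraction),
           sprintf("seed=%d", truth$seed),
           sprintf("channels=%s", paste(names(images), collapse = ",")))
  writeLines(rec, file.path(dir, "scene_params.txt"))
  invisible(dir)
}

#' Read back a scene written by [write_scene()]
#'
#' @param dir Directory produced by [write_scene()].
#' @return List with `images` (named channel matrices) and `truth`, a
#'   `scene_truth` rebuilt from the label sidecars (pixel sets identical to
#'   the original; generator-internal fields like cell centers are not
#'   stored).
#' @export
read_scene <- function(dir) {
  par_file <- file.path(dir, "scene_params.txt")
  if (!file.exists(par_file)) stop("not a scene directory (no scene_params.txt): ", dir)
  kv <- strsplit(readLines(par_file), "=", fixed = TRUE)
  rec <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  channels <- strsplit(rec[["channels"]], ",", fixed = TRUE)[[1]]
  images <- lapply(channels, function(ch) {
    img <- read_tiff(file.path(dir, paste0(ch, ".tif")))
    attr(img, "bit_depth") <- NULL
    storage.mode(img) <- "double"
    img
  })
  names(images) <- channels
  cl <- read_tiff(file.path(dir, "truth_cells.tif")); attr(cl, "bit_depth") <- NULL
  nl <- read_tiff(file.path(dir, "truth_nucleoids.tif")); attr(nl, "bit_depth") <- NULL
  pl <- read_tiff(file.path(dir, "truth_poles.tif")); attr(pl, "bit_depth") <- NULL
  n_cells <- as.integer(rec[["n_cells"]])
  cells <- lapply(seq_len(n_cells), function(id) {
    pick <- function(lab) {
      idx <- which(lab == id, arr.ind = TRUE)
      idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
      colnames(idx) <- c("row", "col")
      idx
    }
    list(id = id, cell = pick(cl), nucleoid = pick(nl), poles = pick(pl))
  })
  truth <- structure(list(image_shape = dim(cl), cells = cells,
                          cell_labels = cl, nucleoid_labels = nl,
                          pole_labels = pl,
                          nucleoid_area_fraction =
                            as.numeric(rec[["nucleoid_area_fraction"]]),
                          seed = as.integer(rec[["seed"]]),
                          params = list()),
                     class = "scene_truth")
  list(images = images, truth = truth)
}
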