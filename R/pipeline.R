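# End-to-end convenience wrappers: simulate a scene, run the image chain
# (threshold -> watershed -> particle/shape filters -> count mask) and
# compute per-cell localization scores.

#' Simulate a complete synthetic scene
#'
#' Geometry plus rendered channels in one call.
#'
#' @param n_cells Number of cells.
#' @param mode RNA localization mode (see [render_channels()]).
#' @param params A [render_params()] object.
#' @param seed Integer seed controlling both geometry and noise.
#' @param signal_level Peak RNA/DAPI signal in counts.
#' @param ... Further arguments to [make_geometry()].
#' @return List with `truth` and `images` (`phase`, `dapi`, `rna`).
#' @export
simulate_scene <- function(n_cells = 30, mode = "uniform",
                           params = render_params(), seed = 1L,
                           signal_level = 1000, ...) {
  truth <- make_geometry(n_cells, seed = seed, ...)
  images <- render_channels(truth, mode = mode, signal_level = signal_level,
                            params = params, seed = seed + 1L)
  list(truth = truth, images = images)
}

#' Segment cells from a phase-contrast image
#'
#' Thresholds the phase image (dark cells), splits touching cells by
#' watershed, extracts particles and applies the shape/saturation filters.
#'
#' @param phase Phase-contrast matrix.
#' @param criteria A [filter_criteria()] object.
#' @param channel_images Named list of fluorescence matrices used for the
#'   saturation check.
#' @return List with `rois` (filtered), `count_mask`, `phase_mask` and the
#'   filter `rejections` counts.
#' @export
segment_phase <- function(phase, criteria = filter_criteria(),
                          channel_images = list()) {
  phase_mask <- threshold_isodata(phase, dark_foreground = TRUE)
  split_mask <- watershed_split(phase_mask)
  rois <- find_particles(split_mask, criteria$area_range)
  kept <- filter_cells(rois, criteria, channel_images)
  cm <- build_count_mask(kept, dim(phase))
  list(rois = kept, count_mask = cm, phase_mask = split_mask,
       rejections = attr(kept, "rejections"))
}

#' Score RNA localization for every cell in a scene
#'
#' Full analysis chain on a set of channel images: optional registration
#' of the fluorescence channels onto phase, segmentation, per-cell
#' top-fraction selection in the reference (DAPI) and signal (RNA)
#' channels, nucleoid TOS, membrane TOS and signal-to-background flags.
#'
#' @param images Named list with `phase`, `dapi` and `rna` matrices.
#' @param f_t Selected fraction (default 0.1).
#' @param criteria [filter_criteria()] for segmentation.
#' @param register Estimate and undo an integer offset of the fluorescence
#'   channels relative to phase (default FALSE; synthetic scenes are
#'   aligned unless an offset was injected).
#' @param max_shift Registration search range in pixels.
#' @param sb_cutoff Signal-to-background inclusion cutoff for the RNA
#'   channel (`NULL` disables the check; 1.2 and 1.3 are the conventional
#'   mRNA and sRNA cutoffs).
#' @param membrane_ranking Passed to [membrane_tos()].
#' @return data.frame, one row per accepted cell: `cell_id`, `area`,
#'   `aspect_ratio`, `min_feret`, `sb_ratio`, `included`, `observed`,
#'   `expected`, `tos`, `membrane_observed`, `membrane_expected`,
#'   `membrane_tos` (NA where the cell is too thin for membrane analysis).
#' @export
score_scene <- function(images, f_t = 0.1, criteria = filter_criteria(),
                        register = FALSE, max_shift = 10L,
                        sb_cutoff = NULL,
                        membrane_ranking = c("eroded", "whole")) {
  membrane_ranking <- match.arg(membrane_ranking)
  stopifnot(all(c("phase", "dapi", "rna") %in% names(images)))
  phase <- images$phase; dapi <- images$dapi; rna <- images$rna
  if (register) {
    phase_mask <- threshold_isodata(phase, dark_foreground = TRUE)
    for (ch in c("dapi", "rna")) {
      m <- threshold_isodata(images[[ch]])
      off <- estimate_offset(phase_mask, m, max_shift = max_shift)
      if (any(off != 0L))
        images[[ch]] <- apply_offset(images[[ch]], -off,
                                     fill = stats::median(images[[ch]]))
    }
    dapi <- images$dapi; rna <- images$rna
  }
  seg <- segment_phase(phase, criteria,
                       channel_images = list(dapi = dapi, rna = rna))
  cm <- seg$count_mask
  dapi_px <- cell_pixels(cm, dapi)
  rna_px <- cell_pixels(cm, rna)
  sb <- if (!is.null(sb_cutoff)) signal_to_background(rna, cm, sb_cutoff)
  rows <- lapply(seg$rois, function(roi) {
    id <- as.character(roi$id)
    ddf <- dapi_px[[id]]; rdf <- rna_px[[id]]
    sel_ref <- select_top_fraction(ddf, f_t)
    sel_sig <- select_top_fraction(rdf, f_t)
    obs <- observed_overlap(sel_sig, sel_ref)
    layers <- suppressMessages(membrane_layers(roi$pixels))
    mem <- membrane_tos(rdf, layers, f_t, ranking = membrane_ranking)
    data.frame(cell_id = roi$id, area = roi$area,
               aspect_ratio = roi$aspect_ratio, min_feret = roi$min_feret,
               sb_ratio = if (is.null(sb)) NA_real_
                          else sb$sb_ratio[sb$cell_id == roi$id],
               included = if (is.null(sb)) TRUE
                          else sb$included[sb$cell_id == roi$id],
               observed = obs, expected = f_t, tos = tos(obs, f_t),
               membrane_observed = if (is.null(mem)) NA_real_ else mem$observed,
               membrane_expected = if (is.null(mem)) NA_real_ else mem$expected,
               membrane_tos = if (is.null(mem)) NA_real_ else mem$tos)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) out <- data.frame(cell_id = integer(0))
  attr(out, "rejections") <- seg$rejections
  out
}

#' Jaccard overlap of segmented ROIs with ground-truth cells
#'
#' Matches each accepted ROI to the truth cell with which it shares the
#' most pixels and reports the Jaccard index of the pair. Used to verify
#' segmentation against the generator's ground truth.
#'
#' @param rois List of `cell_roi`.
#' @param truth A `scene_truth`.
#' @return data.frame `roi_id`, `truth_id`, `jaccard`.
#' @export
match_truth <- function(rois, truth) {
  rows <- lapply(rois, function(roi) {
    labs <- truth$cell_labels[roi$pixels]
    labs <- labs[labs > 0L]
    if (length(labs) == 0)
      return(data.frame(roi_id = roi$id, truth_id = NA_integer_, jaccard = 0))
    best <- as.integer(names(which.max(table(labs))))
    tpix <- truth$cells[[best]]$cell
    inter <- sum(pixel_key(roi$pixels) %in% pixel_key(tpix))
    uni <- roi$area + nrow(tpix) - inter
    data.frame(roi_id = roi$id, truth_id = best, jaccard = inter / uni)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
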