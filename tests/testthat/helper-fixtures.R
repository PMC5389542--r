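# Shared fixtures built in code.

# rendering with all corruption switched off
noiseless_params <- function(...) {
  fishloc::render_params(psf_sigma = 0, poisson = FALSE, read_noise_sd = 0, ...)
}

# pixel-set key helper for set comparisons in oracles (complex keys keep the
# oracle independent of the package's own pixel_key helper)
ckey <- function(m) complex(real = m[, 1], imaginary = m[, 2])

# a mask containing two spherocylinders touching end-to-end
two_touching_rods <- function() {
  shp <- c(200L, 200L)
  m <- matrix(FALSE, shp[1], shp[2])
  u <- c(cos(0.3), sin(0.3))
  c1 <- c(60, 60)
  c2 <- c1 + 43 * u
  m[fishloc:::rasterize_spherocylinder(c1, 0.3, 45, 13, shp)] <- TRUE
  m[fishloc:::rasterize_spherocylinder(c2, 0.3, 45, 13, shp)] <- TRUE
  m
}

# random per-cell pixel array: unique coordinates with random intensities
random_cell_df <- function(n_approx = 120, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  coords <- unique(cbind(sample.int(40, n_approx, TRUE),
                         sample.int(40, n_approx, TRUE)))
  data.frame(row = coords[, 1], col = coords[, 2],
             value = stats::rnorm(nrow(coords)))
}

# hypergeometric null distribution of the median TOS for a set of cell
# areas: the independent oracle for uniform-null calibration
null_median_tos <- function(areas, f_t = 0.1, reps = 1000) {
  replicate(reps, {
    ns <- pmax(1, floor(f_t * areas + 0.5))
    k <- stats::rhyper(length(areas), ns, areas - ns, ns)
    stats::median(fishloc::tos(k / ns, f_t))
  })
}
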