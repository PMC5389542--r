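test_that("find_particles applies the inclusive area range in raster order", {
  expect_length(find_particles(matrix(FALSE, 10, 10)), 0)
  m <- matrix(FALSE, 40, 60)
  m[5:14, 5:14] <- TRUE          # 100 px, top-left first
  m[20:26, 40:46] <- TRUE        # 49 px
  m[28:37, 20:29] <- TRUE        # 100 px
  rois <- find_particles(m, c(50, 200))
  expect_length(rois, 2)
  expect_identical(vapply(rois, `[[`, 0L, "id"), 1:2)
  expect_identical(vapply(rois, `[[`, 0L, "area"), c(100L, 100L))
  expect_identical(rois[[1]]$pixels[1, ], c(row = 5L, col = 5L))
  # min boundary is inclusive
  expect_length(find_particles(m, c(49, 200)), 3)
})

test_that("watershed split separates touching rods and leaves single blobs alone", {
  sq <- matrix(FALSE, 40, 40); sq[10:30, 12:32] <- TRUE
  expect_identical(as.vector(watershed_split(sq)), as.vector(sq))
  expect_identical(watershed_split(matrix(FALSE, 5, 5)),
                   matrix(FALSE, 5, 5))
  m <- two_touching_rods()
  expect_identical(max(fishloc:::.cc_label(m)), 1L)
  split <- watershed_split(m)
  expect_identical(max(fishloc:::.cc_label(split)), 2L)
  # the separation line is thin: almost all pixels survive
  expect_gt(sum(split) / sum(m), 0.97)
})

test_that("filter_cells enforces strict AR, MinFeret, border and saturation rules", {
  fake_roi <- function(id, area = 200, ar = 3, mf = 12, border = FALSE,
                       pixels = cbind(row = 10L, col = 10L)) {
    structure(list(id = as.integer(id), pixels = pixels, area = area,
                   aspect_ratio = ar,
                   min_feret = mf, touches_border = border,
                   max_intensity = numeric(0)), class = "cell_roi")
  }
  crit <- filter_criteria(area_range = c(100, 1200), ar_threshold = 2.01,
                          max_min_feret = 20)
  # aspect ratio exactly at the threshold is rejected (strict >)
  out <- filter_cells(list(fake_roi(1, ar = 2.01), fake_roi(2, ar = 2.0100001)),
                      crit)
  expect_identical(vapply(out, `[[`, 0L, "id"), 2L)
  expect_identical(attr(out, "rejections")[["aspect_ratio"]], 1L)
  # MinFeret at the limit rejected (strict <)
  expect_length(filter_cells(list(fake_roi(1, mf = 20)), crit), 0)
  # border exclusion honours the flag
  expect_length(filter_cells(list(fake_roi(1, border = TRUE)), crit), 0)
  keep <- filter_cells(list(fake_roi(1, border = TRUE)),
                       filter_criteria(exclude_border = FALSE))
  expect_length(keep, 1)
  # a single saturated pixel in any channel rejects the cell
  img <- matrix(0, 20, 20); img[10, 10] <- 65535
  expect_length(filter_cells(list(fake_roi(1)), crit,
                             channel_images = list(dapi = img)), 0)
  img[10, 10] <- 65534
  expect_length(filter_cells(list(fake_roi(1)), crit,
                             channel_images = list(dapi = img)), 1)
  # conservation: kept + rejected counts = input
  rois <- list(fake_roi(1, area = 50), fake_roi(2, ar = 1.5), fake_roi(3))
  out2 <- filter_cells(rois, crit)
  expect_identical(length(out2) + sum(attr(out2, "rejections")), length(rois))
  # purity: permuting input permutes output identically
  out_perm <- filter_cells(rois[c(3, 1, 2)], crit)
  expect_identical(vapply(out_perm, `[[`, 0L, "id"),
                   vapply(out2, `[[`, 0L, "id"))
})

test_that("ground-truth cells pass the shape filters and are recovered", {
  tr <- make_geometry(20, seed = 115, image_shape = c(420L, 420L))
  im <- render_channels(tr, "uniform", params = noiseless_params(), seed = 1)
  seg <- segment_phase(im$phase, channel_images = im[c("dapi", "rna")])
  expect_length(seg$rois, 20)
  mt <- match_truth(seg$rois, tr)
  expect_true(all(mt$jaccard >= 0.9))
})

test_that("count mask construction and pixel harvesting are consistent", {
  expect_true(all(build_count_mask(list(), c(8, 8)) == 0L))
  m <- matrix(FALSE, 30, 30)
  m[2:6, 2:6] <- TRUE; m[10:15, 10:17] <- TRUE; m[20:24, 3:9] <- TRUE
  rois <- find_particles(m, c(1, 1e4))
  cm <- build_count_mask(rois, dim(m))
  h <- table(cm[cm > 0])
  expect_identical(length(h), 3L)
  expect_identical(as.integer(h), vapply(rois, `[[`, 0L, "area"))
  # round trip: ROIs extracted from the count mask have identical pixels
  rois2 <- find_particles(cm > 0L, c(1, 1e4))
  for (i in seq_along(rois))
    expect_identical(rois2[[i]]$pixels, rois[[i]]$pixels)
  # overlapping ROIs refuse to build
  bad <- rois
  bad[[2]]$pixels <- rois[[1]]$pixels
  expect_error(build_count_mask(bad, dim(m)), "overlap")

  img <- matrix(runif(900), 30, 30)
  px <- cell_pixels(cm, img)
  expect_identical(vapply(px, nrow, 0L),
                   stats::setNames(vapply(rois, `[[`, 0L, "area"),
                                   as.character(1:3)))
  # conservation of intensity over labeled pixels
  expect_equal(sum(vapply(px, function(d) sum(d$value), 0)),
               sum(img[cm > 0]))
  # constant image gives constant arrays
  pc <- cell_pixels(cm, matrix(4, 30, 30))
  expect_true(all(vapply(pc, function(d) all(d$value == 4), TRUE)))
  expect_error(cell_pixels(cm, img[1:10, ]), "shape")
})

test_that("shape descriptors behave on known geometry", {
  # a 21x5 rectangle: moment AR near 21/5, MinFeret equals its width 5
  m <- matrix(FALSE, 40, 40); m[10:30, 10:14] <- TRUE
  roi <- find_particles(m, c(1, 1e4))[[1]]
  expect_lt(abs(roi$min_feret - 5), 1e-6)
  expect_lt(abs(roi$aspect_ratio - 21 / 5), 0.15)
  expect_false(roi$touches_border)
  m2 <- matrix(FALSE, 20, 20); m2[1, 5:9] <- TRUE
  roi2 <- find_particles(m2, c(1, 100))[[1]]
  expect_true(roi2$touches_border)
})
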