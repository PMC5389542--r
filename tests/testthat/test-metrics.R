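test_that("global normalization rescales by the joint extremes", {
  out <- normalize_global(list(matrix(c(0, 50, 100), 1)))
  expect_equal(as.vector(out[[1]]), c(0, 0.5, 1))
  a <- matrix(c(10, 60), 1); b <- matrix(c(20, 110), 1)
  out2 <- normalize_global(list(a = a, b = b))
  expect_equal(max(out2$b), 1)
  expect_lt(max(out2$a), 1)        # global max lives in image b only
  expect_true(all(diff(order(c(out2$a, out2$b))) ==
                  diff(order(c(a, b)))))  # monotone map preserves order
  expect_error(normalize_global(list(matrix(3, 2, 2))), "normalize")
})

test_that("cellular normalization maps each cell to [0,1] and flags constants", {
  cells <- list(data.frame(row = 1:3, col = 1, value = c(10, 20, 30)),
                data.frame(row = 1:3, col = 1, value = c(5, 9, 7)),
                data.frame(row = 1:2, col = 1, value = c(4, 4)))
  out <- normalize_cellular(cells)
  expect_equal(out[[1]]$heat, c(0, 0.5, 1))
  expect_equal(range(out[[2]]$heat), c(0, 1))
  expect_identical(order(out[[2]]$heat), order(cells[[2]]$value))
  expect_equal(out[[3]]$heat, c(0.5, 0.5))
  expect_identical(attr(out, "constant_cells"), 3L)
})

test_that("select_top_fraction sizes the selection and breaks ties by raster order", {
  set.seed(116)
  df300 <- data.frame(row = rep(1:20, 15), col = rep(1:15, each = 20),
                      value = rnorm(300))
  expect_identical(select_top_fraction(df300, 0.1)$n_sel, 30L)
  df10 <- data.frame(row = 1:10, col = 1, value = 10:1)
  s <- select_top_fraction(df10, 0.1)
  expect_identical(s$n_sel, 1L)
  expect_equal(unname(s$selected[1, ]), c(1, 1))
  # all-equal values: earliest raster pixels win
  df20 <- data.frame(row = rep(1:4, each = 5), col = rep(1:5, 4), value = 1)
  s2 <- select_top_fraction(df20, 0.1)
  expect_identical(unname(s2$selected),
                   cbind(c(1L, 1L), c(1L, 2L)))
  # property: n_sel = max(1, round-half-up) and selection is a subset
  for (i in 1:20) {
    df <- random_cell_df(sample(30:200, 1))
    ft <- runif(1, 0.02, 0.6)
    sel <- select_top_fraction(df, ft)
    expect_identical(sel$n_sel,
                     max(1L, as.integer(floor(ft * nrow(df) + 0.5))))
    expect_true(all(ckey(sel$selected) %in%
                    ckey(as.matrix(df[c("row", "col")]))))
    # every selected value >= every unselected value
    sel_k <- ckey(sel$selected)
    in_sel <- ckey(as.matrix(df[c("row", "col")])) %in% sel_k
    expect_gte(min(df$value[in_sel]), max(df$value[!in_sel]))
  }
})

test_that("observed_overlap equals brute-force set intersection", {
  mk <- function(m) structure(list(selected = m, n_sel = nrow(m),
                                   n_cell_pixels = 100, f_t = 0.1),
                              class = "threshold_selection")
  a <- cbind(row = c(1L, 2L, 3L), col = c(1L, 1L, 1L))
  expect_equal(observed_overlap(mk(a), mk(a)), 1)
  b <- cbind(row = c(9L, 9L, 9L), col = 1:3)
  expect_equal(observed_overlap(mk(a), mk(b)), 0)
  c3 <- cbind(row = c(3L, 4L, 5L), col = c(1L, 1L, 1L))
  expect_equal(observed_overlap(mk(a), mk(c3)), 1 / 3)
  set.seed(117)
  for (i in 1:200) {
    df <- random_cell_df(80)
    s1 <- select_top_fraction(transform(df, value = rnorm(nrow(df))), 0.15)
    s2 <- select_top_fraction(transform(df, value = rnorm(nrow(df))), 0.15)
    oracle <- length(intersect(ckey(s1$selected), ckey(s2$selected))) /
      nrow(s2$selected)
    expect_equal(observed_overlap(s1, s2), oracle)
  }
})

test_that("tos matches its defining branches and is monotone and continuous", {
  expect_identical(tos(0.1, 0.1), 0)
  expect_identical(tos(0, 0.1), -1)
  expect_identical(tos(1, 0.1), 1)
  expect_equal(tos(0.05, 0.1), -0.5)
  expect_error(tos(0.5, 0), "expected")
  expect_error(tos(0.5, 1), "expected")
  expect_error(tos(1.2, 0.5), "observed")
  for (e in c(0.05, 0.1, 0.3, 0.7)) {
    g <- tos(seq(0, 1, by = 0.001), e)
    expect_true(all(diff(g) > 0))                   # strictly increasing
    expect_lt(abs(tos(e + 1e-9, e) - tos(e - 1e-9, e)), 1e-6)  # continuous
    expect_equal(range(g), c(-1, 1))
  }
})

test_that("null expected overlap equals F_T at the reference cell size of 300 pixels", {
  expect_equal(null_expected_overlap(300, 0.1), 0.1, tolerance = 1e-12)
  # Monte-Carlo oracle at a small size
  set.seed(118)
  n <- 40; ns <- max(1, round(0.1 * n))
  mc <- mean(replicate(4000, {
    length(intersect(sample.int(n, ns), sample.int(n, ns))) / ns
  }))
  expect_lt(abs(null_expected_overlap(n, 0.1) - mc), 0.01)
})

test_that("membrane layers partition the cell via successive erosion", {
  sq <- expand.grid(row = 11:20, col = 21:30)
  lay <- membrane_layers(as.matrix(sq))
  expect_identical(nrow(lay$discarded_edge), 36L)
  expect_identical(nrow(lay$membrane), 28L)
  expect_identical(nrow(lay$interior), 36L)
  # partition property on an irregular ROI
  set.seed(119)
  m <- matrix(FALSE, 30, 30); m[5:25, 8:20] <- TRUE; m[10:15, 18:26] <- TRUE
  pix <- which(m, arr.ind = TRUE)
  lay2 <- membrane_layers(pix)
  all_keys <- sort(c(ckey(lay2$discarded_edge), ckey(lay2$membrane),
                     ckey(lay2$interior)))
  expect_identical(all_keys, sort(ckey(pix)))
  # a 3-px-wide cell has no interior and is excluded
  thin <- as.matrix(expand.grid(row = 1:3 + 4L, col = 1:20 + 4L))
  expect_message(out <- membrane_layers(thin), "excluded")
  expect_null(out)
})

test_that("membrane TOS hits its extremes for concentrated signal", {
  sq <- as.matrix(expand.grid(row = 1:12, col = 1:12))
  lay <- membrane_layers(sq)
  base <- data.frame(row = sq[, 1], col = sq[, 2], value = 0)
  on_mem <- base; on_mem$value[ckey(sq) %in% ckey(lay$membrane)] <- 100
  expect_equal(membrane_tos(on_mem, lay, 0.1)$tos, 1)
  deep <- base
  # put signal on the innermost pixels only
  inner <- lay$interior[lay$interior[, 1] %in% 5:8 & lay$interior[, 2] %in% 5:8, ]
  deep$value[ckey(sq) %in% ckey(inner)] <- 100
  expect_equal(membrane_tos(deep, lay, 0.1)$tos, -1)
  expect_null(membrane_tos(base, NULL, 0.1))
})

test_that("signal-to-background keeps the boundary and excludes flat cells", {
  cm <- matrix(0L, 20, 20); cm[5:8, 5:12] <- 1L; cm[12:15, 5:12] <- 2L
  class(cm) <- c("count_mask", class(cm))
  img <- matrix(100, 20, 20)
  img[cm == 1L] <- 130
  sb <- signal_to_background(img, cm, cutoff = 1.3)
  expect_equal(sb$sb_ratio, c(1.3, 1.0), tolerance = 1e-3)
  expect_identical(sb$included, c(TRUE, FALSE))   # equality is retained
  sb2 <- signal_to_background(img, cm, cutoff = 1.2)
  expect_identical(sb2$included, c(TRUE, FALSE))
  expect_error(signal_to_background(img, matrix(1L, 20, 20)), "unlabeled")
})
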