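test_that("rolling-ball background subtraction removes flat and smooth background", {
  expect_true(all(subtract_background(matrix(7, 20, 20), 4) == 0))
  # single bright pixel on zero background survives within quantization
  img <- matrix(0, 31, 31); img[16, 16] <- 500
  out <- subtract_background(img, 5)
  expect_gt(out[16, 16], 498)
  # gradient background under a synthetic cell: in-cell signal restored
  grad <- outer(seq(0, 50, length.out = 128), seq(0, 30, length.out = 128), "+")
  cell <- matrix(0, 128, 128); cell[60:72, 40:80] <- 1000
  out2 <- subtract_background(grad + cell, 25)
  expect_lt(abs(mean(out2[cell > 0]) - 1000) / 1000, 0.05)
  # idempotence within quantization on its own output
  out3 <- subtract_background(out2, 25)
  expect_lt(max(abs(out3 - out2)), 2)
})

test_that("oversized ball radius errors", {
  expect_error(subtract_background(matrix(0, 10, 10), 20), "too large")
  expect_error(subtract_background(matrix(0, 10, 10), 0.5), ">= 1")
})

test_that("ISODATA threshold separates a bimodal image exactly", {
  set.seed(111)
  img <- matrix(sample(c(10, 200), 400, TRUE), 20, 20)
  m <- threshold_isodata(img)
  expect_identical(as.vector(m), as.vector(img == 200))
  expect_gt(attr(m, "threshold"), 10)
  expect_lt(attr(m, "threshold"), 200)
  # polarity flag gives the complementary mask (no value sits on the threshold)
  m2 <- threshold_isodata(img, dark_foreground = TRUE)
  expect_identical(which(m2), which(!m))
  expect_error(threshold_isodata(matrix(5, 4, 4)), "constant")
})

test_that("threshold of a noiseless phase render stays within a 2-px band of truth", {
  tr <- make_geometry(10, seed = 112, image_shape = c(300L, 300L))
  im <- render_channels(tr, "uniform", params = noiseless_params(), seed = 1)
  mask <- threshold_isodata(im$phase, dark_foreground = TRUE)
  truth <- tr$cell_labels > 0L
  grow <- function(m, k) { for (i in seq_len(k)) m <- m | !erode_oracle(!m); m }
  # oracle erosion independent of the package helper
  erode_oracle <- function(m) {
    out <- m
    nr <- nrow(m); nc <- ncol(m)
    pad <- matrix(FALSE, nr + 2, nc + 2); pad[2:(nr + 1), 2:(nc + 1)] <- m
    for (dy in -1:1) for (dx in -1:1) {
      out <- out & pad[2:(nr + 1) + dy, 2:(nc + 1) + dx]
    }
    out
  }
  expect_true(all(mask[!grow(truth, 2)] == FALSE))   # no mask beyond +2 px
  shrunk <- truth; for (i in 1:2) shrunk <- erode_oracle(shrunk)
  expect_true(all(mask[shrunk]))                     # no hole deeper than 2 px
})

test_that("estimate_offset equals brute-force search and honours tie-breaks", {
  expect_identical(as.integer(estimate_offset(matrix(c(TRUE, FALSE), 8, 8),
                                          matrix(c(TRUE, FALSE), 8, 8), 3)),
                   c(0L, 0L))
  # shifted mask round trip
  set.seed(113)
  base <- matrix(runif(900) < 0.2, 30, 30)
  moved <- fishloc:::shift_matrix(base, 2L, -1L, fill = FALSE)
  expect_identical(as.integer(estimate_offset(base, moved, 5)), c(2L, -1L))
  # independent brute-force oracle on random mask pairs
  for (i in 1:10) {
    a <- matrix(runif(400) < 0.3, 20, 20)
    b <- matrix(runif(400) < 0.3, 20, 20)
    best <- -1L; best_off <- NULL
    for (dy in -3:3) for (dx in -3:3) {
      sh <- matrix(FALSE, 20, 20)
      rs <- (1:20) + dy; cs <- (1:20) + dx
      ok_r <- rs >= 1 & rs <= 20; ok_c <- cs >= 1 & cs <= 20
      sh[rs[ok_r], cs[ok_c]] <- a[which(ok_r), which(ok_c)]
      sc <- sum(sh & b)
      better <- sc > best ||
        (sc == best && (abs(dy) + abs(dx) < sum(abs(best_off)) ||
          (abs(dy) + abs(dx) == sum(abs(best_off)) &&
             (dy < best_off[1] || (dy == best_off[1] && dx < best_off[2])))))
      if (better) { best <- sc; best_off <- c(dy, dx) }
    }
    got <- estimate_offset(a, b, 3)
    expect_identical(as.integer(got), as.integer(best_off))
    expect_identical(attr(got, "overlap"), best)
  }
  # total tie resolves to the origin
  ones <- matrix(TRUE, 6, 6)
  expect_identical(as.integer(estimate_offset(ones, ones, 2)), c(0L, 0L))
  expect_error(estimate_offset(matrix(FALSE, 3, 3), ones[1:3, 1:3]), "empty")
})

test_that("apply_offset translates, fills, and inverts on the interior", {
  img <- matrix(1:30, 5, 6)
  expect_equal(apply_offset(img, c(0L, 0L)), img, ignore_attr = TRUE)
  sh <- apply_offset(img, c(1L, -2L), fill = -9)
  expect_identical(sh[1, ], rep(-9, 6))
  back <- apply_offset(sh, c(-1L, 2L), fill = -9)
  # the doubly-interior region survives the round trip
  expect_equal(back[1:4, 3:6], img[1:4, 3:6], ignore_attr = TRUE)
})

test_that("scene-level registration round trip cancels the injected offset", {
  tr <- make_geometry(6, seed = 114, image_shape = c(220L, 220L))
  for (off in list(c(3L, 2L), c(-2L, 4L), c(0L, -3L))) {
    im <- render_channels(tr, "uniform",
                          params = noiseless_params(channel_offset = off),
                          seed = 2)
    pm <- threshold_isodata(im$phase, dark_foreground = TRUE)
    est <- estimate_offset(pm, threshold_isodata(im$rna), max_shift = 6)
    expect_identical(as.integer(est), off)
    fixed <- apply_offset(im$rna, -est, fill = 100)
    resid <- estimate_offset(pm, threshold_isodata(fixed), max_shift = 6)
    expect_identical(as.integer(resid), c(0L, 0L))
  }
})
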