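test_that("grid position counts follow the closed-form formula", {
  g <- make_grid(c(500, 500), patch_scale("S", 250), 125)
  expect_identical(g$n_rows * g$n_cols, 9L)
  expect_identical(g$row_offsets, c(0L, 125L, 250L))

  g1 <- make_grid(c(250, 250), patch_scale("S", 250), 5)
  expect_identical(g1$n_rows * g1$n_cols, 1L)

  g2 <- make_grid(c(260, 260), patch_scale("S", 250), 5)
  expect_identical(g2$n_rows * g2$n_cols, 9L)
  expect_identical(g2$col_offsets, c(0L, 5L, 10L))
})

test_that("grid counts equal brute-force offset enumeration", {
  set.seed(17)
  for (i in 1:25) {
    dim <- sample(20:90, 1)
    size <- sample(5:min(40, dim), 1)
    stride <- sample(1:15, 1)
    g <- make_grid(c(dim, dim + 3), patch_scale("S", size), stride)
    expect_identical(g$row_offsets, as.integer(enumerate_offsets(dim, size, stride)))
    expect_identical(g$col_offsets, as.integer(enumerate_offsets(dim + 3, size, stride)))
  }
})

test_that("oversized patches are rejected naming the offending axis", {
  expect_error(make_grid(c(200, 500), patch_scale("S", 250), 5), "height")
  expect_error(make_grid(c(500, 200), patch_scale("S", 250), 5), "width")
})

test_that("extraction is deterministic, ordered row-major, unresampled", {
  set.seed(4)
  slide <- array(sample(0:255, 60 * 60 * 3, replace = TRUE), c(60, 60, 3))
  storage.mode(slide) <- "integer"
  g <- make_grid(c(60, 60), patch_scale("S", 20), 20)
  p1 <- extract_patches(slide, g)
  p2 <- extract_patches(slide, g)
  expect_identical(p1, p2)
  expect_length(p1, 9L)
  # row-major: second element moves along columns
  expect_identical(p1[[2]]$rect, c(0L, 20L, 20L, 40L))
  # pixel blocks are exact copies
  expect_identical(p1[[5]]$pixels, slide[21:40, 21:40, , drop = FALSE])
})

test_that("uniform background slides produce uniform patches", {
  slide <- array(0L, c(40, 40, 3))
  slide[, , 2] <- 255L
  g <- make_grid(c(40, 40), patch_scale("S", 20), 10)
  ps <- extract_patches(slide, g)
  for (p in ps) expect_true(all(p$pixels[, , 2] == 255L) && all(p$pixels[, , 1] == 0L))
})

test_that("background filtering keeps patches at or below the threshold", {
  bg <- c(0L, 255L, 0L)
  mk <- function(n_bg, size = 250) {
    arr <- array(10L, c(size, size, 3))
    if (n_bg > 0) {
      idx <- seq_len(n_bg)
      for (ch in 1:3) {
        plane <- arr[, , ch]
        plane[idx] <- bg[ch]
        arr[, , ch] <- plane
      }
    }
    list(pixels = arr, rect = c(0L, 0L, size, size))
  }
  all_bg <- mk(250 * 250)
  none <- mk(0)
  heavy <- mk(40000)  # 0.64 of 62500
  res <- filter_background(list(all_bg, none, heavy), bg, 0.5)
  expect_identical(res$removed, 2L)
  expect_length(res$kept, 1L)
  expect_equal(res$bg_fraction, c(1, 0, 40000 / 62500))
  # exact-threshold patch is kept
  half <- mk(31250)
  expect_length(filter_background(list(half), bg, 0.5)$kept, 1L)
})

test_that("patch majority labels follow modal class with low-id ties", {
  map <- matrix(3L, 250, 250)
  expect_identical(patch_majority_label(map, c(0L, 0L, 250L, 250L)), 3L)

  # counts 30000 of class 3 vs 32500 of class 4
  m2 <- matrix(4L, 250, 250)
  m2[seq_len(30000)] <- 3L
  expect_identical(patch_majority_label(m2, c(0L, 0L, 250L, 250L)), 4L)

  expect_identical(patch_majority_label(matrix(0L, 30, 30), c(0L, 0L, 30L, 30L)), 0L)

  # tie between classes 2 and 3 resolves to 2
  m3 <- matrix(0L, 10, 10)
  m3[1:20] <- 2L; m3[21:40] <- 3L
  expect_identical(patch_majority_label(m3, c(0L, 0L, 10L, 10L)), 2L)

  expect_error(patch_majority_label(matrix(1L, 10, 10), c(0L, 0L, 11L, 10L)),
               "outside")
})

test_that("training stride convention is half the patch size", {
  for (s in c("S", "M", "L")) {
    sc <- patch_scale(s)
    expect_identical(sc$size %% 2L, 0L)
    expect_identical(sc$size %/% 2L, c(S = 125L, M = 175L, L = 225L)[[s]])
  }
})

test_that("dense-stride interior pixels collect (size/stride)^2 patches", {
  # surrogate scale: size 20, stride 5 on a 60x60 slide
  g <- make_grid(c(60, 60), patch_scale("S", 20), 5)
  v <- accumulate_votes(g, rep(1L, g$n_rows * g$n_cols))
  cover <- v$counts[, , 1]
  interior <- cover[21:40, 21:40]  # >= size from every border
  expect_true(all(interior == (20 / 5)^2))
  vb <- brute_force_votes(g, rep(1L, g$n_rows * g$n_cols))
  expect_identical(v$counts, vb)
})
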