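test_that("vote accumulation matches the brute-force rectangle tally", {
  g <- make_grid(c(40, 40), patch_scale("S", 20), 5)
  withr::with_seed(3, {
    labs <- sample(1:4, g$n_rows * g$n_cols, replace = TRUE)
    mask <- matrix(runif(1600) < 0.1, 40, 40)
  })
  v <- accumulate_votes(g, labs, mask)
  expect_identical(v$counts, brute_force_votes(g, labs, mask))
  expect_true(all(v$counts[, , 1][mask] == 0L))
})

test_that("single and overlapping patches cast the expected votes", {
  g1 <- make_grid(c(250, 250), patch_scale("S", 250), 250)
  v1 <- accumulate_votes(g1, 2L)
  expect_true(all(v1$counts[, , 2] == 1L))
  expect_true(all(v1$counts[, , -2] == 0L))

  g2 <- make_grid(c(20, 30), patch_scale("S", 20), 10)  # two patches, cols 0 and 10
  v2 <- accumulate_votes(g2, c(2L, 3L))
  overlap <- v2$counts[5, 15, ]
  expect_identical(overlap, c(0L, 1L, 1L, 0L))
  expect_identical(v2$counts[5, 5, ], c(0L, 1L, 0L, 0L))

  expect_error(accumulate_votes(g2, c(2L, 5L)), "1..4")
})

test_that("majority maps equal the per-pixel argmax oracle with low-id ties", {
  withr::with_seed(9, {
    counts <- array(sample(0:3, 20 * 20 * 4, replace = TRUE), c(20, 20, 4))
  })
  storage.mode(counts) <- "integer"
  v <- structure(list(counts = counts, mask = NULL, height = 20L, width = 20L),
                 class = "vote_tensor")
  m <- vote_to_map(v)
  for (i in 1:20) for (j in 1:20) {
    cnt <- counts[i, j, ]
    want <- if (sum(cnt) == 0L) 0L else which.max(cnt)
    expect_identical(m[i, j], as.integer(want))
  }
})

test_that("explicit tie votes resolve to the lowest class id", {
  counts <- array(0L, c(1, 1, 4))
  counts[1, 1, ] <- c(0L, 2L, 2L, 0L)
  v <- structure(list(counts = counts, mask = NULL, height = 1L, width = 1L),
                 class = "vote_tensor")
  expect_identical(vote_to_map(v)[1, 1], 2L)
  counts[1, 1, ] <- c(0L, 3L, 1L, 0L)
  v$counts <- counts
  expect_identical(vote_to_map(v)[1, 1], 2L)
})

test_that("scale fusion takes the mode and defers 3-way ties to the M map", {
  mk <- function(v) matrix(as.integer(v), 1, 1)
  fuse1 <- function(s, m, l) {
    fuse_scales(list(S = mk(s), M = mk(m), L = mk(l)))[1, 1]
  }
  expect_identical(fuse1(2, 2, 4), 2L)
  expect_identical(fuse1(1, 1, 1), 1L)
  expect_identical(fuse1(1, 2, 3), 2L)  # all differ: medium scale wins
  expect_identical(fuse1(4, 1, 4), 4L)
  expect_error(fuse_scales(list(S = matrix(1L, 2, 2), M = matrix(1L, 3, 3))),
               "mismatched")
})

test_that("ggmrf local energy matches hand-computed values", {
  map <- matrix(2L, 5, 5)
  expect_identical(ggmrf_energy(map, c(3, 3), 2L), 0)

  map[2, 2] <- 3L
  expect_equal(ggmrf_energy(map, c(3, 3), 2L), 5^1.01 * sqrt(2) * 1^1.01)

  expect_error(ggmrf_energy(map, c(3, 3), 0L), "frozen")
  map0 <- matrix(0L, 3, 3)
  expect_error(ggmrf_energy(map0, c(2, 2), 1L), "background")
})

test_that("ggmrf energy is non-decreasing in disagreeing neighbours", {
  prev <- -1
  for (k in 0:8) {
    map <- matrix(2L, 3, 3)
    nbrs <- which(matrix(TRUE, 3, 3) & !(row(map) == 2 & col(map) == 2))
    if (k > 0) map[nbrs[seq_len(k)]] <- 3L
    e <- ggmrf_energy(map, c(2, 2), 2L)
    expect_gte(e, prev)
    prev <- e
  }
})

test_that("constant maps are fixed points and background never changes", {
  mc <- matrix(3L, 16, 16)
  sm <- ggmrf_smooth(mc)
  expect_identical(as.vector(sm), as.vector(mc))

  mb <- matrix(2L, 16, 16)
  mb[1:3, ] <- 0L
  sb <- ggmrf_smooth(mb)
  expect_identical(as.vector(sb[1:3, ]), as.vector(mb[1:3, ]))
  expect_true(all(sb[4:16, ] == 2L))
})

test_that("an isolated disagreeing pixel flips to its surroundings", {
  map <- matrix(2L, 9, 9)
  map[5, 5] <- 4L
  # stay energy 8 * 5^1.01 * sqrt(2) * 2^1.01 dominates the flip data cost 4
  sm <- ggmrf_smooth(map)
  expect_identical(sm[5, 5], 2L)
  expect_true(all(sm == 2L))
})

test_that("total energy is non-increasing across relaxation sweeps", {
  fix <- make_noisy_two_region_map(32, 0.25, seed = 13)
  p <- ggmrf_params()
  energies <- vapply(0:4, function(k) {
    est <- if (k == 0) fix$noisy
           else ggmrf_smooth(fix$noisy, ggmrf_params(max_sweeps = k))
    ggmrf_total_energy(est, fix$noisy, p)
  }, numeric(1))
  expect_true(all(diff(energies) <= 1e-9))
})

test_that("a converged map is a fixed point of a further sweep", {
  fix <- make_noisy_two_region_map(32, 0.2, seed = 5)
  conv <- ggmrf_smooth(fix$noisy, ggmrf_params(max_sweeps = 20))
  again <- ggmrf_smooth(matrix(as.integer(conv), nrow(conv)),
                        ggmrf_params(max_sweeps = 1))
  expect_identical(as.vector(again), as.vector(conv))
})

test_that("smoothing a seeded noisy map reduces disagreement and helps accuracy", {
  fix <- make_noisy_two_region_map(64, 0.1, seed = 42)
  before <- mean(fix$noisy != fix$clean)
  sm <- ggmrf_smooth(fix$noisy)
  after <- mean(sm != fix$clean)
  expect_lt(after, before)  # strict decrease
  acc_before <- pixelwise_accuracy(fix$noisy, fix$clean)
  acc_after <- pixelwise_accuracy(matrix(as.integer(sm), 64), fix$clean)
  expect_gte(acc_after, acc_before)
  # label conservation
  expect_true(all(sm %in% 1:4))
})

test_that("potts distance is available as an alternative potential", {
  map <- matrix(2L, 5, 5); map[2, 2] <- 4L
  p <- ggmrf_params(distance = "potts")
  # disagreement cost is 1 regardless of code distance
  expect_equal(ggmrf_energy(map, c(3, 3), 2L, p), 5^1.01 * sqrt(2))
  expect_equal(ggmrf_energy(map, c(3, 3), 3L, p),
               1 + 8 * 5^1.01 * sqrt(2))
})
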