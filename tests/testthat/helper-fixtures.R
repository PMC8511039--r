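# Shared fixture builders and independent oracles.

# A single-texture patch of one tissue class (raw, not preprocessed),
# rendered by the generator itself on a minimal single-region slide.
make_class_patch <- function(cls, size, seed = 1) {
  s <- generate_slide(synthetic_slide_spec(
    size, size, n_regions = 1, classes = as.integer(cls), seed = seed,
    largest_patch = size))
  s$image
}

# Brute-force enumeration of valid patch offsets along one axis.
enumerate_offsets <- function(dim, size, stride) {
  offs <- seq(0, dim, by = stride)
  offs[offs + size <= dim]
}

# Brute-force per-pixel vote tally over grid rectangles.
brute_force_votes <- function(grid, labels, mask = NULL) {
  H <- grid$slide_height; W <- grid$slide_width
  rects <- pyramidwsi:::grid_rects(grid)
  v <- array(0L, c(H, W, 4))
  for (i in seq_len(nrow(rects))) {
    r <- rects[i, ]
    for (rr in (r$row0 + 1):r$row1) {
      for (cc in (r$col0 + 1):r$col1) {
        if (is.null(mask) || !mask[rr, cc]) {
          v[rr, cc, labels[i]] <- v[rr, cc, labels[i]] + 1L
        }
      }
    }
  }
  v
}

# Nested-loop 2-D convolution with replicate padding (integer output,
# clipped like the implementation).
brute_force_sharpen <- function(img, h) {
  n <- nrow(img[, , 1]); m <- ncol(img[, , 1])
  kr <- (nrow(h) - 1) / 2; kc <- (ncol(h) - 1) / 2
  out <- img
  for (ch in 1:3) {
    pad <- img[c(rep(1, kr), 1:n, rep(n, kr)),
               c(rep(1, kc), 1:m, rep(m, kc)), ch]
    o <- matrix(0, n, m)
    for (i in 1:n) for (j in 1:m) {
      s <- 0
      for (di in -kr:kr) for (dj in -kc:kc) {
        s <- s + h[kr + 1 - di, kc + 1 - dj] * pad[i + kr + di, j + kc + dj]
      }
      o[i, j] <- s
    }
    out[, , ch] <- pmin(pmax(round(o), 0), 255)
  }
  out
}

# Two-region label map with seeded iid label noise, for smoothing benchmarks.
make_noisy_two_region_map <- function(n = 64, noise = 0.1, seed = 42) {
  withr::with_seed(seed, {
    clean <- matrix(2L, n, n)
    clean[, (n / 2 + 1):n] <- 3L
    noisy <- clean
    flip <- runif(n * n) < noise
    noisy[flip] <- sample(1:4, sum(flip), replace = TRUE)
    list(clean = clean, noisy = noisy)
  })
}
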