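#' Patch scales
#'
#' The three pyramid scales: small (250), medium (350) and large (450)
#' pixels.  Training uses a 50% overlap (stride = size/2); inference uses a
#' dense 5-pixel shift so every tissue pixel collects many patch votes.
#'
#' @param name One of "S", "M", "L".
#' @param size Patch side length in pixels; defaults to the scale's standard
#'   size.
#' @return An object of class `patch_scale` with fields `name` and `size`.
#' @export
patch_scale <- function(name = c("S", "M", "L"), size = NULL) {
  name <- match.arg(name)
  if (is.null(size)) size <- c(S = 250L, M = 350L, L = 450L)[[name]]
  size <- as.integer(size)
  if (size <= 0) stop("patch size must be positive")
  structure(list(name = name, size = size), class = "patch_scale")
}

#' Default pyramid scales
#' @return Named list of the three [patch_scale()] objects.
#' @export
default_scales <- function() {
  list(S = patch_scale("S"), M = patch_scale("M"), L = patch_scale("L"))
}

#' Build a deterministic patch grid
#'
#' Positions are 0-based, top-left anchored, half-open rectangles
#' `[r, r+size) x [c, c+size)`.  Offsets along an axis are `0, stride,
#' 2*stride, ...` up to the last offset `<= dim - size`; right/bottom margins
#' narrower than a stride step are dropped (no partial patches, no padding).
#'
#' @param slide_dims `c(height, width)` in pixels.
#' @param scale A [patch_scale()].
#' @param stride Step between neighbouring patch origins, in pixels.  Use
#'   `size/2` for the training convention and 5 for dense inference.
#' @return A `patch_grid` with the offset vectors and grid shape.
#' @examples
#' g <- make_grid(c(500, 500), patch_scale("S"), stride = 125)
#' g$n_rows * g$n_cols  # 9 patches
#' @export
make_grid <- function(slide_dims, scale, stride) {
  stopifnot(inherits(scale, "patch_scale"))
  stride <- as.integer(stride)
  if (stride < 1) stop("stride must be >= 1")
  size <- scale$size
  for (ax in 1:2) {
    if (size > slide_dims[ax]) {
      stop(sprintf("patch size %d exceeds slide %s (%d)",
                   size, c("height", "width")[ax], slide_dims[ax]))
    }
  }
  row_offsets <- seq.int(0L, slide_dims[1] - size, by = stride)
  col_offsets <- seq.int(0L, slide_dims[2] - size, by = stride)
  structure(
    list(scale = scale, stride = stride,
         slide_height = as.integer(slide_dims[1]),
         slide_width = as.integer(slide_dims[2]),
         row_offsets = as.integer(row_offsets),
         col_offsets = as.integer(col_offsets),
         n_rows = length(row_offsets), n_cols = length(col_offsets)),
    class = "patch_grid"
  )
}

# All grid rectangles in row-major order, as a data frame of 0-based
# half-open coordinates (row0, col0, row1, col1) plus grid indices.
grid_rects <- function(grid) {
  size <- grid$scale$size
  # row-major: columns vary fastest
  data.frame(
    row_idx = rep(seq_len(grid$n_rows), each = grid$n_cols),
    col_idx = rep(seq_len(grid$n_cols), times = grid$n_rows),
    row0 = rep(grid$row_offsets, each = grid$n_cols),
    col0 = rep(grid$col_offsets, times = grid$n_rows),
    row1 = rep(grid$row_offsets, each = grid$n_cols) + size,
    col1 = rep(grid$col_offsets, times = grid$n_rows) + size
  )
}

#' Extract all patches of a grid from a slide
#'
#' Pixel blocks are plain copies of the slide (no resampling), returned in
#' row-major grid order.
#'
#' @param slide H x W x 3 image array.
#' @param grid A [make_grid()] built for this slide's dimensions.
#' @return List of patches; each has `pixels` (size x size x 3), `row_idx`,
#'   `col_idx` and `rect` (0-based half-open `c(row0, col0, row1, col1)`).
#' @export
extract_patches <- function(slide, grid) {
  stopifnot(inherits(grid, "patch_grid"))
  d <- dim(slide)
  if (d[1] != grid$slide_height || d[2] != grid$slide_width) {
    stop("grid was built for different slide dimensions")
  }
  rects <- grid_rects(grid)
  lapply(seq_len(nrow(rects)), function(i) {
    r <- rects[i, ]
    list(
      pixels = slide[(r$row0 + 1):r$row1, (r$col0 + 1):r$col1, , drop = FALSE],
      row_idx = r$row_idx, col_idx = r$col_idx,
      rect = c(r$row0, r$col0, r$row1, r$col1)
    )
  })
}

#' Remove patches dominated by background
#'
#' A patch is kept iff the fraction of its pixels exactly equal to the
#' background colour is at most `max_bg_fraction`.
#'
#' @param patches List of patches from [extract_patches()].
#' @param background_color RGB triple.
#' @param max_bg_fraction Maximum tolerated background fraction (default 0.5,
#'   i.e. background-majority patches are dropped).
#' @return List with `kept` (surviving patches), `removed` (count) and
#'   `bg_fraction` (per input patch).
#' @export
filter_background <- function(patches, background_color, max_bg_fraction = 0.5) {
  if (max_bg_fraction < 0 || max_bg_fraction > 1) {
    stop("max_bg_fraction must be in [0, 1]")
  }
  frac <- vapply(patches, function(p) {
    mean(background_mask(p$pixels, background_color))
  }, numeric(1))
  keep <- frac <= max_bg_fraction
  list(kept = patches[keep], removed = sum(!keep), bg_fraction = frac)
}

#' Majority ground-truth label of a patch rectangle
#'
#' Training labels for patches are derived from the pixel ground truth: the
#' modal non-background class inside the rectangle, ties broken by the lowest
#' class id.  A rectangle of pure background gets label 0.
#'
#' @param map H x W integer label matrix.
#' @param rect 0-based half-open rectangle `c(row0, col0, row1, col1)`.
#' @return Integer class code in 0..4.
#' @export
patch_majority_label <- function(map, rect) {
  if (rect[1] < 0 || rect[2] < 0 || rect[3] > nrow(map) || rect[4] > ncol(map)) {
    stop("rect lies outside the label map")
  }
  block <- map[(rect[1] + 1):rect[3], (rect[2] + 1):rect[4]]
  counts <- tabulate(block[block > 0L], nbins = N_TISSUE_CLASSES)
  if (all(counts == 0L)) return(0L)
  which.max(counts)  # first maximum = lowest class id on ties
}
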