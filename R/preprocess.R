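#' CLAHE parameters
#'
#' Contrast limited adaptive histogram equalization splits the patch into a
#' grid of contextual tiles, equalizes each tile's histogram with the
#' amplification clipped, and blends neighbouring tile mappings bilinearly to
#' remove tile seams.
#'
#' @param clip_limit Relative histogram-clip factor (fraction of the tile's
#'   pixel count a single bin may claim); default 0.01.
#' @param tile_grid `c(rows, cols)` of contextual tiles; default `c(8, 8)`.
#' @param bins Number of histogram bins.
#' @return An object of class `clahe_params`.
#' @export
clahe_params <- function(clip_limit = 0.01, tile_grid = c(8L, 8L), bins = 256L) {
  if (clip_limit <= 0) stop("clip_limit must be > 0")
  if (any(tile_grid < 1)) stop("tile_grid must be at least c(1, 1)")
  structure(list(clip_limit = clip_limit,
                 tile_grid = as.integer(tile_grid),
                 bins = as.integer(bins)),
            class = "clahe_params")
}

#' Sharpening kernel
#'
#' A small odd-sized convolution kernel whose coefficients sum to 1, so flat
#' regions are preserved while edges are amplified.  The default is the
#' Laplacian-sharpen kernel; any constant-preserving odd kernel (e.g. read
#' from a CSV grid) can be substituted.
#'
#' @param h Numeric matrix of coefficients; odd dimensions, sum 1.
#' @return An object of class `sharpen_kernel`.
#' @export
sharpen_kernel <- function(h = matrix(c(0, -1, 0, -1, 5, -1, 0, -1, 0), 3, 3)) {
  if (!is.matrix(h)) stop("kernel must be a matrix")
  if (any(dim(h) %% 2 == 0)) stop("kernel dimensions must be odd")
  if (abs(sum(h) - 1) > 1e-8) stop("kernel coefficients must sum to 1")
  structure(list(h = h), class = "sharpen_kernel")
}

#' Read a sharpening kernel from a CSV grid
#' @param path CSV file whose cells are the kernel coefficients.
#' @return A [sharpen_kernel()].
#' @export
read_kernel_csv <- function(path) {
  h <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(h) <- NULL
  sharpen_kernel(h)
}

# Rec.601 luma of an RGB array scaled to [0, 1].
luma01 <- function(img) {
  (0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]) / 255
}

#' Contrast limited adaptive histogram equalization of an RGB patch
#'
#' Equalization runs on the luma channel only; each RGB pixel is then
#' rescaled by its luma gain, so chrominance ratios are untouched and no hue
#' shift is introduced.  Contrast-free (constant) patches stay constant.
#'
#' @param patch H x W x 3 array with 8-bit values 0..255.
#' @param params A [clahe_params()].
#' @return Array of the same shape and 0..255 range.
#' @export
clahe <- function(patch, params = clahe_params()) {
  check_slide_image(patch, "patch")
  if (any(patch != round(patch))) stop("patch must hold 8-bit integer values")
  y <- luma01(patch)
  if (diff(range(y)) == 0) return(patch)  # no contrast to redistribute
  # the tile decomposition needs dimensions divisible by the grid:
  # replicate-pad to the next multiple and crop the result back
  H <- nrow(y); W <- ncol(y)
  ny <- params$tile_grid[1]; nx <- params$tile_grid[2]
  Hp <- ceiling(H / ny) * ny; Wp <- ceiling(W / nx) * nx
  ypad <- y[pmin(seq_len(Hp), H), pmin(seq_len(Wp), W)]
  # EBImage images are width x height; its `limit` is relative to the mean
  # bin height, so scale the relative clip factor by the bin count.
  yi <- EBImage::Image(t(ypad))
  ye <- EBImage::clahe(yi, nx = nx, ny = ny,
                       bins = params$bins,
                       limit = params$clip_limit * params$bins,
                       keep.range = FALSE)
  yeq <- t(EBImage::imageData(ye))[seq_len(H), seq_len(W)]
  gain <- yeq / pmax(y, 1 / 255)
  out <- patch
  for (ch in 1:3) out[, , ch] <- patch[, , ch] * gain
  out <- round(pmin(pmax(out, 0), 255))
  storage.mode(out) <- "integer"
  out
}

#' Sharpen an RGB patch by spatial convolution
#'
#' Per-channel 2-D convolution with a constant-preserving kernel, replicate
#' padding at the borders (no dark halos), output clipped back to 0..255.
#'
#' @param patch H x W x 3 array with 8-bit values 0..255.
#' @param kernel A [sharpen_kernel()].
#' @return Array of the same shape and dtype.
#' @export
sharpen <- function(patch, kernel = sharpen_kernel()) {
  check_slide_image(patch, "patch")
  stopifnot(inherits(kernel, "sharpen_kernel"))
  # filter2 performs true convolution; transposing kernel and image together
  # keeps the orientation of the R row/column frame.
  out <- patch
  for (ch in 1:3) {
    x <- EBImage::Image(t(patch[, , ch] / 255))
    f <- EBImage::filter2(x, t(kernel$h), boundary = "replicate")
    out[, , ch] <- t(EBImage::imageData(f)) * 255
  }
  out <- round(pmin(pmax(out, 0), 255))
  storage.mode(out) <- "integer"
  out
}

#' Full preprocessing of a patch
#'
#' Fixed order: adaptive histogram equalization first, then edge enhancement.
#'
#' @inheritParams clahe
#' @inheritParams sharpen
#' @return Preprocessed patch, same shape and dtype.
#' @export
preprocess_patch <- function(patch, params = clahe_params(),
                             kernel = sharpen_kernel()) {
  sharpen(clahe(patch, params), kernel)
}
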