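#' Default synthetic tissue textures
#'
#' Procedural stand-ins for the four H&E tissue appearances: each class is a
#' base RGB colour plus stationary Gaussian texture — iid pixel noise and/or
#' a spatially smoothed noise field with a class-specific correlation length
#' (a crude analogue of cellular architecture at different scales) — and an
#' optional sinusoidal pattern.  Two constraints shape the defaults: classes
#' are coded by chrominance (distinct RGB ratios) rather than brightness,
#' because adaptive histogram equalization renormalizes each patch's
#' luminance while colour ratios pass through the pipeline unchanged; and
#' the textures are translation-stationary (random-phase), so classifiers
#' trained on one patch alignment generalize to arbitrary patch offsets.
#'
#' @return A named list with one entry per tissue class id ("1".."4"), each a
#'   list with `base` (RGB triple, 0..255), `noise_sd` (iid Gaussian
#'   amplitude), `texture_sd` and `texture_sigma` (amplitude and Gaussian
#'   correlation length of the smoothed field; 0 disables it), and
#'   `pattern_amp`/`pattern_freq` (optional sinusoid, cycles per pixel).
#' @export
default_class_textures <- function() {
  list(
    `1` = list(base = c(238, 225, 240), noise_sd = 5,  texture_sd = 0,  texture_sigma = 0,
               pattern_amp = 0, pattern_freq = 0),
    `2` = list(base = c(205, 95, 125),  noise_sd = 20, texture_sd = 0,  texture_sigma = 0,
               pattern_amp = 0, pattern_freq = 0),
    `3` = list(base = c(130, 115, 215), noise_sd = 5,  texture_sd = 25, texture_sigma = 3,
               pattern_amp = 0, pattern_freq = 0),
    `4` = list(base = c(235, 200, 165), noise_sd = 5,  texture_sd = 25, texture_sigma = 8,
               pattern_amp = 0, pattern_freq = 0)
  )
}

#' Specify a synthetic slide
#'
#' Describes one synthetic slide: its size, how many contiguous tissue
#' regions it contains (seeded Voronoi cells, so boundaries are irregular
#' like tumour margins), which tissue classes those regions cycle through,
#' the per-class texture parameters, the uniform background colour, and an
#' optional background frame around the tissue.
#'
#' @param height,width Slide dimensions in pixels.  Must be at least
#'   `largest_patch` so every patch scale fits.
#' @param n_regions Number of Voronoi regions.
#' @param classes Tissue class ids (subset of 1:4) assigned to regions in
#'   round-robin order.
#' @param class_textures Per-class texture parameters; see
#'   [default_class_textures()].
#' @param background_color RGB triple for background pixels.  Defaults to
#'   pure green, the scanner background convention for these slides.
#' @param background_margin Width in pixels of a background frame around the
#'   tissue area (0 for none).
#' @param seed Integer seed; generation is a pure function of the spec
#'   including this seed.
#' @param largest_patch Largest patch size the pipeline will request; used
#'   only to validate the dimensions.
#' @return An object of class `synthetic_slide_spec`.
#' @seealso [generate_slide()]
#' @export
synthetic_slide_spec <- function(height = 1200L, width = 1200L,
                                 n_regions = 4L, classes = 1:4,
                                 class_textures = default_class_textures(),
                                 background_color = c(0L, 255L, 0L),
                                 background_margin = 0L,
                                 seed = 1L, largest_patch = 450L) {
  height <- as.integer(height); width <- as.integer(width)
  if (height < largest_patch || width < largest_patch) {
    stop(sprintf("slide dimensions %dx%d are smaller than the largest patch size (%d)",
                 height, width, largest_patch))
  }
  if (n_regions < 1) stop("n_regions must be >= 1")
  if (!all(classes %in% 1:4)) stop("classes must be a subset of 1:4")
  if (length(background_color) != 3) stop("background_color must be an RGB triple")
  bases <- vapply(class_textures[as.character(sort(unique(classes)))],
                  function(t) paste(deparse(t), collapse = ""),
                  character(1))
  if (anyDuplicated(bases)) {
    stop("textures of distinct classes must differ in at least one parameter")
  }
  structure(
    list(height = height, width = width, n_regions = as.integer(n_regions),
         classes = as.integer(classes), class_textures = class_textures,
         background_color = as.integer(background_color),
         background_margin = as.integer(background_margin),
         seed = as.integer(seed)),
    class = "synthetic_slide_spec"
  )
}

#' Generate a synthetic slide image and ground-truth label map
#'
#' Partitions the slide into `n_regions` seeded Voronoi cells, assigns tissue
#' classes round-robin, renders each class's procedural texture, and paints
#' an optional background frame in the exact background colour.  By
#' construction a pixel is labelled 0 if and only if its image colour equals
#' the background colour exactly.
#'
#' @param spec A [synthetic_slide_spec()].
#' @return A list with `image` (H x W x 3 integer array, 0..255), `map`
#'   (H x W integer matrix over {0..4}) and `spec`.
#' @examples
#' s <- generate_slide(synthetic_slide_spec(600, 600, n_regions = 2, seed = 7))
#' table(s$map)
#' @export
generate_slide <- function(spec) {
  stopifnot(inherits(spec, "synthetic_slide_spec"))
  H <- spec$height; W <- spec$width
  with_seed(spec$seed, {
    sites_r <- runif(spec$n_regions, 1, H)
    sites_c <- runif(spec$n_regions, 1, W)
    region_class <- rep_len(spec$classes, spec$n_regions)

    rows <- seq_len(H); cols <- seq_len(W)
    best <- matrix(Inf, H, W)
    region <- matrix(1L, H, W)
    for (k in seq_len(spec$n_regions)) {
      d2 <- outer((rows - sites_r[k])^2, (cols - sites_c[k])^2, "+")
      hit <- d2 < best
      region[hit] <- k
      best[hit] <- d2[hit]
    }
    map <- matrix(region_class[region], H, W)

    m <- spec$background_margin
    if (m > 0) {
      map[c(seq_len(m), (H - m + 1):H), ] <- 0L
      map[, c(seq_len(m), (W - m + 1):W)] <- 0L
    }

    img <- array(0, dim = c(H, W, 3))
    coord_sum <- outer(rows, cols, "+")
    for (cls in sort(unique(spec$classes))) {
      idx <- which(map == cls)
      if (length(idx) == 0) next
      tx <- spec$class_textures[[as.character(cls)]]
      pattern <- if (tx$pattern_amp > 0) {
        tx$pattern_amp * sin(2 * pi * tx$pattern_freq * coord_sum[idx])
      } else 0
      # stationary brightness texture: smoothed Gaussian field, rescaled to
      # the requested amplitude, shared across channels
      tex <- 0
      if (!is.null(tx$texture_sd) && tx$texture_sd > 0 && tx$texture_sigma > 0) {
        field <- matrix(rnorm(H * W), H, W)
        field <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(field)),
                                                     sigma = tx$texture_sigma)))
        field <- field / stats::sd(field) * tx$texture_sd
        tex <- field[idx]
      }
      for (ch in 1:3) {
        v <- tx$base[ch] + pattern + tex + rnorm(length(idx), sd = tx$noise_sd)
        img[idx + (ch - 1) * H * W] <- pmin(255, pmax(0, round(v)))
      }
    }
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[map == 0L] <- spec$background_color[ch]
      img[, , ch] <- plane
    }
    # Tissue pixels must never collide with the exact background colour.
    clash <- background_mask(img, spec$background_color) & map != 0L
    if (any(clash)) {
      plane <- img[, , 1]
      plane[clash] <- ifelse(plane[clash] >= 255, plane[clash] - 1, plane[clash] + 1)
      img[, , 1] <- plane
    }
    storage.mode(img) <- "integer"
    list(image = img, map = map, spec = spec)
  })
}

guess_raster_writer <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") return("png")
  if (ext %in% c("tif", "tiff")) return("tiff")
  stop(sprintf("'%s': only lossless PNG/TIFF encodings are supported", path))
}

#' Write a slide image and/or label map to lossless raster files
#'
#' Slides are written as 8-bit RGB PNG/TIFF; label maps as single-channel
#' 8-bit rasters whose integer codes {0..4} survive the round trip exactly.
#' Lossy formats are refused.
#'
#' @param image H x W x 3 array (0..255), or NULL.
#' @param map H x W integer label matrix, or NULL.
#' @param image_path,map_path Output paths (.png, .tif or .tiff).
#' @return Invisibly, the paths written.
#' @export
write_slide <- function(image = NULL, map = NULL,
                        image_path = NULL, map_path = NULL) {
  if (!is.null(image) && !is.null(map)) {
    if (!identical(dim(image)[1:2], dim(map))) {
      stop("image and label map dimensions differ")
    }
  }
  out <- character(0)
  if (!is.null(image)) {
    check_slide_image(image)
    fmt <- guess_raster_writer(image_path)
    arr <- image / 255
    if (fmt == "png") png::writePNG(arr, image_path)
    else tiff::writeTIFF(arr, image_path, bits.per.sample = 8L, compression = "none")
    out <- c(out, image_path)
  }
  if (!is.null(map)) {
    check_label_map(map)
    fmt <- guess_raster_writer(map_path)
    arr <- map / 255
    if (fmt == "png") png::writePNG(arr, map_path)
    else tiff::writeTIFF(arr, map_path, bits.per.sample = 8L, compression = "none")
    out <- c(out, map_path)
  }
  invisible(out)
}

#' Read a slide image written by [write_slide()]
#' @param path PNG or TIFF file.
#' @return H x W x 3 integer array with values 0..255.
#' @export
read_slide_image <- function(path) {
  fmt <- guess_raster_writer(path)
  arr <- if (fmt == "png") png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(arr)) == 2) stop(sprintf("'%s' is single-channel; expected RGB", path))
  img <- round(arr[, , 1:3] * 255)
  storage.mode(img) <- "integer"
  img
}

#' Read a label map written by [write_slide()]
#' @param path PNG or TIFF file holding a single-channel label raster.
#' @return H x W integer matrix.
#' @export
read_label_map <- function(path) {
  fmt <- guess_raster_writer(path)
  arr <- if (fmt == "png") png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  map <- round(arr * 255)
  storage.mode(map) <- "integer"
  check_label_map(map)
  map
}
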