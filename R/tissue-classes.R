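#' Tissue class codes
#'
#' The pipeline labels pixels and patches with five integer codes: 0 is
#' reserved for slide background (the uniform scanner background colour) and
#' is never a network output class; 1--4 are the four kidney tissue classes.
#'
#' @return A data frame with columns `id` and `name`, one row per code.
#' @examples
#' tissue_classes()
#' @export
tissue_classes <- function() {
  data.frame(
    id = 0:4,
    name = c("background", "fat", "parenchyma",
             "clear cell papillary RCC", "clear cell RCC"),
    stringsAsFactors = FALSE
  )
}

#' @rdname tissue_classes
#' @format NULL
#' @export
N_TISSUE_CLASSES <- 4L

# Validate an integer label map (matrix over {0..4}).
check_label_map <- function(map, arg = "map") {
  if (!is.matrix(map)) stop(sprintf("`%s` must be a matrix", arg))
  vals <- unique(as.vector(map))
  bad <- setdiff(vals, 0:4)
  if (length(bad) > 0) {
    stop(sprintf("`%s` contains codes outside {0..4}: %s",
                 arg, paste(bad, collapse = ", ")))
  }
  invisible(map)
}

# Validate an H x W x 3 image array with values in 0..255.
check_slide_image <- function(img, arg = "image") {
  d <- dim(img)
  if (length(d) != 3 || d[3] != 3) {
    stop(sprintf("`%s` must be an H x W x 3 array", arg))
  }
  if (min(img) < 0 || max(img) > 255) {
    stop(sprintf("`%s` must hold 8-bit values in 0..255", arg))
  }
  invisible(img)
}

# Logical matrix: pixels exactly equal to the background colour.
background_mask <- function(img, background_color) {
  img[, , 1] == background_color[1] &
    img[, , 2] == background_color[2] &
    img[, , 3] == background_color[3]
}
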