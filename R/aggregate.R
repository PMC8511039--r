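#' Accumulate per-pixel class votes from patch labels
#'
#' Each classified patch casts one vote for its label on every
#' non-background pixel of its rectangle.  Votes are accumulated with a
#' corner-delta/integral-image scheme, so cost is independent of patch size.
#' Background-masked pixels accrue no votes and keep the background label to
#' the end.
#'
#' @param grid A [make_grid()].
#' @param patch_labels Integer vector in 1..4, one label per grid cell in
#'   row-major order.
#' @param background_mask Logical H x W matrix (`TRUE` = background pixel),
#'   or NULL for none.
#' @return A `vote_tensor`: H x W x 4 integer array of counts plus the mask.
#' @export
accumulate_votes <- function(grid, patch_labels, background_mask = NULL) {
  stopifnot(inherits(grid, "patch_grid"))
  rects <- grid_rects(grid)
  if (length(patch_labels) != nrow(rects)) {
    stop(sprintf("expected %d patch labels, got %d", nrow(rects),
                 length(patch_labels)))
  }
  if (any(patch_labels < 1 | patch_labels > N_TISSUE_CLASSES)) {
    stop("patch labels must be tissue classes in 1..4")
  }
  H <- grid$slide_height; W <- grid$slide_width
  if (!is.null(background_mask) &&
      !identical(dim(background_mask), c(H, W))) {
    stop("background mask dimensions do not match the grid's slide")
  }
  votes <- array(0L, dim = c(H, W, N_TISSUE_CLASSES))
  for (cls in seq_len(N_TISSUE_CLASSES)) {
    idx <- which(patch_labels == cls)
    if (length(idx) == 0) next
    delta <- matrix(0L, H + 1L, W + 1L)
    r0 <- rects$row0[idx] + 1L; c0 <- rects$col0[idx] + 1L
    r1 <- rects$row1[idx] + 1L; c1 <- rects$col1[idx] + 1L  # first excluded row/col
    add_at <- function(r, c, v) {
      lin <- r + (c - 1L) * (H + 1L)
      tab <- tapply(rep(v, length(lin)), lin, sum)
      pos <- as.integer(names(tab))
      delta[pos] <<- delta[pos] + as.integer(tab)
    }
    add_at(r0, c0, 1L); add_at(r1, c1, 1L)
    add_at(r0, c1, -1L); add_at(r1, c0, -1L)
    counts <- apply(apply(delta, 2, cumsum), 1, cumsum)  # transposes
    votes[, , cls] <- t(counts)[seq_len(H), seq_len(W)]
  }
  if (!is.null(background_mask)) {
    for (cls in seq_len(N_TISSUE_CLASSES)) {
      plane <- votes[, , cls]
      plane[background_mask] <- 0L
      votes[, , cls] <- plane
    }
  }
  structure(list(counts = votes, mask = background_mask,
                 height = H, width = W),
            class = "vote_tensor")
}

#' Majority-vote label map from a vote tensor
#'
#' Every unmasked pixel with at least one vote takes its modal class (ties
#' broken by the lowest class id); masked pixels and pixels with no votes are
#' labelled background (0).
#'
#' @param votes A `vote_tensor` from [accumulate_votes()].
#' @return H x W integer label map.
#' @export
vote_to_map <- function(votes) {
  stopifnot(inherits(votes, "vote_tensor"))
  H <- votes$height; W <- votes$width
  flat <- matrix(votes$counts, H * W, N_TISSUE_CLASSES)
  lab <- max.col(flat, ties.method = "first")
  lab[rowSums(flat) == 0L] <- 0L
  if (!is.null(votes$mask)) lab[as.vector(votes$mask)] <- 0L
  matrix(as.integer(lab), H, W)
}

#' Fuse scale-specific label maps by per-pixel majority
#'
#' With three maps the pixel takes the modal label; when all three disagree
#' the medium-scale map wins (the best-performing single scale).  With two
#' maps, disagreements defer to the medium map when present, else to the
#' later (larger-scale) map.  Background must agree by construction and
#' stays background.
#'
#' @param maps Named list of label maps (names among "S", "M", "L"), all of
#'   identical dimensions.
#' @return Fused H x W integer label map.
#' @export
fuse_scales <- function(maps) {
  maps <- maps[!vapply(maps, is.null, logical(1))]
  if (length(maps) == 0) stop("no label maps to fuse")
  dims <- lapply(maps, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("label maps have mismatched dimensions")
  }
  if (length(maps) == 1) return(maps[[1]])
  ref <- if ("M" %in% names(maps)) maps[["M"]] else maps[[length(maps)]]
  if (length(maps) == 2) {
    a <- maps[[1]]; b <- maps[[2]]
    out <- ifelse(a == b, a, ref)
  } else {
    a <- maps[[1]]; b <- maps[[2]]; c3 <- maps[[3]]
    out <- ifelse(a == b | a == c3, a, ifelse(b == c3, b, ref))
  }
  out <- matrix(as.integer(out), nrow(maps[[1]]), ncol(maps[[1]]))
  out[maps[[1]] == 0L] <- 0L
  out
}

#' GGMRF smoothing parameters
#'
#' The generalized Gauss-Markov random field prior scores a candidate label
#' `c` at pixel `s` as `|delta_s - c|^alpha + rho^alpha * lambda^beta *
#' sum_r eta * |delta_r - c|^beta` over the 8-neighborhood.  `alpha` selects
#' a Laplace (1) or Gaussian (2) data prior; `beta` controls smoothness.
#' Defaults are the operating point used for kidney slides: alpha 2,
#' beta 1.01, rho 1, lambda 5, eta sqrt(2).
#'
#' @param alpha Data-term exponent, 1 or 2.
#' @param beta Pair-term exponent, >= 1.
#' @param rho,lambda Scaling factors (> 0).
#' @param eta Pair potential (> 0).
#' @param max_sweeps Maximum raster sweeps of the relaxation.
#' @param distance "linear" uses `|i - j|` on the integer class codes (the
#'   absolute-difference potential); "potts" treats all unequal pairs as
#'   distance 1, ignoring code ordering.
#' @return An object of class `ggmrf_params`.
#' @export
ggmrf_params <- function(alpha = 2, beta = 1.01, rho = 1, lambda = 5,
                         eta = sqrt(2), max_sweeps = 10L,
                         distance = c("linear", "potts")) {
  if (!alpha %in% c(1, 2)) stop("alpha must be 1 or 2")
  if (beta < 1) stop("beta must be >= 1")
  if (rho <= 0 || lambda <= 0 || eta <= 0) stop("rho, lambda, eta must be > 0")
  structure(list(alpha = alpha, beta = beta, rho = rho, lambda = lambda,
                 eta = eta, max_sweeps = as.integer(max_sweeps),
                 distance = match.arg(distance)),
            class = "ggmrf_params")
}

class_distance <- function(a, b, params) {
  if (params$distance == "potts") as.numeric(a != b) else abs(a - b)
}

#' Local GGMRF energy of a candidate label
#'
#' The quantity the relaxation minimizes at one pixel: the data term against
#' the pixel's observed label plus the scaled pair terms against the current
#' labels of its 8-neighborhood.  Background neighbours and off-image
#' positions are excluded from the sum.
#'
#' @param map H x W label map (observed labels).
#' @param s Pixel as `c(row, col)` (1-based).
#' @param candidate Tissue class in 1..4 (background cannot be a candidate;
#'   it is frozen).
#' @param params A [ggmrf_params()].
#' @return Scalar energy.
#' @export
ggmrf_energy <- function(map, s, candidate, params = ggmrf_params()) {
  check_label_map(map)
  if (candidate < 1 || candidate > N_TISSUE_CLASSES) {
    stop("candidate must be a tissue class in 1..4; background is frozen")
  }
  obs <- map[s[1], s[2]]
  if (obs == 0L) stop("pixel s is background; background labels are frozen")
  e <- class_distance(obs, candidate, params)^params$alpha
  nb <- expand.grid(dr = -1:1, dc = -1:1)
  nb <- nb[!(nb$dr == 0 & nb$dc == 0), ]
  for (k in seq_len(nrow(nb))) {
    r <- s[1] + nb$dr[k]; c <- s[2] + nb$dc[k]
    if (r < 1 || r > nrow(map) || c < 1 || c > ncol(map)) next
    lab <- map[r, c]
    if (lab == 0L) next
    e <- e + params$rho^params$alpha * params$lambda^params$beta * params$eta *
      class_distance(lab, candidate, params)^params$beta
  }
  e
}

#' Total GGMRF energy of a label configuration
#'
#' Data terms against the observed map plus each unordered neighbour pair
#' counted once.  Raster-order relaxation never increases this quantity.
#'
#' @param est Current label estimate (H x W).
#' @param observed Observed label map the data term refers to.
#' @param params A [ggmrf_params()].
#' @return Scalar energy.
#' @export
ggmrf_total_energy <- function(est, observed, params = ggmrf_params()) {
  tissue <- observed != 0L
  data_term <- sum(class_distance(observed[tissue], est[tissue], params)^params$alpha)
  pair_scale <- params$rho^params$alpha * params$lambda^params$beta * params$eta
  pair_term <- 0
  H <- nrow(est); W <- ncol(est)
  shifts <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  for (sh in shifts) {
    r1 <- seq_len(H - abs(sh[1])); c1 <- seq_len(W - abs(sh[2]))
    r2 <- r1 + abs(sh[1])
    if (sh[2] >= 0) { ca <- c1; cb <- c1 + sh[2] }
    else { ca <- c1 - sh[2]; cb <- c1 }
    a <- est[r1, ca, drop = FALSE]; b <- est[r2, cb, drop = FALSE]
    ok <- a != 0L & b != 0L
    pair_term <- pair_term + sum(class_distance(a[ok], b[ok], params)^params$beta)
  }
  data_term + pair_scale * pair_term
}

#' Smooth a label map with GGMRF relaxation
#'
#' Iterated conditional modes: raster-order sweeps set every non-background
#' pixel to the class in 1..4 minimizing its local energy given the current
#' map, stopping when a sweep flips no pixel or after `max_sweeps`.
#' Background pixels never change.
#'
#' @param map H x W label map over {0..4}.
#' @param params A [ggmrf_params()].
#' @return Smoothed label map with attribute `flips` (per-sweep flip counts).
#' @export
ggmrf_smooth <- function(map, params = ggmrf_params()) {
  check_label_map(map)
  res <- ggmrf_icm_cpp(map, params$alpha, params$beta, params$rho,
                       params$lambda, params$eta, params$max_sweeps,
                       params$distance == "potts", N_TISSUE_CLASSES)
  structure(res$map, flips = res$flips)
}
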