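#' CNN architecture specification
#'
#' The patch classifier is a lightweight network shared by all three pyramid
#' scales: four blocks, each two 3x3 valid convolutions (9 filters, stride 1,
#' no padding) followed by a 2x2 stride-2 max-pool, then a flatten, a
#' 12-unit fully connected layer, a 4-unit fully connected layer and a
#' soft-max.  Activations are leaky ReLU (slope 0.01).  Dropout (rate 0.2 by
#' default) is applied to the conv-stack output (the flatten input) and
#' after the first fully connected layer.
#'
#' @param input_size Patch side length in pixels (250, 350 or 450 for the
#'   standard scales).  Valid 3x3 convolutions and floor pooling shrink each
#'   block by `n -> floor((n-4)/2)`, so the smallest workable input is 76.
#' @param n_filters Filters per convolutional layer (9).
#' @param fc1_units Width of the first fully connected layer (12).
#' @param n_classes Number of output tissue classes (4).
#' @param dropout Dropout rate in the conv blocks and first FC layer.
#' @return An object of class `cnn_spec`.
#' @export
cnn_spec <- function(input_size, n_filters = 9L, fc1_units = 12L,
                     n_classes = 4L, dropout = 0.2) {
  structure(
    list(input_size = as.integer(input_size), input_channels = 3L,
         n_blocks = 4L, convs_per_block = 2L,
         n_filters = as.integer(n_filters), kernel = 3L,
         fc1_units = as.integer(fc1_units), n_classes = as.integer(n_classes),
         dropout = dropout),
    class = "cnn_spec"
  )
}

#' Analytic layer schedule of the architecture
#'
#' Applies the shape recurrence -- a valid 3x3 convolution shrinks each side
#' by 2, a 2x2 stride-2 max-pool halves it (flooring on odd sides) -- and the
#' closed-form weight counts (`3*3*depth_in*depth_out` per convolution,
#' `fan_in*fan_out` per fully connected layer).  The reported per-layer
#' parameter counts and their total exclude biases, which are tallied
#' separately in the attributes.
#'
#' @param spec A [cnn_spec()].
#' @return A data frame with one row per layer (layer, type, depth, out_size,
#'   weights) and attributes `total_weights`, `total_biases` and
#'   `flatten_length`.
#' @examples
#' sch <- derive_schedule(cnn_spec(250))
#' attr(sch, "total_weights")   # 18462
#' attr(sch, "flatten_length")  # 1089 = 11 * 11 * 9
#' @export
derive_schedule <- function(spec) {
  stopifnot(inherits(spec, "cnn_spec"))
  rows <- list()
  add <- function(layer, type, depth, out, weights) {
    rows[[length(rows) + 1]] <<- data.frame(
      layer = layer, type = type, depth = as.integer(depth),
      out_size = as.integer(out), weights = as.numeric(weights),
      stringsAsFactors = FALSE)
  }
  size <- spec$input_size
  depth <- spec$input_channels
  add("input", "input", depth, size, 0)
  li <- 0L
  for (blk in seq_len(spec$n_blocks)) {
    for (k in seq_len(spec$convs_per_block)) {
      li <- li + 1L
      out <- size - (spec$kernel - 1L)
      if (out < 1L) {
        stop(sprintf("input %d is too small: conv %d would output %d x %d",
                     spec$input_size, li, out, out))
      }
      add(sprintf("conv%d", li), "conv", spec$n_filters, out,
          spec$kernel^2 * depth * spec$n_filters)
      size <- out
      depth <- spec$n_filters
    }
    out <- size %/% 2L
    if (out < 1L) {
      stop(sprintf("input %d is too small: max-pool %d would output %d x %d",
                   spec$input_size, blk, out, out))
    }
    add(sprintf("pool%d", blk), "max-pool", depth, out, 0)
    size <- out
  }
  flat <- as.integer(size)^2 * as.integer(depth)
  flat <- as.integer(flat)
  add("flatten", "flatten", 1L, flat, 0)
  add("fc1", "full", 1L, spec$fc1_units, flat * spec$fc1_units)
  add("fc2", "full", 1L, spec$n_classes, spec$fc1_units * spec$n_classes)
  add("softmax", "softmax", 1L, spec$n_classes, 0)
  out <- do.call(rbind, rows)
  n_biases <- spec$n_filters * spec$n_blocks * spec$convs_per_block +
    spec$fc1_units + spec$n_classes
  structure(out,
            total_weights = sum(out$weights),
            total_biases = n_biases,
            flatten_length = flat)
}

#' Build a trainable model from a specification
#'
#' Convolutional kernels and the first fully connected layer are
#' He-initialized (`N(0, sqrt(2/fan_in))`); the output layer starts at zero
#' so the network begins exactly at the uniform prediction.  Starting the
#' head at zero removes the early incentive to shrink activations toward the
#' class prior — with a randomly initialized head, the quickest loss
#' reduction on small batches is damping the feature extractor, a collapse
#' this narrow architecture does not recover from.  All biases start at zero.
#'
#' @param spec A [cnn_spec()].
#' @param seed Integer seed for the initialization.
#' @return An object of class `cnn_model` holding `spec`, `params` and (after
#'   training) `history`.
#' @export
build_cnn <- function(spec, seed = 1L) {
  sch <- derive_schedule(spec)  # validates the size
  with_seed(seed, {
    he <- function(nr, nc) matrix(rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)
    conv <- vector("list", spec$n_blocks * spec$convs_per_block)
    depth_in <- spec$input_channels
    for (i in seq_along(conv)) {
      conv[[i]] <- list(W = he(spec$kernel^2 * depth_in, spec$n_filters),
                        b = numeric(spec$n_filters))
      depth_in <- spec$n_filters
    }
    flat <- attr(sch, "flatten_length")
    params <- list(
      conv = conv,
      fc1 = list(W = he(flat, spec$fc1_units), b = numeric(spec$fc1_units)),
      fc2 = list(W = matrix(0, spec$fc1_units, spec$n_classes),
                 b = numeric(spec$n_classes))
    )
    structure(list(spec = spec, params = params, history = NULL),
              class = "cnn_model")
  })
}

#' Count a model's parameters
#' @param model A [build_cnn()] model.
#' @return List with `weights` (kernel/FC products, the convention of the
#'   architecture table) and `biases`.
#' @export
count_parameters <- function(model) {
  w <- 0L; b <- 0L
  walk <- function(x) {
    for (n in seq_along(x)) {
      el <- x[[n]]
      if (is.list(el)) walk(el)
      else if (identical(names(x)[n], "W")) w <<- w + length(el)
      else if (identical(names(x)[n], "b")) b <<- b + length(el)
    }
  }
  walk(model$params)
  list(weights = w, biases = b)
}

#' One-hot encoding of a class label
#' @param label Integer class in `1..n_classes`.
#' @param n_classes Number of classes.
#' @return Binary indicator vector with a single 1.
#' @export
one_hot <- function(label, n_classes = 4L) {
  if (label < 1 || label > n_classes) stop("label out of range")
  y <- numeric(n_classes); y[label] <- 1; y
}

#' Cross-entropy loss
#'
#' `-sum(y * log(p))` with natural logarithm; probabilities are floored at a
#' small epsilon before the log.
#'
#' @param p Probability vector (entries in `[0,1]` summing to 1).
#' @param y One-hot indicator of the true class.
#' @param eps Floor applied to probabilities.
#' @return Scalar loss.
#' @examples
#' cross_entropy(rep(0.25, 4), one_hot(2))  # log(4)
#' @export
cross_entropy <- function(p, y, eps = 1e-12) {
  if (length(p) != length(y)) stop("probability and indicator lengths differ")
  if (abs(sum(y) - 1) > 1e-9 || !all(y %in% c(0, 1))) {
    stop("y must be a one-hot indicator")
  }
  -sum(y * log(pmax(p, eps)))
}

# ---- parameter-tree helpers (Adam) ----------------------------------------

tree_map <- function(x, f) {
  if (is.list(x)) lapply(x, tree_map, f = f) else f(x)
}

tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- Map(function(x, y) tree_map2(x, y, f), a, b)
    out
  } else f(a, b)
}

adam_init <- function(params) {
  list(m = tree_map(params, function(x) x * 0),
       v = tree_map(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, conv_lr_scale = 1,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- tree_map2(state$m, state$v, function(m, v) {
    lr * (m / c1) / (sqrt(v / c2) + eps)
  })
  if (conv_lr_scale != 1) {
    upd$conv <- tree_map(upd$conv, function(x) x * conv_lr_scale)
  }
  list(params = tree_map2(params, upd, `-`), state = state)
}

# ---- augmentation ----------------------------------------------------------

rot90_mat <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]

apply_channels <- function(x, f) {
  planes <- lapply(seq_len(dim(x)[3]), function(ch) f(x[, , ch]))
  array(unlist(planes), dim = c(dim(planes[[1]]), dim(x)[3]))
}

# Random rotation / flip / scale jitter of a [0,1]-valued square patch.
# Uses the calling RNG stream, so reproducibility follows the training seed.
augment_patch <- function(x, rotation = TRUE, scaling = TRUE, flipping = TRUE) {
  if (rotation) {
    k <- sample(0:3, 1)
    for (i in seq_len(k)) x <- apply_channels(x, rot90_mat)
  }
  if (flipping) {
    if (runif(1) < 0.5) x <- x[rev(seq_len(dim(x)[1])), , , drop = FALSE]
    if (runif(1) < 0.5) x <- x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
  }
  if (scaling) {
    S <- dim(x)[1]
    f <- runif(1, 0.9, 1.1)
    newS <- as.integer(round(S * f))
    if (newS != S && newS > 1) {
      x <- apply_channels(x, function(m) {
        r <- EBImage::resize(EBImage::Image(t(m)), w = newS, h = newS)
        t(EBImage::imageData(r))
      })
      start <- floor((newS - S) / 2)
      idx <- pmin(pmax(seq_len(S) + start, 1L), newS)  # crop or replicate-pad
      x <- x[idx, idx, , drop = FALSE]
      x <- pmin(pmax(x, 0), 1)
    }
  }
  x
}

# ---- training --------------------------------------------------------------

#' Training configuration
#'
#' Defaults follow the grid-searched operating point of the framework: Adam,
#' learning rate 0.001, mini-batches of 32, 60 epochs, a 20% validation
#' hold-out with best-validation-accuracy model selection, and augmentation
#' by random rotation, scaling and flipping.
#'
#' @param epochs Training epochs.
#' @param learning_rate Adam learning rate.
#' @param optimizer Only "adam" is supported.
#' @param batch_size Mini-batch size.
#' @param validation_fraction Fraction of the training data held out for
#'   per-epoch validation (strictly between 0 and 1).
#' @param rotation,scaling,flipping Augmentation switches.
#' @param warmup_steps Full-batch Adam steps of head pre-fitting before the
#'   epoch loop.  With the convolutional layers frozen the flatten features
#'   are constant, so they are computed once and the two FC layers are fitted
#'   on them exactly (no dropout, no augmentation).  Starting end-to-end
#'   training from a working head keeps the narrow feature extractor from
#'   collapsing under noisy early gradients.
#' @param conv_lr_scale Multiplier on the learning rate for convolutional
#'   layers after warmup (default 0.1): the head trains at the configured
#'   rate while the feature extractor fine-tunes gently, the usual
#'   discriminative-rate arrangement that keeps the conv stack from being
#'   destroyed by aggressive per-parameter Adam steps.
#' @param n_classes Number of classes (4).
#' @param seed Seed governing the split, shuffling, augmentation and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 60L, learning_rate = 0.001,
                         optimizer = "adam", batch_size = 32L,
                         validation_fraction = 0.2,
                         rotation = TRUE, scaling = TRUE, flipping = TRUE,
                         warmup_steps = 300L, conv_lr_scale = 0.1,
                         n_classes = 4L, seed = 1L) {
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    stop("validation_fraction must be strictly between 0 and 1")
  }
  if (!identical(optimizer, "adam")) stop("only the adam optimizer is supported")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 optimizer = optimizer, batch_size = as.integer(batch_size),
                 validation_fraction = validation_fraction,
                 rotation = rotation, scaling = scaling, flipping = flipping,
                 warmup_steps = as.integer(warmup_steps),
                 conv_lr_scale = conv_lr_scale,
                 n_classes = as.integer(n_classes), seed = as.integer(seed)),
            class = "train_config")
}

# Network input convention: 8-bit values mapped to [-0.5, 0.5].  Centering
# removes the large shared DC component of histology patches, which would
# otherwise dominate every activation and drown the class contrast.
patch_to_unit <- function(p) {
  x <- if (is.list(p)) p$pixels else p
  x / 255 - 0.5
}

#' Train a patch classifier
#'
#' Minimizes the cross-entropy with Adam over mini-batches; a validation
#' hold-out is scored after every epoch and the returned model is the epoch
#' snapshot with the highest validation accuracy (earliest epoch on ties).
#' The whole run is a deterministic function of the configuration seed.
#'
#' @param model A [build_cnn()] model.
#' @param patches List of patches (arrays or [extract_patches()] entries)
#'   matching the model's input size.
#' @param labels Integer class labels in 1..4, one per patch.
#' @param config A [train_config()].
#' @return The model with trained `params` and a `history` data frame
#'   (epoch, train_loss, val_loss, val_accuracy).
#' @export
train_cnn <- function(model, patches, labels, config = train_config()) {
  stopifnot(inherits(model, "cnn_model"), inherits(config, "train_config"))
  n <- length(patches)
  if (n == 0) stop("no training patches supplied")
  if (length(labels) != n) stop("labels and patches lengths differ")
  missing_cls <- setdiff(seq_len(config$n_classes), unique(labels))
  if (length(missing_cls) > 0) {
    warning(sprintf("classes absent from training data: %s",
                    paste(missing_cls, collapse = ", ")))
  }
  with_seed(config$seed, {
    n_val <- max(1L, floor(n * config$validation_fraction))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    if (length(tr_idx) == 0) stop("validation split leaves no training patches")

    params <- model$params

    validate <- function(params) {
      val_loss <- 0; val_correct <- 0
      for (i in val_idx) {
        p <- cnn_forward_cpp(patch_to_unit(patches[[i]]), params)
        val_loss <- val_loss + cross_entropy(p, one_hot(labels[i], config$n_classes))
        val_correct <- val_correct + (which.max(p) == labels[i])
      }
      list(loss = val_loss / n_val, acc = val_correct / n_val)
    }

    # Head pre-fit: with frozen conv layers the flatten features are
    # constant, so compute them once and fit the two FC layers on them with
    # full-batch Adam (no dropout).  Each patch also contributes its
    # rotated/flipped variants: the orientations permute the feature grid
    # spatially, so the fitted head must rely on pooled statistics rather
    # than cell positions, which is what lets it generalize to patches at
    # arbitrary offsets during dense inference.
    if (config$warmup_steps > 0) {
      roll <- function(x, dr, dc) {
        n <- dim(x)[1]; m <- dim(x)[2]
        x[c((dr + 1):n, seq_len(dr)), c((dc + 1):m, seq_len(dc)), , drop = FALSE]
      }
      orientations <- list(
        function(x) x,
        function(x) apply_channels(x, rot90_mat),
        function(x) x[rev(seq_len(dim(x)[1])), rev(seq_len(dim(x)[2])), , drop = FALSE],
        function(x) x[rev(seq_len(dim(x)[1])), , , drop = FALSE],
        # circular shifts emulate other patch/grid alignments (the textures
        # are stationary, so the wrap seam is a minor perturbation)
        function(x) roll(x, 8L, 8L),
        function(x) roll(x, 13L, 5L)
      )
      flat_dim <- nrow(params$fc1$W)
      feats <- do.call(cbind, lapply(orientations, function(orient) {
        vapply(tr_idx, function(i) {
          cnn_flat_cpp(orient(patch_to_unit(patches[[i]])), params)
        }, numeric(flat_dim))
      }))
      params <- fit_head(params, feats,
                         rep(labels[tr_idx], length(orientations)),
                         steps = config$warmup_steps,
                         lr = config$learning_rate,
                         n_classes = config$n_classes)
    }

    v0 <- validate(params)
    best <- list(acc = v0$acc, params = params, epoch = 0L)

    state <- adam_init(params)
    hist <- vector("list", config$epochs)
    for (epoch in seq_len(config$epochs)) {
      order_idx <- sample(tr_idx)
      losses <- numeric(0)
      for (start in seq(1, length(order_idx), by = config$batch_size)) {
        batch <- order_idx[start:min(start + config$batch_size - 1, length(order_idx))]
        gsum <- NULL
        bl <- 0
        for (i in batch) {
          raw <- if (is.list(patches[[i]])) patches[[i]]$pixels else patches[[i]]
          x01 <- raw / 255
          if (config$rotation || config$scaling || config$flipping) {
            x01 <- augment_patch(x01, config$rotation, config$scaling, config$flipping)
          }
          x <- x01 - 0.5
          dseed <- sample.int(.Machine$integer.max, 1)
          res <- cnn_grad_cpp(x, params, as.integer(labels[i]),
                              model$spec$dropout, dseed)
          bl <- bl + res$loss
          gsum <- if (is.null(gsum)) res$grads else tree_map2(gsum, res$grads, `+`)
        }
        g <- tree_map(gsum, function(x) x / length(batch))
        stepped <- adam_step(params, g, state, config$learning_rate,
                             conv_lr_scale = config$conv_lr_scale)
        params <- stepped$params
        state <- stepped$state
        losses <- c(losses, bl / length(batch))
      }
      v <- validate(params)
      hist[[epoch]] <- data.frame(epoch = epoch,
                                  train_loss = mean(losses),
                                  val_loss = v$loss,
                                  val_accuracy = v$acc)
      if (v$acc > best$acc) best <- list(acc = v$acc, params = params, epoch = epoch)
    }
    model$params <- best$params
    model$best_epoch <- best$epoch
    model$best_val_accuracy <- best$acc
    model$history <- do.call(rbind, hist)
    model
  })
}

# Full-batch Adam fit of the two FC layers on cached flatten features.
# feats: flat_dim x n matrix; mirrors the compiled forward (leaky ReLU 0.01).
fit_head <- function(params, feats, labels, steps, lr, n_classes = 4L,
                     leak = 0.01) {
  W1 <- params$fc1$W; b1 <- params$fc1$b
  W2 <- params$fc2$W; b2 <- params$fc2$b
  n <- ncol(feats)
  Y <- matrix(0, n_classes, n); Y[cbind(labels, seq_len(n))] <- 1
  st <- list(W1 = W1 * 0, b1 = b1 * 0, W2 = W2 * 0, b2 = b2 * 0)
  m <- st; v <- st; t <- 0
  for (it in seq_len(steps)) {
    h1pre <- crossprod(W1, feats) + b1
    h1 <- ifelse(h1pre > 0, h1pre, leak * h1pre)
    z <- crossprod(W2, h1) + b2
    zs <- sweep(z, 2, apply(z, 2, max))
    P <- sweep(exp(zs), 2, colSums(exp(zs)), "/")
    dz <- (P - Y) / n
    g <- list(W2 = h1 %*% t(dz), b2 = rowSums(dz))
    dh1 <- W2 %*% dz
    dh1pre <- dh1 * ifelse(h1pre > 0, 1, leak)
    g$W1 <- feats %*% t(dh1pre); g$b1 <- rowSums(dh1pre)
    t <- t + 1
    c1 <- 1 - 0.9^t; c2 <- 1 - 0.999^t
    for (nm in names(st)) {
      m[[nm]] <- 0.9 * m[[nm]] + 0.1 * g[[nm]]
      v[[nm]] <- 0.999 * v[[nm]] + 0.001 * g[[nm]]^2
      upd <- lr * (m[[nm]] / c1) / (sqrt(v[[nm]] / c2) + 1e-8)
      assign(nm, get(nm) - upd)
    }
  }
  params$fc1$W <- W1; params$fc1$b <- b1
  params$fc2$W <- W2; params$fc2$b <- b2
  params
}

#' Classify one patch
#'
#' Inference is deterministic (dropout off).
#'
#' @param model A trained [cnn_model][build_cnn()].
#' @param patch Array (or patch object) matching the model's input size.
#' @return List with `class` (integer 1..4) and `probs` (length-4 vector
#'   summing to 1).
#' @export
classify_patch <- function(model, patch) {
  x <- patch_to_unit(patch)
  d <- dim(x)
  if (d[1] != model$spec$input_size || d[2] != model$spec$input_size) {
    stop(sprintf("patch is %dx%d but the model expects %dx%d",
                 d[1], d[2], model$spec$input_size, model$spec$input_size))
  }
  p <- cnn_forward_cpp(x, model$params)
  list(class = which.max(p), probs = p)
}

#' Classify a list of patches
#' @inheritParams classify_patch
#' @param patches List of patches.
#' @return Integer vector of predicted classes.
#' @export
predict_patches <- function(model, patches) {
  vapply(patches, function(p) classify_patch(model, p)$class, integer(1))
}

#' Save / load a model checkpoint
#'
#' The model is serialized natively (RDS); a JSON sidecar records the
#' architecture specification and training history for audit.
#'
#' @param model A [cnn_model][build_cnn()].
#' @param path Checkpoint path (`.rds`); the sidecar is written to
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  side <- list(spec = unclass(model$spec), best_epoch = model$best_epoch,
               history = model$history)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "cnn_model"))
  model
}
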