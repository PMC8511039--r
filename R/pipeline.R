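#' Pipeline configuration
#'
#' One object carrying every stage's parameters: the pyramid scales and their
#' stride conventions (50% overlap for training, a dense 5-pixel shift for
#' inference, overridable for tractability on large slides), background
#' filtering, preprocessing, training hyperparameters, GGMRF smoothing and
#' the train/test split.
#'
#' @param scales Named list of [patch_scale()]s (default S/M/L).
#' @param infer_stride Patch shift in pixels at inference (default 5).
#' @param max_bg_fraction Background-dominance threshold for patch removal.
#' @param background_color RGB triple of the slide background.
#' @param clahe [clahe_params()].
#' @param kernel [sharpen_kernel()].
#' @param train [train_config()].
#' @param ggmrf [ggmrf_params()].
#' @param split_fraction Fraction of patches used for training (default 0.7,
#'   patch-level split within slides).
#' @param max_patches_per_scale Optional cap on the number of patches a
#'   scale's manifest may contribute (seeded subsample); bounds training
#'   time on large slide sets.  NULL keeps everything.
#' @param seed Master seed; every stochastic stage derives its stream from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(scales = default_scales(), infer_stride = 5L,
                            max_bg_fraction = 0.5,
                            background_color = c(0L, 255L, 0L),
                            clahe = clahe_params(), kernel = sharpen_kernel(),
                            train = train_config(), ggmrf = ggmrf_params(),
                            split_fraction = 0.7,
                            max_patches_per_scale = NULL, seed = 1L) {
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop("split_fraction must be strictly between 0 and 1")
  }
  structure(list(scales = scales, infer_stride = as.integer(infer_stride),
                 max_bg_fraction = max_bg_fraction,
                 background_color = as.integer(background_color),
                 clahe = clahe, kernel = kernel, train = train,
                 ggmrf = ggmrf, split_fraction = split_fraction,
                 max_patches_per_scale =
                   if (is.null(max_patches_per_scale)) NULL
                   else as.integer(max_patches_per_scale),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Training patch manifest for one scale across slides: extract with the 50%
# overlap convention, drop background-dominated patches, attach majority
# ground-truth labels.  Preprocessing happens after any subsampling cap.
build_scale_manifest <- function(config, scale, slides) {
  out <- list(patches = list(), labels = integer(0), slide = integer(0))
  for (si in seq_along(slides)) {
    sl <- slides[[si]]
    dims <- dim(sl$image)[1:2]
    if (any(dims < scale$size)) next
    grid <- make_grid(dims, scale, stride = scale$size %/% 2L)
    patches <- extract_patches(sl$image, grid)
    flt <- filter_background(patches, config$background_color,
                             config$max_bg_fraction)
    for (p in flt$kept) {
      lab <- patch_majority_label(sl$map, p$rect)
      if (lab == 0L) next
      out$patches[[length(out$patches) + 1]] <- p$pixels
      out$labels <- c(out$labels, lab)
      out$slide <- c(out$slide, si)
    }
  }
  out
}

#' Train the three-scale pyramid
#'
#' For every scale: build 50%-overlap patch grids over the slides, drop
#' background-dominated patches, label each patch by the majority ground
#' truth, preprocess, split patches 70/30 into train/test with a seed derived
#' from the configuration, train the scale's CNN (best-validation-accuracy
#' snapshot) and score the held-out patches.
#'
#' @param config A [pipeline_config()].
#' @param slides List of slides, each `list(image =, map =)` as produced by
#'   [generate_slide()] (or read from disk).
#' @param out_dir Optional directory for checkpoints and the report.
#' @return List with `models` (per scale), `report` (per-scale data frame)
#'   and `splits` (per-scale train/test index manifests).
#' @export
run_train <- function(config, slides, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  models <- list(); report <- list(); splits <- list()
  for (sn in names(config$scales)) {
    scale <- config$scales[[sn]]
    man <- build_scale_manifest(config, scale, slides)
    n <- length(man$patches)
    if (n == 0) stop(sprintf("no usable patches at scale %s", sn))
    cap <- config$max_patches_per_scale
    if (!is.null(cap) && n > cap) {
      keep <- with_seed(config$seed + 10L * match(sn, names(config$scales)),
                        sort(sample.int(n, cap)))
      man$patches <- man$patches[keep]
      man$labels <- man$labels[keep]
      man$slide <- man$slide[keep]
      n <- cap
    }
    man$patches <- lapply(man$patches, preprocess_patch,
                          params = config$clahe, kernel = config$kernel)
    if (length(unique(man$labels)) < config$train$n_classes) {
      stop(sprintf("scale %s: missing tissue classes in training data (have %s)",
                   sn, paste(sort(unique(man$labels)), collapse = ",")))
    }
    split_seed <- config$seed + match(sn, names(config$scales))
    tr <- with_seed(split_seed,
                    sample.int(n, max(1L, floor(n * config$split_fraction))))
    te <- setdiff(seq_len(n), tr)
    splits[[sn]] <- list(train = tr, test = te, n = n)

    spec <- cnn_spec(scale$size, dropout = 0.2)
    model <- build_cnn(spec, seed = config$seed + 100L + match(sn, names(config$scales)))
    tcfg <- config$train
    tcfg$seed <- as.integer(config$seed + 200L + match(sn, names(config$scales)))
    model <- train_cnn(model, man$patches[tr], man$labels[tr], tcfg)

    test_acc <- if (length(te) > 0) {
      pred <- predict_patches(model, man$patches[te])
      patchwise_accuracy(pred, man$labels[te])
    } else NA_real_
    models[[sn]] <- model
    report[[sn]] <- data.frame(
      scale = sn, size = scale$size, n_patches = n,
      n_train = length(tr), n_test = length(te),
      best_epoch = model$best_epoch,
      best_val_accuracy = model$best_val_accuracy,
      test_patchwise_accuracy = test_acc
    )
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      save_checkpoint(model, file.path(out_dir, sprintf("cnn_%s.rds", sn)))
    }
  }
  report <- do.call(rbind, report)
  rownames(report) <- NULL
  if (!is.null(out_dir)) {
    utils::write.csv(report, file.path(out_dir, "train_report.csv"),
                     row.names = FALSE)
  }
  list(models = models, report = report, splits = splits)
}

# Classify every patch of a dense inference grid, streaming patch by patch so
# full-slide grids never materialize in memory.
classify_grid <- function(model, slide, grid, config) {
  rects <- grid_rects(grid)
  labels <- integer(nrow(rects))
  for (i in seq_len(nrow(rects))) {
    r <- rects[i, ]
    block <- slide[(r$row0 + 1):r$row1, (r$col0 + 1):r$col1, , drop = FALSE]
    block <- preprocess_patch(block, config$clahe, config$kernel)
    labels[i] <- classify_patch(model, block)$class
  }
  labels
}

#' Pixelwise inference on one slide
#'
#' Divides the slide into dense overlapping patches at each available scale,
#' classifies them, reconstructs a per-scale pixel label map by majority
#' voting (background pixels keep label 0 throughout), fuses the per-scale
#' maps by per-pixel majority, and smooths the fused map with the GGMRF
#' relaxation.  Scales larger than the slide are skipped with a warning and
#' fusion degrades to the available maps.
#'
#' @param config A [pipeline_config()].
#' @param models Named list of trained models (from [run_train()]).
#' @param slide H x W x 3 image array.
#' @param truth Optional ground-truth label map; when supplied, patchwise and
#'   pixelwise accuracies before and after smoothing are reported.
#' @param stride Optional override of `config$infer_stride`.
#' @return List with `scale_maps`, `fused`, `smoothed`, `votes` and (when
#'   truth is given) `metrics`.
#' @export
run_infer <- function(config, models, slide, truth = NULL, stride = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stride <- if (is.null(stride)) config$infer_stride else as.integer(stride)
  dims <- dim(slide)[1:2]
  bg <- background_mask(slide, config$background_color)
  scale_maps <- list(); votes_list <- list(); patch_acc <- list()
  for (sn in names(config$scales)) {
    scale <- config$scales[[sn]]
    if (any(dims < scale$size)) {
      warning(sprintf("slide %dx%d smaller than scale %s (%d); scale skipped",
                      dims[1], dims[2], sn, scale$size))
      next
    }
    if (is.null(models[[sn]])) {
      warning(sprintf("no model for scale %s; scale skipped", sn))
      next
    }
    grid <- make_grid(dims, scale, stride)
    labels <- classify_grid(models[[sn]], slide, grid, config)
    votes <- accumulate_votes(grid, labels, bg)
    scale_maps[[sn]] <- vote_to_map(votes)
    votes_list[[sn]] <- votes
    if (!is.null(truth)) {
      rects <- grid_rects(grid)
      true_lab <- vapply(seq_len(nrow(rects)), function(i) {
        patch_majority_label(truth, c(rects$row0[i], rects$col0[i],
                                      rects$row1[i], rects$col1[i]))
      }, integer(1))
      keep <- true_lab != 0L
      patch_acc[[sn]] <- if (any(keep)) {
        patchwise_accuracy(labels[keep], true_lab[keep])
      } else NA_real_
    }
  }
  if (length(scale_maps) == 0) stop("no scale produced a label map")
  fused <- fuse_scales(scale_maps)
  smoothed <- ggmrf_smooth(fused, config$ggmrf)
  metrics <- NULL
  if (!is.null(truth)) {
    metrics <- list(
      patchwise = unlist(patch_acc),
      pixelwise_by_scale = vapply(scale_maps, pixelwise_accuracy,
                                  numeric(1), map_true = truth),
      pixelwise_fused = pixelwise_accuracy(fused, truth),
      pixelwise_smoothed = pixelwise_accuracy(smoothed, truth)
    )
  }
  list(scale_maps = scale_maps, fused = fused, smoothed = smoothed,
       votes = votes_list, metrics = metrics)
}
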