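test_that("the layer schedule reproduces the published 250-input arithmetic", {
  sch <- derive_schedule(cnn_spec(250))
  chain <- sch$out_size[sch$type %in% c("conv", "max-pool")]
  expect_identical(chain,
                   c(248L, 246L, 123L, 121L, 119L, 59L, 57L, 55L, 27L, 25L, 23L, 11L))
  expect_identical(attr(sch, "flatten_length"), 1089L)  # 11 * 11 * 9
  expect_identical(attr(sch, "total_weights"), 18462)
  expect_identical(sum(sch$type == "conv"), 8L)
  expect_identical(sum(sch$type == "max-pool"), 4L)
  expect_true(all(sch$depth[sch$type == "conv"] == 9L))
  # component sums: conv 5346 + fc1 13068 + fc2 48
  expect_identical(sum(sch$weights[sch$type == "conv"]), 5346)
  expect_identical(sch$weights[sch$layer == "fc1"], 1089 * 12)
  expect_identical(sch$weights[sch$layer == "fc2"], 48)
})

test_that("the shape recurrence covers the other scales and the minimum input", {
  expect_identical(attr(derive_schedule(cnn_spec(350)), "flatten_length"), 2916L)
  expect_identical(attr(derive_schedule(cnn_spec(450)), "flatten_length"), 5184L)
  # smallest input surviving four blocks under floor pooling: 76 -> 1x1x9
  expect_identical(attr(derive_schedule(cnn_spec(76)), "flatten_length"), 9L)
  expect_error(derive_schedule(cnn_spec(34)), "too small")
  expect_error(derive_schedule(cnn_spec(75)), "too small")
})

test_that("built models agree with the analytic schedule at runtime", {
  for (size in c(76L, 100L)) {
    spec <- cnn_spec(size)
    sch <- derive_schedule(spec)
    model <- build_cnn(spec, seed = 3)
    counts <- count_parameters(model)
    expect_identical(as.numeric(counts$weights), as.numeric(attr(sch, "total_weights")))
    expect_identical(counts$biases, attr(sch, "total_biases"))
    x <- array(runif(size * size * 3), c(size, size, 3))
    trace <- pyramidwsi:::cnn_trace_cpp(x, model$params)
    want <- sch$out_size[sch$type %in% c("conv", "max-pool")]
    expect_identical(trace[1:12], want)
    expect_identical(trace[13], attr(sch, "flatten_length"))
  }
})

test_that("the 250-scale model carries exactly 18462 weight parameters", {
  model <- build_cnn(cnn_spec(250), seed = 1)
  expect_identical(as.numeric(count_parameters(model)$weights), 18462)
})

test_that("forward passes produce normalized probabilities", {
  model <- build_cnn(cnn_spec(76), seed = 7)
  withr::with_seed(1, {
    for (i in 1:5) {
      x <- array(runif(76 * 76 * 3), c(76, 76, 3))
      p <- pyramidwsi:::cnn_forward_cpp(x, model$params)
      expect_length(p, 4L)
      expect_true(all(p >= 0 & p <= 1))
      expect_lt(abs(sum(p) - 1), 1e-6)
    }
  })
})

test_that("cross-entropy matches its closed forms", {
  expect_identical(cross_entropy(one_hot(3), one_hot(3)), 0)
  expect_equal(cross_entropy(rep(0.25, 4), one_hot(2)), log(4))
  expect_equal(cross_entropy(c(0.5, 0.25, 0.125, 0.125), one_hot(1)), -log(0.5))
  # epsilon guard instead of -Inf
  expect_true(is.finite(cross_entropy(c(0, 1, 0, 0), one_hot(1))))
  expect_error(cross_entropy(c(0.5, 0.5), one_hot(1)), "lengths differ")
  expect_error(cross_entropy(rep(0.25, 4), c(0.5, 0.5, 0, 0)), "one-hot")
})

test_that("analytic gradients match finite differences", {
  model <- build_cnn(cnn_spec(76), seed = 3)
  x <- withr::with_seed(10, array(runif(76 * 76 * 3) - 0.5, c(76, 76, 3)))
  g <- pyramidwsi:::cnn_grad_cpp(x, model$params, 2L, 0, 1L)
  fd <- function(mutate) {
    eps <- 5e-4
    lp <- pyramidwsi:::cnn_grad_cpp(x, mutate(model$params, eps), 2L, 0, 1L)$loss
    lm <- pyramidwsi:::cnn_grad_cpp(x, mutate(model$params, -eps), 2L, 0, 1L)$loss
    (lp - lm) / (2 * eps)
  }
  checks <- list(
    list(an = g$grads$conv[[1]]$W[5],
         mut = function(p, e) { p$conv[[1]]$W[5] <- p$conv[[1]]$W[5] + e; p }),
    list(an = g$grads$fc1$W[40],
         mut = function(p, e) { p$fc1$W[40] <- p$fc1$W[40] + e; p }),
    list(an = g$grads$fc2$b[2],
         mut = function(p, e) { p$fc2$b[2] <- p$fc2$b[2] + e; p })
  )
  for (chk in checks) {
    v <- fd(chk$mut)
    expect_lt(abs(v - chk$an), 0.05 * max(abs(v), abs(chk$an), 0.05))
  }
})

test_that("classification is deterministic and validates input size", {
  model <- build_cnn(cnn_spec(76), seed = 5)
  p <- make_class_patch(2, 76, seed = 1)
  r1 <- classify_patch(model, p)
  r2 <- classify_patch(model, p)
  expect_identical(r1$probs, r2$probs)
  expect_true(r1$class %in% 1:4)
  expect_error(classify_patch(model, make_class_patch(2, 80, seed = 1)),
               "expects 76x76")
})

test_that("training is reproducible, records history, and selects by validation", {
  patches <- lapply(rep(1:4, each = 6), make_class_patch, size = 76)
  patches <- withr::with_seed(2, lapply(rep(1:4, each = 6), function(cls) {
    make_class_patch(cls, 76)
  }))
  labels <- rep(1:4, each = 6)
  cfg <- train_config(epochs = 3, batch_size = 4, learning_rate = 0.002, seed = 11)
  m1 <- train_cnn(build_cnn(cnn_spec(76), seed = 4), patches, labels, cfg)
  m2 <- train_cnn(build_cnn(cnn_spec(76), seed = 4), patches, labels, cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  expect_identical(nrow(m1$history), 3L)
  # selection: either the head-prefit state (epoch 0) or the best joint epoch,
  # never worse than any recorded epoch
  expect_true(m1$best_epoch %in% c(0L, which(m1$history$val_accuracy ==
                                               max(m1$history$val_accuracy))))
  expect_gte(m1$best_val_accuracy, max(m1$history$val_accuracy))
})

test_that("degenerate training inputs are diagnosed", {
  patches <- withr::with_seed(3, lapply(rep(1:2, each = 4), function(cls) {
    make_class_patch(cls, 76)
  }))
  labels <- rep(1:2, each = 4)
  cfg <- train_config(epochs = 1, batch_size = 4, seed = 1)
  expect_warning(train_cnn(build_cnn(cnn_spec(76), seed = 1), patches, labels, cfg),
                 "absent")
  expect_error(train_cnn(build_cnn(cnn_spec(76), seed = 1), list(), integer(0), cfg),
               "no training patches")
})

test_that("a small memorization task is learnable", {
  # loss on 10 distinct patches falls decisively under sustained training
  patches <- withr::with_seed(6, lapply(1:10, function(i) {
    arr <- array(sample(0:255, 76 * 76 * 3, replace = TRUE), c(76, 76, 3))
    storage.mode(arr) <- "integer"
    arr
  }))
  labels <- rep(1:4, length.out = 10)
  cfg <- train_config(epochs = 120, batch_size = 10, learning_rate = 0.01,
                      validation_fraction = 0.1,
                      rotation = FALSE, scaling = FALSE, flipping = FALSE,
                      seed = 8)
  model <- build_cnn(cnn_spec(76, dropout = 0), seed = 2)
  model <- train_cnn(model, patches, labels, cfg)
  expect_lt(min(model$history$train_loss), 0.05)
})

test_that("checkpoints round-trip with their JSON sidecar", {
  model <- build_cnn(cnn_spec(76), seed = 9)
  model$history <- data.frame(epoch = 1L, train_loss = 1, val_loss = 1,
                              val_accuracy = 0.5)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, model$params)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(side$spec$input_size, 76L)
  unlink(c(path, paste0(path, ".json")))
})
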