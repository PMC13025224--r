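# Classifier architectures, training loop, early stopping and prediction.

test_that("TinyViT-Hybrid exposes the specified structural constants", {
  m <- build_model(model_spec("tinyvit_hybrid"))
  expect_identical(m$structure$n_tokens, 49L)
  expect_identical(m$structure$token_dim, 512L)
  expect_identical(m$structure$ffn_inner_dim, 2048L)
  expect_identical(m$structure$n_heads, 8L)
  expect_identical(m$structure$n_blocks, 2L)
})

test_that("every architecture maps a batch to finite two-class logits", {
  set.seed(1)
  # full-resolution contract for the transformer hybrid (7x7 token grid),
  # reduced resolution for the pure CNNs to keep the check fast
  cases <- list(list("tinyvit_hybrid", 224L, 2L),
                list("resnet18", 64L, 5L),
                list("mobilenet_v3", 64L, 5L),
                list("efficientnet_b0", 64L, 5L),
                list("tiny_cnn", 32L, 5L))
  for (cs in cases) {
    m <- build_model(model_spec(cs[[1]], input_size = cs[[2]]))
    xb <- array(runif(cs[[2]]^2 * 3 * cs[[3]]), c(cs[[2]], cs[[2]], 3, cs[[3]]))
    lg <- eegtfr:::model_forward(m, xb)
    expect_identical(dim(lg), c(2L, cs[[3]]))
    expect_true(all(is.finite(lg)))
  }
  expect_error(build_model(model_spec("tiny_cnn", pretrained = TRUE)),
               "pretrained")
})

test_that("early stopping follows the patience rule exactly", {
  # constructed non-improving sequence: stop after epoch 4 with patience 3
  expect_identical(early_stop_epoch(c(0.5, 0.6, 0.7, 0.8), 3L), 4L)
  # brute-force simulator over random loss sequences
  simulate_stop <- function(losses, patience) {
    best <- Inf; bad <- 0L
    for (e in seq_along(losses)) {
      if (losses[e] < best) { best <- losses[e]; bad <- 0L }
      else { bad <- bad + 1L; if (bad >= patience) return(e) }
    }
    length(losses)
  }
  set.seed(8)
  for (i in 1:200) {
    losses <- round(runif(sample(1:10, 1)), 2)
    pat <- sample(1:4, 1)
    expect_identical(early_stop_epoch(losses, pat), simulate_stop(losses, pat))
  }
})

test_that("fine_tune separates a linearly separable image set", {
  toy <- make_toy_images(30, size = 16, gap = 0.4)
  idx_val <- c(1:3, 31:33)
  tr <- image_set(toy$images[-idx_val], toy$labels[-idx_val])
  va <- image_set(toy$images[idx_val], toy$labels[idx_val])
  m <- build_model(model_spec("tiny_cnn", input_size = 16L))
  ft <- fine_tune(m, tr, va, train_config(lr = 1e-3, batch_size = 16,
                                          max_epochs = 8, patience = 3))
  pr <- predict(ft$model, tr)
  expect_gte(mean(pr$label == tr$labels), 0.99)
  expect_lte(nrow(ft$history), 8L)
})

test_that("fine_tune is deterministic under a fixed seed and bounded", {
  toy <- make_toy_images(10, size = 16, gap = 0.3, seed = 3)
  tr <- image_set(toy$images[1:16], toy$labels[1:16])
  va <- image_set(toy$images[17:20], toy$labels[17:20])
  cfg <- train_config(lr = 1e-3, batch_size = 8, max_epochs = 3, patience = 3)
  run <- function() {
    set.seed(99)       # same model initialisation
    m <- build_model(model_spec("tiny_cnn", input_size = 16L))
    fine_tune(m, tr, va, cfg, fold_index = 2L)$history
  }
  h1 <- run(); h2 <- run()
  expect_equal(h1$train_loss, h2$train_loss, tolerance = 1e-12)
  expect_equal(h1$val_loss, h2$val_loss, tolerance = 1e-12)
  # max_epochs = 1 records exactly one epoch
  set.seed(1)
  m <- build_model(model_spec("tiny_cnn", input_size = 16L))
  one <- fine_tune(m, tr, va, train_config(lr = 1e-3, batch_size = 8,
                                           max_epochs = 1, patience = 1))
  expect_identical(nrow(one$history), 1L)
  # single-class training split is refused
  bad <- image_set(toy$images[1:5], rep("R", 5))
  expect_error(fine_tune(m, bad, va, cfg), "single class")
})

test_that("prediction applies softmax with the responder as class index 1", {
  toy <- make_toy_images(3, size = 16)
  set.seed(2)
  m <- build_model(model_spec("tiny_cnn", input_size = 16L))
  pr <- predict(m, toy)
  expect_identical(nrow(pr), 6L)
  expect_equal(pr$p_R + pr$p_NR, rep(1, 6))
  # softmax closed form on raw logits
  p <- exp(2) / (exp(2) + exp(-1))
  expect_gt(p, 0.95)
  expect_equal(eegtfr:::softmax_xent(matrix(c(2, -1)), 1L)$probs[1L, 1L], p)
  expect_equal(eegtfr:::softmax_xent(matrix(c(0, 0)), 1L)$probs[, 1L],
               c(0.5, 0.5))
})

test_that("gradients of core layers match numerical differentiation", {
  set.seed(12)
  num_check <- function(layer, x) {
    loss_of <- function(xx) sum(layer$forward(xx, TRUE)^2) / 2
    y <- layer$forward(x, TRUE)
    eegtfr:::zero_grads(layer)
    dx <- layer$backward(y)
    i <- sample(length(x), min(12L, length(x)))
    for (j in i) {
      xp <- x; xp[j] <- xp[j] + 1e-5
      xm <- x; xm[j] <- xm[j] - 1e-5
      expect_equal(dx[j], (loss_of(xp) - loss_of(xm)) / 2e-5,
                   tolerance = 1e-4)
    }
  }
  x4 <- array(rnorm(3 * 6 * 6 * 2), c(3, 6, 6, 2))
  num_check(eegtfr:::nn_conv2d(3, 4, 3, stride = 2, pad = 1), x4)
  num_check(eegtfr:::nn_depthwise_conv2d(3, 3), x4)
  num_check(eegtfr:::nn_maxpool(3, 2, 1), x4)
  num_check(eegtfr:::nn_se(3, reduced = 2), x4)
  xt <- array(rnorm(8 * 5 * 2), c(8, 5, 2))
  num_check(eegtfr:::nn_mhsa(8, 2, proj_drop = 0), xt)
  num_check(eegtfr:::nn_vit_block(8, 2, mlp_ratio = 2, dropout = 0), xt)
})

test_that("image-level CV on a strong synthetic effect beats chance decisively", {
  base <- c(delta = 1.5, theta = 1.0, alpha = 1.0, beta = 0.6, gamma = 0.3)
  cfg <- list(
    synthetic = list(n_responders = 3, n_nonresponders = 3, duration_s = 60,
                     fs = 128, noise_sd = 2,
                     band_powers = list(R = replace(base, "alpha", 3.0),
                                        NR = base),
                     effect_channels = montage_1020()),
    preprocess = list(low = 0.5, high = 45, notch = 50, mspca = FALSE),
    tfr = list(repr = "cwt", image_size = 24, write_png = FALSE,
               cwt = list(fmin = 2, fmax = 45)),
    model = list(name = "tiny_cnn"),
    train = list(lr = 1e-3, batch_size = 32, max_epochs = 6, patience = 6),
    eval = list(strategy = "image", n_folds = 3),
    out_dir = tempfile("imglvl"), seed = 7)
  res <- run_pipeline(cfg, verbose = FALSE)
  pred <- res$predictions
  n_correct <- sum(pred$prediction == pred$label)
  p <- stats::binom.test(n_correct, nrow(pred), 0.5,
                         alternative = "greater")$p.value
  expect_lt(p, 0.01)
})
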