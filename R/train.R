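# Fine-tuning loop: AdamW, cosine-annealed learning rate, cross-entropy loss,
# early stopping on validation loss with best-weight restoration.

#' Training configuration
#'
#' @param lr Initial learning rate (default 1e-4).
#' @param weight_decay Decoupled weight decay (default 1e-4).
#' @param batch_size Mini-batch size (default 32).
#' @param max_epochs Maximum epochs per fold (default 8).
#' @param patience Early-stopping patience in epochs, monitoring validation
#'   loss (default 3; must not exceed `max_epochs`).
#' @param t_max,lr_min Cosine annealing period and floor (defaults 8 and 1e-6).
#' @param seed Base random seed (default 42). Per-fold runs use
#'   `seed + 100 * fold_index` to diversify initialisation across folds.
#' @param normalise Per-channel input normalisation; defaults to ImageNet
#'   statistics.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, weight_decay = 1e-4, batch_size = 32L,
                         max_epochs = 8L, patience = 3L,
                         t_max = 8, lr_min = 1e-6, seed = 42L,
                         normalise = imagenet_norm()) {
  assert_count(batch_size, "batch_size")
  assert_count(max_epochs, "max_epochs")
  assert_count(patience, "patience")
  if (patience > max_epochs)
    stop("`patience` must not exceed `max_epochs`", call. = FALSE)
  structure(list(lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 t_max = t_max, lr_min = lr_min, seed = as.integer(seed),
                 normalise = normalise),
            class = "train_config")
}

#' ImageNet channel statistics
#'
#' @return List with `mean` and `std` RGB vectors.
#' @export
imagenet_norm <- function() {
  list(mean = c(0.485, 0.456, 0.406), std = c(0.229, 0.224, 0.225))
}

#' Labelled image set
#'
#' @param images List of `H x W x 3` arrays in `[0, 1]`.
#' @param labels Class labels (`"R"` / `"NR"` or factor); responder is class
#'   index 1 (the positive class).
#' @param meta Optional data frame of per-image metadata (subject, channel,
#'   epoch) with one row per image.
#' @return An object of class `image_set`.
#' @export
image_set <- function(images, labels, meta = NULL) {
  labels <- factor(as.character(labels), levels = c("R", "NR"))
  if (length(images) != length(labels))
    stop("`images` and `labels` lengths differ", call. = FALSE)
  if (anyNA(labels)) stop("labels must be 'R' or 'NR'", call. = FALSE)
  if (!is.null(meta) && nrow(meta) != length(images))
    stop("`meta` must have one row per image", call. = FALSE)
  structure(list(images = images, labels = labels, meta = meta),
            class = "image_set")
}

#' @export
print.image_set <- function(x, ...) {
  cat(sprintf("<image_set> %d images (%s)\n", length(x$images),
              paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' Early-stopping decision rule
#'
#' Given the validation losses observed so far, returns the 1-based epoch
#' after which training stops (the epoch completing `patience` consecutive
#' non-improving epochs), or `length(val_losses)` if the rule never fires.
#' An epoch improves when its loss is strictly below the best seen before it.
#'
#' @param val_losses Numeric vector of per-epoch validation losses.
#' @param patience Number of consecutive non-improving epochs tolerated.
#' @return Integer stopping epoch.
#' @export
early_stop_epoch <- function(val_losses, patience) {
  best <- Inf
  bad <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience) return(e)
    }
  }
  length(val_losses)
}

eval_on <- function(model, set, cfg) {
  n <- length(set$images)
  y <- as.integer(set$labels)
  loss_tot <- 0
  correct <- 0L
  i <- 1L
  while (i <= n) {
    j <- min(i + cfg$batch_size - 1L, n)
    xb <- image_batch(set$images[i:j], normalise = cfg$normalise)
    logits <- model_forward(model, xb, train = FALSE)
    sx <- softmax_xent(logits, y[i:j])
    loss_tot <- loss_tot + sx$loss * (j - i + 1L)
    correct <- correct + sum(apply(sx$probs, 2L, which.max) == y[i:j])
    i <- j + 1L
  }
  list(loss = loss_tot / n, acc = correct / n)
}

#' Fine-tune a classifier on labelled images
#'
#' Trains with AdamW (decoupled weight decay), a cosine-annealed learning
#' rate, and cross-entropy loss; stops early when the validation loss fails
#' to improve for `patience` consecutive epochs and restores the weights of
#' the best validation epoch.
#'
#' @param model An [build_model()] classifier.
#' @param train_set,val_set [image_set()] objects; the training set must
#'   contain both classes.
#' @param cfg A [train_config()].
#' @param fold_index 0-based fold index; the effective seed is
#'   `cfg$seed + 100 * fold_index`.
#' @param verbose Print one line per epoch.
#' @return List with `model` (best weights restored) and `history`, a data
#'   frame of per-epoch train/val loss and accuracy with attributes
#'   `stopped_epoch` and `best_val_loss`.
#' @export
fine_tune <- function(model, train_set, val_set, cfg = train_config(),
                      fold_index = 0L, verbose = FALSE) {
  stopifnot(inherits(model, "eegtfr_model"), inherits(train_set, "image_set"),
            inherits(val_set, "image_set"))
  if (length(train_set$images) == 0L || length(val_set$images) == 0L)
    stop("training and validation sets must be non-empty", call. = FALSE)
  if (nlevels(droplevels(train_set$labels)) < 2L)
    stop("training split contains a single class; cannot fit a discriminator",
         call. = FALSE)
  set.seed(cfg$seed + 100L * fold_index)
  y <- as.integer(train_set$labels)
  n <- length(train_set$images)
  opt <- adamw_new(collect_params(model$net), lr = cfg$lr,
                   weight_decay = cfg$weight_decay)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     train_acc = numeric(), val_loss = numeric(),
                     val_acc = numeric())
  best_loss <- Inf
  best_snap <- NULL
  bad_epochs <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    lr_e <- cosine_lr(epoch - 1L, cfg$lr, cfg$t_max, cfg$lr_min)
    ord <- sample.int(n)
    loss_tot <- 0; correct <- 0L
    i <- 1L
    while (i <= n) {
      take <- ord[i:min(i + cfg$batch_size - 1L, n)]
      xb <- image_batch(train_set$images[take], normalise = cfg$normalise)
      zero_grads(model$net)
      logits <- model_forward(model, xb, train = TRUE)
      sx <- softmax_xent(logits, y[take])
      model$net$backward(sx$dlogits)
      adamw_step(opt, lr = lr_e)
      loss_tot <- loss_tot + sx$loss * length(take)
      correct <- correct + sum(apply(sx$probs, 2L, which.max) == y[take])
      i <- i + cfg$batch_size
    }
    ev <- eval_on(model, val_set, cfg)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = loss_tot / n,
                                   train_acc = correct / n,
                                   val_loss = ev$loss, val_acc = ev$acc))
    if (verbose)
      message(sprintf("epoch %d: train loss %.4f acc %.3f | val loss %.4f acc %.3f (lr %.2g)",
                      epoch, loss_tot / n, correct / n, ev$loss, ev$acc, lr_e))
    if (ev$loss < best_loss) {
      best_loss <- ev$loss
      best_snap <- snapshot_params(model$net)
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= cfg$patience) break
    }
  }
  if (!is.null(best_snap)) restore_params(model$net, best_snap)
  attr(hist, "stopped_epoch") <- nrow(hist)
  attr(hist, "best_val_loss") <- best_loss
  list(model = model, history = hist)
}

#' Predict class labels and probabilities for images
#'
#' @param object A trained [build_model()] classifier.
#' @param images An [image_set()] or list of `H x W x 3` arrays.
#' @param cfg A [train_config()] (used for batch size and normalisation).
#' @param ... Unused.
#' @return Data frame with columns `label` (factor `R`/`NR`), `p_R`, `p_NR`;
#'   one row per image. Probabilities sum to one per image.
#' @export
predict.eegtfr_model <- function(object, images, cfg = train_config(), ...) {
  imgs <- if (inherits(images, "image_set")) images$images else images
  n <- length(imgs)
  pR <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + cfg$batch_size - 1L, n)
    xb <- image_batch(imgs[i:j], normalise = cfg$normalise)
    logits <- model_forward(object, xb, train = FALSE)
    m <- apply(logits, 2L, max)
    z <- exp(sweep(logits, 2L, m))
    p <- sweep(z, 2L, colSums(z), "/")
    pR[i:j] <- p[1L, ]
    i <- j + 1L
  }
  data.frame(label = factor(ifelse(pR >= 0.5, "R", "NR"), levels = c("R", "NR")),
             p_R = pR, p_NR = 1 - pR)
}
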