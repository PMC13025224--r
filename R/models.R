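# Classifier architectures: ResNet-18, MobileNet-V3-Large, EfficientNet-B0,
# the hybrid convolutional/transformer TinyViT-Hybrid, and a deliberately
# small tiny_cnn for fast experiments. All map image batches
# (H, W, 3, B as built by `image_batch`) to two-class logits.

#' Classifier model specification
#'
#' @param name One of `"resnet18"`, `"mobilenet_v3"`, `"efficientnet_b0"`,
#'   `"tinyvit_hybrid"` or `"tiny_cnn"` (the last is a deliberately small
#'   two-convolution network for fast experiments, not one of the four
#'   reference architectures).
#' @param n_classes Number of output classes (default 2: responder vs
#'   non-responder).
#' @param input_size Input image edge length in pixels (default 224). The
#'   TinyViT token grid is `(input_size / 32)^2`.
#' @param pretrained Whether to initialise from pretrained weights. No weight
#'   files are bundled, so only `FALSE` is supported; requesting `TRUE`
#'   raises an informative error.
#' @param n_layers,n_heads,mlp_ratio,dropout TinyViT-Hybrid transformer
#'   hyperparameters (2 encoder blocks, 8 heads, MLP ratio 4, dropout 0.1).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(name = c("tiny_cnn", "resnet18", "mobilenet_v3",
                                "efficientnet_b0", "tinyvit_hybrid"),
                       n_classes = 2L, input_size = 224L, pretrained = FALSE,
                       n_layers = 2L, n_heads = 8L, mlp_ratio = 4,
                       dropout = 0.1) {
  name <- match.arg(name)
  assert_count(n_classes, "n_classes", min = 2L)
  assert_count(input_size, "input_size", min = 8L)
  structure(list(name = name, n_classes = as.integer(n_classes),
                 input_size = as.integer(input_size),
                 pretrained = isTRUE(pretrained),
                 n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
                 mlp_ratio = mlp_ratio, dropout = dropout),
            class = "model_spec")
}

conv_bn_act <- function(in_ch, out_ch, k, stride = 1L, act = nn_relu) {
  nn_sequential(nn_conv2d(in_ch, out_ch, k, stride = stride,
                          pad = (k - 1L) %/% 2L, bias = FALSE),
                nn_batchnorm2d(out_ch), act())
}

# ResNet basic block
resnet_block <- function(in_ch, out_ch, stride = 1L) {
  main <- nn_sequential(
    nn_conv2d(in_ch, out_ch, 3L, stride = stride, pad = 1L, bias = FALSE),
    nn_batchnorm2d(out_ch), nn_relu(),
    nn_conv2d(out_ch, out_ch, 3L, stride = 1L, pad = 1L, bias = FALSE),
    nn_batchnorm2d(out_ch))
  short <- if (stride != 1L || in_ch != out_ch)
    nn_sequential(nn_conv2d(in_ch, out_ch, 1L, stride = stride, bias = FALSE),
                  nn_batchnorm2d(out_ch)) else NULL
  nn_residual(main, short, post_relu = TRUE)
}

# ResNet-18 feature extractor: stem + 4 stages -> (512, s/32, s/32, B)
resnet18_features <- function() {
  nn_sequential(
    nn_conv2d(3L, 64L, 7L, stride = 2L, pad = 3L, bias = FALSE),
    nn_batchnorm2d(64L), nn_relu(),
    nn_maxpool(3L, 2L, 1L),
    resnet_block(64L, 64L), resnet_block(64L, 64L),
    resnet_block(64L, 128L, 2L), resnet_block(128L, 128L),
    resnet_block(128L, 256L, 2L), resnet_block(256L, 256L),
    resnet_block(256L, 512L, 2L), resnet_block(512L, 512L))
}

# MobileNet-V3 inverted residual block
mnv3_block <- function(in_ch, exp_ch, out_ch, k, stride, use_se, act) {
  layers <- list()
  if (exp_ch != in_ch) layers <- c(layers, list(
    nn_conv2d(in_ch, exp_ch, 1L, bias = FALSE), nn_batchnorm2d(exp_ch), act()))
  layers <- c(layers, list(
    nn_depthwise_conv2d(exp_ch, k, stride = stride),
    nn_batchnorm2d(exp_ch), act()))
  if (use_se) layers <- c(layers, list(nn_se(exp_ch)))
  layers <- c(layers, list(
    nn_conv2d(exp_ch, out_ch, 1L, bias = FALSE), nn_batchnorm2d(out_ch)))
  main <- nn_sequential(layers)
  if (stride == 1L && in_ch == out_ch) nn_residual(main) else main
}

mobilenet_v3_net <- function(n_classes, dropout = 0.2) {
  # (kernel, expansion, out, SE, activation, stride) - the Large configuration
  cfgs <- list(
    list(3L,  16L,  16L, FALSE, nn_relu,     1L),
    list(3L,  64L,  24L, FALSE, nn_relu,     2L),
    list(3L,  72L,  24L, FALSE, nn_relu,     1L),
    list(5L,  72L,  40L, TRUE,  nn_relu,     2L),
    list(5L, 120L,  40L, TRUE,  nn_relu,     1L),
    list(5L, 120L,  40L, TRUE,  nn_relu,     1L),
    list(3L, 240L,  80L, FALSE, nn_hardswish, 2L),
    list(3L, 200L,  80L, FALSE, nn_hardswish, 1L),
    list(3L, 184L,  80L, FALSE, nn_hardswish, 1L),
    list(3L, 184L,  80L, FALSE, nn_hardswish, 1L),
    list(3L, 480L, 112L, TRUE,  nn_hardswish, 1L),
    list(3L, 672L, 112L, TRUE,  nn_hardswish, 1L),
    list(5L, 672L, 160L, TRUE,  nn_hardswish, 2L),
    list(5L, 960L, 160L, TRUE,  nn_hardswish, 1L),
    list(5L, 960L, 160L, TRUE,  nn_hardswish, 1L))
  layers <- list(conv_bn_act(3L, 16L, 3L, stride = 2L, act = nn_hardswish))
  in_ch <- 16L
  for (cf in cfgs) {
    layers <- c(layers, list(mnv3_block(in_ch, cf[[2]], cf[[3]], cf[[1]],
                                        cf[[6]], cf[[4]], cf[[5]])))
    in_ch <- cf[[3]]
  }
  layers <- c(layers, list(conv_bn_act(160L, 960L, 1L, act = nn_hardswish),
                           nn_global_avgpool(),
                           nn_linear(960L, 1280L), nn_hardswish(),
                           nn_dropout(dropout), nn_linear(1280L, n_classes)))
  nn_sequential(layers)
}

# EfficientNet MBConv block
mbconv_block <- function(in_ch, out_ch, k, stride, expand) {
  exp_ch <- in_ch * expand
  layers <- list()
  if (expand != 1L) layers <- c(layers, list(
    nn_conv2d(in_ch, exp_ch, 1L, bias = FALSE), nn_batchnorm2d(exp_ch), nn_silu()))
  layers <- c(layers, list(
    nn_depthwise_conv2d(exp_ch, k, stride = stride),
    nn_batchnorm2d(exp_ch), nn_silu(),
    nn_se(exp_ch, reduced = max(1L, in_ch %/% 4L), gate = "sigmoid"),
    nn_conv2d(exp_ch, out_ch, 1L, bias = FALSE), nn_batchnorm2d(out_ch)))
  main <- nn_sequential(layers)
  if (stride == 1L && in_ch == out_ch) nn_residual(main) else main
}

efficientnet_b0_net <- function(n_classes, dropout = 0.2) {
  # (expand, kernel, stride, out, repeats) - the B0 configuration
  cfgs <- list(list(1L, 3L, 1L, 16L, 1L), list(6L, 3L, 2L, 24L, 2L),
               list(6L, 5L, 2L, 40L, 2L), list(6L, 3L, 2L, 80L, 3L),
               list(6L, 5L, 1L, 112L, 3L), list(6L, 5L, 2L, 192L, 4L),
               list(6L, 3L, 1L, 320L, 1L))
  layers <- list(conv_bn_act(3L, 32L, 3L, stride = 2L, act = nn_silu))
  in_ch <- 32L
  for (cf in cfgs) {
    for (r in seq_len(cf[[5]])) {
      s <- if (r == 1L) cf[[3]] else 1L
      layers <- c(layers, list(mbconv_block(in_ch, cf[[4]], cf[[2]], s, cf[[1]])))
      in_ch <- cf[[4]]
    }
  }
  layers <- c(layers, list(conv_bn_act(320L, 1280L, 1L, act = nn_silu),
                           nn_global_avgpool(), nn_dropout(dropout),
                           nn_linear(1280L, n_classes)))
  nn_sequential(layers)
}

tinyvit_hybrid_net <- function(spec) {
  n_tokens <- as.integer((spec$input_size / 32L)^2)
  blocks <- lapply(seq_len(spec$n_layers), function(i)
    nn_vit_block(512L, spec$n_heads, spec$mlp_ratio, spec$dropout))
  nn_sequential(c(
    list(resnet18_features(), nn_tokens(), nn_posembed(512L, n_tokens)),
    blocks,
    list(nn_layernorm(512L), nn_token_mean(), nn_linear(512L, spec$n_classes))))
}

tiny_cnn_net <- function(n_classes, input_size) {
  if (input_size %% 4L != 0L)
    stop("tiny_cnn requires an input size divisible by 4", call. = FALSE)
  feat <- 16L * (input_size %/% 4L)^2
  nn_sequential(
    nn_conv2d(3L, 8L, 3L, pad = 1L, bias = FALSE), nn_batchnorm2d(8L),
    nn_relu(), nn_maxpool(2L, 2L),
    nn_conv2d(8L, 16L, 3L, pad = 1L, bias = FALSE), nn_batchnorm2d(16L),
    nn_relu(), nn_maxpool(2L, 2L),
    nn_flatten(), nn_linear(feat, n_classes))
}

#' Build a classifier from a model specification
#'
#' Returns a trainable model mapping RGB image batches (arrays
#' `H x W x 3 x B` in `[0, 1]`, see [image_batch()]) to class logits. The
#' TinyViT-Hybrid keeps the ResNet-18 backbone through its final
#' convolutional stage, reshapes the resulting `512 x 7 x 7` feature map
#' (224-pixel input) into 49 tokens of dimension 512, adds learnable 1-D
#' positional embeddings, applies two 8-head self-attention encoder blocks
#' with feed-forward inner width `4 x 512 = 2048` and dropout 0.1, then layer
#' normalisation, mean pooling over tokens and a linear head.
#'
#' @param spec A [model_spec()].
#' @return An object of class `eegtfr_model` with elements `net`, `spec` and
#'   `structure` (architecture constants read back from the built weights).
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$pretrained)
    stop(paste0("no pretrained weight files are bundled with this package; ",
                "build with pretrained = FALSE"), call. = FALSE)
  net <- switch(spec$name,
    tiny_cnn = tiny_cnn_net(spec$n_classes, spec$input_size),
    resnet18 = nn_sequential(resnet18_features(), nn_global_avgpool(),
                             nn_linear(512L, spec$n_classes)),
    mobilenet_v3 = mobilenet_v3_net(spec$n_classes),
    efficientnet_b0 = efficientnet_b0_net(spec$n_classes),
    tinyvit_hybrid = tinyvit_hybrid_net(spec),
    stop(sprintf("unknown model '%s'", spec$name), call. = FALSE))
  structure(list(net = net, spec = spec,
                 structure = model_structure(net, spec)),
            class = "eegtfr_model")
}

# read architecture constants back out of the instantiated layers
model_structure <- function(net, spec) {
  out <- list(n_parameters = n_params(net))
  if (spec$name == "tinyvit_hybrid") {
    pe <- Find(function(l) l$type == "posembed", net$children)
    blk1 <- net$children[[4L]]                     # first transformer block
    mlp_fc1 <- blk1$children[[2L]]$main$children[[2L]]$lin
    attn <- blk1$children[[1L]]$main$children[[2L]]
    out$n_tokens <- ncol(pe$P)
    out$token_dim <- nrow(pe$P)
    out$ffn_inner_dim <- nrow(mlp_fc1$W)
    out$n_heads <- attn$heads
    out$n_blocks <- spec$n_layers
  }
  out
}

#' @export
print.eegtfr_model <- function(x, ...) {
  cat(sprintf("<eegtfr_model %s> %s classes = %d, input %dpx, %.2fM parameters\n",
              x$spec$name, ifelse(x$spec$pretrained, "(pretrained)", ""),
              x$spec$n_classes, x$spec$input_size,
              x$structure$n_parameters / 1e6))
  if (!is.null(x$structure$n_tokens))
    cat(sprintf("  tokens: %d x dim %d, %d transformer blocks, %d heads, FFN %d\n",
                x$structure$n_tokens, x$structure$token_dim,
                x$structure$n_blocks, x$structure$n_heads,
                x$structure$ffn_inner_dim))
  invisible(x)
}

#' Stack a list of RGB images into a model input batch
#'
#' @param imgs List of `H x W x 3` arrays in `[0, 1]` (as produced by
#'   [render_png()]), all the same size.
#' @param normalise Optional list with `mean` and `std` vectors of length 3
#'   applied per channel (e.g. ImageNet statistics).
#' @return Array `H x W x 3 x B`.
#' @export
image_batch <- function(imgs, normalise = NULL) {
  d <- dim(imgs[[1L]])
  out <- array(0, c(d, length(imgs)))
  for (i in seq_along(imgs)) out[, , , i] <- imgs[[i]]
  if (!is.null(normalise))
    for (c in 1:3)
      out[, , c, ] <- (out[, , c, ] - normalise$mean[c]) / normalise$std[c]
  out
}

# (H, W, 3, B) user layout -> (C, H, W, B) engine layout
to_chw <- function(x) aperm(x, c(3L, 1L, 2L, 4L))

# forward a batch through a model, returning logits (n_classes, B)
model_forward <- function(model, batch, train = FALSE) {
  model$net$forward(to_chw(batch), train = train)
}
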