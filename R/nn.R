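# A compact neural-network engine in base R.
#
# Layers are environments exposing forward(x, train) / backward(dy), with
# parameters and accumulated gradients stored as fields (`W` and `gW`, ...).
# Convolutions are computed as im2col gathers followed by BLAS GEMMs; the
# depthwise path uses a fully vectorised per-channel gather. Activations,
# batch/layer normalisation, pooling, multi-head self-attention, learnable
# positional embeddings, dropout and residual composition cover everything
# the model zoo needs. Gradients of every layer are validated against
# numerical differentiation in the test suite.
#
# Tensor layout: feature maps are arrays (C, H, W, B); token sequences are
# arrays (dim, T, B); feature vectors are matrices (dim, B). Channel-first
# order makes im2col indices contiguous in R's column-major storage.

new_layer <- function(type, children = list()) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$children <- children
  e$param_names <- character()
  e
}

# recursively collect (layer, parameter-name) pairs
collect_params <- function(layer) {
  out <- list()
  for (nm in layer$param_names) out[[length(out) + 1L]] <- list(env = layer, name = nm)
  for (ch in layer$children) out <- c(out, collect_params(ch))
  out
}

zero_grads <- function(layer) {
  for (p in collect_params(layer)) {
    g <- paste0("g", p$name)
    p$env[[g]] <- p$env[[p$name]] * 0
  }
  invisible(NULL)
}

snapshot_params <- function(layer) lapply(collect_params(layer),
                                          function(p) p$env[[p$name]])

restore_params <- function(layer, snap) {
  ps <- collect_params(layer)
  for (i in seq_along(ps)) ps[[i]]$env[[ps[[i]]$name]] <- snap[[i]]
  invisible(NULL)
}

n_params <- function(layer) sum(vapply(collect_params(layer),
                                       function(p) length(p$env[[p$name]]), numeric(1)))

# sequential container --------------------------------------------------

nn_sequential <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && is.list(layers[[1L]]) && !is.environment(layers[[1L]]))
    layers <- layers[[1L]]
  self <- new_layer("sequential", children = layers)
  self$forward <- function(x, train = FALSE) {
    for (ly in self$children) x <- ly$forward(x, train)
    x
  }
  self$backward <- function(dy) {
    for (ly in rev(self$children)) dy <- ly$backward(dy)
    dy
  }
  self
}

# residual wrapper: y = act(main(x) + shortcut(x))
nn_residual <- function(main, shortcut = NULL, post_relu = FALSE) {
  children <- if (is.null(shortcut)) list(main) else list(main, shortcut)
  self <- new_layer("residual", children = children)
  self$main <- main; self$shortcut <- shortcut; self$post_relu <- post_relu
  self$forward <- function(x, train = FALSE) {
    y <- self$main$forward(x, train) +
      (if (is.null(self$shortcut)) x else self$shortcut$forward(x, train))
    if (self$post_relu) { self$mask <- y > 0; y <- y * self$mask }
    y
  }
  self$backward <- function(dy) {
    if (self$post_relu) dy <- dy * self$mask
    dx <- self$main$backward(dy)
    dx + (if (is.null(self$shortcut)) dy else self$shortcut$backward(dy))
  }
  self
}

# dense layer ------------------------------------------------------------

nn_linear <- function(n_in, n_out, bias = TRUE) {
  self <- new_layer("linear")
  self$W <- matrix(stats::rnorm(n_out * n_in, 0, sqrt(2 / n_in)), n_out, n_in)
  self$gW <- self$W * 0
  self$param_names <- "W"
  if (bias) {
    self$b <- numeric(n_out); self$gb <- numeric(n_out)
    self$param_names <- c("W", "b")
  }
  self$forward <- function(x, train = FALSE) {
    self$x <- x
    y <- self$W %*% x
    if (!is.null(self$b)) y <- y + self$b
    y
  }
  self$backward <- function(dy) {
    self$gW <- self$gW + tcrossprod(dy, self$x)
    if (!is.null(self$b)) self$gb <- self$gb + rowSums(dy)
    crossprod(self$W, dy)
  }
  self
}

# activations ------------------------------------------------------------

nn_relu <- function() {
  self <- new_layer("relu")
  self$forward <- function(x, train = FALSE) { self$mask <- x > 0; x * self$mask }
  self$backward <- function(dy) dy * self$mask
  self
}

nn_gelu <- function() {
  self <- new_layer("gelu")
  self$forward <- function(x, train = FALSE) { self$x <- x; x * stats::pnorm(x) }
  self$backward <- function(dy) dy * (stats::pnorm(self$x) + self$x * stats::dnorm(self$x))
  self
}

nn_silu <- function() {
  self <- new_layer("silu")
  self$forward <- function(x, train = FALSE) {
    self$s <- 1 / (1 + exp(-x)); self$x <- x; x * self$s
  }
  self$backward <- function(dy) dy * (self$s * (1 + self$x * (1 - self$s)))
  self
}

nn_hardswish <- function() {
  self <- new_layer("hardswish")
  self$forward <- function(x, train = FALSE) {
    self$x <- x
    x * pmin(pmax(x + 3, 0), 6) / 6
  }
  self$backward <- function(dy) {
    x <- self$x
    d <- ifelse(x <= -3, 0, ifelse(x >= 3, 1, (2 * x + 3) / 6))
    dy * d
  }
  self
}

hardsigmoid_fwd <- function(x) pmin(pmax(x + 3, 0), 6) / 6
hardsigmoid_bwd <- function(x) ifelse(x > -3 & x < 3, 1 / 6, 0)

# dropout ----------------------------------------------------------------

nn_dropout <- function(p = 0.1) {
  self <- new_layer("dropout")
  self$p <- p
  self$forward <- function(x, train = FALSE) {
    if (!train || self$p <= 0) { self$mask <- NULL; return(x) }
    self$mask <- array(stats::rbinom(length(x), 1L, 1 - self$p) / (1 - self$p), dim(x))
    x * self$mask
  }
  self$backward <- function(dy) if (is.null(self$mask)) dy else dy * self$mask
  self
}

# shape adapters ---------------------------------------------------------

nn_flatten <- function() {
  self <- new_layer("flatten")
  self$forward <- function(x, train = FALSE) {
    self$dims <- dim(x)
    b <- self$dims[length(self$dims)]
    matrix(x, ncol = b)
  }
  self$backward <- function(dy) array(dy, self$dims)
  self
}

# (C, H, W, B) -> token sequence (C, H*W, B)
nn_tokens <- function() {
  self <- new_layer("tokens")
  self$forward <- function(x, train = FALSE) {
    self$dims <- dim(x)
    array(x, c(self$dims[1L], self$dims[2L] * self$dims[3L], self$dims[4L]))
  }
  self$backward <- function(dy) array(dy, self$dims)
  self
}

nn_token_mean <- function() {
  self <- new_layer("token_mean")
  self$forward <- function(x, train = FALSE) {
    self$dims <- dim(x)
    apply(x, c(1L, 3L), mean)
  }
  # spread dy (dim, B) uniformly over tokens
  self$backward <- function(dy) {
    d <- self$dims
    out <- array(0, d)
    for (b in seq_len(d[3L])) out[, , b] <- matrix(dy[, b] / d[2L], d[1L], d[2L])
    out
  }
  self
}

nn_posembed <- function(dim, n_tokens, init_sd = 0.02) {
  self <- new_layer("posembed")
  self$P <- matrix(stats::rnorm(dim * n_tokens, 0, init_sd), dim, n_tokens)
  self$gP <- self$P * 0
  self$param_names <- "P"
  self$forward <- function(x, train = FALSE) {
    self$b <- dim(x)[3L]
    x + array(self$P, dim(x))
  }
  self$backward <- function(dy) {
    self$gP <- self$gP + apply(dy, c(1L, 2L), sum)
    dy
  }
  self
}

# pooling ----------------------------------------------------------------

nn_maxpool <- function(k = 2L, stride = k, pad = 0L) {
  self <- new_layer("maxpool")
  self$k <- as.integer(k); self$stride <- as.integer(stride); self$pad <- as.integer(pad)
  self$forward <- function(x, train = FALSE) {
    d <- dim(x); C <- d[1L]; H <- d[2L]; W <- d[3L]; B <- d[4L]
    k <- self$k; s <- self$stride; p <- self$pad
    Hp <- H + 2L * p; Wp <- W + 2L * p
    Ho <- (Hp - k) %/% s + 1L; Wo <- (Wp - k) %/% s + 1L
    key <- paste(d, collapse = "x")
    if (!identical(self$geom_key, key)) {          # cache gather indices
      hi <- (rep(seq_len(Ho), times = Wo) - 1L) * s
      wi <- (rep(seq_len(Wo), each = Ho) - 1L) * s
      P <- Ho * Wo
      base <- matrix(0L, k * k, P)
      r <- 0L
      for (b in 0:(k - 1L)) for (a in 0:(k - 1L)) {
        r <- r + 1L
        base[r, ] <- (hi + a) + Hp * (wi + b)
      }
      off <- (seq_len(C * B) - 1L) * (Hp * Wp)
      self$idx1 <- base[, rep(seq_len(P), C * B), drop = FALSE] +
        matrix(rep(off, each = P), k * k, P * C * B, byrow = TRUE) + 1L
      self$geom_key <- key
    }
    xp <- array(-Inf, c(Hp, Wp, C, B))
    xp[p + seq_len(H), p + seq_len(W), , ] <- aperm(x, c(2L, 3L, 1L, 4L))
    cols <- matrix(xp[self$idx1], k * k)
    val <- cols[1L, ]; arg <- rep(1L, ncol(cols))
    if (k * k > 1L) for (r in 2:(k * k)) {
      sel <- cols[r, ] > val
      val[sel] <- cols[r, sel]; arg[sel] <- r
    }
    self$cache <- list(arg = arg, d = d, Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo)
    y <- array(val, c(Ho, Wo, C, B))
    aperm(y, c(3L, 1L, 2L, 4L))
  }
  self$backward <- function(dy) {
    cc <- self$cache; d <- cc$d
    C <- d[1L]; B <- d[4L]
    dyv <- as.vector(aperm(dy, c(2L, 3L, 1L, 4L)))
    dxp <- numeric(cc$Hp * cc$Wp * C * B)
    for (r in seq_len(nrow(self$idx1))) {
      sel <- cc$arg == r
      if (any(sel)) {
        pos <- self$idx1[r, sel]
        dxp[pos] <- dxp[pos] + dyv[sel]
      }
    }
    dxp <- array(dxp, c(cc$Hp, cc$Wp, C, B))
    p <- self$pad
    dx <- dxp[p + seq_len(d[2L]), p + seq_len(d[3L]), , , drop = FALSE]
    aperm(dx, c(3L, 1L, 2L, 4L))
  }
  self
}

nn_global_avgpool <- function() {
  self <- new_layer("gap")
  self$forward <- function(x, train = FALSE) {
    self$dims <- dim(x)
    d <- self$dims
    xm <- array(x, c(d[1L], d[2L] * d[3L], d[4L]))
    out <- matrix(0, d[1L], d[4L])
    for (b in seq_len(d[4L])) out[, b] <- rowMeans(xm[, , b, drop = FALSE][, , 1L])
    out
  }
  self$backward <- function(dy) {
    d <- self$dims
    hw <- d[2L] * d[3L]
    dx <- array(0, d)
    for (b in seq_len(d[4L])) dx[, , , b] <- array(rep(dy[, b] / hw, hw), d[1:3])
    dx
  }
  self
}

# normalisation ----------------------------------------------------------

nn_batchnorm2d <- function(C, momentum = 0.1, eps = 1e-5) {
  self <- new_layer("batchnorm2d")
  self$gamma <- rep(1, C); self$beta <- rep(0, C)
  self$ggamma <- rep(0, C); self$gbeta <- rep(0, C)
  self$running_mean <- rep(0, C); self$running_var <- rep(1, C)
  self$momentum <- momentum; self$eps <- eps
  self$param_names <- c("gamma", "beta")
  self$forward <- function(x, train = FALSE) {
    d <- dim(x); C <- d[1L]
    xm <- matrix(x, C)
    if (train) {
      mu <- rowMeans(xm)
      v <- rowMeans(xm * xm) - mu^2
      self$running_mean <- (1 - self$momentum) * self$running_mean + self$momentum * mu
      self$running_var <- (1 - self$momentum) * self$running_var + self$momentum * v
    } else {
      mu <- self$running_mean; v <- self$running_var
    }
    inv <- 1 / sqrt(v + self$eps)
    xhat <- (xm - mu) * inv
    self$cache <- list(xhat = xhat, inv = inv, d = d, train = train)
    array(xhat * self$gamma + self$beta, d)
  }
  self$backward <- function(dy) {
    cc <- self$cache; d <- cc$d; C <- d[1L]
    dym <- matrix(dy, C)
    self$ggamma <- self$ggamma + rowSums(dym * cc$xhat)
    self$gbeta <- self$gbeta + rowSums(dym)
    if (cc$train) {
      n <- ncol(dym)
      dx <- (self$gamma * cc$inv) *
        (dym - rowMeans(dym) - cc$xhat * rowMeans(dym * cc$xhat))
    } else {
      dx <- (self$gamma * cc$inv) * dym
    }
    array(dx, d)
  }
  self
}

nn_layernorm <- function(dim, eps = 1e-5) {
  self <- new_layer("layernorm")
  self$gamma <- rep(1, dim); self$beta <- rep(0, dim)
  self$ggamma <- rep(0, dim); self$gbeta <- rep(0, dim)
  self$eps <- eps
  self$param_names <- c("gamma", "beta")
  self$forward <- function(x, train = FALSE) {
    d <- dim(x)
    xm <- matrix(x, d[1L])
    mu <- colMeans(xm)
    v <- colMeans(xm * xm) - mu^2
    inv <- rep(1 / sqrt(v + self$eps), each = d[1L])
    xhat <- (xm - rep(mu, each = d[1L])) * inv
    self$cache <- list(xhat = xhat, inv = inv, d = d)
    array(xhat * self$gamma + self$beta, d)
  }
  self$backward <- function(dy) {
    cc <- self$cache; d <- cc$d; n <- d[1L]
    dym <- matrix(dy, n)
    self$ggamma <- self$ggamma + rowSums(dym * cc$xhat)
    self$gbeta <- self$gbeta + rowSums(dym)
    g <- dym * self$gamma
    m1 <- rep(colMeans(g), each = n)
    m2 <- rep(colMeans(g * cc$xhat), each = n)
    array(cc$inv * (g - m1 - cc$xhat * m2), d)
  }
  self
}

# convolution ------------------------------------------------------------

# standard (groups = 1) convolution via im2col + GEMM
nn_conv2d <- function(in_ch, out_ch, k, stride = 1L, pad = 0L, bias = TRUE) {
  self <- new_layer("conv2d")
  self$in_ch <- as.integer(in_ch); self$out_ch <- as.integer(out_ch)
  self$k <- as.integer(k); self$stride <- as.integer(stride); self$pad <- as.integer(pad)
  fan_in <- in_ch * k * k
  self$W <- matrix(stats::rnorm(out_ch * fan_in, 0, sqrt(2 / fan_in)), out_ch, fan_in)
  self$gW <- self$W * 0
  self$param_names <- "W"
  if (bias) {
    self$b <- numeric(out_ch); self$gb <- numeric(out_ch)
    self$param_names <- c("W", "b")
  }
  self$forward <- function(x, train = FALSE) {
    d <- dim(x); C <- d[1L]; H <- d[2L]; W <- d[3L]; B <- d[4L]
    k <- self$k; s <- self$stride; p <- self$pad
    Hp <- H + 2L * p; Wp <- W + 2L * p
    Ho <- (Hp - k) %/% s + 1L; Wo <- (Wp - k) %/% s + 1L
    key <- paste(d, collapse = "x")
    if (!identical(self$geom_key, key)) {          # cache gather indices
      P <- Ho * Wo
      hi <- (rep(seq_len(Ho), times = Wo) - 1L) * s
      wi <- (rep(seq_len(Wo), each = Ho) - 1L) * s
      M <- C * k * k
      base <- matrix(0L, M, P)
      r <- 0L
      for (b in 0:(k - 1L)) for (a in 0:(k - 1L)) for (cc in 0:(C - 1L)) {
        r <- r + 1L
        base[r, ] <- cc + C * ((hi + a) + Hp * (wi + b))
      }
      off <- (seq_len(B) - 1L) * (C * Hp * Wp)
      self$idx1 <- base[, rep(seq_len(P), B), drop = FALSE] +
        matrix(rep(off, each = P), M, P * B, byrow = TRUE) + 1L
      self$geom_key <- key
    }
    xp <- array(0, c(C, Hp, Wp, B))
    xp[, p + seq_len(H), p + seq_len(W), ] <- x
    cols <- matrix(xp[self$idx1], nrow(self$idx1))
    y <- self$W %*% cols
    if (!is.null(self$b)) y <- y + self$b
    self$cache <- list(cols = cols, d = d, Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo)
    array(y, c(self$out_ch, Ho, Wo, B))
  }
  self$backward <- function(dy) {
    cc <- self$cache; d <- cc$d
    B <- d[4L]
    dym <- matrix(dy, self$out_ch)
    self$gW <- self$gW + tcrossprod(dym, cc$cols)
    if (!is.null(self$b)) self$gb <- self$gb + rowSums(dym)
    dcols <- crossprod(self$W, dym)
    dxp <- numeric(d[1L] * cc$Hp * cc$Wp * B)
    for (r in seq_len(nrow(self$idx1))) {
      pos <- self$idx1[r, ]
      dxp[pos] <- dxp[pos] + dcols[r, ]
    }
    dxp <- array(dxp, c(d[1L], cc$Hp, cc$Wp, B))
    p <- self$pad
    dxp[, p + seq_len(d[2L]), p + seq_len(d[3L]), , drop = FALSE]
  }
  self
}

# depthwise convolution (one filter per channel)
nn_depthwise_conv2d <- function(ch, k, stride = 1L, pad = (k - 1L) %/% 2L,
                                bias = FALSE) {
  self <- new_layer("depthwise")
  self$ch <- as.integer(ch); self$k <- as.integer(k)
  self$stride <- as.integer(stride); self$pad <- as.integer(pad)
  self$W <- matrix(stats::rnorm(k * k * ch, 0, sqrt(2 / (k * k))), k * k, ch)
  self$gW <- self$W * 0
  self$param_names <- "W"
  if (bias) { self$b <- numeric(ch); self$gb <- numeric(ch)
              self$param_names <- c("W", "b") }
  self$forward <- function(x, train = FALSE) {
    d <- dim(x); C <- d[1L]; H <- d[2L]; W <- d[3L]; B <- d[4L]
    k <- self$k; s <- self$stride; p <- self$pad
    Hp <- H + 2L * p; Wp <- W + 2L * p
    Ho <- (Hp - k) %/% s + 1L; Wo <- (Wp - k) %/% s + 1L
    key <- paste(d, collapse = "x")
    if (!identical(self$geom_key, key)) {          # cache gather indices
      P <- Ho * Wo
      hi <- (rep(seq_len(Ho), times = Wo) - 1L) * s
      wi <- (rep(seq_len(Wo), each = Ho) - 1L) * s
      base <- matrix(0L, k * k, P)
      r <- 0L
      for (b in 0:(k - 1L)) for (a in 0:(k - 1L)) {
        r <- r + 1L
        base[r, ] <- (hi + a) + Hp * (wi + b)
      }
      off <- (seq_len(C * B) - 1L) * (Hp * Wp)
      self$idx1 <- base[, rep(seq_len(P), C * B), drop = FALSE] +
        matrix(rep(off, each = P), k * k, P * C * B, byrow = TRUE) + 1L
      self$kmap <- rep(rep(seq_len(C), each = P), B)  # channel per column
      self$geom_key <- key
    }
    xp <- array(0, c(Hp, Wp, C, B))
    xp[p + seq_len(H), p + seq_len(W), , ] <- aperm(x, c(2L, 3L, 1L, 4L))
    cols <- matrix(xp[self$idx1], k * k)
    Kexp <- self$W[, self$kmap, drop = FALSE]
    yv <- colSums(cols * Kexp)
    if (!is.null(self$b)) yv <- yv + self$b[self$kmap]
    self$cache <- list(cols = cols, d = d, Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo)
    aperm(array(yv, c(Ho, Wo, C, B)), c(3L, 1L, 2L, 4L))
  }
  self$backward <- function(dy) {
    cc <- self$cache; d <- cc$d
    C <- d[1L]; B <- d[4L]; k <- self$k
    P <- cc$Ho * cc$Wo
    dyv <- as.vector(aperm(dy, c(2L, 3L, 1L, 4L)))
    # weight gradient: sum products over positions and batch per channel
    prods <- cc$cols * matrix(dyv, k * k, length(dyv), byrow = TRUE)
    dim(prods) <- c(k * k, P, C, B)
    self$gW <- self$gW + apply(prods, c(1L, 3L), sum)
    if (!is.null(self$b)) {
      dy3 <- dyv; dim(dy3) <- c(P, C, B)
      self$gb <- self$gb + apply(dy3, 2L, sum)
    }
    # input gradient
    Kexp <- self$W[, self$kmap, drop = FALSE]
    dcols <- Kexp * matrix(dyv, k * k, length(dyv), byrow = TRUE)
    dxp <- numeric(cc$Hp * cc$Wp * C * B)
    for (r in seq_len(k * k)) {
      pos <- self$idx1[r, ]
      dxp[pos] <- dxp[pos] + dcols[r, ]
    }
    dxp <- array(dxp, c(cc$Hp, cc$Wp, C, B))
    p <- self$pad
    dx <- dxp[p + seq_len(d[2L]), p + seq_len(d[3L]), , , drop = FALSE]
    aperm(dx, c(3L, 1L, 2L, 4L))
  }
  self
}

# squeeze-and-excitation block -------------------------------------------

nn_se <- function(ch, reduced = max(8L, round(ch / 4 / 8) * 8L),
                  gate = c("hardsigmoid", "sigmoid")) {
  gate <- match.arg(gate)
  self <- new_layer("se")
  self$fc1 <- nn_linear(ch, reduced)
  self$fc2 <- nn_linear(reduced, ch)
  self$gate <- gate
  self$children <- list(self$fc1, self$fc2)
  self$forward <- function(x, train = FALSE) {
    d <- dim(x); C <- d[1L]; hw <- d[2L] * d[3L]; B <- d[4L]
    xm <- array(x, c(C, hw, B))
    pooled <- matrix(0, C, B)
    for (b in seq_len(B)) pooled[, b] <- rowMeans(xm[, , b, drop = FALSE][, , 1L])
    h <- self$fc1$forward(pooled, train)
    self$hmask <- h > 0
    h <- h * self$hmask
    z <- self$fc2$forward(h, train)
    s <- if (self$gate == "hardsigmoid") hardsigmoid_fwd(z) else 1 / (1 + exp(-z))
    self$cache <- list(x = x, s = s, z = z, d = d)
    sx <- aperm(array(s, c(C, B, hw)), c(1L, 3L, 2L))
    x * array(sx, d)
  }
  self$backward <- function(dy) {
    cc <- self$cache; d <- cc$d
    C <- d[1L]; hw <- d[2L] * d[3L]; B <- d[4L]
    sx <- array(aperm(array(cc$s, c(C, B, hw)), c(1L, 3L, 2L)), d)
    dx_direct <- dy * sx
    # gradient through the gate
    prod <- array(dy * cc$x, c(C, hw, B))
    ds <- matrix(0, C, B)
    for (b in seq_len(B)) ds[, b] <- rowSums(prod[, , b, drop = FALSE][, , 1L])
    dz <- ds * (if (self$gate == "hardsigmoid") hardsigmoid_bwd(cc$z)
                else { sg <- 1 / (1 + exp(-cc$z)); sg * (1 - sg) })
    dh <- self$fc2$backward(dz) * self$hmask
    dpool <- self$fc1$backward(dh)
    dxp <- array(0, d)
    for (b in seq_len(B)) dxp[, , , b] <- array(rep(dpool[, b] / hw, hw), d[1:3])
    dx_direct + dxp
  }
  self
}

# multi-head self-attention ----------------------------------------------

nn_mhsa <- function(dim, heads, proj_drop = 0.1) {
  stopifnot(dim %% heads == 0L)
  self <- new_layer("mhsa")
  self$dim <- as.integer(dim); self$heads <- as.integer(heads)
  self$hd <- as.integer(dim / heads)
  self$qkv <- nn_linear(dim, 3L * dim)
  self$proj <- nn_linear(dim, dim)
  self$drop <- nn_dropout(proj_drop)
  self$children <- list(self$qkv, self$proj, self$drop)
  self$forward <- function(x, train = FALSE) {
    d <- dim(x)                               # (dim, T, B)
    Tn <- d[2L]; B <- d[3L]
    xm <- matrix(x, d[1L])                    # (dim, T*B)
    qkv <- self$qkv$forward(xm, train)        # (3*dim, T*B)
    cache <- vector("list", B)
    out <- matrix(0, self$dim, Tn * B)
    sc <- 1 / sqrt(self$hd)
    for (b in seq_len(B)) {
      colsel <- (b - 1L) * Tn + seq_len(Tn)
      hc <- vector("list", self$heads)
      for (h in seq_len(self$heads)) {
        rows <- (h - 1L) * self$hd + seq_len(self$hd)
        Q <- qkv[rows, colsel, drop = FALSE]
        K <- qkv[self$dim + rows, colsel, drop = FALSE]
        V <- qkv[2L * self$dim + rows, colsel, drop = FALSE]
        S <- crossprod(Q, K) * sc             # (T, T), rows = queries
        S <- S - apply(S, 1L, max)
        A <- exp(S); A <- A / rowSums(A)
        out[rows, colsel] <- V %*% t(A)
        hc[[h]] <- list(Q = Q, K = K, V = V, A = A)
      }
      cache[[b]] <- hc
    }
    self$cache <- list(d = d, heads = cache)
    y <- self$proj$forward(out, train)
    y <- self$drop$forward(y, train)
    array(y, d)
  }
  self$backward <- function(dy) {
    d <- self$cache$d
    Tn <- d[2L]; B <- d[3L]
    sc <- 1 / sqrt(self$hd)
    dym <- matrix(dy, d[1L])
    dout <- self$proj$backward(self$drop$backward(dym))
    dqkv <- matrix(0, 3L * self$dim, Tn * B)
    for (b in seq_len(B)) {
      colsel <- (b - 1L) * Tn + seq_len(Tn)
      for (h in seq_len(self$heads)) {
        rows <- (h - 1L) * self$hd + seq_len(self$hd)
        cc <- self$cache$heads[[b]][[h]]
        G <- dout[rows, colsel, drop = FALSE] # (hd, T)
        dV <- G %*% cc$A
        dA <- crossprod(G, cc$V)              # (T, T): dOut w.r.t. attention
        dS <- cc$A * (dA - rowSums(dA * cc$A))
        dQ <- cc$K %*% t(dS) * sc
        dK <- cc$Q %*% dS * sc
        dqkv[rows, colsel] <- dQ
        dqkv[self$dim + rows, colsel] <- dK
        dqkv[2L * self$dim + rows, colsel] <- dV
      }
    }
    dx <- self$qkv$backward(dqkv)
    array(dx, d)
  }
  self
}

# transformer encoder block (pre-norm, MLP ratio `mlp_ratio`)
nn_vit_block <- function(dim, heads, mlp_ratio = 4, dropout = 0.1) {
  inner <- as.integer(mlp_ratio * dim)
  attn_path <- nn_sequential(nn_layernorm(dim), nn_mhsa(dim, heads, proj_drop = dropout))
  mlp_path <- nn_sequential(nn_layernorm(dim),
                            nn_tokens_linear(dim, inner),
                            nn_gelu(),
                            nn_dropout(dropout),
                            nn_tokens_linear(inner, dim),
                            nn_dropout(dropout))
  nn_sequential(nn_residual(attn_path), nn_residual(mlp_path))
}

# linear applied token-wise to a (dim, T, B) array
nn_tokens_linear <- function(n_in, n_out) {
  self <- new_layer("tokens_linear")
  self$lin <- nn_linear(n_in, n_out)
  self$children <- list(self$lin)
  self$forward <- function(x, train = FALSE) {
    d <- dim(x)
    self$dims <- d
    y <- self$lin$forward(matrix(x, d[1L]), train)
    array(y, c(nrow(y), d[2L], d[3L]))
  }
  self$backward <- function(dy) {
    d <- dim(dy)
    dx <- self$lin$backward(matrix(dy, d[1L]))
    array(dx, self$dims)
  }
  self
}

# loss and optimiser ------------------------------------------------------

# softmax cross-entropy; y is an integer class vector (1-based)
softmax_xent <- function(logits, y) {
  B <- ncol(logits)
  m <- apply(logits, 2L, max)
  z <- exp(sweep(logits, 2L, m))
  p <- sweep(z, 2L, colSums(z), "/")
  loss <- -mean(log(pmax(p[cbind(y, seq_len(B))], 1e-12)))
  dlogits <- p
  dlogits[cbind(y, seq_len(B))] <- dlogits[cbind(y, seq_len(B))] - 1
  list(loss = loss, dlogits = dlogits / B, probs = p)
}

# decoupled AdamW with optional cosine-annealed learning rate
adamw_new <- function(params, lr = 1e-4, weight_decay = 1e-4,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$m <- lapply(params, function(p) p$env[[p$name]] * 0)
  st$v <- st$m
  st$t <- 0L
  st$lr <- lr; st$wd <- weight_decay
  st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st
}

adamw_step <- function(st, lr = st$lr) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$beta1^st$t
  bc2 <- 1 - st$beta2^st$t
  for (i in seq_along(st$params)) {
    p <- st$params[[i]]
    g <- p$env[[paste0("g", p$name)]]
    st$m[[i]] <- st$beta1 * st$m[[i]] + (1 - st$beta1) * g
    st$v[[i]] <- st$beta2 * st$v[[i]] + (1 - st$beta2) * g * g
    mhat <- st$m[[i]] / bc1
    vhat <- st$v[[i]] / bc2
    w <- p$env[[p$name]]
    p$env[[p$name]] <- w - lr * (mhat / (sqrt(vhat) + st$eps) + st$wd * w)
  }
  invisible(NULL)
}

cosine_lr <- function(epoch, lr0, t_max = 8, lr_min = 1e-6) {
  lr_min + 0.5 * (lr0 - lr_min) * (1 + cos(pi * min(epoch, t_max) / t_max))
}
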