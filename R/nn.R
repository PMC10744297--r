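#' Minimal 1D neural-network engine
#'
#' A small, self-contained engine for the compact one-dimensional
#' convolutional architectures used for spectral classification: conv1d
#' (same padding), ReLU, batch normalization, inverted dropout, average
#' pooling, global average pooling, flatten, dense, residual blocks, Adam,
#' and binary cross-entropy on a sigmoid output. Activations are stored as
#' (batch, length, channels) arrays. Everything is deterministic given the
#' R RNG state (used for initialization, shuffling and dropout masks).
#'
#' @name nn-engine
#' @keywords internal
NULL

.glorot <- function(fan_in, fan_out, dims) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -limit, limit), dims)
}

nn_layer_conv1d <- function(in_ch, out_ch, kernel = 3L, l2 = 1e-4) {
  list(type = "conv1d", in_ch = in_ch, out_ch = out_ch, kernel = kernel,
       l2 = l2,
       params = list(
         W = .glorot(kernel * in_ch, kernel * out_ch,
                     c(kernel * in_ch, out_ch)),
         b = numeric(out_ch)))
}

nn_layer_bn <- function(ch, momentum = 0.9, eps = 1e-3) {
  list(type = "bn", ch = ch, momentum = momentum, eps = eps,
       params = list(gamma = rep(1, ch), beta = numeric(ch)),
       state = list(mean = numeric(ch), var = rep(1, ch)))
}

nn_layer_relu <- function() list(type = "relu")
nn_layer_dropout <- function(rate = 0.25) list(type = "dropout", rate = rate)
nn_layer_avgpool <- function(size = 8L) list(type = "avgpool", size = size)
nn_layer_flatten <- function() list(type = "flatten")
nn_layer_gap <- function() list(type = "gap")

nn_layer_dense <- function(in_dim, out_dim = 1L, l2 = 1e-4) {
  list(type = "dense", in_dim = in_dim, out_dim = out_dim, l2 = l2,
       params = list(W = .glorot(in_dim, out_dim, c(in_dim, out_dim)),
                     b = numeric(out_dim)))
}

nn_layer_resblock <- function(in_ch, out_ch, l2 = 1e-4) {
  sub <- list(conv1 = nn_layer_conv1d(in_ch, out_ch, 3L, l2),
              bn1 = nn_layer_bn(out_ch),
              conv2 = nn_layer_conv1d(out_ch, out_ch, 3L, l2),
              bn2 = nn_layer_bn(out_ch))
  if (in_ch != out_ch)
    sub$proj <- nn_layer_conv1d(in_ch, out_ch, 1L, l2)
  list(type = "resblock", in_ch = in_ch, out_ch = out_ch, sub = sub)
}

# ---- forward ---------------------------------------------------------------

.conv_forward <- function(layer, x) {
  d <- dim(x); B <- d[1]; L <- d[2]; Cin <- d[3]
  k <- layer$kernel; p <- (k - 1L) %/% 2L
  if (p > 0L) {
    xp <- array(0, c(B, L + 2L * p, Cin))
    xp[, (p + 1L):(p + L), ] <- x
  } else xp <- x
  X2 <- matrix(0, B * L, k * Cin)
  for (j in seq_len(k))
    X2[, ((j - 1L) * Cin + 1L):(j * Cin)] <-
      matrix(xp[, j:(j + L - 1L), , drop = FALSE], B * L, Cin)
  Y2 <- X2 %*% layer$params$W
  Y2 <- Y2 + matrix(layer$params$b, nrow(Y2), ncol(Y2), byrow = TRUE)
  list(out = array(Y2, c(B, L, layer$out_ch)),
       cache = list(X2 = X2, dims = c(B, L, Cin)))
}

.conv_backward <- function(layer, cache, dout) {
  B <- cache$dims[1]; L <- cache$dims[2]; Cin <- cache$dims[3]
  k <- layer$kernel; p <- (k - 1L) %/% 2L
  dY2 <- matrix(dout, B * L, layer$out_ch)
  dW <- crossprod(cache$X2, dY2) + 2 * layer$l2 * layer$params$W
  db <- colSums(dY2)
  dX2 <- dY2 %*% t(layer$params$W)
  dxp <- array(0, c(B, L + 2L * p, Cin))
  for (j in seq_len(k)) {
    cols <- ((j - 1L) * Cin + 1L):(j * Cin)
    dxp[, j:(j + L - 1L), ] <- dxp[, j:(j + L - 1L), , drop = FALSE] +
      array(dX2[, cols], c(B, L, Cin))
  }
  dx <- if (p > 0L) dxp[, (p + 1L):(p + L), , drop = FALSE] else dxp
  list(dx = dx, grads = list(W = dW, b = db))
}

.bn_forward <- function(layer, x, training) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3])
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    m <- layer$momentum
    layer$state$mean <- m * layer$state$mean + (1 - m) * mu
    layer$state$var <- m * layer$state$var + (1 - m) * v
  } else {
    mu <- layer$state$mean
    v <- layer$state$var
  }
  inv <- 1 / sqrt(v + layer$eps)
  xhat <- sweep(sweep(xm, 2L, mu, "-"), 2L, inv, "*")
  ym <- sweep(sweep(xhat, 2L, layer$params$gamma, "*"), 2L,
              layer$params$beta, "+")
  list(out = array(ym, d), layer = layer,
       cache = list(xhat = xhat, inv = inv, dims = d, training = training))
}

.bn_backward <- function(layer, cache, dout) {
  d <- cache$dims
  dym <- matrix(dout, d[1] * d[2], d[3])
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2L, layer$params$gamma, "*")
  if (cache$training) {
    n <- d[1] * d[2]
    # dx = inv/n * (n*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * cache$xhat)
    dxm <- sweep(dxhat, 2L, s1 / n, "-") -
      sweep(cache$xhat, 2L, s2 / n, "*")
    dxm <- sweep(dxm, 2L, cache$inv, "*")
  } else {
    dxm <- sweep(dxhat, 2L, cache$inv, "*")
  }
  list(dx = array(dxm, d), grads = list(gamma = dgamma, beta = dbeta))
}

.avgpool_forward <- function(layer, x) {
  d <- dim(x); B <- d[1]; L <- d[2]; C <- d[3]; s <- layer$size
  Lp <- L %/% s
  if (Lp < 1L) stop("input too short for pooling", call. = FALSE)
  acc <- array(0, c(B, Lp, C))
  for (j in seq_len(s))
    acc <- acc + x[, seq(j, Lp * s, by = s), , drop = FALSE]
  list(out = acc / s, cache = list(dims = d))
}

.avgpool_backward <- function(layer, cache, dout) {
  d <- cache$dims; s <- layer$size; Lp <- d[2] %/% s
  dx <- array(0, d)
  for (j in seq_len(s))
    dx[, seq(j, Lp * s, by = s), ] <- dout / s
  list(dx = dx, grads = NULL)
}

.gap_forward <- function(layer, x) {
  d <- dim(x)
  xm <- matrix(x, d[1], d[2] * d[3])
  y <- vapply(seq_len(d[3]), function(c)
    rowMeans(xm[, ((c - 1L) * d[2] + 1L):(c * d[2]), drop = FALSE]),
    numeric(d[1]))
  list(out = matrix(y, d[1], d[3]), cache = list(dims = d))
}

.gap_backward <- function(layer, cache, dout) {
  d <- cache$dims
  dx <- array(dout[, rep(seq_len(d[3]), each = d[2])] / d[2], d)
  list(dx = dx, grads = NULL)
}

nn_layer_forward <- function(layer, x, training) {
  switch(layer$type,
    conv1d = c(.conv_forward(layer, x), list(layer = layer)),
    bn = .bn_forward(layer, x, training),
    relu = {
      mask <- x > 0
      list(out = x * mask, cache = list(mask = mask), layer = layer)
    },
    dropout = {
      if (training && layer$rate > 0) {
        mask <- array((stats::runif(length(x)) >= layer$rate) /
                        (1 - layer$rate), dim(x))
        list(out = x * mask, cache = list(mask = mask), layer = layer)
      } else list(out = x, cache = list(mask = NULL), layer = layer)
    },
    avgpool = c(.avgpool_forward(layer, x), list(layer = layer)),
    flatten = {
      d <- dim(x)
      list(out = matrix(x, d[1], d[2] * d[3]), cache = list(dims = d),
           layer = layer)
    },
    gap = c(.gap_forward(layer, x), list(layer = layer)),
    dense = {
      y <- x %*% layer$params$W
      y <- y + matrix(layer$params$b, nrow(y), ncol(y), byrow = TRUE)
      list(out = y, cache = list(x = x), layer = layer)
    },
    resblock = .resblock_forward(layer, x, training),
    stop(sprintf("unknown layer type '%s'", layer$type), call. = FALSE))
}

nn_layer_backward <- function(layer, cache, dout) {
  switch(layer$type,
    conv1d = .conv_backward(layer, cache, dout),
    bn = .bn_backward(layer, cache, dout),
    relu = list(dx = dout * cache$mask, grads = NULL),
    dropout = {
      if (is.null(cache$mask)) list(dx = dout, grads = NULL)
      else list(dx = dout * cache$mask, grads = NULL)
    },
    avgpool = .avgpool_backward(layer, cache, dout),
    flatten = list(dx = array(dout, cache$dims), grads = NULL),
    gap = .gap_backward(layer, cache, dout),
    dense = list(dx = dout %*% t(layer$params$W),
                 grads = list(W = crossprod(cache$x, dout) +
                                2 * layer$l2 * layer$params$W,
                              b = colSums(dout))),
    resblock = .resblock_backward(layer, cache, dout),
    stop(sprintf("unknown layer type '%s'", layer$type), call. = FALSE))
}

.resblock_forward <- function(layer, x, training) {
  sub <- layer$sub; caches <- list()
  step <- function(nm, inp) {
    r <- if (sub[[nm]]$type == "resblock") stop("nested resblock")
         else nn_layer_forward(sub[[nm]], inp, training)
    if (!is.null(r$layer)) sub[[nm]] <<- r$layer
    caches[[nm]] <<- r$cache
    r$out
  }
  h <- step("conv1", x)
  h <- step("bn1", h)
  relu1_mask <- h > 0
  h <- h * relu1_mask
  h <- step("conv2", h)
  h <- step("bn2", h)
  s <- if (!is.null(sub$proj)) step("proj", x) else x
  pre <- h + s
  out_mask <- pre > 0
  layer$sub <- sub
  list(out = pre * out_mask, layer = layer,
       cache = list(sub = caches, relu1_mask = relu1_mask,
                    out_mask = out_mask, has_proj = !is.null(sub$proj)))
}

.resblock_backward <- function(layer, cache, dout) {
  sub <- layer$sub
  dpre <- dout * cache$out_mask
  grads <- list()
  back <- function(nm, g) {
    r <- nn_layer_backward(sub[[nm]], cache$sub[[nm]], g)
    grads[[nm]] <<- r$grads
    r$dx
  }
  g <- back("bn2", dpre)
  g <- back("conv2", g)
  g <- g * cache$relu1_mask
  g <- back("bn1", g)
  dx_main <- back("conv1", g)
  dx_skip <- if (cache$has_proj) back("proj", dpre) else dpre
  list(dx = dx_main + dx_skip, grads = grads)
}

#' Forward pass through a layer list
#'
#' @param net list with element \code{layers}.
#' @param x input array (batch, length, 1) or matrix (batch, length).
#' @param training logical; enables batch statistics and dropout.
#' @return list: \code{logit} (numeric vector), \code{outputs} (per-layer
#'   outputs), \code{caches}, and the (possibly updated) \code{net}.
#' @keywords internal
nn_forward <- function(net, x, training = FALSE) {
  if (is.matrix(x)) x <- array(x, c(nrow(x), ncol(x), 1L))
  if (length(dim(x)) == 2L) x <- array(x, c(dim(x), 1L))
  caches <- vector("list", length(net$layers))
  outputs <- vector("list", length(net$layers))
  h <- x
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    r <- if (ly$type == "resblock") .resblock_forward(ly, h, training)
         else nn_layer_forward(ly, h, training)
    if (!is.null(r$layer)) net$layers[[i]] <- r$layer
    caches[[i]] <- r$cache
    outputs[[i]] <- r$out
    h <- r$out
  }
  list(logit = as.numeric(h), outputs = outputs, caches = caches, net = net)
}

#' Backward pass; returns per-layer parameter gradients and the gradient
#' arriving at each layer's output
#' @keywords internal
nn_backward <- function(net, fwd, dlogit) {
  n <- length(net$layers)
  grads <- vector("list", n)
  grad_at_output <- vector("list", n)
  g <- matrix(dlogit, ncol = 1L)
  for (i in rev(seq_len(n))) {
    ly <- net$layers[[i]]
    grad_at_output[[i]] <- g
    r <- if (ly$type == "resblock")
      .resblock_backward(ly, fwd$caches[[i]], g)
    else nn_layer_backward(ly, fwd$caches[[i]], g)
    grads[i] <- list(r$grads)  # [[<-]] with NULL would drop the slot
    g <- r$dx
  }
  list(grads = grads, grad_at_output = grad_at_output, dinput = g)
}

# ---- Adam ------------------------------------------------------------------

.adam_init_like <- function(layers) {
  lapply(layers, function(ly) {
    if (!is.null(ly$sub)) return(.adam_init_like(ly$sub))
    if (is.null(ly$params)) return(NULL)
    lapply(ly$params, function(p) list(m = p * 0, v = p * 0))
  })
}

.adam_apply <- function(layers, grads, state, lr, t,
                        b1 = 0.9, b2 = 0.999, eps = 1e-7) {
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    # sublayer grads are collected in backward order; align by name
    gi <- if (!is.null(names(layers))) grads[[names(layers)[i]]]
          else grads[[i]]
    if (!is.null(ly$sub)) {
      r <- .adam_apply(ly$sub, gi, state[[i]], lr, t, b1, b2, eps)
      ly$sub <- r$layers
      layers[[i]] <- ly
      state[[i]] <- r$state
      next
    }
    if (is.null(ly$params) || is.null(gi)) next
    for (nm in names(ly$params)) {
      g <- gi[[nm]]
      st <- state[[i]][[nm]]
      st$m <- b1 * st$m + (1 - b1) * g
      st$v <- b2 * st$v + (1 - b2) * g^2
      mhat <- st$m / (1 - b1^t)
      vhat <- st$v / (1 - b2^t)
      ly$params[[nm]] <- ly$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[nm]] <- st
    }
    layers[[i]] <- ly
  }
  list(layers = layers, state = state)
}

# L2 penalty term of the loss (matches the gradient terms added in the
# conv/dense backward passes)
.nn_l2_penalty <- function(layers) {
  tot <- 0
  for (ly in layers) {
    if (!is.null(ly$sub)) tot <- tot + .nn_l2_penalty(ly$sub)
    else if (ly$type %in% c("conv1d", "dense"))
      tot <- tot + ly$l2 * sum(ly$params$W^2)
  }
  tot
}
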