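#' Compact 1D deep-learning classifiers
#'
#' Two architectures for binary spectral classification, built on the
#' package's own array-based layer engine:
#' \itemize{
#'   \item \strong{cnn1d} — conv(10 filters, kernel 3) -> ReLU -> batch
#'     norm -> dropout -> conv(25 filters, kernel 3) -> ReLU -> batch norm
#'     -> dropout -> average pool(8) -> flatten -> dense(1) -> sigmoid.
#'   \item \strong{resnet1d} — three residual blocks (16/32/64 channels,
#'     two conv(3)+batch-norm layers each, 1x1 projection shortcut on
#'     channel change), global average pooling, dense(1) -> sigmoid.
#' }
#' Convolution uses "same" zero padding so feature maps stay aligned with
#' the input axis (needed for saliency mapping). Conv and dense kernels
#' carry an L2 weight penalty (default 1e-4).
#'
#' @name classifiers-dl
NULL

#' Build an untrained 1D CNN
#'
#' @param input_length number of spectral channels (>= 32).
#' @param dropout dropout rate (default 0.25).
#' @param l2_strength L2 kernel penalty (default 1e-4).
#' @param seed integer seed for weight initialization.
#' @return a \code{dl_model} (untrained).
#' @export
build_cnn1d <- function(input_length, dropout = 0.25, l2_strength = 1e-4,
                        seed = 1L) {
  input_length <- as.integer(input_length)
  if (input_length < 32L)
    stop("cnn1d needs input_length >= 32", call. = FALSE)
  if (input_length %/% 8L < 1L)
    stop("input too short for pooling", call. = FALSE)
  set.seed(seed)
  layers <- list(
    nn_layer_conv1d(1L, 10L, 3L, l2_strength),
    nn_layer_relu(),
    nn_layer_bn(10L),
    nn_layer_dropout(dropout),
    nn_layer_conv1d(10L, 25L, 3L, l2_strength),
    nn_layer_relu(),
    nn_layer_bn(25L),
    nn_layer_dropout(dropout),
    nn_layer_avgpool(8L),
    nn_layer_flatten(),
    nn_layer_dense((input_length %/% 8L) * 25L, 1L, l2_strength))
  structure(list(family = "cnn1d", input_length = input_length,
                 net = list(layers = layers), trained = FALSE,
                 target_conv = 5L,  # index of the last conv layer
                 dropout = dropout, l2_strength = l2_strength, seed = seed),
            class = "dl_model")
}

#' Build an untrained 1D residual network
#'
#' @inheritParams build_cnn1d
#' @param input_length number of spectral channels (>= 64).
#' @return a \code{dl_model} (untrained).
#' @export
build_resnet1d <- function(input_length, dropout = 0.25, l2_strength = 1e-4,
                           seed = 1L) {
  input_length <- as.integer(input_length)
  if (input_length < 64L)
    stop("resnet1d needs input_length >= 64", call. = FALSE)
  set.seed(seed)
  layers <- list(
    nn_layer_resblock(1L, 16L, l2_strength),
    nn_layer_dropout(dropout),
    nn_layer_resblock(16L, 32L, l2_strength),
    nn_layer_dropout(dropout),
    nn_layer_resblock(32L, 64L, l2_strength),
    nn_layer_gap(),
    nn_layer_dense(64L, 1L, l2_strength))
  structure(list(family = "resnet1d", input_length = input_length,
                 net = list(layers = layers), trained = FALSE,
                 target_conv = 5L,  # last residual block output
                 dropout = dropout, l2_strength = l2_strength, seed = seed),
            class = "dl_model")
}

#' Architecture summary
#'
#' @param object a \code{dl_model}.
#' @param ... ignored.
#' @return data.frame describing the layer stack (type, output channels,
#'   kernel/pool size, parameter count).
#' @export
#' @method summary dl_model
summary.dl_model <- function(object, ...) {
  count_params <- function(ly) {
    if (!is.null(ly$sub)) return(sum(vapply(ly$sub, count_params, numeric(1))))
    if (is.null(ly$params)) return(0)
    sum(vapply(ly$params, length, numeric(1)))
  }
  rows <- lapply(object$net$layers, function(ly) {
    data.frame(
      type = ly$type,
      channels = if (!is.null(ly$out_ch)) ly$out_ch
                 else if (ly$type == "dense") ly$out_dim else NA,
      size = if (ly$type == "conv1d") ly$kernel
             else if (ly$type == "avgpool") ly$size
             else if (ly$type == "dropout") ly$rate else NA,
      n_params = count_params(ly))
  })
  out <- do.call(rbind, rows)
  attr(out, "family") <- object$family
  attr(out, "input_length") <- object$input_length
  out
}

#' Training recipe for the deep models
#'
#' @param epochs number of passes over the training data (default 40).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size minibatch size (default 32).
#' @return a list with the validated fields.
#' @export
dl_recipe <- function(epochs = 40L, learning_rate = 0.001, batch_size = 32L) {
  stopifnot(epochs >= 1, learning_rate > 0, batch_size >= 1)
  list(epochs = as.integer(epochs), learning_rate = learning_rate,
       batch_size = as.integer(batch_size))
}

#' Train a deep model
#'
#' Adam on the binary cross-entropy loss (plus the architecture's L2 weight
#' penalty). Shuffling and dropout are driven by the R RNG, seeded from
#' \code{seed}, so training is reproducible.
#'
#' @param model an untrained (or trained) \code{dl_model}.
#' @param x training matrix (spectra x input_length).
#' @param y integer labels (0/1).
#' @param validation optional list(x =, y =) used only to record a
#'   validation-loss history.
#' @param recipe a \code{\link{dl_recipe}}.
#' @param seed RNG seed for shuffling/dropout (default: the model's
#'   initialization seed).
#' @return the trained \code{dl_model}, with \code{history} (per-epoch mean
#'   training loss; same length as \code{epochs}) and, when validation data
#'   are given, \code{val_history}.
#' @export
train_dl <- function(model, x, y, validation = NULL, recipe = dl_recipe(),
                     seed = model$seed) {
  stopifnot(inherits(model, "dl_model"))
  x <- as.matrix(x); y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  if (ncol(x) != model$input_length)
    stop(sprintf("model expects input_length %d, got %d",
                 model$input_length, ncol(x)), call. = FALSE)
  set.seed(seed)
  n <- nrow(x)
  net <- model$net
  adam <- .adam_init_like(net$layers)
  t_step <- 0L
  history <- numeric(recipe$epochs)
  val_history <- if (!is.null(validation)) numeric(recipe$epochs) else NULL
  for (epoch in seq_len(recipe$epochs)) {
    ord <- sample.int(n)
    batch_losses <- c()
    for (start in seq(1L, n, by = recipe$batch_size)) {
      idx <- ord[start:min(start + recipe$batch_size - 1L, n)]
      xb <- x[idx, , drop = FALSE]
      yb <- y[idx]
      fwd <- nn_forward(net, xb, training = TRUE)
      net <- fwd$net
      p <- stats::plogis(fwd$logit)
      eps <- 1e-12
      loss <- -mean(yb * log(p + eps) + (1 - yb) * log(1 - p + eps)) +
        .nn_l2_penalty(net$layers)
      if (!is.finite(loss))
        stop(sprintf("NaN/Inf training loss at epoch %d (lr too high or degenerate input)",
                     epoch), call. = FALSE)
      batch_losses <- c(batch_losses, loss)
      dlogit <- (p - yb) / length(yb)
      bwd <- nn_backward(net, fwd, dlogit)
      t_step <- t_step + 1L
      upd <- .adam_apply(net$layers, bwd$grads, adam,
                         recipe$learning_rate, t_step)
      net$layers <- upd$layers
      adam <- upd$state
    }
    history[epoch] <- mean(batch_losses)
    if (!is.null(validation)) {
      fv <- nn_forward(net, as.matrix(validation$x), training = FALSE)
      pv <- stats::plogis(fv$logit)
      yv <- as.numeric(validation$y)
      val_history[epoch] <- -mean(yv * log(pv + 1e-12) +
                                    (1 - yv) * log(1 - pv + 1e-12))
    }
  }
  model$net <- net
  model$trained <- TRUE
  model$history <- history
  model$val_history <- val_history
  model$recipe <- recipe
  model
}

#' @export
predict_prob.dl_model <- function(model, x) {
  fwd <- nn_forward(model$net, as.matrix(x), training = FALSE)
  stats::plogis(fwd$logit)
}

#' @export
fit_model.dl_model <- function(model, x, y, ...) {
  args <- list(...)
  recipe <- if (!is.null(args$recipe)) {
    args$recipe
  } else if (!is.null(model$spec)) {
    hp <- model$spec$hyperparams
    dl_recipe(epochs = hp$epochs, learning_rate = hp$learning_rate,
              batch_size = hp$batch_size)
  } else dl_recipe()
  train_dl(model, x, y, recipe = recipe)
}

#' Build any model family from a spec
#'
#' Dispatcher used by the cross-validation driver: classical families go
#' through \code{\link{build_ml_model}}, deep families are instantiated for
#' the given input length.
#'
#' @param spec a \code{model_spec}.
#' @param input_length spectral input length (needed for deep families).
#' @return an untrained \code{ml_model} or \code{dl_model}.
#' @export
build_model <- function(spec, input_length = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$family %in% .ML_FAMILIES) return(build_ml_model(spec))
  hp <- spec$hyperparams
  if (is.null(input_length))
    stop("input_length is required for deep model families", call. = FALSE)
  builder <- if (spec$family == "cnn1d") build_cnn1d else build_resnet1d
  m <- builder(input_length, dropout = hp$dropout,
               l2_strength = hp$l2_strength, seed = spec$seed)
  m$spec <- spec
  m
}
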