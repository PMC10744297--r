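#' Grad-CAM saliency for 1D convolutional classifiers
#'
#' Gradient-weighted class activation mapping adapted to one-dimensional
#' spectra: the class-score gradient (taken at the pre-sigmoid logit for
#' the cancerous class, which avoids saturated-sigmoid vanishing
#' gradients) is averaged over positions of the target convolutional
#' feature maps to give per-filter weights; the rectified weighted sum of
#' the feature maps, interpolated back to the input axis and min-max
#' normalized, is the saliency map.
#'
#' @name interpret
NULL

#' Grad-CAM saliency map for one spectrum
#'
#' The target layer is the model's last convolutional layer (for the
#' residual network, the output of the last residual block).
#'
#' @param model a trained \code{dl_model} (cnn1d or resnet1d).
#' @param spectrum preprocessed intensity vector of the model's input
#'   length.
#' @param shifts optional Raman-shift axis of the same length, attached to
#'   the map.
#' @return a \code{saliency_map}: \code{importance} (per input channel, in
#'   [0, 1] with max 1 unless degenerate), \code{shifts}, \code{degenerate}
#'   (TRUE when the raw map is identically zero; the map is then returned
#'   un-normalized), \code{family}.
#' @export
gradcam_map <- function(model, spectrum, shifts = NULL) {
  stopifnot(inherits(model, "dl_model"))
  if (!model$trained)
    warning("computing Grad-CAM on an untrained model")
  x <- matrix(as.numeric(spectrum), nrow = 1)
  if (ncol(x) != model$input_length)
    stop(sprintf("spectrum length %d does not match model input length %d",
                 ncol(x), model$input_length), call. = FALSE)
  ti <- model$target_conv
  fwd <- nn_forward(model$net, x, training = FALSE)
  bwd <- nn_backward(model$net, fwd, dlogit = 1)
  A <- fwd$outputs[[ti]]       # (1, L', K) feature maps
  dA <- bwd$grad_at_output[[ti]]
  dA <- array(dA, dim(A))
  Lp <- dim(A)[2]; K <- dim(A)[3]
  Amat <- matrix(A[1, , ], Lp, K)
  Gmat <- matrix(dA[1, , ], Lp, K)
  alpha <- colMeans(Gmat)
  raw <- pmax(as.numeric(Amat %*% alpha), 0)
  L <- model$input_length
  if (Lp != L)
    raw <- stats::approx(seq(0, 1, length.out = Lp), raw,
                         xout = seq(0, 1, length.out = L))$y
  mx <- max(raw)
  degenerate <- !is.finite(mx) || mx <= 0
  importance <- if (degenerate) raw else raw / mx
  if (!is.null(shifts) && length(shifts) != L)
    stop("shifts length does not match model input length", call. = FALSE)
  structure(list(importance = importance, shifts = shifts,
                 degenerate = degenerate, family = model$family,
                 target_layer = ti),
            class = "saliency_map")
}

#' Aggregate saliency maps and extract salient bands
#'
#' Averages the maps pointwise, re-normalizes to unit maximum, and returns
#' the contiguous runs whose importance exceeds the threshold as
#' wavenumber intervals with their mean importance.
#'
#' @param maps list of \code{saliency_map} sharing a grid.
#' @param threshold fraction of the maximum (default 0.5).
#' @return a \code{band_set}: \code{bands} data.frame (lo, hi, mean
#'   importance, in grid units), \code{mean_map} (the normalized aggregate
#'   \code{saliency_map}), \code{threshold}.
#' @export
aggregate_saliency <- function(maps, threshold = 0.5) {
  if (length(maps) == 0L) stop("no saliency maps supplied", call. = FALSE)
  stopifnot(all(vapply(maps, inherits, logical(1), "saliency_map")))
  n <- length(maps[[1]]$importance)
  shifts <- maps[[1]]$shifts
  for (m in maps) {
    if (length(m$importance) != n)
      stop("saliency maps have mismatched lengths", call. = FALSE)
    if (!is.null(shifts) && !is.null(m$shifts) &&
        max(abs(m$shifts - shifts)) > 1e-9)
      stop("saliency maps are on different grids", call. = FALSE)
  }
  mean_imp <- Reduce(`+`, lapply(maps, `[[`, "importance")) / length(maps)
  mx <- max(mean_imp)
  degenerate <- !is.finite(mx) || mx <= 0
  if (!degenerate) mean_imp <- mean_imp / mx
  axis <- if (!is.null(shifts)) shifts else seq_len(n)
  above <- mean_imp > threshold
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  bands <- do.call(rbind, lapply(keep, function(i) {
    idx <- starts[i]:ends[i]
    data.frame(lo = axis[starts[i]], hi = axis[ends[i]],
               mean_importance = mean(mean_imp[idx]), n_points = length(idx))
  }))
  if (is.null(bands))
    bands <- data.frame(lo = numeric(0), hi = numeric(0),
                        mean_importance = numeric(0), n_points = integer(0))
  mean_map <- structure(list(importance = mean_imp, shifts = shifts,
                             degenerate = degenerate, family = "aggregate",
                             target_layer = NA),
                        class = "saliency_map")
  structure(list(bands = bands, mean_map = mean_map, threshold = threshold),
            class = "band_set")
}
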