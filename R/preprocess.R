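#' Spectral preprocessing operators
#'
#' Per-spectrum operators used by the classification pipelines: SNIP
#' baseline correction, L2 and SNV normalization, median filtering and
#' Savitzky-Golay / Gaussian smoothing. All length-preserving operators use
#' reflect padding (mirror about the edge without repeating the edge
#' sample).
#'
#' @name preprocess
NULL

# reflect-pad a vector by r samples on each side (no edge repetition)
.reflect_pad <- function(x, r) {
  n <- length(x)
  if (r >= n) stop("padding exceeds signal length", call. = FALSE)
  if (r == 0L) return(x)
  c(x[(r + 1L):2L], x, x[(n - 1L):(n - r)])
}

#' SNIP baseline estimation and subtraction
#'
#' Statistics-sensitive nonlinear iterative peak clipping: the working
#' signal is clipped iteratively with window
#' \eqn{v_i \leftarrow \min(v_i, (v_{i-m}+v_{i+m})/2)} for half-windows
#' m = 1..iterations (increasing by default). Clipping is applied only
#' where the full window fits inside the signal, which leaves smooth
#' backgrounds (e.g. a linear ramp) invariant instead of eroding them in
#' from the edges.
#'
#' By default clipping operates directly on intensities. The LLS
#' compression \eqn{v = \ln(\ln(\sqrt{y+1}+1)+1)} (useful for
#' photon-counting spectra with very large dynamic range) is available via
#' \code{lls = TRUE}; on the moderate-dynamic-range autofluorescence
#' backgrounds this package targets it systematically underestimates the
#' baseline, so it is off by default.
#'
#' @param spectrum numeric intensity vector (non-negative; if negative
#'   values are present the signal is shifted for the working transform and
#'   the shift is undone on the baseline).
#' @param iterations number of clipping passes, i.e. the maximal half-window
#'   in samples (default 80).
#' @param lls apply the LLS compression before clipping (default FALSE).
#' @param decreasing run the half-window schedule from \code{iterations}
#'   down to 1 instead of 1 up to \code{iterations} (default FALSE).
#' @return list with elements \code{corrected} (spectrum minus baseline) and
#'   \code{baseline}; the baseline never exceeds the spectrum (within 1e-9).
#' @export
snip_baseline <- function(spectrum, iterations = 80L, lls = FALSE,
                          decreasing = FALSE) {
  if (length(spectrum) == 0L) stop("empty spectrum", call. = FALSE)
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1L)
    stop("iterations must be >= 1", call. = FALSE)
  offset <- min(spectrum, 0)
  y <- spectrum - offset
  v <- if (lls) log(log(sqrt(y + 1) + 1) + 1) else y
  n <- length(v)
  ms <- if (decreasing) rev(seq_len(iterations)) else seq_len(iterations)
  for (m in ms) {
    if (2L * m >= n) next  # window does not fit anywhere
    i <- (m + 1L):(n - m)
    w <- v
    w[i] <- pmin(v[i], (v[i - m] + v[i + m]) / 2)
    v <- w
  }
  baseline <- (if (lls) (exp(exp(v) - 1) - 1)^2 - 1 else v) + offset
  list(corrected = spectrum - baseline, baseline = baseline)
}

#' Euclidean (L2) normalization
#'
#' Divides a spectrum by its Euclidean norm
#' \eqn{\|x\|_2 = \sqrt{x_1^2 + \dots + x_n^2}}.
#'
#' @param spectrum numeric vector with non-zero norm.
#' @return unit-norm vector.
#' @export
l2_normalize <- function(spectrum) {
  nrm <- sqrt(sum(spectrum^2))
  if (!is.finite(nrm) || nrm == 0)
    stop("cannot L2-normalize a zero-norm spectrum", call. = FALSE)
  spectrum / nrm
}

#' Standard normal variate (SNV) normalization
#'
#' Centers each spectrum and scales it to unit population standard
#' deviation (divide-by-n).
#'
#' @param spectrum numeric vector with positive variance.
#' @return vector with mean 0 and population sd 1.
#' @export
snv_normalize <- function(spectrum) {
  mu <- mean(spectrum)
  sdev <- sqrt(mean((spectrum - mu)^2))
  if (!is.finite(sdev) || sdev == 0)
    stop("cannot SNV-normalize a zero-variance (constant) spectrum",
         call. = FALSE)
  (spectrum - mu) / sdev
}

#' Sliding-window median filter
#'
#' @param spectrum numeric vector.
#' @param window odd window size >= 3 and <= length (default 5).
#' @return filtered vector of the same length (reflect padding).
#' @export
median_filter <- function(spectrum, window = 5L) {
  window <- as.integer(window)
  if (is.na(window) || window %% 2L == 0L || window < 3L)
    stop("median filter window must be an odd integer >= 3", call. = FALSE)
  if (window > length(spectrum))
    stop("median filter window exceeds spectrum length", call. = FALSE)
  r <- (window - 1L) %/% 2L
  padded <- .reflect_pad(spectrum, r)
  out <- stats::runmed(padded, k = window, endrule = "keep")
  out[(r + 1L):(r + length(spectrum))]
}

#' Savitzky-Golay or Gaussian smoothing
#'
#' Savitzky-Golay: local least-squares polynomial smoothing
#' (\code{signal::sgolay} coefficients). Gaussian: convolution with a
#' normalized discrete Gaussian kernel truncated at 4 sigma. Both use
#' reflect padding and preserve length.
#'
#' @param spectrum numeric vector.
#' @param method \code{"savgol"} or \code{"gaussian"}.
#' @param window odd Savitzky-Golay window (default 11).
#' @param polyorder Savitzky-Golay polynomial order (default 3, must be <
#'   window).
#' @param sigma Gaussian kernel sd in samples (default 2).
#' @return smoothed vector.
#' @export
smooth_spectrum <- function(spectrum, method = c("savgol", "gaussian"),
                            window = 11L, polyorder = 3L, sigma = 2) {
  method <- match.arg(method)
  if (method == "savgol") {
    window <- as.integer(window)
    if (window %% 2L == 0L || window < 3L)
      stop("Savitzky-Golay window must be an odd integer >= 3", call. = FALSE)
    if (polyorder >= window)
      stop("Savitzky-Golay polyorder must be smaller than the window",
           call. = FALSE)
    r <- (window - 1L) %/% 2L
    coef <- signal::sgolay(p = polyorder, n = window, m = 0)
    kern <- as.numeric(coef[r + 1L, ])  # central (steady-state) filter row
    padded <- .reflect_pad(spectrum, r)
    out <- stats::filter(padded, rev(kern), method = "convolution", sides = 2)
    as.numeric(out[(r + 1L):(r + length(spectrum))])
  } else {
    if (sigma <= 0) stop("gaussian sigma must be positive", call. = FALSE)
    r <- max(1L, as.integer(ceiling(4 * sigma)))
    kern <- exp(-((-r:r)^2) / (2 * sigma^2))
    kern <- kern / sum(kern)
    padded <- .reflect_pad(spectrum, r)
    out <- stats::filter(padded, rev(kern), method = "convolution", sides = 2)
    as.numeric(out[(r + 1L):(r + length(spectrum))])
  }
}
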