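#' Principal-component dimensionality reduction
#'
#' Mean-centered PCA via a deterministic (full) singular value
#' decomposition; no randomized solver, so results are seed-free.
#'
#' @name dimreduce
NULL

#' Fit a PCA projection
#'
#' @param matrix numeric matrix, spectra in rows, features (grid points or
#'   stage outputs) in columns.
#' @param n_components number of components, at most
#'   \code{min(nrow, ncol)}.
#' @return an object of class \code{pca_state}: \code{mean} (feature means),
#'   \code{components} (\code{n_components x n_features}, orthonormal rows,
#'   ordered by decreasing variance), \code{explained_variance_ratio} and
#'   \code{n_components}.
#' @export
fit_pca <- function(matrix, n_components) {
  matrix <- as.matrix(matrix)
  n <- nrow(matrix); p <- ncol(matrix)
  n_components <- as.integer(n_components)
  if (is.na(n_components) || n_components < 1L ||
      n_components > min(n, p))
    stop(sprintf("n_components must be in [1, min(n, p)] = [1, %d]",
                 min(n, p)), call. = FALSE)
  mu <- colMeans(matrix)
  xc <- sweep(matrix, 2L, mu, "-")
  sv <- svd(xc, nu = 0, nv = n_components)
  var_all <- sv$d^2 / max(1L, n - 1L)
  total <- sum(var_all)
  ratios <- if (total > 0) var_all[seq_len(n_components)] / total
            else rep(0, n_components)
  structure(list(mean = mu,
                 components = t(sv$v),
                 explained_variance_ratio = ratios,
                 n_components = n_components),
            class = "pca_state")
}

#' Project data onto fitted principal components
#'
#' @param state a \code{pca_state}.
#' @param matrix numeric matrix with the same number of features the state
#'   was fitted on.
#' @return score matrix (\code{nrow(matrix) x n_components}).
#' @export
transform_pca <- function(state, matrix) {
  stopifnot(inherits(state, "pca_state"))
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != length(state$mean))
    stop(sprintf("feature count mismatch: state fitted on %d features, data has %d",
                 length(state$mean), ncol(matrix)), call. = FALSE)
  sweep(matrix, 2L, state$mean, "-") %*% t(state$components)
}

#' Cumulative explained-variance table
#'
#' @param matrix data matrix (spectra x features).
#' @param component_counts component counts to report (default
#'   \code{c(10, 20, 30, 40)}).
#' @return data.frame with columns \code{n_components},
#'   \code{cumulative_pct} (rounded to 1 decimal) and
#'   \code{cumulative_pct_raw}; non-decreasing down the table.
#' @export
variance_table <- function(matrix, component_counts = c(10L, 20L, 30L, 40L)) {
  component_counts <- as.integer(component_counts)
  kmax <- max(component_counts)
  st <- fit_pca(matrix, kmax)
  cum <- cumsum(st$explained_variance_ratio) * 100
  raw <- cum[component_counts]
  data.frame(n_components = component_counts,
             cumulative_pct = round(raw, 1),
             cumulative_pct_raw = raw)
}
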