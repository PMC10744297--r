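#' Spectral axis and wavenumber-region utilities
#'
#' A spectral grid is a strictly increasing numeric vector of Raman shifts
#' (cm^-1). Region selection works on closed intervals with a small absolute
#' endpoint tolerance so that on-grid endpoints survive floating-point
#' construction of the axis.
#'
#' @name spectral-grid
NULL

# absolute tolerance (cm^-1) for closed-interval endpoint comparisons
.REGION_EPS <- 1e-6

#' Validate a spectral grid
#'
#' @param shifts numeric vector of Raman shifts in cm^-1.
#' @return the validated grid, invisibly usable as-is.
#' @export
validate_grid <- function(shifts) {
  if (!is.numeric(shifts) || length(shifts) < 2L)
    stop("spectral grid must be a numeric vector of length >= 2", call. = FALSE)
  if (anyNA(shifts))
    stop("spectral grid contains NA values", call. = FALSE)
  if (any(shifts < 0) || any(shifts >= 10000))
    stop("spectral grid values must lie in [0, 10000) cm^-1", call. = FALSE)
  if (any(diff(shifts) <= 0))
    stop("spectral grid must be strictly increasing (non-monotone axis)",
         call. = FALSE)
  shifts
}

#' Default Raman-shift axis covering 500-3200 cm^-1
#'
#' Piecewise-uniform axis with two segments: a fingerprint-side segment
#' starting at 500 cm^-1 with spacing 1100/1210 cm^-1 (2530 points, ending
#' just below 2800) and a denser CH-stretch-side segment starting at
#' 2800 cm^-1 with spacing 300/476 cm^-1 (635 points, ending near
#' 3199.6 cm^-1). The spacings are chosen so that the standard fingerprint
#' (700-1800 cm^-1) and high-wavenumber (2800-3100 cm^-1) selections contain
#' 1211 and 477 points respectively, matching the dimensionalities of the
#' acquisition axis this package emulates. Total length is 3165 points.
#'
#' @return numeric vector of 3165 strictly increasing Raman shifts (cm^-1).
#' @examples
#' g <- build_default_grid()
#' length(g)
#' sum(g >= 700 & g <= 1800 + 1e-6)
#' @export
build_default_grid <- function() {
  seg_a <- 500 + (0:2529) * (1100 / 1210)
  seg_b <- 2800 + (0:634) * (300 / 476)
  validate_grid(c(seg_a, seg_b))
}

#' Named wavenumber region specifications
#'
#' Standard regions: \code{low} (fingerprint, 700-1800 cm^-1), \code{high}
#' (CH stretch, 2800-3100 cm^-1), \code{low_plus_high} (their union) and
#' \code{full} (the entire grid).
#'
#' @param name one of \code{"low"}, \code{"high"}, \code{"low_plus_high"},
#'   \code{"full"}.
#' @return an object of class \code{region_spec} with fields \code{name} and
#'   \code{intervals} (a list of \code{c(lo, hi)} pairs; empty for
#'   \code{full}).
#' @export
region_spec <- function(name = c("low", "high", "low_plus_high", "full")) {
  name <- match.arg(name)
  intervals <- switch(name,
    low           = list(c(700, 1800)),
    high          = list(c(2800, 3100)),
    low_plus_high = list(c(700, 1800), c(2800, 3100)),
    full          = list()
  )
  structure(list(name = name, intervals = intervals), class = "region_spec")
}

#' Indices of grid points falling inside a region
#'
#' @param shifts spectral grid.
#' @param region a \code{region_spec} or a region name.
#' @return integer indices, in increasing order.
#' @export
region_indices <- function(shifts, region) {
  if (is.character(region)) region <- region_spec(region)
  stopifnot(inherits(region, "region_spec"))
  if (region$name == "full" || length(region$intervals) == 0L)
    return(seq_along(shifts))
  keep <- rep(FALSE, length(shifts))
  for (iv in region$intervals) {
    if (iv[1] >= iv[2]) stop("region interval must have lo < hi", call. = FALSE)
    hit <- shifts >= iv[1] - .REGION_EPS & shifts <= iv[2] + .REGION_EPS
    if (!any(hit))
      stop(sprintf("region interval [%g, %g] selects no grid points",
                   iv[1], iv[2]), call. = FALSE)
    keep <- keep | hit
  }
  which(keep)
}

#' Restrict a cohort to a wavenumber region
#'
#' Keeps exactly the grid columns inside any of the region's closed intervals
#' (endpoint tolerance 1e-6 cm^-1); column order and all per-spectrum
#' metadata are preserved.
#'
#' @param cohort a \code{raman_cohort}.
#' @param region a \code{region_spec} or region name.
#' @return a new \code{raman_cohort} on the restricted grid.
#' @export
select_region <- function(cohort, region) {
  stopifnot(inherits(cohort, "raman_cohort"))
  if (is.character(region)) region <- region_spec(region)
  idx <- region_indices(cohort$shifts, region)
  out <- cohort
  out$shifts <- cohort$shifts[idx]
  out$intensities <- cohort$intensities[, idx, drop = FALSE]
  out$provenance <- c(cohort$provenance,
                      sprintf("region=%s (%d points)", region$name, length(idx)))
  out
}
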