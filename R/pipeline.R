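#' Preprocessing pipeline specification and execution
#'
#' A pipeline is an ordered list of stages applied per spectrum on the full
#' grid, a wavenumber region selection applied at a configurable position,
#' and optionally a final PCA projection (fitted on training data and reused
#' on held-out data).
#'
#' @name pipeline
NULL

.STAGE_KINDS <- c("snip_baseline", "l2_normalize", "snv_normalize",
                  "median_filter", "savgol_smooth", "gaussian_smooth", "pca")

#' Pipeline stage specification
#'
#' @param kind one of \code{snip_baseline}, \code{l2_normalize},
#'   \code{snv_normalize}, \code{median_filter}, \code{savgol_smooth},
#'   \code{gaussian_smooth}, \code{pca}.
#' @param ... stage parameters: \code{iterations} (snip, default 80),
#'   \code{window} (median default 5; savgol default 11), \code{polyorder}
#'   (savgol, default 3), \code{sigma} (gaussian, default 2),
#'   \code{n_components} (pca, default 30).
#' @return a \code{stage_spec} list.
#' @export
stage_spec <- function(kind, ...) {
  if (!kind %in% .STAGE_KINDS)
    stop(sprintf("unknown stage kind '%s'", kind), call. = FALSE)
  params <- list(...)
  defaults <- switch(kind,
    snip_baseline   = list(iterations = 80L),
    median_filter   = list(window = 5L),
    savgol_smooth   = list(window = 11L, polyorder = 3L),
    gaussian_smooth = list(sigma = 2),
    pca             = list(n_components = 30L),
    list())
  params <- utils::modifyList(defaults, params)
  if (kind == "snip_baseline" && params$iterations < 1L)
    stop("snip_baseline iterations must be >= 1", call. = FALSE)
  if (kind == "median_filter" &&
      (params$window < 3L || params$window %% 2L == 0L))
    stop("median_filter window must be odd and >= 3", call. = FALSE)
  if (kind == "savgol_smooth" &&
      (params$window %% 2L == 0L || params$polyorder >= params$window))
    stop("savgol_smooth needs odd window and polyorder < window",
         call. = FALSE)
  if (kind == "gaussian_smooth" && params$sigma <= 0)
    stop("gaussian_smooth sigma must be > 0", call. = FALSE)
  if (kind == "pca" && params$n_components < 1L)
    stop("pca n_components must be >= 1", call. = FALSE)
  structure(list(kind = kind, params = params), class = "stage_spec")
}

#' Pipeline specification
#'
#' @param name pipeline label.
#' @param stages ordered list of \code{stage_spec}; at most one \code{pca}
#'   stage, and it must be last.
#' @param region \code{region_spec} or region name; applied at
#'   \code{region_position}.
#' @param region_position number of per-spectrum stages executed before
#'   region selection (default: all non-PCA stages, i.e. spectral operators
#'   run on the full grid, then the region is cut, then PCA if present).
#' @return a \code{pipeline_spec} object.
#' @export
pipeline_spec <- function(name, stages, region = "full",
                          region_position = NULL) {
  if (is.character(region)) region <- region_spec(region)
  stopifnot(all(vapply(stages, inherits, logical(1), "stage_spec")))
  kinds <- vapply(stages, `[[`, character(1), "kind")
  n_pca <- sum(kinds == "pca")
  if (n_pca > 1L) stop("at most one pca stage is allowed", call. = FALSE)
  if (n_pca == 1L && kinds[length(kinds)] != "pca")
    stop("the pca stage must be last", call. = FALSE)
  n_spectral <- length(kinds) - n_pca
  if (is.null(region_position)) region_position <- n_spectral
  if (region_position < 0L || region_position > n_spectral)
    stop("region_position outside stage list bounds", call. = FALSE)
  structure(list(name = name, stages = stages, region = region,
                 region_position = as.integer(region_position)),
            class = "pipeline_spec")
}

#' Named pipeline presets
#'
#' \describe{
#'   \item{paper_ml}{SNIP(80), L2, median(5) on the full grid, then
#'     low+high region, then PCA(30) — the machine-learning input pipeline.}
#'   \item{paper_dl}{SNIP(80), L2, then low+high region — the deep-learning
#'     input pipeline (no median filter, no PCA).}
#'   \item{pipeline_a}{Savitzky-Golay(11,3), SNIP(80), SNV, region, PCA(30).}
#'   \item{pipeline_b}{Gaussian(sigma 2), SNIP(80), SNV, region, PCA(30).}
#'   \item{pipeline_c}{SNIP(80), SNV, Savitzky-Golay(11,3), region, no PCA.}
#' }
#'
#' @param name preset name.
#' @param region region for presets (default \code{"low_plus_high"}).
#' @return a \code{pipeline_spec}.
#' @export
pipeline_preset <- function(name = c("paper_ml", "paper_dl", "pipeline_a",
                                     "pipeline_b", "pipeline_c"),
                            region = "low_plus_high") {
  name <- match.arg(name)
  s <- stage_spec
  stages <- switch(name,
    paper_ml   = list(s("snip_baseline"), s("l2_normalize"),
                      s("median_filter"), s("pca", n_components = 30L)),
    paper_dl   = list(s("snip_baseline"), s("l2_normalize")),
    pipeline_a = list(s("savgol_smooth"), s("snip_baseline"),
                      s("snv_normalize"), s("pca", n_components = 30L)),
    pipeline_b = list(s("gaussian_smooth"), s("snip_baseline"),
                      s("snv_normalize"), s("pca", n_components = 30L)),
    pipeline_c = list(s("snip_baseline"), s("snv_normalize"),
                      s("savgol_smooth")))
  pipeline_spec(name, stages, region = region)
}

# apply one per-spectrum stage to all rows of a matrix
.apply_stage_matrix <- function(mat, stage) {
  f <- switch(stage$kind,
    snip_baseline = function(x)
      snip_baseline(x, stage$params$iterations)$corrected,
    l2_normalize  = l2_normalize,
    snv_normalize = snv_normalize,
    median_filter = function(x) median_filter(x, stage$params$window),
    savgol_smooth = function(x)
      smooth_spectrum(x, "savgol", window = stage$params$window,
                      polyorder = stage$params$polyorder),
    gaussian_smooth = function(x)
      smooth_spectrum(x, "gaussian", sigma = stage$params$sigma),
    stop(sprintf("stage '%s' is not a per-spectrum stage", stage$kind),
         call. = FALSE))
  if (nrow(mat) == 0L) return(mat)
  t(apply(mat, 1L, f))
}

#' Run the per-spectrum and region stages of a pipeline
#'
#' Internal workhorse shared by \code{apply_pipeline} and the
#' cross-validation driver: everything except PCA, which is fit-dependent.
#'
#' @param cohort a \code{raman_cohort}.
#' @param spec a \code{pipeline_spec}.
#' @return a \code{raman_cohort} on the region grid.
#' @keywords internal
apply_spectral_stages <- function(cohort, spec) {
  kinds <- vapply(spec$stages, `[[`, character(1), "kind")
  spectral <- spec$stages[kinds != "pca"]
  mat <- cohort$intensities
  shifts <- cohort$shifts
  pos <- spec$region_position
  region_applied <- FALSE
  cut_region <- function() {
    idx <- region_indices(shifts, spec$region)
    mat <<- mat[, idx, drop = FALSE]
    shifts <<- shifts[idx]
    region_applied <<- TRUE
  }
  i <- 0L
  for (st in spectral) {
    if (i == pos && !region_applied) cut_region()
    mat <- .apply_stage_matrix(mat, st)
    i <- i + 1L
  }
  if (!region_applied) cut_region()
  out <- cohort
  out$shifts <- shifts
  out$intensities <- mat
  out$provenance <- c(cohort$provenance, sprintf("pipeline=%s", spec$name))
  if (ncol(out$intensities) != length(out$shifts))
    stop("internal error: stage/region bookkeeping mismatch", call. = FALSE)
  out
}

#' Apply a preprocessing pipeline
#'
#' Runs the per-spectrum stages in order on the full grid, cuts the
#' wavenumber region at \code{region_position}, and — if the pipeline ends
#' in PCA — either fits the projection (when \code{fitted_state} is NULL)
#' or reuses a previously fitted one, so held-out data are transformed
#' without leakage.
#'
#' @param cohort a \code{raman_cohort}.
#' @param spec a \code{pipeline_spec} (or preset name).
#' @param fitted_state optional state returned by a previous fit call.
#' @return list with \code{data} (a \code{raman_cohort} when no PCA stage is
#'   present, otherwise a score matrix with rownames = spectrum ids),
#'   \code{meta} (per-spectrum metadata), and \code{state} (reusable fitted
#'   state; NULL-free for stateless pipelines).
#' @export
apply_pipeline <- function(cohort, spec, fitted_state = NULL) {
  if (is.character(spec)) spec <- pipeline_preset(spec)
  stopifnot(inherits(spec, "pipeline_spec"))
  kinds <- vapply(spec$stages, `[[`, character(1), "kind")
  pca_stage <- if (any(kinds == "pca")) spec$stages[[which(kinds == "pca")]]
               else NULL
  region_cohort <- apply_spectral_stages(cohort, spec)
  if (is.null(pca_stage)) {
    return(list(data = region_cohort, meta = region_cohort$meta,
                state = list(pipeline = spec$name, pca = NULL)))
  }
  if (is.null(fitted_state) || is.null(fitted_state$pca)) {
    pca <- fit_pca(region_cohort$intensities, pca_stage$params$n_components)
    pca$region <- spec$region$name
  } else {
    pca <- fitted_state$pca
    if (length(pca$mean) != ncol(region_cohort$intensities))
      stop("fitted state grid/region mismatch with transformed cohort",
           call. = FALSE)
  }
  scores <- transform_pca(pca, region_cohort$intensities)
  rownames(scores) <- region_cohort$meta$spectrum_id
  list(data = scores, meta = region_cohort$meta,
       state = list(pipeline = spec$name, pca = pca))
}
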