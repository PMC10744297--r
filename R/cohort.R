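#' Patient-structured spectral cohorts
#'
#' A cohort bundles a spectra matrix (rows = spectra, columns = grid points)
#' with per-spectrum metadata: spectrum id, patient id and a binary tissue
#' label (0 = healthy, 1 = cancerous).
#'
#' @name raman-cohort
NULL

#' Construct and validate a cohort
#'
#' @param shifts spectral grid (strictly increasing Raman shifts, cm^-1).
#' @param intensities numeric matrix, one row per spectrum, columns aligned
#'   to \code{shifts}. Raw acquisitions are non-negative; preprocessed
#'   intensities may be negative (e.g. after baseline subtraction).
#' @param meta data.frame with columns \code{spectrum_id}, \code{patient_id},
#'   \code{label} (integer 0 = healthy, 1 = cancerous).
#' @param provenance character vector of free-text provenance notes
#'   (generator settings, seed, applied stages).
#' @return an object of class \code{raman_cohort}.
#' @export
raman_cohort <- function(shifts, intensities, meta, provenance = character()) {
  validate_grid(shifts)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (ncol(intensities) != length(shifts))
    stop(sprintf("intensity matrix has %d columns but grid has %d points",
                 ncol(intensities), length(shifts)), call. = FALSE)
  req <- c("spectrum_id", "patient_id", "label")
  if (!all(req %in% names(meta)))
    stop("metadata must contain columns spectrum_id, patient_id, label",
         call. = FALSE)
  meta <- data.frame(spectrum_id = as.character(meta$spectrum_id),
                     patient_id = as.character(meta$patient_id),
                     label = as.integer(meta$label),
                     stringsAsFactors = FALSE)
  if (nrow(meta) != nrow(intensities))
    stop(sprintf("metadata has %d rows but intensity matrix has %d",
                 nrow(meta), nrow(intensities)), call. = FALSE)
  if (anyDuplicated(meta$spectrum_id))
    stop(sprintf("duplicate spectrum_id: %s",
                 meta$spectrum_id[duplicated(meta$spectrum_id)][1]),
         call. = FALSE)
  bad <- !(meta$label %in% c(0L, 1L)) | is.na(meta$label)
  if (any(bad))
    stop(sprintf("unknown label for spectrum '%s' (labels must be 0 or 1)",
                 meta$spectrum_id[bad][1]), call. = FALSE)
  rownames(intensities) <- meta$spectrum_id
  structure(list(shifts = as.numeric(shifts), intensities = intensities,
                 meta = meta, provenance = as.character(provenance)),
            class = "raman_cohort")
}

#' @export
#' @method print raman_cohort
print.raman_cohort <- function(x, ...) {
  cat(sprintf(
    "raman_cohort: %d spectra x %d grid points [%.1f-%.1f cm^-1]\n",
    nrow(x$intensities), length(x$shifts), min(x$shifts), max(x$shifts)))
  cat(sprintf("  patients: %d | labels: %d healthy / %d cancerous\n",
              length(unique(x$meta$patient_id)),
              sum(x$meta$label == 0L), sum(x$meta$label == 1L)))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = "; "), "\n")
  invisible(x)
}

#' @export
dim.raman_cohort <- function(x) dim(x$intensities)

#' Read a cohort from a spectra matrix and a JSON manifest
#'
#' The spectra file is CSV (or TSV) whose header row holds the Raman shifts,
#' whose first column holds spectrum ids, and whose remaining cells hold
#' intensities. The manifest is a JSON array of objects with fields
#' \code{spectrum_id}, \code{patient_id} and \code{label}.
#'
#' @param spectra_path path to the spectra CSV/TSV.
#' @param manifest_path path to the manifest JSON.
#' @param sep field separator of the spectra file (\code{","} or tab).
#' @return a validated \code{raman_cohort}.
#' @export
read_cohort <- function(spectra_path, manifest_path, sep = ",") {
  header_line <- readLines(spectra_path, n = 1L)
  if (length(header_line) == 0L) stop("spectra file is empty", call. = FALSE)
  header_cells <- strsplit(header_line, sep, fixed = TRUE)[[1]][-1]
  header <- suppressWarnings(as.numeric(header_cells))
  if (anyNA(header))
    stop("spectra header row contains non-numeric Raman shifts", call. = FALSE)
  if (length(header) >= 2 && any(diff(header) <= 0))
    stop("non-monotone grid: spectra header shifts must be strictly increasing",
         call. = FALSE)
  n_lines <- length(readLines(spectra_path))
  body <- if (n_lines <= 1L) {
    data.frame(spectrum_id = character())
  } else {
    utils::read.table(spectra_path, header = FALSE, sep = sep, skip = 1L,
                      colClasses = c("character",
                                     rep("numeric", length(header))),
                      stringsAsFactors = FALSE, check.names = FALSE)
  }
  ids <- if (nrow(body)) as.character(body[[1]]) else character()
  mat <- if (nrow(body) == 0L) {
    matrix(numeric(0), nrow = 0, ncol = length(header))
  } else {
    as.matrix(body[, -1, drop = FALSE])
  }
  dimnames(mat) <- NULL
  manifest <- jsonlite::fromJSON(manifest_path, simplifyDataFrame = TRUE)
  if (length(manifest) == 0L)
    manifest <- data.frame(spectrum_id = character(), patient_id = character(),
                           label = integer())
  missing_in_manifest <- setdiff(ids, manifest$spectrum_id)
  if (length(missing_in_manifest))
    stop(sprintf("spectrum_id '%s' present in spectra file but missing from manifest",
                 missing_in_manifest[1]), call. = FALSE)
  missing_in_matrix <- setdiff(manifest$spectrum_id, ids)
  if (length(missing_in_matrix))
    stop(sprintf("spectrum_id '%s' present in manifest but missing from spectra file",
                 missing_in_matrix[1]), call. = FALSE)
  meta <- manifest[match(ids, manifest$spectrum_id), , drop = FALSE]
  raman_cohort(header, mat, meta,
               provenance = sprintf("read from %s", spectra_path))
}

#' Write a cohort to a spectra CSV and a JSON manifest
#'
#' Numeric values are written with 15 significant digits so a
#' read/write/read round trip preserves intensities to at least 12
#' significant digits.
#'
#' @param cohort a \code{raman_cohort}.
#' @param spectra_path output path for the spectra CSV.
#' @param manifest_path output path for the manifest JSON.
#' @return invisibly, the cohort.
#' @export
write_cohort <- function(cohort, spectra_path, manifest_path) {
  stopifnot(inherits(cohort, "raman_cohort"))
  fmt <- function(x) formatC(x, digits = 15, format = "g")
  con <- file(spectra_path, open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines(paste(c("spectrum_id", fmt(cohort$shifts)), collapse = ","), con)
  n <- nrow(cohort$intensities)
  if (n > 0) {
    rows <- vapply(seq_len(n), function(i) {
      paste(c(cohort$meta$spectrum_id[i], fmt(cohort$intensities[i, ])),
            collapse = ",")
    }, character(1))
    writeLines(rows, con)
  }
  jsonlite::write_json(cohort$meta, manifest_path, dataframe = "rows",
                       auto_unbox = FALSE, digits = NA)
  invisible(cohort)
}
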