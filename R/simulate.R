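#' Synthetic patient-structured Raman cohorts
#'
#' The simulator emulates an ex-vivo tissue study: a fixed library of
#' Lorentzian Raman bands whose amplitudes differ between healthy and
#' cancerous tissue, a smooth autofluorescence background, per-spectrum
#' multiplicative gain, additive Gaussian noise, sparse impulse artifacts
#' (cosmic-ray-like spikes) and per-patient random effects on biochemical
#' band groups (protein / lipid / collagen).
#'
#' @name synthetic-cohort
NULL

#' Band (peak) specification
#'
#' @param center band center in cm^-1 (must lie inside the grid span when
#'   used).
#' @param fwhm full width at half maximum in cm^-1, in (0, 200].
#' @param amp_healthy,amp_cancer non-negative peak amplitudes per class.
#' @param group biochemical group the band belongs to (drives patient-level
#'   random effects): \code{"protein"}, \code{"lipid"}, \code{"collagen"} or
#'   \code{"other"}.
#' @return a \code{peak_spec} list.
#' @export
peak_spec <- function(center, fwhm, amp_healthy, amp_cancer,
                      group = c("protein", "lipid", "collagen", "other")) {
  group <- match.arg(group)
  if (!is.numeric(fwhm) || fwhm <= 0 || fwhm > 200)
    stop("peak fwhm must be in (0, 200] cm^-1", call. = FALSE)
  if (amp_healthy < 0 || amp_cancer < 0)
    stop("peak amplitudes must be non-negative", call. = FALSE)
  structure(list(center = center, fwhm = fwhm, amp_healthy = amp_healthy,
                 amp_cancer = amp_cancer, group = group),
            class = "peak_spec")
}

#' Default band library
#'
#' Ten class-differential bands (six fingerprint, four CH-stretch) plus four
#' weaker secondary bands at known protein/collagen/lipid positions. Protein
#' and collagen bands are up-modulated in the cancerous class (amplitude
#' ratios 1.3 and 1.2) while lipid bands are down-modulated (ratio 0.7),
#' encoding the higher lipid-to-protein ratio of normal tissue. Fingerprint
#' bands default to 15 cm^-1 FWHM, CH-stretch bands to 40 cm^-1.
#'
#' @return list of \code{peak_spec}.
#' @export
default_peak_library <- function() {
  ratio <- function(g) switch(g, protein = 1.3, collagen = 1.2, lipid = 0.7,
                              other = 1.0)
  main <- list(
    c(866,  "collagen"), c(1005, "protein"), c(1342, "protein"),
    c(1437, "lipid"),    c(1671, "protein"), c(1748, "lipid"),
    c(2852, "lipid"),    c(2890, "lipid"),   c(2935, "protein"),
    c(2974, "protein"))
  secondary <- list(
    c(1250, "collagen"), c(1330, "protein"), c(1450, "lipid"),
    c(1658, "protein"))
  build <- function(entries, amp) {
    lapply(entries, function(e) {
      ctr <- as.numeric(e[1]); grp <- e[2]
      peak_spec(center = ctr, fwhm = if (ctr >= 2800) 40 else 15,
                amp_healthy = amp, amp_cancer = amp * ratio(grp),
                group = grp)
    })
  }
  c(build(main, amp = 1.0), build(secondary, amp = 0.25))
}

#' Simulator configuration
#'
#' Defaults reproduce the cohort shape of the emulated study: 22 patients,
#' 10 healthy and 10 cancerous spectra per patient, plus one extra pair
#' assigned to the first patient, for 221 + 221 = 442 spectra in total.
#'
#' @param n_patients number of patients (>= 1).
#' @param spectra_per_patient_per_class spectra per patient and class.
#' @param extra_pairs additional healthy+cancerous spectrum pairs given to
#'   the first patient (the deterministic remainder policy producing 442).
#' @param peaks band library (list of \code{peak_spec}).
#' @param baseline_amplitude autofluorescence scale (0 disables baseline).
#' @param baseline_sd log-sd of the per-spectrum log-normal multiplier on the
#'   autofluorescence scale (tissue spots fluoresce unevenly).
#' @param noise_sd additive Gaussian noise standard deviation (counts).
#' @param gain_sd log-sd of the per-spectrum log-normal multiplicative gain.
#' @param patient_effect_sd log-sd of per-patient log-normal multipliers on
#'   the protein / lipid / collagen band groups.
#' @param spike_prob per-channel probability of an impulse artifact.
#' @param spike_amp impulse amplitude scale (actual amplitudes are uniform
#'   in [0.5, 1.5] times this value).
#' @param seed integer RNG seed; the full cohort is deterministic given the
#'   configuration and seed.
#' @param grid spectral grid to synthesize on (default
#'   \code{build_default_grid()}).
#' @return a validated \code{simulator_config} list.
#' @export
simulator_config <- function(n_patients = 22L,
                             spectra_per_patient_per_class = 10L,
                             extra_pairs = 1L,
                             peaks = default_peak_library(),
                             baseline_amplitude = 5,
                             baseline_sd = 0.3,
                             noise_sd = 0.02,
                             gain_sd = 0.1,
                             patient_effect_sd = 0.15,
                             spike_prob = 5e-4,
                             spike_amp = 3,
                             seed = 1L,
                             grid = build_default_grid()) {
  cfg <- list(n_patients = as.integer(n_patients),
              spectra_per_patient_per_class =
                as.integer(spectra_per_patient_per_class),
              extra_pairs = as.integer(extra_pairs),
              peaks = peaks,
              baseline_amplitude = baseline_amplitude,
              baseline_sd = baseline_sd,
              noise_sd = noise_sd, gain_sd = gain_sd,
              patient_effect_sd = patient_effect_sd,
              spike_prob = spike_prob, spike_amp = spike_amp,
              seed = as.integer(seed), grid = grid)
  bad <- character()
  if (cfg$n_patients < 1L) bad <- c(bad, "n_patients < 1")
  if (cfg$spectra_per_patient_per_class < 1L)
    bad <- c(bad, "spectra_per_patient_per_class < 1")
  if (cfg$extra_pairs < 0L) bad <- c(bad, "extra_pairs < 0")
  for (fld in c("baseline_amplitude", "baseline_sd", "noise_sd", "gain_sd",
                "patient_effect_sd", "spike_amp"))
    if (cfg[[fld]] < 0) bad <- c(bad, paste(fld, "< 0"))
  if (cfg$spike_prob < 0 || cfg$spike_prob > 1)
    bad <- c(bad, "spike_prob outside [0, 1]")
  span <- range(cfg$grid)
  for (p in cfg$peaks) {
    if (!inherits(p, "peak_spec")) bad <- c(bad, "peaks must be peak_spec objects")
    else if (p$center < span[1] || p$center > span[2])
      bad <- c(bad, sprintf("peak center %g outside grid span", p$center))
  }
  if (length(bad))
    stop("invalid simulator config: ", paste(unique(bad), collapse = "; "),
         call. = FALSE)
  structure(cfg, class = "simulator_config")
}

#' Noise-free class spectrum from the band library
#'
#' Sum of Lorentzian lineshapes
#' \eqn{L(\nu) = (\Gamma/2)^2 / ((\nu - c)^2 + (\Gamma/2)^2)} weighted by the
#' class amplitude of each band and by its group's patient-level multiplier.
#'
#' @param grid spectral grid.
#' @param peaks list of \code{peak_spec}.
#' @param label 0 (healthy) or 1 (cancerous).
#' @param patient_multipliers named numeric vector of group multipliers
#'   (names among protein/lipid/collagen/other; missing groups default to 1).
#' @return numeric intensity vector aligned to \code{grid}.
#' @export
synth_clean_spectrum <- function(grid, peaks, label,
                                 patient_multipliers = c(protein = 1,
                                                         lipid = 1,
                                                         collagen = 1)) {
  stopifnot(label %in% c(0L, 1L))
  out <- numeric(length(grid))
  for (p in peaks) {
    amp <- if (label == 1L) p$amp_cancer else p$amp_healthy
    mult <- patient_multipliers[p$group]
    if (is.na(mult)) mult <- 1
    hw2 <- (p$fwhm / 2)^2
    out <- out + amp * mult * hw2 / ((grid - p$center)^2 + hw2)
  }
  out
}

#' Smooth autofluorescence background shape
#'
#' Decaying exponential plus a broad Gaussian hump centered at 1400 cm^-1
#' (sd 600 cm^-1), normalized to unit maximum. Multiplied by
#' \code{baseline_amplitude} by the generator.
#'
#' @param grid spectral grid.
#' @return numeric vector with maximum 1.
#' @export
autofluorescence_shape <- function(grid) {
  b <- exp(-(grid - 500) / 1200) + 0.8 * exp(-(grid - 1400)^2 / (2 * 600^2))
  b / max(b)
}

#' Generate a synthetic cohort
#'
#' Deterministic given the configuration (including its seed). Per spectrum:
#' clean class signal times a log-normal gain, plus autofluorescence scaled
#' by a per-spectrum log-normal factor, plus Gaussian noise, plus sparse
#' impulse spikes; negative values are clipped at 0. The RNG draw order is
#' fixed: patient group multipliers first, then per spectrum (in patient,
#' class, replicate order) gain, baseline factor, noise vector, spike mask
#' and spike amplitudes.
#'
#' @param config a \code{simulator_config}.
#' @return a \code{raman_cohort} with balanced labels per patient.
#' @export
generate_cohort <- function(config = simulator_config()) {
  stopifnot(inherits(config, "simulator_config"))
  grid <- config$grid
  n_pt <- config$n_patients
  per <- config$spectra_per_patient_per_class
  baseline <- config$baseline_amplitude * autofluorescence_shape(grid)
  groups <- c("protein", "lipid", "collagen", "other")

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(config$seed)

  # per-patient log-normal multipliers, one per biochemical group
  pt_mult <- matrix(
    exp(stats::rnorm(n_pt * 3, 0, config$patient_effect_sd)),
    nrow = n_pt, ncol = 3, dimnames = list(NULL, groups[1:3]))
  pt_mult <- cbind(pt_mult, other = rep(1, n_pt))

  n_grid <- length(grid)
  rows <- list(); meta <- list(); k <- 0L
  for (pt in seq_len(n_pt)) {
    mults <- pt_mult[pt, ]
    clean <- list(
      `0` = synth_clean_spectrum(grid, config$peaks, 0L, mults),
      `1` = synth_clean_spectrum(grid, config$peaks, 1L, mults))
    n_rep <- per + if (pt == 1L) config$extra_pairs else 0L
    for (lab in c(0L, 1L)) {
      for (rep_i in seq_len(n_rep)) {
        gain <- exp(stats::rnorm(1, 0, config$gain_sd))
        bscale <- exp(stats::rnorm(1, 0, config$baseline_sd))
        noise <- stats::rnorm(n_grid, 0, config$noise_sd)
        spikes <- numeric(n_grid)
        hit <- stats::runif(n_grid) < config$spike_prob
        if (any(hit))
          spikes[hit] <- config$spike_amp * stats::runif(sum(hit), 0.5, 1.5)
        y <- clean[[as.character(lab)]] * gain + baseline * bscale +
          noise + spikes
        k <- k + 1L
        rows[[k]] <- pmax(y, 0)
        meta[[k]] <- data.frame(
          spectrum_id = sprintf("P%02d_%s_%03d", pt,
                                if (lab == 1L) "C" else "H", rep_i),
          patient_id = sprintf("P%02d", pt), label = lab)
      }
    }
  }
  raman_cohort(grid, do.call(rbind, rows), do.call(rbind, meta),
               provenance = sprintf("synthetic cohort (seed=%d)", config$seed))
}
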