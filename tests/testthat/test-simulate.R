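test_that("default simulator emits the emulated cohort shape", {
  co <- generate_cohort(simulator_config(seed = 7))
  expect_equal(nrow(co$intensities), 442L)
  expect_equal(sum(co$meta$label == 0L), 221L)
  expect_equal(sum(co$meta$label == 1L), 221L)
  expect_equal(length(unique(co$meta$patient_id)), 22L)
  # labels balanced within each patient
  by_pt <- table(co$meta$patient_id, co$meta$label)
  expect_true(all(by_pt[, 1] == by_pt[, 2]))
  expect_true(all(co$intensities >= 0))
})

test_that("cohort generation is deterministic in the seed", {
  cfg <- small_sim_config(seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$intensities, b$intensities)
  expect_identical(a$meta, b$meta)
  c2 <- generate_cohort(small_sim_config(seed = 12))
  expect_false(isTRUE(all.equal(a$intensities, c2$intensities)))
})

test_that("with all stochastic terms off every spectrum equals its clean template", {
  cfg <- small_sim_config(seed = 1, noise_sd = 0, gain_sd = 0,
                          baseline_amplitude = 0, spike_prob = 0,
                          patient_effect_sd = 0)
  co <- generate_cohort(cfg)
  clean0 <- synth_clean_spectrum(cfg$grid, cfg$peaks, 0L)
  clean1 <- synth_clean_spectrum(cfg$grid, cfg$peaks, 1L)
  for (i in seq_len(nrow(co$intensities))) {
    tmpl <- if (co$meta$label[i] == 1L) clean1 else clean0
    expect_equal(unname(co$intensities[i, ]), tmpl, tolerance = 1e-12)
  }
})

test_that("Lorentzian lineshape honours amplitude and FWHM definitions", {
  g <- seq(900, 1100, by = 0.5)
  pk <- peak_spec(1000, fwhm = 20, amp_healthy = 2, amp_cancer = 3,
                  group = "protein")
  s <- synth_clean_spectrum(g, list(pk), 0L, c(protein = 1.5))
  expect_equal(s[g == 1000], 2 * 1.5)               # apex = amp * multiplier
  expect_equal(s[g == 1010], 2 * 1.5 / 2)           # half height at c + fwhm/2
  expect_equal(s[g == 990], 2 * 1.5 / 2)
  s_c <- synth_clean_spectrum(g, list(pk), 1L)
  expect_equal(s_c[g == 1000], 3)
})

test_that("class-difference spectrum peaks at the configured differential bands", {
  g <- build_default_grid()
  lib <- default_peak_library()
  d <- synth_clean_spectrum(g, lib, 1L) - synth_clean_spectrum(g, lib, 0L)
  mains <- c(866, 1005, 1342, 1437, 1671, 1748, 2852, 2890, 2935, 2974)
  for (ctr in mains) {
    win <- which(abs(g - ctr) <= 25)
    argmax <- g[win[which.max(abs(d[win]))]]
    fwhm <- if (ctr >= 2800) 40 else 15
    expect_lt(abs(argmax - ctr), fwhm / 2)
  }
})

test_that("contamination grows monotonically with the noise level", {
  grid <- coarse_grid(8)
  mads <- vapply(c(0, 0.05, 0.2, 1), function(sd) {
    cfg <- simulator_config(n_patients = 6L, spectra_per_patient_per_class = 10L,
                            extra_pairs = 0L, grid = grid, seed = 5,
                            noise_sd = sd, gain_sd = 0, baseline_amplitude = 0,
                            spike_prob = 0, patient_effect_sd = 0)
    co <- generate_cohort(cfg)
    clean0 <- synth_clean_spectrum(grid, cfg$peaks, 0L)
    clean1 <- synth_clean_spectrum(grid, cfg$peaks, 1L)
    tmpl <- rbind(clean0, clean1)[co$meta$label + 1L, ]
    mean(abs(co$intensities - tmpl))
  }, numeric(1))
  expect_true(all(diff(mads) >= 0))
})

test_that("class mean spectra recover the clean templates without baseline", {
  grid <- coarse_grid(8)
  noise_sd <- 0.01
  # broad equal-amplitude pedestal keeps the clean signal well above zero so
  # the generator's non-negativity clip cannot bias channel means
  peaks <- c(default_peak_library(),
             list(peak_spec(1850, 200, 5, 5, "other")))
  cfg <- simulator_config(n_patients = 22L, spectra_per_patient_per_class = 10L,
                          extra_pairs = 1L, grid = grid, seed = 3,
                          peaks = peaks, noise_sd = noise_sd, gain_sd = 0,
                          baseline_amplitude = 0, spike_prob = 0,
                          patient_effect_sd = 0)
  co <- generate_cohort(cfg)
  for (lab in c(0L, 1L)) {
    tmpl <- synth_clean_spectrum(grid, cfg$peaks, lab)
    rows <- co$meta$label == lab
    m <- colMeans(co$intensities[rows, ])
    # restrict to channels where the clean signal sits far enough above
    # zero that the generator's non-negativity clip never fires; elsewhere
    # the clip biases the mean upward by design
    ok <- tmpl > 5 * noise_sd
    z <- (abs(m - tmpl) / (noise_sd / sqrt(sum(rows))))[ok]
    # per-channel sampling error: nearly all channels inside 3 sigma, the
    # max over ~340 channels inside 4 sigma
    expect_gte(mean(z <= 3), 0.99)
    expect_lt(max(z), 4)
  }
})

test_that("invalid simulator configurations list the offending fields", {
  expect_error(simulator_config(noise_sd = -1), "noise_sd")
  expect_error(simulator_config(spike_prob = 2), "spike_prob")
  expect_error(simulator_config(n_patients = 0), "n_patients")
  expect_error(
    simulator_config(peaks = list(peak_spec(100, 10, 1, 1, "other"))),
    "outside grid span")
  expect_error(peak_spec(1000, 300, 1, 1), "fwhm")
})
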