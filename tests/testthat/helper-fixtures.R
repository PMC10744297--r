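# Shared fixtures: everything is generated in code at test time.

# tiny hand-built cohort for I/O and region tests
tiny_cohort <- function(n = 3L, shifts = seq(500, 509, by = 1)) {
  set.seed(99)
  mat <- matrix(abs(rnorm(n * length(shifts), 10, 2)), nrow = n)
  meta <- data.frame(
    spectrum_id = sprintf("S%02d", seq_len(n)),
    patient_id = sprintf("P%02d", ((seq_len(n) - 1L) %% 2L) + 1L),
    label = rep_len(c(0L, 1L), n))
  raman_cohort(shifts, mat, meta)
}

# coarse axis covering the full acquisition range; keeps simulator-driven
# tests fast while preserving both wavenumber regions
coarse_grid <- function(step = 4) seq(500, 3200, by = step)

# small patient-structured simulated cohort on the coarse axis
small_sim_config <- function(seed = 1L, n_patients = 8L, per_class = 6L,
                             grid = coarse_grid(), ...) {
  simulator_config(n_patients = n_patients,
                   spectra_per_patient_per_class = per_class,
                   extra_pairs = 0L, grid = grid, seed = seed, ...)
}

# independent SNIP oracle: literal double-loop clipping, no vectorization
snip_oracle <- function(y, iterations, lls = FALSE) {
  v <- if (lls) log(log(sqrt(y + 1) + 1) + 1) else y
  n <- length(v)
  for (m in seq_len(iterations)) {
    if (2 * m >= n) next
    w <- v
    for (i in (m + 1):(n - m)) {
      a <- (v[i - m] + v[i + m]) / 2
      if (a < v[i]) w[i] <- a
    }
    v <- w
  }
  b <- if (lls) (exp(exp(v) - 1) - 1)^2 - 1 else v
  list(baseline = b, corrected = y - b)
}

# brute-force metrics oracle from raw label vectors
metrics_oracle <- function(truth, pred) {
  tp1 <- sum(truth == 1 & pred == 1); tn <- sum(truth == 0 & pred == 0)
  fp1 <- sum(truth == 0 & pred == 1); fn1 <- sum(truth == 1 & pred == 0)
  prec1 <- if (tp1 + fp1 > 0) tp1 / (tp1 + fp1) else 0
  rec1 <- if (tp1 + fn1 > 0) tp1 / (tp1 + fn1) else 0
  prec0 <- if (tn + fn1 > 0) tn / (tn + fn1) else 0
  rec0 <- if (tn + fp1 > 0) tn / (tn + fp1) else 0
  list(accuracy = (tp1 + tn) / length(truth) * 100,
       precision = c(prec0, prec1) * 100, recall = c(rec0, rec1) * 100)
}
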