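## Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

## Reference-parameter batch (beta = 1.4, I = 0.1, k = 0.6, theta = 0.1256).
ref_batch <- function(n = 400L, beta = 1.4, seed = 101L, keep_epochs = TRUE) {
  key <- sprintf("batch_%d_%s_%d_%d", n, format(beta), seed, keep_epochs)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- run_batch(
      accum_params(),
      noise_params(beta = beta, standardize = FALSE),
      n_trials = n, master_seed = seed, keep_epochs = keep_epochs
    )
  }
  .fixtures[[key]]
}

## Small calibrated subject / cohort used by several files.
small_cohort <- function(n_subjects = 6L, trials = 40L, seed = 77L,
                         beta_sd = 0.52, beta_mean = 1.4) {
  key <- sprintf("cohort_%d_%d_%d_%s_%s", n_subjects, trials, seed,
                 format(beta_sd), format(beta_mean))
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- generate_cohort(cohort_config(
      n_subjects = n_subjects, trials_per_subject = trials,
      beta_mean = beta_mean, beta_sd = beta_sd,
      n_calibration = 40L, master_seed = seed
    ))
  }
  .fixtures[[key]]
}

## Independent oracle for the spectral slope: raw full-series periodogram
## plus ordinary least squares in log-log coordinates, over the central
## band (10th resolved frequency up to one tenth of Nyquist).
periodogram_slope <- function(x) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  f <- seq_len(n %/% 2) / n
  p <- p[2:(n %/% 2 + 1)]
  sel <- seq.int(10L, floor(n / 20))
  co <- stats::coef(stats::lm(log10(p[sel]) ~ log10(f[sel])))
  -unname(co[2])
}

sample_skewness <- function(x) {
  z <- (x - mean(x)) / stats::sd(x)
  mean(z^3)
}
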