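test_that("white noise is independent, flat-spectrum and reproducible", {
  w <- generate_white(noise_params(n_samples = 1e5, seed = 11))
  expect_lt(abs(stats::acf(w, lag.max = 1, plot = FALSE)$acf[2]), 0.01)

  w2 <- generate_white(noise_params(n_samples = 1e5, seed = 11))
  expect_identical(w, w2)

  wl <- generate_white(noise_params(n_samples = 2^16, seed = 3))
  expect_lt(abs(periodogram_slope(wl)), 0.05)

  expect_error(generate_white(noise_params(n_samples = 1)), "at least 2")
})

test_that("spectral shaping imposes the requested 1/f exponent", {
  ## beta = 0 leaves the (standardized) series untouched
  w <- generate_white(noise_params(n_samples = 4096, seed = 5))
  expect_equal(shape_spectrum(w, 0), (w - mean(w)) / stats::sd(w),
               tolerance = 1e-10)

  ## reference exponent, high resolution: slope recovered to 0.05
  sl <- vapply(1:10, function(s) {
    x <- shape_spectrum(generate_white(noise_params(n_samples = 2^17, seed = s)), 1.4)
    periodogram_slope(x)
  }, numeric(1))
  expect_lt(abs(mean(sl) - 1.4), 0.05)

  ## steep exponent: slope and strong lag-1 autocorrelation
  x2 <- shape_spectrum(generate_white(noise_params(n_samples = 2^17, seed = 21)), 2)
  expect_lt(abs(periodogram_slope(x2) - 2), 0.1)
  expect_gt(stats::acf(x2, lag.max = 1, plot = FALSE)$acf[2], 0.9)

  expect_error(shape_spectrum(c(1, NA, 3), 1), "non-finite")
  expect_error(shape_spectrum(rnorm(8), 3), "beta")
})

test_that("slope recovery holds across the admissible exponent range", {
  for (b in c(0, 0.5, 1, 1.4, 2, 2.5)) {
    sl <- vapply(1:10, function(s) {
      x <- shape_spectrum(
        generate_white(noise_params(n_samples = 2^15, seed = 1000 * b + s)), b)
      periodogram_slope(x)
    }, numeric(1))
    expect_lt(abs(mean(sl) - b), 0.1)
  }
})

test_that("every emitted series is standardized, deterministically", {
  for (b in c(0, 1.4, 2.5)) {
    p <- noise_params(beta = b, n_samples = 20000, seed = 7)
    x <- generate_noise(p)
    expect_lt(abs(mean(x)), 1e-10)
    expect_lt(abs(stats::var(x) - 1), 1e-6)
    expect_identical(x, generate_noise(p))
  }
  lp <- noise_params(n_samples = 20000, kind = "lowpass_white",
                     cutoff_hz = 1, fs = 1000, seed = 7)
  y <- generate_noise(lp)
  expect_lt(abs(mean(y)), 1e-10)
  expect_lt(abs(stats::var(y) - 1), 1e-6)
})

test_that("unstandardized shaping is a pure filter that attenuates with beta", {
  w <- generate_white(noise_params(n_samples = 2^15, seed = 9))
  v <- vapply(c(0.5, 1.4, 2.2),
              function(b) stats::var(shape_spectrum(w, b, standardize = FALSE)),
              numeric(1))
  expect_true(all(diff(v) < 0))  # total power decreases as beta grows
  expect_lt(v[2], stats::var(w)) # and is below the white-noise input's
})

test_that("low-pass filtered white noise shows the single-pole roll-off", {
  p <- noise_params(n_samples = 2^17, kind = "lowpass_white", cutoff_hz = 1,
                    filter_order = 1L, fs = 1000, seed = 13)
  y <- lowpass_white(p)
  ## far above the cutoff the log-log PSD slope approaches 2
  ps <- welch_psd(y, fs = 1000, seglen = 8192)
  expect_lt(abs(fit_loglog_slope(ps$freq, ps$psd, c(10, 100)) - 2), 0.15)

  ## DC gain 1: passband power matches the unfiltered white noise
  w <- generate_white(p)
  p2 <- p; p2$standardize <- FALSE
  y_raw <- lowpass_white(p2)
  pw <- welch_psd(w, fs = 1000, seglen = 8192)
  py <- welch_psd(y_raw, fs = 1000, seglen = 8192)
  lowf <- pw$freq <= 0.3 * p$cutoff_hz
  ratio <- mean(py$psd[lowf]) / mean(pw$psd[lowf])
  expect_gt(ratio, 0.75)
  expect_lt(ratio, 1.15)

  expect_error(
    lowpass_white(noise_params(n_samples = 100, kind = "lowpass_white",
                               cutoff_hz = 600, fs = 1000)),
    "cutoff_hz")
})
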