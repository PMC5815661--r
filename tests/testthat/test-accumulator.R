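test_that("noiseless trajectory follows the closed-form leaky integrator", {
  ## x(t) = (I/k)(1 - exp(-kt)); crossing t* = -(1/k) log(1 - k*theta/I)
  p <- accum_params(c = 0, dt = 1e-4, max_samples = 60000L)
  tr <- simulate_trial(p, rep(0, 60000))
  tt <- seq_len(30000) * p$dt
  expect_lt(max(abs(tr$output[1:30000] - (p$I / p$k) * (1 - exp(-p$k * tt)))),
            2e-5)
  tstar <- -(1 / p$k) * log(1 - p$k * p$threshold / p$I)   # 2.3348
  expect_lt(abs(tr$crossing_idx * p$dt - tstar), 2 * p$dt + 1e-3)
  ## closed-form value at the end of the simulated window (t = 6 s)
  expect_lt(abs(tr$output[60000] - (p$I / p$k) * (1 - exp(-p$k * 6))), 1e-4)
})

test_that("zero dynamics never cross: trial is censored, not an error", {
  p <- accum_params(I = 0, c = 0, dt = 1e-3, max_samples = 2000L)
  tr <- simulate_trial(p, rep(0, 2000))
  expect_true(tr$censored)
  expect_true(is.na(tr$crossing_idx))
  expect_true(all(tr$output == 0))
})

test_that("first-crossing detection uses a closed threshold and 1-based indexing", {
  ## third sample is the first at or above the level
  expect_identical(detect_first_crossing(c(0, 0.05, 0.13), 0.1256), 3L)
  expect_true(is.na(detect_first_crossing(c(0, 0.05, 0.1), 0.1256)))
  ## a series starting at the level crosses immediately
  expect_identical(detect_first_crossing(c(0.2, 0.1), 0.1256), 1L)
  expect_error(detect_first_crossing(numeric(0), 1), "empty")
  expect_error(detect_first_crossing(c(1, NA), 1), "non-finite")
})

test_that("the W delay matches the two closed-form first-passage times", {
  p <- accum_params(c = 0, dt = 1e-4, max_samples = 60000L)
  tr <- simulate_trial(p, rep(0, 60000))
  t_th <- -(1 / p$k) * log(1 - p$k * p$threshold / p$I)
  t_w <- -(1 / p$k) * log(1 - p$k * p$w_threshold / p$I)
  expect_lt(abs(tr$w_delay - (t_w - t_th)), 4 * p$dt + 1e-3)  # ~ -0.445
  expect_lt(tr$w_delay, 0)

  ## steeper drift -> strictly smaller |delay|
  p2 <- accum_params(I = 0.12, c = 0, dt = 1e-4, max_samples = 60000L)
  tr2 <- simulate_trial(p2, rep(0, 60000))
  expect_lt(abs(tr2$w_delay), abs(tr$w_delay))

  ## degenerate: one step jumps from below theta_w to above theta
  fake <- structure(list(output = c(0, 0.2), crossing_idx = 2L,
                         params = accum_params()),
                    class = "accum_trial")
  expect_equal(as.numeric(compute_w_delay(fake)), 0)

  expect_error(accum_params(w_threshold = 0.2, threshold = 0.1256),
               "w_threshold")
})

test_that("epoch extraction aligns the crossing at offset zero with missing head", {
  mk_trial <- function(ci, n = 8000) {
    structure(list(input = seq_len(n), output = seq_len(n) / n,
                   crossing_idx = as.integer(ci),
                   params = accum_params(max_samples = n)),
              class = "accum_trial")
  }
  ep <- extract_epochs(mk_trial(6000))
  expect_length(ep$input_epoch, 5501L)
  expect_identical(ep$input_epoch, as.numeric(1000:6500))  # samples 1000..6500
  expect_identical(ep$offsets[5001], 0L)
  expect_identical(ep$input_epoch[5001], 6000)             # value at the crossing

  ## crossing earlier than the window: leading samples flagged missing
  ep2 <- extract_epochs(mk_trial(3000))
  expect_true(all(is.na(ep2$input_epoch[1:2001])))
  expect_true(all(is.finite(ep2$input_epoch[2002:5501])))

  cens <- structure(list(crossing_idx = NA_integer_), class = "accum_trial")
  expect_error(extract_epochs(cens), "censored")
})

test_that("batches are reproducible and deterministic in the noiseless limit", {
  p <- accum_params(c = 0, dt = 1e-3, max_samples = 4000L)
  np <- noise_params(beta = 1.4, standardize = FALSE)
  b <- run_batch(p, np, n_trials = 5, master_seed = 3, keep_epochs = FALSE)
  tstar <- -(1 / p$k) * log(1 - p$k * p$threshold / p$I)
  expect_true(all(abs(b$crossing_times - tstar) < 2e-3))

  b1 <- ref_batch(80L, seed = 55L)
  b2 <- run_batch(accum_params(), noise_params(beta = 1.4, standardize = FALSE),
                  n_trials = 80, master_seed = 55)
  expect_identical(b1$crossing_times, b2$crossing_times)
  expect_identical(b1$input_epochs, b2$input_epochs)
})

test_that("the output stays strictly below threshold before the first crossing", {
  p <- accum_params()
  np <- noise_params(beta = 1.4, standardize = FALSE,
                     n_samples = 60500, fs = 1000)
  for (s in 1:5) {
    np$seed <- 300L + s
    tr <- simulate_trial(p, generate_noise(np))
    if (tr$censored) next
    expect_true(all(tr$output[seq_len(tr$crossing_idx - 1L)] < p$threshold))
    expect_gte(tr$output[tr$crossing_idx], p$threshold)
  }
})

test_that("first-crossing times at reference parameters are right-skewed", {
  b <- ref_batch(400L)
  expect_gt(length(b$crossing_times), 350)
  expect_gt(sample_skewness(b$crossing_times), 0)
  ## unimodal-right-skew signature: mode (earliest density peak) before mean
  expect_lt(stats::median(b$crossing_times), mean(b$crossing_times))
})

test_that("all-censored batches warn and return an empty distribution", {
  p <- accum_params(I = 0, c = 1e-8, threshold = 0.5, dt = 1e-3,
                    max_samples = 2000L)
  np <- noise_params(beta = 0.5, standardize = FALSE)
  expect_warning(b <- run_batch(p, np, n_trials = 3, master_seed = 1,
                                keep_epochs = FALSE),
                 "censored")
  expect_length(b$crossing_times, 0L)
  expect_identical(b$n_censored, 3L)
})
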