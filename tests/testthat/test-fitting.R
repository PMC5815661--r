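## shared small-scale fitting configuration: shorter trial cap keeps the
## Monte-Carlo cheap; censoring at these parameters stays low
FIT_MS <- 20000L

make_target <- function(n = 300L, seed = 7L, mode = "rp_as_input",
                        scale = 1) {
  ## noise length matches the objective's internal simulation exactly, so
  ## a same-seed evaluation reproduces the target bit for bit
  b <- run_batch(accum_params(max_samples = FIT_MS),
                 noise_params(beta = 1.4, standardize = FALSE,
                              n_samples = FIT_MS + 500L),
                 n_trials = n, master_seed = seed,
                 pre = 3000L, post = 0L)
  wf <- average_event_locked(b, mode)
  fit_target(scale * wf, b$offsets * 0.001, wait_times = b$crossing_times,
             n_trials_represented = n)
}

test_that("event-locked averaging respects the missing-data mask", {
  m <- matrix(rep(1:5, each = 4), nrow = 5, byrow = TRUE)
  expect_equal(average_event_locked(m), colMeans(m))

  m2 <- matrix(1, 5, 3)
  m2[1:2, 2] <- NA             # time point covered by 3 of 5 epochs
  m2[3:5, 2] <- c(2, 4, 6)
  expect_equal(average_event_locked(m2)[2], 4)

  expect_error(average_event_locked(matrix(numeric(0), 0, 3)), "no epochs")
})

test_that("waiting-time histograms are normalized densities", {
  br <- 0:10
  d1 <- wait_histogram(rep(2.5, 20), br)
  expect_equal(d1[3], 1)
  expect_equal(sum(d1), 1)

  d2 <- wait_histogram(seq(0.5, 9.5, by = 1), br)
  expect_true(all(abs(d2 - 0.1) < 1e-12))

  b <- ref_batch(400L)
  d3 <- wait_histogram(b$crossing_times,
                       seq(0, max(b$crossing_times), length.out = 41))
  expect_equal(sum(d3), 1)
  ## right-skewed: modal bin earlier than the mean
  mids <- seq(0, max(b$crossing_times), length.out = 41)
  mids <- (mids[-1] + mids[-41]) / 2
  expect_lt(mids[which.max(d3)], mean(b$crossing_times))

  expect_error(wait_histogram(c(NA, NaN), br), "no finite")
})

test_that("the objective is zero at self-consistency and scales linearly", {
  tg <- make_target(n = 200L, seed = 7L)
  truth <- list(beta = 1.4, I = 0.1, k = 0.6, threshold = 0.1256)
  m0 <- accum_objective(truth, tg, "rp_as_input", n_sim_trials = 200L,
                        seed = 7L, max_samples = FIT_MS)
  expect_lt(m0, 1e-20)  # identical simulation, amplitude profiled exactly

  ## curves differing by a factor of 2: the profiled scale absorbs it
  tg2 <- make_target(n = 200L, seed = 7L, scale = 2)
  m2 <- accum_objective(truth, tg2, "rp_as_input", n_sim_trials = 200L,
                        seed = 7L, max_samples = FIT_MS)
  expect_lt(m2, 1e-20)

  ## common random numbers: deterministic in the parameters
  m0b <- accum_objective(truth, tg, "rp_as_input", n_sim_trials = 200L,
                         seed = 7L, max_samples = FIT_MS)
  expect_identical(m0, m0b)
})

test_that("the objective discriminates a misspecified leak", {
  tg <- make_target(n = 200L, seed = 13L)
  truth <- list(beta = 1.4, I = 0.1, k = 0.6, threshold = 0.1256)
  worse <- replace(truth, "k", 0.9)
  d <- vapply(1:5, function(s) {
    mt <- accum_objective(truth, tg, "rp_as_input", n_sim_trials = 150L,
                          seed = 100L + s, max_samples = FIT_MS)
    mw <- accum_objective(worse, tg, "rp_as_input", n_sim_trials = 150L,
                          seed = 100L + s, max_samples = FIT_MS)
    mw - mt
  }, numeric(1))
  expect_gt(mean(d), 0)
})

test_that("an amplitude-only fit of matching curves returns scale 1, mse ~ 0", {
  tg <- make_target(n = 150L, seed = 21L)
  f <- accum_fit(tg, mode = "rp_as_input", free = character(0),
                 n_sim_trials = 150L, n_final_trials = 150L, seed = 21L,
                 max_samples = FIT_MS)
  expect_equal(unname(coef(f)["amp_scale"]), 1, tolerance = 1e-8)
  expect_lt(f$mse, 1e-20)
  expect_s3_class(f, "accum_fit")
})

test_that("fitted parameters always respect the configured bounds", {
  tg <- make_target(n = 120L, seed = 33L)
  f <- accum_fit(tg, mode = "rp_as_input", free = "k",
                 init = list(beta = 1.4, I = 0.1, k = 1.9, threshold = 0.1256),
                 n_sim_trials = 100L, n_final_trials = 100L,
                 grid_points = 2L, restarts = 1L, maxit = 15L, seed = 33L,
                 max_samples = FIT_MS)
  expect_gte(f$par[["k"]], f$lower[["k"]])
  expect_lte(f$par[["k"]], f$upper[["k"]])
  expect_true(all(c("beta", "I", "k", "threshold") %in% names(f$par)))
  expect_true(is.data.frame(f$trace) && nrow(f$trace) > 0)
})

test_that("fit methods return coherent predictions and residuals", {
  tg <- make_target(n = 150L, seed = 21L)
  f <- accum_fit(tg, mode = "rp_as_input", free = character(0),
                 n_sim_trials = 150L, n_final_trials = 150L, seed = 21L,
                 max_samples = FIT_MS)
  p <- predict(f)
  expect_length(p$waveform, length(tg$rp_times))
  expect_equal(sum(p$density), 1, tolerance = 1e-12)
  r <- residuals(f)
  expect_lt(max(abs(r$waveform)), 1e-10)
  b <- simulate(f, nsim = 20L, seed = 5L)
  expect_s3_class(b, "accum_batch")
  expect_gt(length(b$crossing_times), 0)
})
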