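test_that("tercile split takes exact thirds and handles ties inward", {
  sp <- tercile_split(1:9)
  expect_identical(sp$short, 1:3)
  expect_identical(sp$long, 7:9)

  expect_error(tercile_split(rep(2, 10)), "degenerate")
  expect_error(tercile_split(c(1, 2)), "at least 3")

  ## duplicates at the 33rd percentile all join the short group
  w <- c(1, 2, 3, 3, 3, 6, 7, 8, 9)
  sp2 <- tercile_split(w)
  expect_true(all(which(w == 3) %in% sp2$short))
  expect_identical(sp2$long, 7:9)
})

test_that("identical groups show no pointwise or window difference", {
  n <- 30; tp <- 40
  ep <- matrix(1.5, n, tp)                 # constant waveforms
  wt <- seq_len(n)                         # waits differ, signals do not
  times <- seq(-3, 0.9, length.out = tp)
  tc <- compare_terciles(ep, wt, times, window = c(-1.5, -0.5))
  expect_true(all(tc$pointwise_p > 0.99, na.rm = TRUE))
  expect_gt(tc$window_p, 0.99)
  expect_equal(tc$window_diff, 0)
})

test_that("tercile comparison is invariant to trial order and offsets", {
  set.seed(8)
  n <- 60; tp <- 50
  ep <- matrix(rnorm(n * tp), n, tp) + outer(seq_len(n) / 10, rep(1, tp))
  wt <- runif(n, 2, 12)
  times <- seq(-3, 0.9, length.out = tp)
  t1 <- compare_terciles(ep, wt, times)
  perm <- sample(n)
  t2 <- compare_terciles(ep[perm, ], wt[perm], times)
  expect_equal(t1$window_diff, t2$window_diff)
  expect_equal(t1$pointwise_p, t2$pointwise_p)
  t3 <- compare_terciles(ep + 100, wt, times)
  expect_equal(t1$window_p, t3$window_p)
  expect_equal(t1$window_diff, t3$window_diff)

  expect_error(compare_terciles(ep, wt, times, window = c(-9, 0)), "window")
})

test_that("the binomial sign test reproduces exact tail probabilities", {
  expect_equal(binomial_sign_test(13, 14), 15 / 16384, tolerance = 1e-12)
  expect_equal(binomial_sign_test(14, 14), 1 / 16384, tolerance = 1e-12)
  expect_equal(binomial_sign_test(7, 14), 9908 / 16384, tolerance = 1e-12)
  expect_equal(binomial_sign_test(0, 14), 1)
  expect_error(binomial_sign_test(15, 14), "n_successes")
})

test_that("wait/W correlation recovers exact linear dependence", {
  waits <- rep(seq(2, 12, length.out = 20), 3)
  w <- -0.05 * waits - 0.02
  ids <- rep(1:3, each = 20)
  cr <- wait_w_correlation(waits, w, ids)
  expect_equal(cr$pooled_r, -1, tolerance = 1e-12)
  expect_equal(cr$pooled_slope, -0.05, tolerance = 1e-12)
  expect_identical(cr$n_negative, 3L)
  expect_equal(unname(cr$per_subject_r), rep(-1, 3), tolerance = 1e-12)

  ## zero-variance subject is excluded with a flag
  w2 <- w; w2[ids == 2] <- -0.1
  cr2 <- wait_w_correlation(waits, w2, ids)
  expect_identical(cr2$excluded_subjects, "2")
  expect_identical(cr2$n_subjects, 2L)
})

test_that("uncorrelated W reports give calibrated null behaviour", {
  set.seed(99)
  rej <- 0; negs <- integer(0)
  for (r in 1:100) {
    waits <- runif(80, 2, 12)
    w <- pmin(0, rnorm(80, -0.2, 0.1))
    ids <- rep(1:4, each = 20)
    cr <- wait_w_correlation(waits, w, ids)
    rej <- rej + (cr$pooled_p < 0.05)
    negs <- c(negs, cr$n_negative)
  }
  expect_lt(rej / 100, 0.12)            # pooled test holds its level
  expect_gt(mean(negs) / 4, 0.3)        # sign counts look like fair coins
  expect_lt(mean(negs) / 4, 0.7)
})

test_that("cluster permutation finds no clusters in identical data", {
  set.seed(5)
  A <- matrix(rnorm(12 * 80), 12, 80)
  ct <- cluster_permutation(A, A, n_perm = 200, seed = 2)
  expect_identical(nrow(ct$clusters), 0L)
})

test_that("an injected offset yields a significant cluster over its window", {
  set.seed(6)
  n <- 12; tp <- 200
  A <- matrix(rnorm(n * tp), n, tp)
  B <- matrix(rnorm(n * tp), n, tp)
  A[, 80:120] <- A[, 80:120] + 1.5
  ct <- cluster_permutation(A, B, n_perm = 500, seed = 3)
  expect_gt(nrow(ct$clusters), 0)
  top <- ct$clusters[which.min(ct$clusters$p), ]
  expect_lt(top$p, 0.05)
  expect_true(top$start <= 120 && top$end >= 80)  # overlaps the true window
})

test_that("cluster permutation holds its family-wise error rate under the null", {
  set.seed(12)
  n_runs <- 250
  fp <- 0
  for (r in seq_len(n_runs)) {
    A <- matrix(rnorm(12 * 100), 12, 100)
    B <- matrix(rnorm(12 * 100), 12, 100)
    ct <- cluster_permutation(A, B, n_perm = 400, seed = 1000 + r)
    if (nrow(ct$clusters) && min(ct$clusters$p) <= 0.05) fp <- fp + 1
  }
  rate <- fp / n_runs
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.08)
})
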