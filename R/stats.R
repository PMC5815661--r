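#' Split trials into short- and long-wait terciles
#'
#' Membership in the lower and upper thirds of the waiting-time
#' distribution (nearest-rank percentiles). Boundary ties are assigned to
#' the inner group on each side (short side uses `<=` the 33rd-percentile
#' value, long side `>=` the 67th), so duplicated waiting times at a
#' boundary fall into the adjacent extreme group. The middle third is
#' excluded.
#'
#' @param wait_times Numeric vector of waiting times (`>= 3` values).
#' @return A list with integer index vectors `short` and `long`.
#' @examples
#' tercile_split(1:9)  # short 1:3, long 7:9
#' @export
tercile_split <- function(wait_times) {
  n <- length(wait_times)
  if (n < 3L) stop("need at least 3 trials for a tercile split", call. = FALSE)
  if (!all(is.finite(wait_times))) stop("non-finite waiting times", call. = FALSE)
  srt <- sort(wait_times)
  q33 <- srt[ceiling(n / 3)]
  q67 <- srt[n - ceiling(n / 3) + 1L]
  if (q33 >= q67) {
    stop("degenerate tercile split: short and long groups would overlap",
         call. = FALSE)
  }
  list(short = which(wait_times <= q33), long = which(wait_times >= q67))
}

## Pointwise two-sided Wilcoxon p-values and signed-rank statistics for a
## paired subjects-by-time difference matrix.
paired_signedrank <- function(D) {
  n <- nrow(D)
  A <- abs(D)
  R <- apply(A, 2L, rank)
  SR <- R * sign(D)                      # signed ranks, |.| fixed under flips
  Tstat <- colSums(SR)
  M <- n * (n + 1) / 2
  Wplus <- (Tstat + M) / 2
  p <- vapply(Wplus, function(w) {
    lo <- stats::psignrank(floor(w), n)
    hi <- stats::psignrank(ceiling(w) - 1, n, lower.tail = FALSE)
    min(1, 2 * min(lo, hi))
  }, numeric(1))
  list(stat = Tstat, p = p, signed_ranks = SR, n = n)
}

#' Compare event-locked waveforms between waiting-time terciles
#'
#' Splits trials by waiting time ([tercile_split()]), averages the
#' waveforms within the short- and long-wait groups, and tests the
#' group difference: pointwise two-sided rank tests at every time point
#' plus one declared-window test on the mean amplitude over
#' `window`. Missing samples (`NA`) are excluded per time point.
#'
#' Two inference modes are provided: `by = "trials"` treats trials as
#' units (rank-sum test between the two groups; single-subject use), and
#' `by = "subjects"` treats subjects as paired units (each subject's
#' short- and long-tercile mean waveforms are formed within subject and
#' compared by a signed-rank test; group-level use).
#'
#' @param epochs Trials-by-time numeric matrix of event-locked waveforms.
#' @param wait_times Waiting time of each trial (length `nrow(epochs)`).
#' @param times Time axis (length `ncol(epochs)`), in seconds relative to
#'   the crossing.
#' @param window Length-2 window `[t1, t2]` (s) for the amplitude test
#'   (default `c(-1.5, -0.5)`).
#' @param by `"trials"` or `"subjects"`.
#' @param subjects Subject id per trial (required for `by = "subjects"`).
#' @return An object of class `tercile_comparison`: `short_mean`,
#'   `long_mean`, `diff` (long minus short), `pointwise_p`,
#'   `window_diff`, `window_p`, `times`, `window`, `by`, `n_short`,
#'   `n_long`.
#' @export
compare_terciles <- function(epochs, wait_times, times,
                             window = c(-1.5, -0.5),
                             by = c("trials", "subjects"), subjects = NULL) {
  by <- match.arg(by)
  stopifnot(is.matrix(epochs), nrow(epochs) == length(wait_times),
            ncol(epochs) == length(times))
  if (window[1] < min(times) || window[2] > max(times)) {
    stop("`window` lies outside the epoch time range", call. = FALSE)
  }
  win <- times >= window[1] & times <= window[2]

  if (by == "trials") {
    grp <- tercile_split(wait_times)
    A <- epochs[grp$short, , drop = FALSE]
    B <- epochs[grp$long, , drop = FALSE]
    short_mean <- colMeans(A, na.rm = TRUE)
    long_mean <- colMeans(B, na.rm = TRUE)
    pointwise_p <- vapply(seq_along(times), function(j) {
      a <- A[, j][is.finite(A[, j])]
      b <- B[, j][is.finite(B[, j])]
      if (length(a) < 2L || length(b) < 2L) return(NA_real_)
      suppressWarnings(stats::wilcox.test(a, b)$p.value)
    }, numeric(1))
    aw <- rowMeans(A[, win, drop = FALSE], na.rm = TRUE)
    bw <- rowMeans(B[, win, drop = FALSE], na.rm = TRUE)
    aw <- aw[is.finite(aw)]; bw <- bw[is.finite(bw)]
    window_p <- suppressWarnings(stats::wilcox.test(aw, bw)$p.value)
    if (is.na(window_p)) window_p <- 1  # all tied: no evidence of difference
    window_diff <- mean(bw) - mean(aw)
    ns <- length(grp$short); nl <- length(grp$long)
  } else {
    if (is.null(subjects)) stop("`subjects` required when by = \"subjects\"", call. = FALSE)
    ids <- unique(subjects)
    mk <- function(id) {
      e <- epochs[subjects == id, , drop = FALSE]
      w <- wait_times[subjects == id]
      grp <- tercile_split(w)
      rbind(colMeans(e[grp$short, , drop = FALSE], na.rm = TRUE),
            colMeans(e[grp$long, , drop = FALSE], na.rm = TRUE))
    }
    per <- lapply(ids, mk)
    S <- do.call(rbind, lapply(per, function(m) m[1L, ]))
    L <- do.call(rbind, lapply(per, function(m) m[2L, ]))
    short_mean <- colMeans(S, na.rm = TRUE)
    long_mean <- colMeans(L, na.rm = TRUE)
    D <- L - S
    pr <- paired_signedrank(D)
    pointwise_p <- pr$p
    dw <- rowMeans(D[, win, drop = FALSE], na.rm = TRUE)
    window_p <- suppressWarnings(stats::wilcox.test(dw)$p.value)
    window_diff <- mean(dw, na.rm = TRUE)
    ns <- nl <- length(ids)
  }
  structure(
    list(short_mean = short_mean, long_mean = long_mean,
         diff = long_mean - short_mean, pointwise_p = pointwise_p,
         window_diff = window_diff, window_p = window_p,
         times = times, window = window, by = by,
         n_short = ns, n_long = nl),
    class = "tercile_comparison"
  )
}

#' @export
print.tercile_comparison <- function(x, ...) {
  cat(sprintf("<tercile_comparison> by %s (n_short = %d, n_long = %d)\n",
              x$by, x$n_short, x$n_long))
  cat(sprintf("  window [%g, %g] s: long - short = %+.4g (p = %.3g)\n",
              x$window[1], x$window[2], x$window_diff, x$window_p))
  cat(sprintf("  %d of %d time points with pointwise p < 0.05\n",
              sum(x$pointwise_p < 0.05, na.rm = TRUE), length(x$pointwise_p)))
  invisible(x)
}

#' @export
plot.tercile_comparison <- function(x, ...) {
  rng <- range(c(x$short_mean, x$long_mean), na.rm = TRUE)
  graphics::plot(x$times, x$long_mean, type = "l", lwd = 2, ylim = rng,
                 xlab = "time relative to crossing (s)", ylab = "amplitude", ...)
  graphics::lines(x$times, x$short_mean, col = "grey55", lwd = 2)
  graphics::abline(v = x$window, lty = 3)
  sig <- which(x$pointwise_p < 0.05)
  if (length(sig)) graphics::points(x$times[sig], rep(rng[1], length(sig)),
                                    pch = "*", cex = 0.6)
  graphics::legend("topleft", c("long wait", "short wait"),
                   col = c("black", "grey55"), lwd = 2, bty = "n")
  invisible(x)
}

#' Cluster-based permutation test for paired waveforms
#'
#' Corrects pointwise paired rank tests for multiple comparisons across
#' time. Clusters are runs of contiguous time points whose uncorrected
#' two-sided signed-rank p-value falls below `cluster_alpha`; the cluster
#' statistic is the sum of the pointwise signed-rank statistics. The null
#' distribution is built by randomly sign-flipping each unit's (subject's)
#' condition difference; positive and negative clusters are formed
#' separately and compared against the permutation distribution of the
#' maximum absolute cluster statistic.
#'
#' @param groupA,groupB Paired units-by-time matrices (same dimensions;
#'   row i of each is the same subject under the two conditions).
#' @param n_perm Number of sign-flip permutations (`>= 100`;
#'   default `1000`).
#' @param cluster_alpha Cluster-forming threshold on the uncorrected
#'   two-sided p-value (default `0.05`).
#' @param seed RNG seed for the permutations.
#' @return An object of class `cluster_test`: a data frame `clusters`
#'   (`start`, `end`, `stat`, `p`), the `pointwise_p` vector, and the
#'   permutation `null_max` distribution.
#' @export
cluster_permutation <- function(groupA, groupB, n_perm = 1000L,
                                cluster_alpha = 0.05, seed = 1L) {
  stopifnot(is.matrix(groupA), is.matrix(groupB),
            all(dim(groupA) == dim(groupB)))
  if (n_perm < 100L) warning("fewer than 100 permutations: corrected p-values are coarse")
  D <- groupA - groupB
  n <- nrow(D)
  pr <- paired_signedrank(D)

  ## threshold on |signed-rank statistic| equivalent to p < cluster_alpha
  M <- n * (n + 1) / 2
  wcrit <- stats::qsignrank(cluster_alpha / 2, n)    # P(W+ <= wcrit) >= alpha/2
  while (wcrit > 0 &&
         2 * stats::psignrank(wcrit, n) > cluster_alpha) wcrit <- wcrit - 1
  tcrit <- M - 2 * wcrit                              # |T| >= tcrit  <=>  p <= alpha

  find_clusters <- function(tv) {
    supra <- abs(tv) >= tcrit & tv != 0
    if (!any(supra)) return(NULL)
    ## contiguous suprathreshold runs, split by sign
    runs <- rle(ifelse(supra, sign(tv), 0))
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- runs$values != 0
    if (!any(keep)) return(NULL)
    data.frame(start = starts[keep], end = ends[keep],
               stat = mapply(function(s, e) sum(tv[s:e]), starts[keep], ends[keep]))
  }

  obs <- find_clusters(pr$stat)
  SR <- pr$signed_ranks
  null_max <- with_seed(seed, {
    eps <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    Tperm <- eps %*% SR                               # n_perm x time
    apply(Tperm, 1L, function(tv) {
      cl <- find_clusters(tv)
      if (is.null(cl)) 0 else max(abs(cl$stat))
    })
  })
  if (!is.null(obs)) {
    obs$p <- vapply(obs$stat, function(s) (1 + sum(null_max >= abs(s))) / (1 + n_perm),
                    numeric(1))
  } else {
    obs <- data.frame(start = integer(), end = integer(),
                      stat = numeric(), p = numeric())
  }
  structure(list(clusters = obs, pointwise_p = pr$p, null_max = null_max,
                 cluster_alpha = cluster_alpha, n_perm = n_perm),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> %d cluster(s) at forming threshold p < %g (%d permutations)\n",
              nrow(x$clusters), x$cluster_alpha, x$n_perm))
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Correlation between waiting time and 'W' time
#'
#' Pearson correlation between per-trial waiting times and reported 'W'
#' times: pooled over all trials (with the OLS regression slope), and
#' separately per subject. The per-subject correlations are tested
#' against zero with a two-sided Wilcoxon signed-rank test, and the count
#' of subjects with a negative correlation with a one-sided binomial sign
#' test ([binomial_sign_test()]).
#'
#' @param waits Waiting times (s), one per trial.
#' @param w_times Reported 'W' times (s, non-positive), one per trial.
#' @param subject_ids Subject identifier per trial.
#' @return An object of class `correlation_report`: `pooled_r`,
#'   `pooled_p`, `pooled_slope`, `per_subject_r` (named vector),
#'   `excluded_subjects`, `signed_rank_p`, `n_negative`, `n_subjects`,
#'   `binomial_p`.
#' @export
wait_w_correlation <- function(waits, w_times, subject_ids) {
  stopifnot(length(waits) == length(w_times),
            length(waits) == length(subject_ids))
  ok <- is.finite(waits) & is.finite(w_times)
  ct <- stats::cor.test(waits[ok], w_times[ok])
  slope <- unname(stats::coef(stats::lm(w_times[ok] ~ waits[ok]))[2L])
  ids <- unique(subject_ids)
  rs <- vapply(ids, function(id) {
    sel <- ok & subject_ids == id
    if (sum(sel) < 3L) return(NA_real_)
    if (stats::sd(waits[sel]) == 0 || stats::sd(w_times[sel]) == 0) return(NA_real_)
    stats::cor(waits[sel], w_times[sel])
  }, numeric(1))
  names(rs) <- as.character(ids)
  excl <- names(rs)[!is.finite(rs)]
  rs_ok <- rs[is.finite(rs)]
  srp <- if (length(rs_ok) >= 2L)
    suppressWarnings(stats::wilcox.test(rs_ok)$p.value) else NA_real_
  nneg <- sum(rs_ok < 0)
  structure(
    list(pooled_r = unname(ct$estimate), pooled_p = ct$p.value,
         pooled_slope = slope, per_subject_r = rs_ok,
         excluded_subjects = excl, signed_rank_p = srp,
         n_negative = nneg, n_subjects = length(rs_ok),
         binomial_p = binomial_sign_test(nneg, length(rs_ok))),
    class = "correlation_report"
  )
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report> pooled r = %+.3f (p = %.3g), slope = %+.4g\n",
              x$pooled_r, x$pooled_p, x$pooled_slope))
  cat(sprintf("  per-subject r: median %+.3f over %d subjects; signed-rank p = %.3g\n",
              stats::median(x$per_subject_r), x$n_subjects, x$signed_rank_p))
  cat(sprintf("  %d of %d subjects negative; binomial sign-test p = %.4g\n",
              x$n_negative, x$n_subjects, x$binomial_p))
  if (length(x$excluded_subjects)) {
    cat("  excluded (undefined r):", paste(x$excluded_subjects, collapse = ", "), "\n")
  }
  invisible(x)
}

#' One-sided binomial sign test
#'
#' Exact upper-tail probability \eqn{P(X \ge k)} for
#' \eqn{X \sim \mathrm{Binomial}(n, 1/2)}: the chance that at least `k`
#' of `n` subjects individually show an effect in the same direction if
#' each direction were a fair coin flip.
#'
#' @param n_successes Observed count `k` (`0 <= k <= n`).
#' @param n_total Number of subjects `n`.
#' @return The exact tail probability.
#' @examples
#' binomial_sign_test(13, 14)  # 15/16384 ~= 0.0009
#' @export
binomial_sign_test <- function(n_successes, n_total) {
  if (n_successes < 0 || n_successes > n_total) {
    stop("`n_successes` must lie in [0, n_total]", call. = FALSE)
  }
  stats::pbinom(n_successes - 1, n_total, 0.5, lower.tail = FALSE)
}
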