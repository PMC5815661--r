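#' Configuration of a synthetic multi-subject cohort
#'
#' Describes the generative conditions of a synthetic study: per-subject
#' accumulator trials with 1/f input noise, event-locked scalp epochs at
#' 250 Hz spanning -3.5 to +1.0 s around movement onset, per-trial
#' waiting times, and clock-quantized 'W' reports.
#'
#' Per-subject 1/f exponents are drawn from a normal distribution
#' (`beta_mean`, `beta_sd`, truncated to `[0.1, 2.9]`). The activation
#' threshold is auto-calibrated per subject by bisection so the median
#' simulated waiting time matches `wait_target`, and the advance-warning
#' threshold so the mean model 'W' delay matches `w_target`; both
#' calibrations can be disabled. Scalp epochs are the sign-reversed,
#' amplitude-scaled stochastic input (negative-going convention),
#' decimated from the 1000-Hz simulation rate to `fs_out` after zero-phase
#' anti-alias filtering, with additive Gaussian sensor noise. 'W' reports
#' are the model delay plus Gaussian report noise, clamped at zero and
#' quantized to the clock tick.
#'
#' @param n_subjects Number of subjects (default `14`).
#' @param trials_per_subject Trials per subject (default `60`).
#' @param beta_mean,beta_sd Mean and between-subject SD of the 1/f
#'   exponent (defaults `1.4` and `0.52`; the SD corresponds to a group
#'   standard error of 0.14 at n = 14).
#' @param I,k,c Accumulator drift, leak and noise scale (reference values).
#' @param threshold Activation threshold used when `calibrate = FALSE`
#'   (default `0.1256`).
#' @param w_frac Advance-warning threshold as a fraction of the activation
#'   threshold when `calibrate_w = FALSE` (default `0.9`).
#' @param dt Simulation step in seconds (default `0.001`).
#' @param max_samples Trial cutoff in samples (default `60000`).
#' @param fs_out Output epoch sampling rate in Hz (default `250`).
#' @param epoch_window Epoch extent `[t_pre, t_post]` in seconds relative
#'   to the crossing (default `c(-3.5, 1)`, i.e. 1126 samples at 250 Hz).
#' @param amp_scale Scalp amplitude per model input unit (microvolts;
#'   default `3000`: the input's event-locked deflection at the
#'   calibrated reference configuration is ~0.0017 input units, so the
#'   late readiness potential reaches a few microvolts, with
#'   tercile-difference effects of 1-2 microvolts as seen empirically).
#' @param sensor_noise_sd SD of the additive background EEG noise per
#'   250-Hz sample (microvolts; default `10`, a realistic single-trial
#'   amplitude after preprocessing). The background noise is generated as
#'   1/f noise with the subject's own exponent: scalp EEG shares the
#'   aperiodic spectrum of the cortical fluctuations that drive the
#'   accumulator, so the epochs carry the subject's spectral exponent.
#' @param w_report_noise_sd SD of the 'W' report noise in seconds
#'   (default `0.15`; a free dial of the generator, not an empirical
#'   estimate -- see the vignette).
#' @param clock_tick 'W' report quantization in seconds (default `0.05`,
#'   one tick of the rotating-clock display).
#' @param wait_target Median waiting time the threshold calibration aims
#'   for, in seconds (default `7.1`).
#' @param w_target Mean model 'W' delay the advance-warning calibration
#'   aims for, in seconds (default `-0.142`).
#' @param calibrate,calibrate_w Enable the two calibrations (default
#'   `TRUE`).
#' @param n_calibration Trials used per subject to calibrate the
#'   threshold (default `60`).
#' @param interruptus_fraction Fraction of trials labelled
#'   `"interruptus"` (a grouping label only; trials are generated
#'   identically; default `0.5`).
#' @param master_seed Master RNG seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 14L, trials_per_subject = 60L,
                          beta_mean = 1.4, beta_sd = 0.52,
                          I = 0.1, k = 0.6, c = 0.1, threshold = 0.1256,
                          w_frac = 0.9, dt = 0.001, max_samples = 60000L,
                          fs_out = 250, epoch_window = c(-3.5, 1),
                          amp_scale = 3000, sensor_noise_sd = 10,
                          w_report_noise_sd = 0.15, clock_tick = 0.05,
                          wait_target = 7.1, w_target = -0.142,
                          calibrate = TRUE, calibrate_w = TRUE,
                          n_calibration = 60L,
                          interruptus_fraction = 0.5, master_seed = 1L) {
  stopifnot(n_subjects >= 1L, trials_per_subject >= 1L)
  fs_sim <- 1 / dt
  dec <- fs_sim / fs_out
  if (abs(dec - round(dec)) > 1e-9) {
    stop("simulation rate must be an integer multiple of `fs_out`", call. = FALSE)
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         trials_per_subject = as.integer(trials_per_subject),
         beta_mean = beta_mean, beta_sd = beta_sd, I = I, k = k, c = c,
         threshold = threshold, w_frac = w_frac, dt = dt,
         max_samples = as.integer(max_samples), fs_out = fs_out,
         epoch_window = epoch_window, amp_scale = amp_scale,
         sensor_noise_sd = sensor_noise_sd,
         w_report_noise_sd = w_report_noise_sd, clock_tick = clock_tick,
         wait_target = wait_target, w_target = w_target,
         calibrate = isTRUE(calibrate), calibrate_w = isTRUE(calibrate_w),
         n_calibration = as.integer(n_calibration),
         interruptus_fraction = interruptus_fraction,
         master_seed = as.integer(master_seed)),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> %d subjects x %d trials, beta ~ N(%g, %g)\n",
              x$n_subjects, x$trials_per_subject, x$beta_mean, x$beta_sd))
  cat(sprintf("  epochs: %g Hz, [%g, %g] s; wait target %g s; W target %g s\n",
              x$fs_out, x$epoch_window[1], x$epoch_window[2],
              x$wait_target, x$w_target))
  invisible(x)
}

## Simulate one trial's full trajectory; returns input, output, crossing.
## The noise length is padded up to an FFT-friendly size.
sim_full_trial <- function(cfg, beta, seed, threshold) {
  n <- smooth_length(cfg$max_samples + ceiling(cfg$epoch_window[2] / cfg$dt) + 1L, direction = 1L)
  np <- noise_params(beta = beta, n_samples = n, standardize = FALSE,
                     fs = 1 / cfg$dt, seed = seed)
  xi <- generate_noise(np)
  drive <- cfg$I * cfg$dt + cfg$c * xi * sqrt(cfg$dt)
  x <- as.numeric(stats::filter(drive, 1 - cfg$k * cfg$dt,
                                method = "recursive", init = 0))
  ci <- which(x[seq_len(cfg$max_samples)] >= threshold)
  list(input = cfg$I + cfg$c * xi, output = x,
       crossing = if (length(ci)) ci[1L] else NA_integer_)
}

## Threshold at which the median first-crossing time of pre-simulated
## trajectories matches `target_s` (bisection; crossing time is monotone
## increasing in the threshold for each trajectory).
calibrate_threshold <- function(outputs, dt, target_s, max_samples,
                                lo = 0.03, hi = 0.35, iters = 14L) {
  med_wait <- function(th) {
    waits <- vapply(outputs, function(x) {
      ci <- which(x[seq_len(max_samples)] >= th)
      if (length(ci)) ci[1L] * dt else Inf
    }, numeric(1))
    stats::median(waits)
  }
  if (med_wait(hi) < target_s) return(hi)
  if (med_wait(lo) > target_s) return(lo)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (med_wait(mid) < target_s) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

## 'W' delays of stored trajectories for a given advance-warning threshold.
w_delays_at <- function(outputs, crossings, thw, dt) {
  mapply(function(x, ci) {
    if (is.na(ci)) return(NA_real_)
    seg <- x[seq_len(ci)]
    above <- seg >= thw
    up <- which(above & c(TRUE, !above[-length(above)]))
    if (!length(up)) return(NA_real_)
    (up[length(up)] - ci) * dt
  }, outputs, crossings)
}

## w_frac whose mean 'W' delay matches target_s (bisection on w_frac).
calibrate_w_frac <- function(outputs, crossings, threshold, dt, target_s,
                             lo = 0.5, hi = 0.999, iters = 20L) {
  mean_w <- function(fr) {
    mean(w_delays_at(outputs, crossings, fr * threshold, dt), na.rm = TRUE)
  }
  if (mean_w(hi) < target_s) return(hi)
  if (mean_w(lo) > target_s) return(lo)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (mean_w(mid) < target_s) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

## Zero-phase anti-alias low-pass + take every `dec`-th sample. NA-aware:
## filters the contiguous non-NA tail, leaves the missing head as NA.
## The segment is demeaned and odd-reflection padded before filtering;
## without this, filtfilt rings at both ends of an offset signal and the
## edge spikes put a broadband floor into every epoch.
decimate_epoch <- function(v, dec, keep_idx) {
  ok <- which(is.finite(v))
  out <- rep(NA_real_, length(v))
  if (length(ok) > 30L) {
    seg <- v[ok[1L]:length(v)]
    m <- mean(seg)
    seg <- seg - m
    n <- length(seg)
    npad <- min(200L, n - 1L)
    padded <- c(2 * seg[1L] - seg[(npad + 1L):2L],
                seg,
                2 * seg[n] - seg[(n - 1L):(n - npad)])
    bf <- signal::butter(4, 0.8 / dec, type = "low")
    filt <- as.numeric(signal::filtfilt(bf, padded))
    out[ok[1L]:length(v)] <- filt[(npad + 1L):(npad + n)] + m
    if (ok[1L] > 1L) out[seq_len(ok[1L] + 10L)] <- NA_real_  # filter edge
  }
  out[keep_idx]
}

#' Generate one synthetic subject
#'
#' Simulates `trials_per_subject` accumulator trials for one subject
#' (resampling censored trials, up to 10 times the requested count),
#' calibrates the activation and advance-warning thresholds if requested,
#' and assembles the subject's scalp epochs, waiting times and 'W'
#' reports. See [cohort_config()] for the generative conventions.
#'
#' @param config A [cohort_config()].
#' @param subject_id Subject identifier (integer; also offsets the seeds).
#' @param subject_seed Seed for this subject (default derived from the
#'   config's `master_seed` and `subject_id`).
#' @return An object of class `subject_dataset`: `subject_id`, `beta`
#'   (the subject's true exponent), `threshold`, `w_threshold`, `epochs`
#'   (trials x time matrix, microvolts, negative-going), `times` (s),
#'   `wait_times` (s), `w_delays` (model delays, s), `w_reports`
#'   (quantized reports, s), `task_label`, and `seed`.
#' @export
generate_subject <- function(config, subject_id = 1L,
                             subject_seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(subject_seed)) {
    subject_seed <- (config$master_seed + 7919L * as.integer(subject_id)) %%
      .Machine$integer.max
  }
  cfg <- config
  beta <- with_seed(subject_seed, {
    b <- stats::rnorm(1, cfg$beta_mean, cfg$beta_sd)
    tries <- 0L
    while ((b < 0.1 || b > 2.9) && tries < 100L) {
      b <- stats::rnorm(1, cfg$beta_mean, cfg$beta_sd); tries <- tries + 1L
    }
    min(max(b, 0.1), 2.9)
  })

  ## calibration trajectories (threshold-independent, so simulated once)
  threshold <- cfg$threshold
  if (cfg$calibrate) {
    cal <- lapply(seq_len(cfg$n_calibration), function(i) {
      sim_full_trial(cfg, beta, (subject_seed + 100003L * i) %% .Machine$integer.max,
                     threshold = Inf)$output
    })
    threshold <- calibrate_threshold(cal, cfg$dt, cfg$wait_target,
                                     cfg$max_samples)
    rm(cal)
  }

  ## subject trials: resample censored ones until enough crossings
  nt <- cfg$trials_per_subject
  outputs <- vector("list", nt); inputs <- vector("list", nt)
  crossings <- rep(NA_integer_, nt)
  got <- 0L; attempt <- 0L
  while (got < nt && attempt < 10L * nt) {
    attempt <- attempt + 1L
    tr <- sim_full_trial(cfg, beta,
                         (subject_seed + 499979L + attempt) %% .Machine$integer.max,
                         threshold)
    if (is.na(tr$crossing)) next
    got <- got + 1L
    outputs[[got]] <- tr$output
    inputs[[got]] <- tr$input
    crossings[got] <- tr$crossing
  }
  if (got < nt) {
    stop(sprintf("subject %s: only %d of %d trials crossed within the attempt cap",
                 subject_id, got, nt), call. = FALSE)
  }

  ## advance-warning threshold
  w_frac <- cfg$w_frac
  if (cfg$calibrate_w) {
    w_frac <- calibrate_w_frac(outputs, crossings, threshold, cfg$dt,
                               cfg$w_target)
  }
  w_delays <- w_delays_at(outputs, crossings, w_frac * threshold, cfg$dt)

  ## scalp epochs: sign-reversed scaled input, decimated to fs_out
  dec <- as.integer(round(1 / (cfg$dt * cfg$fs_out)))
  pre <- as.integer(round(-cfg$epoch_window[1] / cfg$dt))
  post <- as.integer(round(cfg$epoch_window[2] / cfg$dt))
  keep <- seq.int(1L, pre + post + 1L, by = dec)
  times <- seq.int(-pre, post, by = dec) * cfg$dt
  ep <- matrix(NA_real_, nt, length(keep))
  for (i in seq_len(nt)) {
    idx <- (crossings[i] - pre):(crossings[i] + post)
    v <- rep(NA_real_, length(idx))
    ok <- idx >= 1L & idx <= length(inputs[[i]])
    v[ok] <- inputs[[i]][idx[ok]]
    ep[i, ] <- decimate_epoch(-cfg$amp_scale * v, dec, keep)
  }
  if (cfg$sensor_noise_sd > 0) {
    ## background EEG: 1/f noise at the subject's exponent, cut into trials
    ## (as epochs cut from a continuous recording would be)
    nbg <- smooth_length(length(ep), direction = 1L)
    bg <- with_seed((subject_seed + 2L) %% .Machine$integer.max, {
      shape_spectrum(stats::rnorm(nbg), beta, standardize = TRUE)
    })
    ep <- ep + cfg$sensor_noise_sd *
      matrix(bg[seq_along(ep)], nrow(ep), ncol(ep), byrow = TRUE)
  }

  wait_times <- crossings * cfg$dt
  w_reports <- with_seed((subject_seed + 3L) %% .Machine$integer.max, {
    raw <- w_delays + stats::rnorm(nt, 0, cfg$w_report_noise_sd)
    raw <- pmin(raw, 0)
    round(raw / cfg$clock_tick) * cfg$clock_tick
  })
  task <- with_seed((subject_seed + 4L) %% .Machine$integer.max, {
    ifelse(stats::runif(nt) < cfg$interruptus_fraction, "interruptus", "classic")
  })

  structure(
    list(subject_id = as.integer(subject_id), beta = beta,
         threshold = threshold, w_threshold = w_frac * threshold,
         epochs = ep, times = times, wait_times = wait_times,
         w_delays = w_delays, w_reports = w_reports, task_label = task,
         seed = as.integer(subject_seed)),
    class = "subject_dataset"
  )
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat(sprintf("<subject_dataset> id %d: %d trials, beta = %.2f, threshold = %.4f\n",
              x$subject_id, nrow(x$epochs), x$beta, x$threshold))
  cat(sprintf("  wait: mean %.2f s (median %.2f); W report: mean %+0.3f s\n",
              mean(x$wait_times), stats::median(x$wait_times),
              mean(x$w_reports)))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Independent subjects via [generate_subject()], with per-subject seeds
#' derived from the config's master seed. Regenerating with the same
#' config reproduces the cohort exactly.
#'
#' @param config A [cohort_config()].
#' @return An object of class `rp_cohort`: a list with `subjects` (list
#'   of `subject_dataset`) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  subs <- lapply(seq_len(config$n_subjects), function(s) {
    generate_subject(config, subject_id = s)
  })
  structure(list(subjects = subs, config = config), class = "rp_cohort")
}

#' @export
print.rp_cohort <- function(x, ...) {
  cat(sprintf("<rp_cohort> %d subjects x %d trials (master seed %d)\n",
              length(x$subjects), x$config$trials_per_subject,
              x$config$master_seed))
  mw <- vapply(x$subjects, function(s) mean(s$wait_times), numeric(1))
  ww <- vapply(x$subjects, function(s) mean(s$w_reports), numeric(1))
  cat(sprintf("  mean wait %.2f s (across subjects); mean W report %+.3f s\n",
              mean(mw), mean(ww)))
  invisible(x)
}

#' Flatten a cohort's behavioural table
#'
#' @param cohort An `rp_cohort`.
#' @return A data frame with `subject_id`, `trial`, `wait_time_s`,
#'   `w_report_s`, `w_delay_s`, `task_label`.
#' @export
cohort_behavior <- function(cohort) {
  stopifnot(inherits(cohort, "rp_cohort"))
  do.call(rbind, lapply(cohort$subjects, function(s) {
    data.frame(subject_id = s$subject_id,
               trial = seq_along(s$wait_times),
               wait_time_s = s$wait_times,
               w_report_s = s$w_reports,
               w_delay_s = s$w_delays,
               task_label = s$task_label)
  }))
}

#' Estimate each subject's spectral exponent from their epochs
#'
#' Concatenates the finite samples of every epoch of each subject (as
#' epochs cut from a continuous recording) and estimates the aperiodic
#' 1/f exponent with [estimate_beta()]. The defaults differ from the
#' continuous-series defaults: Welch segments no longer than one epoch
#' (so that segments rarely span epoch splices) and a fit band starting
#' at 0.5 Hz (the lowest frequency an epoch of a few seconds resolves
#' cleanly). Exponents above ~2 are compressed toward 2 by the finite
#' epoch length; see the vignette.
#'
#' @param cohort An `rp_cohort`.
#' @param band Fit band in Hz (default `c(0.5, 30)`).
#' @param seglen Welch segment length in samples (default `1024`).
#' @return Numeric vector of per-subject exponent estimates (named by
#'   subject id).
#' @export
estimate_cohort_beta <- function(cohort, band = c(0.5, 30), seglen = 1024L) {
  stopifnot(inherits(cohort, "rp_cohort"))
  out <- vapply(cohort$subjects, function(s) {
    v <- as.vector(t(s$epochs))
    v <- v[is.finite(v)]
    estimate_beta(v, fs = cohort$config$fs_out, band = band,
                  seglen = seglen)$beta_hat
  }, numeric(1))
  names(out) <- vapply(cohort$subjects, function(s) as.character(s$subject_id),
                       character(1))
  out
}
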