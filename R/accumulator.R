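#' Accumulator parameter set
#'
#' Parameters of the leaky stochastic accumulator
#' \deqn{dx = (I - kx)\,dt + c\,\xi_\beta\,\sqrt{dt}}
#' integrated at `dt` time units per sample. `I` is the drift rate (the
#' imperative to move), `k` the leak, `c` the noise scale, and a movement
#' is triggered when the output `x` first reaches `threshold`. A second,
#' lower advance-warning threshold `w_threshold` models the subjectively
#' reported time of the urge to move ('W' time) as the delay between the
#' crossings of the two thresholds.
#'
#' The packaged default configuration is the best-fit reference
#' parameterization `I = 0.1`, `k = 0.6`, `c = 0.1`, `threshold = 0.1256`
#' (with input-noise exponent `beta = 1.4`). Time is measured in seconds
#' with `dt = 0.001` (1000 samples per second), so rates `I` and `k` are
#' per second.
#'
#' @param I Drift rate per time unit (default `0.1`).
#' @param k Leak per time unit (default `0.6`, must be `> 0`).
#' @param c Noise scaling factor (default `0.1`).
#' @param threshold Activation threshold \eqn{\theta} (default `0.1256`,
#'   must be `> 0`).
#' @param w_frac Advance-warning threshold expressed as a fraction of
#'   `threshold` (default `0.9`); must lie in `(0, 1)`.
#' @param w_threshold Advance-warning threshold \eqn{\theta_w} in output
#'   units; overrides `w_frac` when supplied. Must satisfy
#'   `0 < w_threshold < threshold`.
#' @param dt Integration step in time units per sample (default `0.001`).
#' @param max_samples Trial cutoff in samples (default `60000`, i.e. 60 s):
#'   a trial with no crossing by then is flagged censored.
#' @param x0 Initial accumulator value (default `0`).
#' @param w_convention Which upward crossing of \eqn{\theta_w} defines the
#'   'W' delay: `"last"` (default) uses the final upward crossing before
#'   the activation crossing (the last approach), `"first"` the earliest.
#'
#' @return An object of class `accum_params` (a named list).
#' @export
accum_params <- function(I = 0.1, k = 0.6, c = 0.1, threshold = 0.1256,
                         w_frac = 0.9, w_threshold = NULL, dt = 0.001,
                         max_samples = 60000L, x0 = 0,
                         w_convention = c("last", "first")) {
  w_convention <- match.arg(w_convention)
  vals <- c(I = I, k = k, c = c, threshold = threshold, dt = dt, x0 = x0)
  if (!all(is.finite(vals))) {
    stop("non-finite accumulator parameter: ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "), call. = FALSE)
  }
  if (k <= 0) stop("`k` must be positive", call. = FALSE)
  if (threshold <= 0) stop("`threshold` must be positive", call. = FALSE)
  if (is.null(w_threshold)) w_threshold <- w_frac * threshold
  if (!is.finite(w_threshold) || w_threshold <= 0 || w_threshold >= threshold) {
    stop("`w_threshold` must satisfy 0 < w_threshold < threshold", call. = FALSE)
  }
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  structure(
    list(I = I, k = k, c = c, threshold = threshold,
         w_threshold = w_threshold, dt = dt,
         max_samples = as.integer(max_samples), x0 = x0,
         w_convention = w_convention),
    class = "accum_params"
  )
}

#' @export
print.accum_params <- function(x, ...) {
  cat(sprintf(
    "<accum_params> I = %g, k = %g, c = %g, threshold = %g, w_threshold = %g\n",
    x$I, x$k, x$c, x$threshold, x$w_threshold))
  cat(sprintf("  dt = %g, max_samples = %d, x0 = %g, w_convention = %s\n",
              x$dt, x$max_samples, x$x0, x$w_convention))
  invisible(x)
}

#' First crossing of a level
#'
#' Smallest index `i` with `series[i] >= level` (the crossing is closed at
#' the level: a series starting at the level crosses at index 1).
#'
#' @param series Numeric vector (finite values).
#' @param level Threshold level.
#' @return Integer index, or `NA_integer_` if the level is never reached.
#' @export
detect_first_crossing <- function(series, level) {
  if (length(series) == 0L) stop("empty series", call. = FALSE)
  if (!all(is.finite(series))) stop("series contains non-finite values", call. = FALSE)
  i <- which(series >= level)
  if (length(i)) i[1L] else NA_integer_
}

#' Simulate one accumulator trial
#'
#' Integrates the leaky accumulator over a supplied noise series using the
#' per-sample update
#' `x[t] = x[t-1] + (I - k * x[t-1]) * dt + c * xi[t] * sqrt(dt)`,
#' and detects the first crossing of the activation threshold and the
#' advance-warning threshold crossing that defines the 'W' delay.
#'
#' The trajectory is computed over the full noise series so that
#' post-crossing samples are available to [extract_epochs()]; the censoring
#' decision (no crossing) is taken with respect to `params$max_samples`.
#'
#' @param params An [accum_params()] object.
#' @param noise Numeric vector: the stochastic input \eqn{\xi} (one sample
#'   per integration step), of length at least `params$max_samples`.
#' @return An object of class `accum_trial`: a list with elements
#'   `input` (the full input series `I + c * xi`), `output` (the decision
#'   variable `x`), `crossing_idx` (sample of the first threshold crossing,
#'   `NA` if censored), `w_crossing_idx`, `w_delay` (in time units,
#'   `<= 0`), `censored`, and `params`.
#' @examples
#' p <- accum_params(c = 0, max_samples = 5000)
#' tr <- simulate_trial(p, rep(0, 5000))
#' tr$crossing_idx * p$dt  # ~= -(1/k) log(1 - k*threshold/I) = 2.335
#' @export
simulate_trial <- function(params, noise) {
  stopifnot(inherits(params, "accum_params"))
  if (length(noise) < params$max_samples) {
    stop("noise series shorter than `max_samples`", call. = FALSE)
  }
  dt <- params$dt
  drive <- params$I * dt + params$c * noise * sqrt(dt)
  x <- as.numeric(stats::filter(drive, 1 - params$k * dt,
                                method = "recursive", init = params$x0))
  ci <- detect_first_crossing(x[seq_len(params$max_samples)], params$threshold)
  trial <- structure(
    list(input = params$I + params$c * noise, output = x,
         crossing_idx = ci, w_crossing_idx = NA_integer_,
         w_delay = NA_real_, censored = is.na(ci), params = params),
    class = "accum_trial"
  )
  if (!is.na(ci)) {
    wd <- compute_w_delay(trial, params)
    trial$w_crossing_idx <- attr(wd, "w_crossing_idx")
    trial$w_delay <- as.numeric(wd)
  }
  trial
}

#' @export
print.accum_trial <- function(x, ...) {
  if (x$censored) {
    cat(sprintf("<accum_trial> censored (no crossing within %d samples)\n",
                x$params$max_samples))
  } else {
    cat(sprintf("<accum_trial> crossing at sample %d (%.3f time units), W delay %.3f\n",
                x$crossing_idx, x$crossing_idx * x$params$dt, x$w_delay))
  }
  invisible(x)
}

#' 'W' delay between the two threshold crossings
#'
#' The model's 'W' time: the delay between the crossing of the
#' advance-warning threshold \eqn{\theta_w} and the activation threshold
#' \eqn{\theta}, expressed relative to the activation crossing (hence a
#' non-positive number, in time units). By default the *last* upward
#' crossing of \eqn{\theta_w} preceding the activation crossing is used
#' (the final approach to threshold); set
#' `accum_params(w_convention = "first")` for the earliest upward
#' crossing.
#'
#' @param trial An `accum_trial` with a threshold crossing.
#' @param params An [accum_params()] object (defaults to the trial's own).
#' @return Numeric delay `<= 0` (time units), with attribute
#'   `w_crossing_idx`. `NA` if the trial is censored.
#' @export
compute_w_delay <- function(trial, params = trial$params) {
  stopifnot(inherits(params, "accum_params"))
  if (params$w_threshold >= params$threshold) {
    stop("`w_threshold` must be below `threshold`", call. = FALSE)
  }
  ci <- trial$crossing_idx
  if (is.na(ci)) return(structure(NA_real_, w_crossing_idx = NA_integer_))
  x <- trial$output[seq_len(ci)]
  thw <- params$w_threshold
  above <- x >= thw
  prev_below <- c(trial$params$x0 < thw, !above[-length(above)])
  up <- which(above & prev_below)
  if (!length(up)) return(structure(NA_real_, w_crossing_idx = NA_integer_))
  wi <- if (params$w_convention == "last") up[length(up)] else up[1L]
  structure((wi - ci) * params$dt, w_crossing_idx = as.integer(wi))
}

#' Extract input- and output-locked epochs around the crossing
#'
#' Cuts fixed-length windows of the stochastic input and of the
#' accumulator output, both time-aligned to the sample at which the output
#' first crossed the activation threshold: from `pre` samples before to
#' `post` samples after the crossing (default 5000 and 500, i.e. -5 s to
#' +0.5 s at 1000 samples per second). Samples that precede the start of
#' the trial are returned as `NA` (missing); on short-wait trials the
#' early tail of an epoch is therefore missing.
#'
#' @param trial An `accum_trial` with a crossing.
#' @param pre,post Window extent in samples before/after the crossing.
#' @return A list of class `epoch_pair`: `input_epoch` and `output_epoch`
#'   (numeric vectors of length `pre + post + 1`), `offsets` (sample
#'   offsets `-pre:post`, 0 at the crossing), and `wait_time` (crossing
#'   time in time units).
#' @export
extract_epochs <- function(trial, pre = 5000L, post = 500L) {
  ci <- trial$crossing_idx
  if (is.na(ci)) stop("cannot extract epochs from a censored trial", call. = FALSE)
  idx <- (ci - pre):(ci + post)
  ok <- idx >= 1L & idx <= length(trial$output)
  take <- function(v) {
    out <- rep(NA_real_, length(idx))
    out[ok] <- v[idx[ok]]
    out
  }
  structure(
    list(input_epoch = take(trial$input), output_epoch = take(trial$output),
         offsets = seq.int(-pre, post), wait_time = ci * trial$params$dt),
    class = "epoch_pair"
  )
}

#' Run a batch of independent accumulator trials
#'
#' Simulates `n_trials` trials, each over an independently generated noise
#' series (per-trial seed derived from `master_seed` plus the trial
#' index), collects first-crossing times, 'W' delays, and (optionally)
#' input- and output-locked epochs. Censored trials are counted and
#' excluded from the crossing-time list and from the epoch matrices.
#'
#' @param params An [accum_params()] object.
#' @param noise_params A [noise_params()] object; its `n_samples` is
#'   raised to `params$max_samples + post` if smaller, and its `seed` is
#'   replaced per trial.
#' @param n_trials Number of trials (`>= 1`).
#' @param master_seed Integer master seed.
#' @param keep_epochs Collect epoch matrices? (Default `TRUE`; turn off to
#'   save memory when only crossing times and 'W' delays are needed.)
#' @param pre,post Epoch window in samples (see [extract_epochs()]).
#' @return An object of class `accum_batch`: a list with
#'   `crossing_times` (time units, crossed trials only), `w_delays`,
#'   `n_censored`, `n_trials`, `offsets`, and -- when `keep_epochs` --
#'   matrices `input_epochs`, `output_epochs` (trial x time, `NA` for
#'   missing samples).
#' @export
run_batch <- function(params, noise_params, n_trials, master_seed = 1L,
                      keep_epochs = TRUE, pre = 5000L, post = 500L) {
  stopifnot(inherits(params, "accum_params"),
            inherits(noise_params, "noise_params"))
  if (n_trials < 1) stop("`n_trials` must be at least 1", call. = FALSE)
  need <- smooth_length(params$max_samples + post, direction = 1L)  # FFT-friendly
  if (noise_params$n_samples < need) noise_params$n_samples <- need
  nt <- as.integer(n_trials)
  crossing <- rep(NA_real_, nt)
  wdel <- rep(NA_real_, nt)
  if (keep_epochs) {
    inp <- matrix(NA_real_, nt, pre + post + 1L)
    outp <- matrix(NA_real_, nt, pre + post + 1L)
  }
  for (i in seq_len(nt)) {
    np <- noise_params
    np$seed <- as.integer((master_seed + i) %% .Machine$integer.max)
    tr <- simulate_trial(params, generate_noise(np))
    if (tr$censored) next
    crossing[i] <- tr$crossing_idx * params$dt
    wdel[i] <- tr$w_delay
    if (keep_epochs) {
      ep <- extract_epochs(tr, pre = pre, post = post)
      inp[i, ] <- ep$input_epoch
      outp[i, ] <- ep$output_epoch
    }
  }
  crossed <- !is.na(crossing)
  if (!any(crossed)) {
    warning("all trials censored: empty crossing-time distribution", call. = FALSE)
  }
  out <- list(crossing_times = crossing[crossed], w_delays = wdel[crossed],
              n_censored = sum(!crossed), n_trials = nt,
              offsets = seq.int(-pre, post), params = params,
              noise_params = noise_params, master_seed = master_seed)
  if (keep_epochs) {
    out$input_epochs <- inp[crossed, , drop = FALSE]
    out$output_epochs <- outp[crossed, , drop = FALSE]
  }
  structure(out, class = "accum_batch")
}

#' @export
print.accum_batch <- function(x, ...) {
  cat(sprintf("<accum_batch> %d trials (%d censored)\n", x$n_trials, x$n_censored))
  if (length(x$crossing_times)) {
    cat(sprintf("  crossing times: mean %.2f, median %.2f, sd %.2f time units\n",
                mean(x$crossing_times), stats::median(x$crossing_times),
                stats::sd(x$crossing_times)))
    cat(sprintf("  W delays: mean %.3f (on %d trials with a defined delay)\n",
                mean(x$w_delays, na.rm = TRUE), sum(is.finite(x$w_delays))))
  }
  invisible(x)
}
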