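#' Average event-locked waveform across epochs
#'
#' Pointwise mean over a trials-by-time epoch matrix, excluding missing
#' (`NA`) samples per time point. `mode` selects which by-product of the
#' simulation is averaged when applied to an [run_batch()] result: the
#' stochastic input to the accumulator (`"rp_as_input"`) or its output,
#' the decision variable (`"rp_as_output"`).
#'
#' @param epochs An `accum_batch` (from [run_batch()]) or a numeric
#'   trials-by-time matrix.
#' @param mode `"rp_as_input"` or `"rp_as_output"` (ignored for a plain
#'   matrix).
#' @return Numeric vector: the pointwise mean waveform.
#' @export
average_event_locked <- function(epochs, mode = c("rp_as_input", "rp_as_output")) {
  mode <- match.arg(mode)
  m <- if (inherits(epochs, "accum_batch")) {
    if (is.null(epochs$input_epochs)) {
      stop("batch was run with `keep_epochs = FALSE`", call. = FALSE)
    }
    if (mode == "rp_as_input") epochs$input_epochs else epochs$output_epochs
  } else {
    epochs
  }
  if (!is.matrix(m) || nrow(m) == 0L) stop("no epochs to average", call. = FALSE)
  colMeans(m, na.rm = TRUE)
}

#' Normalized waiting-time histogram
#'
#' Histogram of waiting times over fixed bins, normalized to unit sum (a
#' discrete probability mass over the bins).
#'
#' @param times Waiting times (finite values are used; `NA` dropped).
#' @param breaks Bin edges (strictly increasing). Times outside the range
#'   are dropped.
#' @return Numeric vector of length `length(breaks) - 1` summing to 1.
#' @export
wait_histogram <- function(times, breaks) {
  times <- times[is.finite(times)]
  if (!length(times)) stop("no finite waiting times", call. = FALSE)
  h <- graphics::hist(times[times >= breaks[1] & times <= breaks[length(breaks)]],
                      breaks = breaks, plot = FALSE)$counts
  if (sum(h) == 0) stop("no waiting times fall inside the bins", call. = FALSE)
  h / sum(h)
}

#' Build a fit target from a waveform and waiting times
#'
#' Packages the two observables the model is fit to: an average
#' event-locked waveform on a fixed time grid and a normalized
#' waiting-time distribution on fixed bins.
#'
#' @param rp_waveform Average event-locked potential (amplitude units).
#' @param rp_times Time grid of the waveform (s, relative to the event;
#'   typically spanning `[-3, 0]`).
#' @param wait_times Per-trial waiting times (s) from which the density is
#'   built, or `NULL` if `wait_density` is supplied directly.
#' @param wait_breaks Histogram bin edges (default: 40 equal-width bins
#'   from 0 to the 99th percentile of `wait_times`).
#' @param wait_density Optional pre-computed density (unit sum) matching
#'   `wait_breaks`.
#' @param n_trials_represented Number of trials behind the target.
#' @return An object of class `fit_target`.
#' @export
fit_target <- function(rp_waveform, rp_times, wait_times = NULL,
                       wait_breaks = NULL, wait_density = NULL,
                       n_trials_represented = NA_integer_) {
  stopifnot(length(rp_waveform) == length(rp_times))
  if (is.null(wait_breaks)) {
    if (is.null(wait_times)) stop("supply `wait_times` or `wait_breaks`", call. = FALSE)
    hi <- stats::quantile(wait_times, 0.99, names = FALSE)
    wait_breaks <- seq(0, hi, length.out = 41L)
  }
  if (is.null(wait_density)) {
    wait_density <- wait_histogram(wait_times, wait_breaks)
  }
  if (any(wait_density < 0)) stop("negative waiting-time density", call. = FALSE)
  wait_density <- wait_density / sum(wait_density)
  structure(
    list(rp_waveform = rp_waveform, rp_times = rp_times,
         wait_breaks = wait_breaks, wait_density = wait_density,
         n_trials_represented = as.integer(n_trials_represented)),
    class = "fit_target"
  )
}

## Simulate the model at `par` (list with beta, I, k, threshold) and return
## the two predicted blocks on the target's grids plus the LS amplitude scale.
simulate_prediction <- function(par, target, mode, n_sim_trials, seed,
                                noise_kind = "powerlaw", cutoff_hz = 1,
                                max_samples = 60000L, dt = 0.001) {
  ap <- accum_params(I = par$I, k = par$k, threshold = par$threshold,
                     dt = dt, max_samples = max_samples)
  np <- noise_params(beta = par$beta, n_samples = max_samples + 500L,
                     kind = noise_kind, cutoff_hz = cutoff_hz,
                     standardize = FALSE, fs = 1 / dt)
  pre <- ceiling(-min(target$rp_times) / dt) + 1L
  b <- run_batch(ap, np, n_trials = n_sim_trials, master_seed = seed,
                 keep_epochs = TRUE, pre = pre, post = 0L)
  if (!length(b$crossing_times)) return(NULL)
  m <- if (mode == "rp_as_input") b$input_epochs else b$output_epochs
  avg <- colMeans(m, na.rm = TRUE)
  ## per-time-point variance of the simulated mean (Monte-Carlo error)
  nok <- colSums(is.finite(m))
  vavg <- (colMeans(m^2, na.rm = TRUE) - avg^2) / pmax(nok - 1, 1)
  sim_times <- b$offsets * dt
  wf <- stats::approx(sim_times, avg, xout = target$rp_times, rule = 2)$y
  vwf <- stats::approx(sim_times, vavg, xout = target$rp_times, rule = 2)$y
  ## all crossings outside the target bins is a (penalized) misfit, not an error
  dens <- tryCatch(wait_histogram(b$crossing_times, target$wait_breaks),
                   error = function(e) NULL)
  if (is.null(dens)) return(NULL)
  ## least-squares amplitude scale and offset of the model waveform onto
  ## the target (the absolute level of a scalp potential is reference-
  ## dependent, so only the shape is compared)
  y <- target$rp_waveform
  ok <- is.finite(wf) & is.finite(y)
  wc <- wf[ok] - mean(wf[ok])
  yc <- y[ok] - mean(y[ok])
  amp <- if (sum(wc^2) > 0) sum(yc * wc) / sum(wc^2) else 1
  offset <- mean(y[ok]) - amp * mean(wf[ok])
  list(waveform = wf, waveform_mc_var = vwf, density = dens,
       amp_scale = amp, offset = offset,
       n_crossed = length(b$crossing_times), n_censored = b$n_censored)
}

#' Objective: mean-squared error of the simultaneous fit
#'
#' Simulates the model at the given parameters and scores the discrepancy
#' between (a) the simulated event-locked average (input or output,
#' amplitude-scaled and offset by least squares: a scalp potential's
#' absolute level is reference-dependent) and the target waveform, and (b)
#' the simulated normalized first-crossing-time distribution and the
#' target waiting-time density. Each residual block is divided by the
#' root-mean-square of its target block, so neither observable dominates,
#' and the mean of all squared residuals is returned. The simulation seed
#' is fixed per evaluation (common random numbers), making the objective
#' a deterministic function of the parameters.
#'
#' @param par Named list or vector with `beta`, `I`, `k`, `threshold`.
#' @param target A [fit_target()].
#' @param mode `"rp_as_input"` or `"rp_as_output"`.
#' @param n_sim_trials Monte-Carlo size per evaluation (default `1000`).
#' @param seed Evaluation seed.
#' @param noise_kind `"powerlaw"` or `"lowpass_white"` (the comparison
#'   input family); `cutoff_hz` applies to the latter.
#' @param cutoff_hz Low-pass cutoff for `noise_kind = "lowpass_white"`.
#' @param max_samples,dt Simulation extent and step.
#' @return The mean-squared error (a large finite penalty, `1e6`, if the
#'   simulation yields no threshold crossings).
#' @export
accum_objective <- function(par, target, mode = c("rp_as_input", "rp_as_output"),
                            n_sim_trials = 1000L, seed = 1L,
                            noise_kind = "powerlaw", cutoff_hz = 1,
                            max_samples = 60000L, dt = 0.001) {
  mode <- match.arg(mode)
  par <- as.list(par)
  sp <- simulate_prediction(par, target, mode, n_sim_trials, seed,
                            noise_kind, cutoff_hz, max_samples, dt)
  if (is.null(sp)) return(1e6)
  rw <- (target$rp_waveform - sp$offset - sp$amp_scale * sp$waveform)
  rd <- (target$wait_density - sp$density)
  sw <- stats::sd(target$rp_waveform)
  sd_ <- sqrt(mean(target$wait_density^2))
  if (sw == 0 || !is.finite(sw)) sw <- 1
  if (sd_ == 0) sd_ <- 1
  ## each block is debiased by an estimate of its own Monte-Carlo error:
  ## the simulated average's sampling variance shrinks as the input noise
  ## does, and without the correction a finite simulation systematically
  ## scores smoother (higher-beta) parameterizations too well
  wf_mc <- sp$amp_scale^2 * mean(sp$waveform_mc_var, na.rm = TRUE) / sw^2
  p <- sp$density
  dens_mc <- mean(p * (1 - p)) / (sp$n_crossed * sd_^2)
  wf_block <- max(0, mean((rw / sw)^2) - wf_mc)
  dens_block <- max(0, mean((rd / sd_)^2) - dens_mc)
  ## equal block weights: the waveform grid is ~60x denser than the
  ## histogram, so a pooled mean would let it dominate
  (wf_block + dens_block) / 2
}

## parameter transforms: simplex searches an unconstrained space
par_to_z <- function(par, lower, upper) {
  z <- numeric(length(par))
  for (i in seq_along(par)) {
    p <- (par[i] - lower[i]) / (upper[i] - lower[i])
    p <- min(max(p, 1e-6), 1 - 1e-6)
    z[i] <- log(p / (1 - p))
  }
  z
}
z_to_par <- function(z, lower, upper) {
  lower + (upper - lower) / (1 + exp(-z))
}

#' Fit the accumulator model to a waveform and waiting-time distribution
#'
#' Simultaneously fits the leaky stochastic accumulator to a target
#' event-locked waveform and a target waiting-time density by Nelder-Mead
#' minimization of the mean-squared error ([accum_objective()]). Free
#' parameters (any subset of `beta`, `I`, `k`, `threshold`) are searched
#' through a logistic transform of box constraints, so the simplex is
#' unconstrained while returned parameters always respect the bounds; the
#' amplitude scaling of the waveform is profiled out analytically at each
#' evaluation. A coarse grid pre-search supplies starting values, the
#' best `restarts` grid points seed independent simplex runs, and the
#' winning fit is re-evaluated at `n_final_trials` simulated trials.
#'
#' @param target A [fit_target()].
#' @param mode Whether the scalp waveform is modelled as the accumulator's
#'   stochastic input (`"rp_as_input"`) or its output (`"rp_as_output"`).
#' @param free Character vector of free parameters (default
#'   `c("beta", "I", "k", "threshold")`).
#' @param init Named list of starting/fixed parameter values (defaults to
#'   the reference configuration).
#' @param lower,upper Named numeric bounds for the free parameters.
#' @param n_sim_trials Monte-Carlo size per objective evaluation.
#' @param n_final_trials Monte-Carlo size of the final re-evaluation.
#' @param grid_points Number of grid values per free parameter in the
#'   pre-search (default `3`).
#' @param restarts Simplex restarts from the best grid points (default `3`).
#' @param maxit Maximum function evaluations per restart (default `150`).
#' @param seed Evaluation seed (common random numbers across evaluations).
#' @param noise_kind,cutoff_hz Input-noise family (see [accum_objective()]).
#' @param max_samples,dt Simulation extent and step.
#' @return An object of class `accum_fit` with components `par` (named
#'   vector: all four model parameters), `amp_scale`, `mse` (at
#'   `n_final_trials`), `mse_search` (best objective during the search),
#'   `mode`, `free`, `convergence`, `trace` (data frame of evaluations),
#'   `target`, and the call configuration. Methods: `print`, `summary`,
#'   `coef`, `predict`, `residuals`, `plot`, `simulate`.
#' @examples
#' \donttest{
#' ref <- accum_params()
#' np <- noise_params(beta = 1.4, standardize = FALSE)
#' b <- run_batch(ref, np, n_trials = 400, master_seed = 42, pre = 3000, post = 0)
#' tg <- fit_target(average_event_locked(b, "rp_as_input"),
#'                  b$offsets * ref$dt, wait_times = b$crossing_times)
#' f <- accum_fit(tg, mode = "rp_as_input", free = "beta",
#'                n_sim_trials = 200, n_final_trials = 400, maxit = 40)
#' coef(f)
#' }
#' @export
accum_fit <- function(target, mode = c("rp_as_input", "rp_as_output"),
                      free = c("beta", "I", "k", "threshold"),
                      init = list(beta = 1.4, I = 0.1, k = 0.6, threshold = 0.1256),
                      lower = c(beta = 0, I = 0.02, k = 0.1, threshold = 0.02),
                      upper = c(beta = 2.9, I = 0.3, k = 2, threshold = 0.3),
                      n_sim_trials = 1000L, n_final_trials = 10000L,
                      grid_points = 3L, restarts = 3L, maxit = 150L,
                      seed = 1L, noise_kind = "powerlaw", cutoff_hz = 1,
                      max_samples = 60000L, dt = 0.001) {
  mode <- match.arg(mode)
  stopifnot(inherits(target, "fit_target"))
  if (length(free)) {
    free <- match.arg(free, c("beta", "I", "k", "threshold"), several.ok = TRUE)
  } else {
    free <- character(0)  # amplitude-only: evaluate at `init`, no simplex
  }
  fixed <- setdiff(c("beta", "I", "k", "threshold"), free)
  if (!all(vapply(init, is.finite, logical(1)))) {
    stop("non-finite starting values", call. = FALSE)
  }
  lo <- lower[free]; up <- upper[free]

  trace_env <- new.env()
  trace_env$rows <- list()
  obj_free <- function(vals) {
    par <- init
    par[free] <- as.list(vals)
    m <- accum_objective(par, target, mode, n_sim_trials, seed,
                         noise_kind, cutoff_hz, max_samples, dt)
    trace_env$rows[[length(trace_env$rows) + 1L]] <-
      c(unlist(par[c("beta", "I", "k", "threshold")]), mse = m)
    m
  }

  if (length(free) == 0L) {
    mse0 <- obj_free(numeric(0))
    best <- list(vals = numeric(0), mse = mse0, convergence = 0L)
    conv <- 0L
  } else if (length(free) == 1L) {
    ## one-dimensional search: golden-section/Brent on the box
    opt <- stats::optimize(function(v) obj_free(stats::setNames(v, free)),
                           interval = c(lo, up),
                           tol = 1e-3 * (up - lo))
    best <- list(vals = stats::setNames(opt$minimum, free),
                 mse = opt$objective, convergence = 0L)
    conv <- 0L
  } else {
  ## coarse grid pre-search for starting values
  grids <- lapply(free, function(p) {
    seq(lo[p], up[p], length.out = grid_points + 2L)[-c(1L, grid_points + 2L)]
  })
  names(grids) <- free
  cand <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  start_vals <- unlist(init[free])
  cand <- rbind(start_vals, cand)
  gscore <- apply(cand, 1L, obj_free)
  ord <- order(gscore)
  starts <- cand[ord[seq_len(min(restarts, nrow(cand)))], , drop = FALSE]

  best <- NULL
  conv <- 1L
  for (r in seq_len(nrow(starts))) {
    z0 <- par_to_z(starts[r, ], lo, up)
    opt <- stats::optim(z0, function(z) obj_free(z_to_par(z, lo, up)),
                        method = "Nelder-Mead",
                        control = list(maxit = maxit))
    pr <- z_to_par(opt$par, lo, up)
    cand_fit <- list(vals = pr, mse = opt$value, convergence = opt$convergence)
    better <- is.null(best) || cand_fit$mse < best$mse ||
      (cand_fit$mse == best$mse && "beta" %in% free &&
         cand_fit$vals["beta"] < best$vals["beta"])  # ties: smaller beta
    if (better) { best <- cand_fit; conv <- opt$convergence }
  }
  }

  par_out <- init
  par_out[free] <- as.list(best$vals)
  par_out <- unlist(par_out[c("beta", "I", "k", "threshold")])

  ## final re-evaluation at larger Monte-Carlo size
  sp <- simulate_prediction(as.list(par_out), target, mode, n_final_trials,
                            seed, noise_kind, cutoff_hz, max_samples, dt)
  final_mse <- accum_objective(as.list(par_out), target, mode, n_final_trials,
                               seed, noise_kind, cutoff_hz, max_samples, dt)
  tr <- as.data.frame(do.call(rbind, trace_env$rows))
  structure(
    list(par = par_out, amp_scale = if (is.null(sp)) NA_real_ else sp$amp_scale,
         mse = final_mse, mse_search = best$mse, mode = mode, free = free,
         fixed = fixed, convergence = conv, trace = tr, target = target,
         time_scale = dt, n_sim_trials = n_sim_trials,
         n_final_trials = n_final_trials, seed = seed,
         noise_kind = noise_kind, cutoff_hz = cutoff_hz,
         max_samples = max_samples, dt = dt,
         lower = lower, upper = upper),
    class = "accum_fit"
  )
}

#' @export
print.accum_fit <- function(x, digits = 4, ...) {
  cat("Leaky stochastic accumulator fit (", x$mode, ")\n", sep = "")
  cat("  noise family:", x$noise_kind, "\n")
  print(round(x$par, digits))
  cat(sprintf("  amp_scale = %.4g, MSE = %.5g (%d trials)\n",
              x$amp_scale, x$mse, x$n_final_trials))
  invisible(x)
}

#' @export
coef.accum_fit <- function(object, ...) {
  c(object$par, amp_scale = object$amp_scale)
}

#' @export
summary.accum_fit <- function(object, ...) {
  cat("Simultaneous fit of event-locked waveform and waiting-time distribution\n")
  cat(sprintf("  mode: %s | noise: %s | free: %s\n", object$mode,
              object$noise_kind, paste(object$free, collapse = ", ")))
  print(round(coef(object), 4))
  cat(sprintf("  search MSE %.5g (%d trials/eval, %d evaluations); final MSE %.5g (%d trials)\n",
              object$mse_search, object$n_sim_trials, nrow(object$trace),
              object$mse, object$n_final_trials))
  if (object$convergence != 0L) {
    cat("  note: simplex did not converge within `maxit`; best-so-far returned\n")
  }
  invisible(object)
}

#' Predicted waveform and waiting-time density of a fitted accumulator
#'
#' Re-simulates the model at the fitted parameters and returns the
#' predicted (amplitude-scaled) event-locked waveform on the target's
#' time grid and the predicted normalized first-crossing density on the
#' target's bins.
#'
#' @param object An `accum_fit`.
#' @param n_sim_trials Monte-Carlo size (default: the fit's final size).
#' @param seed Simulation seed (default: the fit's evaluation seed).
#' @param ... Unused.
#' @return A list with `waveform`, `times`, `density`, `breaks`.
#' @export
predict.accum_fit <- function(object, n_sim_trials = object$n_final_trials,
                              seed = object$seed, ...) {
  sp <- simulate_prediction(as.list(object$par), object$target, object$mode,
                            n_sim_trials, seed, object$noise_kind,
                            object$cutoff_hz, object$max_samples, object$dt)
  if (is.null(sp)) stop("no crossings at the fitted parameters", call. = FALSE)
  list(waveform = sp$offset + sp$amp_scale * sp$waveform,
       times = object$target$rp_times,
       density = sp$density, breaks = object$target$wait_breaks)
}

#' @export
residuals.accum_fit <- function(object, ...) {
  p <- predict(object, ...)
  list(waveform = object$target$rp_waveform - p$waveform,
       density = object$target$wait_density - p$density)
}

#' Simulate trials from a fitted accumulator
#'
#' @param object An `accum_fit`.
#' @param nsim Number of trials.
#' @param seed Master seed.
#' @param ... Unused.
#' @return An `accum_batch` (see [run_batch()]).
#' @export
simulate.accum_fit <- function(object, nsim = 1000L, seed = 1L, ...) {
  ap <- accum_params(I = object$par[["I"]], k = object$par[["k"]],
                     threshold = object$par[["threshold"]],
                     dt = object$dt, max_samples = object$max_samples)
  np <- noise_params(beta = object$par[["beta"]],
                     n_samples = object$max_samples + 500L,
                     kind = object$noise_kind, cutoff_hz = object$cutoff_hz,
                     standardize = FALSE, fs = 1 / object$dt)
  run_batch(ap, np, n_trials = nsim, master_seed = seed)
}

#' @export
plot.accum_fit <- function(x, ...) {
  p <- predict(x)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  mids <- (p$breaks[-1] + p$breaks[-length(p$breaks)]) / 2
  graphics::plot(mids, x$target$wait_density, type = "l", col = "grey55", lwd = 2,
                 xlab = "waiting time (s)", ylab = "normalized density",
                 main = "first-crossing times")
  graphics::lines(mids, p$density, lty = 2, lwd = 2)
  graphics::plot(x$target$rp_times, x$target$rp_waveform, type = "l",
                 col = "grey55", lwd = 2, xlab = "time to crossing (s)",
                 ylab = "amplitude", main = sprintf("event-locked fit (%s)", x$mode))
  graphics::lines(x$target$rp_times, p$waveform, lty = 2, lwd = 2)
  invisible(x)
}
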