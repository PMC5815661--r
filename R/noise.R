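#' Noise-generator parameter set
#'
#' Bundles the parameters describing one stochastic input series: its 1/f
#' exponent, length, scaling, family (power-law shaped vs low-pass filtered
#' white noise) and RNG seed. `noise_params()` validates and returns a
#' `noise_params` object accepted by [generate_noise()] and [run_batch()].
#'
#' @param beta 1/f exponent of the target power spectrum (unitless). Power is
#'   shaped as \eqn{P(f) \propto f^{-\beta}}; must satisfy `0 <= beta < 3`.
#'   Ignored when `kind = "lowpass_white"`.
#' @param n_samples Series length in samples (`>= 2`).
#' @param c Noise scaling factor applied by the accumulator (unitless,
#'   default `0.1`). Carried here so a single object describes the input.
#' @param kind `"powerlaw"` (FFT spectral shaping) or `"lowpass_white"`
#'   (Butterworth low-pass filtered white noise).
#' @param cutoff_hz Low-pass cutoff in Hz (only for `kind = "lowpass_white"`;
#'   must lie strictly below the Nyquist frequency `fs/2`).
#' @param filter_order Butterworth filter order (default `1`).
#' @param fs Nominal sampling rate in Hz (default `1000`, the simulation
#'   rate: 1000 samples per second).
#' @param seed Integer RNG seed; every generated series is reproducible.
#' @param standardize Logical; if `TRUE` (default) emitted series are
#'   re-standardized to zero mean and unit variance after shaping/filtering.
#'   If `FALSE` the raw output of the shaping filter is returned (the form
#'   the accumulator integrates over; see [shape_spectrum()]).
#'
#' @return An object of class `noise_params` (a named list).
#' @seealso [generate_noise()], [shape_spectrum()], [lowpass_white()]
#' @export
noise_params <- function(beta = 1.4, n_samples = 60500, c = 0.1,
                         kind = c("powerlaw", "lowpass_white"),
                         cutoff_hz = 1, filter_order = 1L, fs = 1000,
                         seed = 1L, standardize = TRUE) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(n_samples), length(n_samples) == 1L)
  if (n_samples < 2) stop("`n_samples` must be at least 2", call. = FALSE)
  if (kind == "powerlaw") {
    if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) ||
        beta < 0 || beta >= 3) {
      stop("`beta` must lie in [0, 3)", call. = FALSE)
    }
  } else {
    if (!is.finite(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
      stop("`cutoff_hz` must lie in (0, fs/2)", call. = FALSE)
    }
  }
  structure(
    list(beta = beta, n_samples = as.integer(n_samples), c = c, kind = kind,
         cutoff_hz = cutoff_hz, filter_order = as.integer(filter_order),
         fs = fs, seed = as.integer(seed), standardize = isTRUE(standardize)),
    class = "noise_params"
  )
}

#' @export
print.noise_params <- function(x, ...) {
  if (x$kind == "powerlaw") {
    cat(sprintf("<noise_params> powerlaw: beta = %g, n = %d, c = %g, seed = %d\n",
                x$beta, x$n_samples, x$c, x$seed))
  } else {
    cat(sprintf(
      "<noise_params> lowpass_white: cutoff = %g Hz (order %d, fs = %g), n = %d, seed = %d\n",
      x$cutoff_hz, x$filter_order, x$fs, x$n_samples, x$seed))
  }
  invisible(x)
}

## Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate Gaussian white noise
#'
#' Independent standard-Gaussian draws, reproducible for a fixed seed. This
#' is the raw material that [shape_spectrum()] colours into 1/f noise.
#'
#' @param params A [noise_params()] object (only `n_samples` and `seed` are
#'   used).
#' @return Numeric vector of length `params$n_samples`.
#' @export
generate_white <- function(params) {
  stopifnot(inherits(params, "noise_params"))
  if (params$n_samples < 2) stop("series length must be at least 2", call. = FALSE)
  with_seed(params$seed, stats::rnorm(params$n_samples))
}

#' Impose a 1/f power spectrum on a time series
#'
#' Shapes the power spectrum of `x` to \eqn{P \propto f^{-\beta}} by FFT:
#' the series is transformed to the frequency domain, the coefficient at
#' physical frequency \eqn{f} is multiplied by \eqn{(f/f_0)^{-\beta/2}}
#' (so power falls log-linearly with slope \eqn{-\beta}), conjugate
#' symmetry is preserved, and the result is transformed back. Phases of
#' the input are untouched. The DC coefficient is set to zero (its
#' multiplier diverges), so the output is mean-zero by construction.
#'
#' The pivot frequency \eqn{f_0} (unit filter gain; default 1/60.5 Hz,
#' the fundamental of the default 60.5-s simulated trial) anchors the
#' filter's absolute gain, making series of different lengths and rates
#' spectrally consistent: a shorter series simply lacks the frequencies
#' below its own fundamental.
#'
#' With `standardize = TRUE` the output is rescaled to unit variance (the
#' pivot is then irrelevant), so a downstream noise scale keeps a fixed
#' meaning across `beta`. With `standardize = FALSE` the raw filter
#' output is returned: the shaping then attenuates total power as `beta`
#' grows (multipliers above the pivot are below 1, and nearly the whole
#' band lies above it), which is the form the accumulator integrates
#' over -- see the package vignette for why the two forms are
#' distinguished.
#'
#' @param x Numeric vector (finite values).
#' @param beta 1/f exponent in `[0, 3)`.
#' @param standardize Re-standardize the output to zero mean, unit
#'   variance? Default `TRUE`.
#' @param fs Sampling rate in Hz (default `1000`, the simulation rate).
#' @param f_pivot Pivot frequency in Hz at which the filter gain is 1
#'   (default `1/60.5`).
#' @return Numeric vector, same length as `x`.
#' @examples
#' w <- generate_white(noise_params(n_samples = 4096, seed = 1))
#' p <- shape_spectrum(w, beta = 1.4)
#' var(p)  # ~1
#' @export
shape_spectrum <- function(x, beta, standardize = TRUE, fs = 1000,
                           f_pivot = 1 / 60.5) {
  if (!all(is.finite(x))) stop("input series contains non-finite values", call. = FALSE)
  if (!is.finite(beta) || beta < 0 || beta >= 3) {
    stop("`beta` must lie in [0, 3)", call. = FALSE)
  }
  n <- length(x)
  if (n < 2) stop("series length must be at least 2", call. = FALSE)
  X <- stats::fft(x)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n          # physical frequency, symmetric
  mult <- ifelse(f > 0, (f / f_pivot)^(-beta / 2), 0)
  y <- Re(stats::fft(X * mult, inverse = TRUE)) / n
  y <- y - mean(y)                      # DC removed; guard rounding
  if (standardize) y <- y / stats::sd(y)
  y
}

#' Low-pass filtered white noise
#'
#' White Gaussian noise passed through a Butterworth low-pass filter of the
#' given order and cutoff -- the comparison input family for the
#' accumulator (a crude alternative to power-law noise that also
#' suppresses high frequencies).
#'
#' @param params A [noise_params()] object with `kind = "lowpass_white"`.
#' @return Numeric vector of length `params$n_samples` (standardized to
#'   zero mean and unit variance unless `params$standardize` is `FALSE`).
#' @export
lowpass_white <- function(params) {
  stopifnot(inherits(params, "noise_params"))
  if (params$kind != "lowpass_white") {
    stop("`params$kind` must be \"lowpass_white\"", call. = FALSE)
  }
  if (params$cutoff_hz >= params$fs / 2) {
    stop("`cutoff_hz` must be below the Nyquist frequency", call. = FALSE)
  }
  w <- with_seed(params$seed, stats::rnorm(params$n_samples))
  bf <- signal::butter(params$filter_order, params$cutoff_hz / (params$fs / 2),
                       type = "low")
  y <- as.numeric(signal::filter(bf, w))
  y <- y - mean(y)
  if (params$standardize) y <- y / stats::sd(y)
  y
}

#' Generate a stochastic input series
#'
#' Dispatches on `params$kind`: spectrally shaped power-law noise
#' ([shape_spectrum()] applied to white noise) or Butterworth low-pass
#' filtered white noise ([lowpass_white()]).
#'
#' @param params A [noise_params()] object.
#' @return Numeric vector of length `params$n_samples`.
#' @export
generate_noise <- function(params) {
  stopifnot(inherits(params, "noise_params"))
  switch(params$kind,
    powerlaw = shape_spectrum(generate_white(params), params$beta,
                              standardize = params$standardize,
                              fs = params$fs),
    lowpass_white = lowpass_white(params)
  )
}
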