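#' Welch power spectral density
#'
#' Averaged modified periodogram: the series is split into Hann-tapered
#' segments with 50% overlap, each segment is demeaned, and the one-sided
#' periodograms are averaged.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate (Hz).
#' @param seglen Segment length in samples (default `4096`); shortened to
#'   `length(x)` if the series is shorter.
#' @param overlap Fractional overlap between segments (default `0.5`).
#' @return A list with `freq` (Hz, DC excluded) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, seglen = 4096L, overlap = 0.5) {
  n <- length(x)
  seglen <- min(as.integer(seglen), n)
  if (seglen < 8L) stop("series too short for a PSD estimate", call. = FALSE)
  step <- max(1L, as.integer(round(seglen * (1 - overlap))))
  starts <- seq.int(1L, n - seglen + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq.int(0L, seglen - 1L) / (seglen - 1L)) # Hann
  scale <- fs * sum(w^2)
  nf <- seglen %/% 2L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seglen - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg))^2 / scale
    half <- p[2:(nf + 1L)] * 2           # one-sided, DC dropped
    if (seglen %% 2L == 0L) half[nf] <- half[nf] / 2  # Nyquist bin not doubled
    acc <- acc + half
  }
  list(freq = seq_len(nf) * fs / seglen, psd = acc / length(starts))
}

#' Separate fractal and oscillatory spectral components (IRASA)
#'
#' Irregular-resampling auto-spectral analysis: for each resampling factor
#' `h` in `hset`, the series is resampled by `h` and by `1/h`
#' (exact band-limited Fourier resampling; spectral truncation is an
#' ideal anti-alias filter), the
#' Welch PSD of each resampled copy is computed on its own rate and
#' interpolated back onto the original frequency grid, and the geometric
#' mean of the pair is taken. A power-law (fractal) spectrum is invariant
#' under this operation while narrow-band oscillatory peaks are displaced
#' and suppressed; the median across `hset` is the fractal component, and
#' the residual (original PSD minus fractal) the oscillatory component.
#'
#' @param x Numeric time series.
#' @param fs Sampling rate (Hz).
#' @param hset Resampling factors, all `> 1` (default `seq(1.1, 1.9, 0.05)`,
#'   the method's reference set). Each `h` is paired with `1/h`. Factors
#'   are snapped to the nearest ratio of FFT-friendly lengths; the
#'   resulting constant power offset does not affect a log-log slope.
#' @param seglen,overlap Welch segmentation (see [welch_psd()]).
#' @return A list with `freq`, `psd` (the original Welch PSD),
#'   `fractal_psd` and `oscillatory_psd` on the same grid.
#' @export
irasa <- function(x, fs, hset = seq(1.1, 1.9, by = 0.05),
                  seglen = 4096L, overlap = 0.5) {
  if (any(hset <= 1)) stop("all `hset` factors must exceed 1", call. = FALSE)
  n <- length(x)
  if (n < max(hset) * seglen) {
    stop("series too short for the largest resampling factor", call. = FALSE)
  }
  ## truncate to an FFT-friendly length (at most ~2% shorter)
  n2 <- smooth_length(n, direction = -1L)
  x <- x[seq_len(n2)]
  X <- stats::fft(x)
  base <- welch_psd(x, fs, seglen, overlap)
  frac <- matrix(NA_real_, length(hset), length(base$freq))
  for (j in seq_along(hset)) {
    h <- hset[j]
    mu <- smooth_length(round(n2 * h))
    md <- smooth_length(round(n2 / h))
    h_up <- mu / n2                        # effective factors (within ~1%)
    h_dn <- n2 / md
    up <- resample_fft(X, n2, mu)          # bandlimited, rate fs * h_up
    dn <- resample_fft(X, n2, md)          # rate fs / h_dn
    pu <- welch_psd(up, fs * h_up, smooth_length(round(seglen * h)), overlap)
    pd <- welch_psd(dn, fs / h_dn, smooth_length(round(seglen / h)), overlap)
    gu <- stats::approx(pu$freq, pu$psd, xout = base$freq, rule = 2)$y
    gd <- stats::approx(pd$freq, pd$psd, xout = base$freq, rule = 2)$y
    frac[j, ] <- sqrt(gu * gd)
  }
  fractal <- apply(frac, 2L, stats::median)
  list(freq = base$freq, psd = base$psd, fractal_psd = fractal,
       oscillatory_psd = base$psd - fractal)
}

## Nearest 5-smooth integer (fast mixed-radix FFT size) at or near `m`.
smooth_length <- function(m, direction = 0L) {
  is_smooth <- function(v) {
    for (p in c(2L, 3L, 5L)) while (v %% p == 0L) v <- v %/% p
    v == 1L
  }
  m <- max(8L, as.integer(m))
  for (d in 0:(m %/% 4L)) {
    if (direction <= 0L && is_smooth(m - d)) return(m - d)
    if (direction >= 0L && is_smooth(m + d)) return(m + d)
  }
  m
}

## Exact bandlimited resampling of a series (given its FFT `X` of length
## `n`) to length `m`: the spectrum is truncated (m < n; an ideal
## anti-alias low-pass) or zero-padded (m > n) and inverted.
resample_fft <- function(X, n, m) {
  keep <- min(n, m) %/% 2L
  Y <- complex(m)
  Y[1:keep] <- X[1:keep]                      # DC .. keep-2 th positive bin
  Y[(m - keep + 2L):m] <- X[(n - keep + 2L):n]  # matching negative bins
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Log-log spectral slope by ordinary least squares
#'
#' Fits `log10(psd) ~ log10(freq)` over a frequency band by OLS and
#' returns the sign-reversed slope: the estimated 1/f exponent.
#'
#' @param freqs Frequencies (Hz).
#' @param psd Power values (`> 0` on the band).
#' @param band Length-2 numeric `[f_lo, f_hi]` in Hz.
#' @return Sign-reversed OLS slope (the 1/f exponent \eqn{\hat\beta}).
#' @examples
#' f <- 1:100
#' fit_loglog_slope(f, f^-2, c(1, 100))  # exactly 2
#' @export
fit_loglog_slope <- function(freqs, psd, band) {
  sel <- freqs >= band[1] & freqs <= band[2] & is.finite(psd)
  if (sum(sel) < 3L) stop("fewer than 3 frequency bins in the fit band", call. = FALSE)
  if (any(psd[sel] <= 0)) stop("non-positive power in the fit band", call. = FALSE)
  co <- stats::lsfit(log10(freqs[sel]), log10(psd[sel]))$coefficients
  -unname(co[2L])
}

#' Estimate the 1/f exponent of a time series
#'
#' The aperiodic (fractal) spectral exponent: the sign-reversed slope of
#' the OLS line fit, in log-log coordinates, to the fractal component of
#' the power spectrum obtained by [irasa()].
#'
#' @param x Numeric time series.
#' @param fs Sampling rate in Hz.
#' @param band Fit band `[f_lo, f_hi]` in Hz (default `c(0.1, 25)`, the
#'   resolvable band of 250-Hz epochs clear of DC and of resampling edge
#'   effects).
#' @param hset,seglen,overlap Passed to [irasa()].
#' @return An object of class `spectral_estimate`: a list with
#'   `beta_hat`, `freqs`, `fractal_psd`, `oscillatory_psd`, `psd`,
#'   `fit_band`, `n_segments`.
#' @examples
#' \donttest{
#' xi <- shape_spectrum(generate_white(noise_params(n_samples = 2^16, seed = 7)), 1.4)
#' estimate_beta(xi, fs = 250)$beta_hat  # ~1.4
#' }
#' @export
estimate_beta <- function(x, fs, band = c(0.1, 25),
                          hset = seq(1.1, 1.9, by = 0.05),
                          seglen = 4096L, overlap = 0.5) {
  ir <- irasa(x, fs, hset = hset, seglen = seglen, overlap = overlap)
  bh <- fit_loglog_slope(ir$freq, ir$fractal_psd, band)
  structure(
    list(beta_hat = bh, freqs = ir$freq, fractal_psd = ir$fractal_psd,
         oscillatory_psd = ir$oscillatory_psd, psd = ir$psd,
         fit_band = band,
         n_segments = max(1L, (length(x) - seglen) %/% (seglen %/% 2L) + 1L)),
    class = "spectral_estimate"
  )
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf("<spectral_estimate> beta_hat = %.3f (band %.2g-%.2g Hz, %d segments)\n",
              x$beta_hat, x$fit_band[1], x$fit_band[2], x$n_segments))
  invisible(x)
}

#' @export
plot.spectral_estimate <- function(x, ...) {
  graphics::plot(x$freqs, x$psd, log = "xy", type = "l", col = "grey60",
                 xlab = "frequency (Hz)", ylab = "power",
                 main = sprintf("fractal spectral fit: beta_hat = %.2f", x$beta_hat),
                 ...)
  graphics::lines(x$freqs, x$fractal_psd, col = "black", lwd = 2)
  graphics::abline(v = x$fit_band, lty = 3)
  invisible(x)
}
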