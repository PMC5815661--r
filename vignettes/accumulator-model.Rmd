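---
title: "A leaky stochastic accumulator with 1/f input noise: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A leaky stochastic accumulator with 1/f input noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(rpaccum)
```

## The problem this package addresses

Self-initiated movements are preceded by the readiness potential (RP), a
slow negative-going scalp potential that builds up for a second or more
before movement onset. One influential account treats movement initiation
as an accumulation-to-bound process: a leaky integrator accumulates a weak
constant imperative plus ongoing stochastic fluctuations, and movement is
triggered when its output first reaches a threshold. Under this account
the RP is not a fixed preparatory signal but the event-locked average of
ongoing activity, conditioned on a threshold crossing having occurred.

`rpaccum` implements a version of this account in which two usually
implicit choices are made explicit and testable:

1. **The spectral content of the stochastic input.** Neural noise is not
   white: its power spectrum falls off as $1/f^{\beta}$ with roughly
   $1 < \beta < 3$. The package treats $\beta$ as a model parameter,
   from $0$ (white) up to (but excluding) $3$.
2. **What the scalp electrode sees.** The RP may reflect the average
   *input* to the accumulator (its stochastic noise component plus the
   imperative) rather than its *output* (the decision variable). The two
   readings make opposite predictions about how the RP's shape varies
   with waiting time, so they can be told apart empirically.

The model connects three observables: the RP waveform, the distribution
of waiting times (trial start to button press), and the subjectively
reported time of the "urge to move" (the 'W' time, a negative number
relative to movement onset).

## The model

The decision variable $x$ evolves as

$$ dx = (I - k x)\,dt + c\,\xi_\beta\,\sqrt{dt}, $$

where $I$ is the drift rate (the imperative to move), $k$ the leak, $c$
a noise scale, and $\xi_\beta$ temporally autocorrelated noise with
spectral exponent $\beta$. A trial starts at $x_0 = 0$ and ends when $x$
first reaches the activation threshold $\theta$ (the model's movement
onset); a trial that never crosses within the allotted time is flagged
*censored* and excluded from crossing-time distributions and epoch
averages. The packaged reference configuration is $I = 0.1$, $k = 0.6$,
$c = 0.1$, $\theta = 0.1256$ with $\beta = 1.4$.

### Time units and discretization

Simulation runs at 1000 samples per second ($dt = 0.001$ s), so the
rates $I$ and $k$ are per second and the epoch conventions (5000 samples
before a crossing to 500 after) span $-5$ to $+0.5$ s. With the
reference parameters the noiseless system crosses at
$t^\ast = -\tfrac{1}{k}\log(1 - k\theta/I) \approx 2.335$ s, and the
simulated trajectory matches the closed form
$x(t) = \tfrac{I}{k}(1 - e^{-kt})$ to $O(dt)$; both facts are asserted
in the test suite.

The noise increment is scaled by $\sqrt{dt}$ (Euler–Maruyama). The choice
matters: at $\beta = 0$ it makes the model *exactly* the classic leaky
stochastic accumulator driven by white Gaussian noise, so the white-noise
limit of this package coincides with the model family it generalizes.
Scaling the noise by $dt$ instead would make white noise integrate to
essentially nothing at this step size, leaving the low-$\beta$ regime
quasi-deterministic.

### Generation of the 1/f input

Power-law noise is produced by FFT spectral shaping
(`shape_spectrum()`): a white Gaussian series is transformed to the
frequency domain, the coefficient at physical frequency $f$ is
multiplied by $(f/f_0)^{-\beta/2}$ — so power falls log-linearly with
slope $-\beta$ — conjugate symmetry is preserved, and the series is
transformed back. Phases are untouched; the DC coefficient is zeroed
(its multiplier diverges), making the output mean-zero by construction.
At $\beta = 0$ the filter is the identity. The pivot $f_0$ (unit gain;
1/60.5 Hz, the fundamental of the default 60.5-s trial) anchors the
filter's absolute gain so that series of different lengths are
spectrally consistent: a shorter trial simply lacks frequencies below
its own fundamental.

Two output conventions are exposed, and the distinction is a substantive
modelling choice:

* `standardize = TRUE` (the default for the public generator functions)
  rescales the output to unit variance. This is the right convention for
  *estimator* work: a noise series of known exponent and fixed amplitude.
* `standardize = FALSE` returns the raw filter output. Because nearly
  the whole band lies above the pivot (where multipliers are below 1),
  total power then *decreases* as $\beta$ grows: shaping a
  unit-variance white series is an attenuating filter, not a
  power-preserving recoloring.

**The accumulator integrates the unstandardized (filter) form.** This is
deliberate. Re-standardizing would make the effective noise amplitude
invariant in $\beta$, and the low-$\beta$ accumulator would then be
nearly noiseless at this step size — in that regime the model's
characteristic predictions (below) hold trivially at *every* exponent,
because each trial's trajectory is a smooth deterministic-like path. With
the filter convention the white-noise end of the scale is strongly
stochastic (matching the classic model) and the pink end is smooth and
slow, and the model's predictions genuinely *depend on the input being
pink*: the negative waiting-time/W-time correlation is absent for
$\beta \lesssim 0.3$ and grows steadily through the pink range, which is
the behaviour that motivates treating $\beta$ as a parameter in the
first place. The cost of this convention is that the effective noise
amplitude at fixed $c$ depends on $\beta$; the per-subject threshold
calibration in the synthetic-data generator absorbs this where absolute
time scales matter.

Low-pass filtered white noise (`lowpass_white()`; first-order
Butterworth, 1 Hz cutoff by default) is provided as the comparison input
family: a crude alternative way to suppress high frequencies, with a
$1/f^2$ roll-off far above the cutoff and unit DC gain.

### The 'W' time

A second, *advance-warning* threshold $\theta_w$ slightly below $\theta$
models the reported time of the urge to move: the model's 'W' is the
delay between the crossing of $\theta_w$ and the crossing of $\theta$,
expressed relative to the latter (hence $\le 0$). A steep final approach
gives a short delay (W close to movement onset); a shallow approach an
early W. Since trajectories can dip back below $\theta_w$ before the
final rise, a convention is needed: by default the **last** upward
crossing of $\theta_w$ before the activation crossing is used (the final
approach), because an early spurious touch followed by a retreat is a
poor "advance warning" of imminent movement. The first-ever crossing is
available via `accum_params(w_convention = "first")`. The default
$\theta_w = 0.9\,\theta$ is configurable and, in the synthetic cohort,
calibrated (below).

## Fitting the model

`accum_fit()` fits the model simultaneously to an average event-locked
waveform and a normalized waiting-time density (`fit_target()`), by
Nelder–Mead minimization of a mean-squared error:

* The model is simulated afresh at each parameter evaluation; the
  event-locked average (input- or output-locked, per `mode`) is
  interpolated onto the target's time grid and the first-crossing
  histogram onto the target's bins.
* The waveform's amplitude scale and offset are linear parameters, so
  they are profiled out analytically (ordinary least squares) at every
  evaluation rather than searched by the simplex. The offset is there
  because a scalp potential's absolute level is reference-dependent:
  only the shape is compared.
* The waveform and density residual blocks are each divided by the
  scale of their target block (the waveform's standard deviation; the
  density's root mean square) and enter with **equal weights**: the
  waveform grid has ~60 times more points than the histogram, so a
  pooled mean over concatenated residuals would let it dominate.
* Each block subtracts an estimate of its own Monte-Carlo sampling
  variance (clamped at zero). Under the filter noise convention the
  simulated average's sampling noise shrinks as $\beta$ grows, and an
  uncorrected finite-simulation objective mistakes that smoothness for
  fit quality, biasing $\beta$ upward; the correction makes comparisons
  across parameters with different intrinsic noise levels unbiased. The comparison window is the
  target's own grid, typically $[-3, 0]$ s where simulated epochs have
  low missingness; the density uses 40 equal-width bins up to the 99th
  percentile of the target times.
* Each evaluation uses a fixed simulation seed (common random numbers),
  making the objective a deterministic, relatively smooth function of
  the parameters. Default Monte-Carlo sizes are 1000 trials per
  evaluation and 10&nbsp;000 for the final re-evaluation of the winning
  parameters; the examples in this vignette and the test suite use
  smaller sizes (a few hundred trials, with a 20&nbsp;s trial cap) —
  these are the package's chosen problem sizes for illustrative work,
  and all tolerances quoted here were set with them.
* Free parameters (any subset of $\beta, I, k, \theta$) are searched
  through a logistic transform of box constraints, so the unconstrained
  simplex can never propose out-of-bounds values. A coarse grid
  pre-search supplies starting points; the best grid points seed
  independent simplex restarts (ties between restarts broken toward
  smaller $\beta$); a single free parameter is optimized by
  golden-section/Brent search instead, which is more reliable in one
  dimension. A simulation yielding no crossings scores a large finite
  penalty rather than an error.

```{r fit-example, eval = FALSE}
## a self-contained parameter-recovery run (a few minutes at this scale)
tgb <- run_batch(accum_params(max_samples = 20000L),
                 noise_params(beta = 1.4, standardize = FALSE),
                 n_trials = 600, master_seed = 909, pre = 2500L, post = 0L)
tg <- fit_target(average_event_locked(tgb, "rp_as_input"),
                 tgb$offsets * 0.001, wait_times = tgb$crossing_times)
f <- accum_fit(tg, mode = "rp_as_input", free = "beta",
               n_sim_trials = 200, n_final_trials = 400,
               seed = 404, max_samples = 20000L)
coef(f)
plot(f)
```

## Estimating the 1/f exponent

`estimate_beta()` returns the sign-reversed slope of an ordinary
least-squares line fit, in log–log coordinates, to the *fractal*
component of the power spectrum, separated from oscillatory structure by
IRASA (`irasa()`): for each factor $h$ in a set of irregular resampling
factors, the series is resampled by $h$ and by $1/h$, the geometric mean
of the two Welch spectra is taken on the original frequency grid, and
the median across factors is the fractal component. A power law is
invariant under this operation; narrow-band peaks are displaced and
suppressed.

Defaults follow the method's reference implementation: $h$ from 1.1 to
1.9 in steps of 0.05; Welch segments of 4096 samples, 50% overlap, Hann
taper; fit band 0.1–25 Hz at a 250 Hz sampling rate. Resampling is exact
band-limited (Fourier) resampling; target lengths are snapped to
FFT-friendly (5-smooth) sizes, which perturbs each factor by well under
1% and changes the fractal component only by a constant multiplicative
offset — invisible to a log–log slope. The estimate is scale invariant
and recovers the generation exponent of shaped noise to better than
$\pm 0.1$ at $2^{17}$ samples.

For epoched data, `estimate_cohort_beta()` concatenates each subject's
epochs and uses segments no longer than one epoch and a fit band from
0.5 Hz: epoch splices destroy coherent power at periods longer than an
epoch, so a continuous-series configuration would underestimate steep
exponents. Even so, exponents above roughly 2 are compressed toward 2 by
the finite (4.5 s) epoch length; group-level summaries should keep this
ceiling in mind.

## The statistical procedures

Two qualitative predictions distinguish the RP-as-input and RP-as-output
readings; both are implemented as reusable procedures.

**Waveform shape by waiting time.** Trials are split at the 33rd and
67th waiting-time percentiles (nearest rank; boundary ties join the
adjacent extreme group; the middle third is dropped; an all-tied split
is an error, not a silent overlap). `compare_terciles()` tests the
short/long difference pointwise and over a declared window (default
$[-1.5, -0.5]$ s), either across trials (rank-sum; single synthetic
subjects) or across subjects (each subject's tercile means as the paired
unit, signed-rank; the group-level mode matching an $N = 14$ study).
Under the model, the *input*-locked average has a **lower** early
amplitude for long waits, the *output*-locked average a **higher** one —
time-locking to the crossing reverses the relationship. All "lower /
higher" statements in the package and its tests are expressed on the
positive-going (sign-reversed relative to the scalp) scale to avoid
double-negation mistakes; empirical-convention waveforms are negative-
going and should be negated before comparison with model averages.

**Cluster-corrected pointwise tests.** `cluster_permutation()` corrects
the pointwise paired signed-rank tests across time: clusters are runs of
contiguous points with uncorrected two-sided $p$ below 0.05 (the
forming threshold), the cluster statistic is the sum of the pointwise
signed-rank statistics, the null is built from random within-subject
sign flips (1000 permutations by default), and positive and negative
clusters are referred to the permutation distribution of the maximum
absolute cluster statistic. Because sign flips leave the magnitude ranks
untouched, the permuted statistics are a single matrix product, so the
test is fast. Its family-wise error under exchangeable null data sits
near the nominal 5% (asserted by simulation in the test suite).

**Waiting time and W time.** `wait_w_correlation()` reports the pooled
Pearson correlation with its regression slope, per-subject correlations
(subjects with fewer than 3 usable trials or zero variance are excluded
with a flag), a two-sided Wilcoxon signed-rank test of the per-subject
$r$'s against zero, and `binomial_sign_test()` — the exact one-sided
tail probability that at least $k$ of $n$ subjects go the same way under
a fair coin. Under the model the correlation is negative: shallow
trajectories take longer to arrive *and* spend longer between the two
thresholds.

## The synthetic cohort generator

`generate_cohort()` produces data with the structure the analyses
assume, so the full pipeline runs without any external recording:

* 14 subjects × 60 trials by default; per-subject exponents drawn from
  $\mathcal{N}(1.4, 0.52)$ truncated to $[0.1, 2.9]$ (the SD corresponds
  to a group standard error of 0.14 at $n = 14$).
* Per-trial waiting times in seconds and W reports quantized to the
  0.05 s tick of a rotating-clock display, clamped at zero.
* Scalp epochs at 250 Hz spanning $-3.5$ to $+1.0$ s around the
  crossing (1126 samples): the sign-reversed, amplitude-scaled
  stochastic input, decimated from the simulation rate by zero-phase
  Butterworth anti-alias filtering, with missing samples before trial
  start left `NA`.

Three generator choices deserve explanation:

* **Threshold calibration.** The activation threshold is tuned per
  subject by bisection until the median simulated waiting time matches a
  7.1 s target — the mean waiting time such experiments report — because
  the mapping from model parameters to absolute waiting times depends on
  the noise-amplitude convention discussed above. Trajectories do not
  depend on the threshold, so calibration re-scans a fixed set of
  simulated trajectories and is cheap. The advance-warning fraction is
  likewise calibrated so the mean model W delay matches $-0.142$ s, a
  typical reported W time. Both calibrations can be disabled.
* **Background EEG noise.** Additive noise is generated as *1/f noise at
  the subject's own exponent* (10 µV per sample by default), not white:
  scalp EEG away from the event shares the aperiodic spectrum of the
  cortical fluctuations that drive the accumulator, and a white sensor
  floor would both misrepresent real epochs and hide the subject's
  exponent from the spectral estimator. The amplitude scale (3000 µV per
  input unit) makes the event-locked deflection a few microvolts with
  tercile differences of 1–2 µV, the magnitudes such studies report.
* **W report noise.** Reports add Gaussian noise (SD 0.15 s) to the
  model delay before clamping and quantization. This is a free dial of
  the generator, not an empirical estimate: real W reports are noisy
  enough that pooled wait–W correlations are weak ($|r| \approx 0.1$),
  and this value lands the synthetic pooled correlation in that regime.
  There is no generative account of report noise in the model itself.

What the generator does **not** emulate: ocular and movement artifacts
(and their removal), volume conduction and electrode montages, any
difference between task variants (an `interruptus` label is carried but
trials are generated identically), non-stationarity across the session,
and any post-movement contribution to W reports. Pipeline tests passing
on synthetic cohorts therefore demonstrate the *internal consistency* of
generator, model and statistics — that the procedures recover what the
generative process puts in — not that real recordings satisfy the
model's assumptions.

## Numerical and degenerate-input conventions

* Threshold crossings are closed (`>=`); a trajectory starting at the
  level crosses at its first sample. Indices are 1-based.
* Simulated noise lengths are padded up to 5-smooth sizes: R's
  mixed-radix FFT degrades badly on lengths with large prime factors.
* Censored trials are excluded from crossing-time lists and epoch
  matrices; an all-censored batch warns and returns an empty
  distribution. A cohort subject that cannot produce enough crossings
  within 10× the requested trials is an error.
* Epoch samples before trial start are `NA` and excluded pointwise from
  averages; the decimation filter leaves a short additional `NA` guard
  after a missing head (filter edge).
* Degenerate tercile splits (overlapping groups) and windows outside the
  epoch are errors; a subject with zero-variance inputs is excluded from
  per-subject correlations with a flag rather than propagating `NaN`.
* Dataset files are plain text with 17 significant digits, so a
  write/read round trip is bitwise; the on-disk schema is versioned
  (major mismatch: error; minor: warning).

## Problem sizes used by the packaged analyses

The emergence scans in `scripts/acceptance.R` use 2000 trials per
exponent (the boundary quantities stabilize well below this); estimator
checks use 20 realizations of $2^{17}$ samples; fitting illustrations
use targets of several hundred trials with a 20 s trial cap. These sizes
are the package's own choices for desk-scale reproduction.

## Known limitations

* The noise-amplitude convention (filter form, $\sqrt{dt}$ scaling) is a
  modelling commitment on a point where reasonable alternatives exist;
  `standardize = TRUE` and the exposed `dt` make the alternatives
  available for sensitivity analysis, and the absolute-time calibrations
  in the generator deliberately absorb the convention's amplitude
  consequences.
* The exact exponent at which each prediction "switches on" depends on
  that convention and on the statistical power of the scan used to
  detect it; treat reported boundaries as properties of the stated scan,
  not constants of nature.
* The epoch-based exponent estimator compresses exponents above ~2.
* Group-level fitting only: no per-subject model fits, no gradient-based
  or Bayesian estimation.
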