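---
title: "Models and methods for binding-turnover analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for binding-turnover analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oriturn)
```

This vignette is the package's own account of the statistical models it
implements, the parameters that matter, the places where the methodology
was genuinely open and a choice had to be made, and what the simulation-
based tests do and do not demonstrate about real data.

The motivating biology is the turnover of the bacterial replication
initiator DnaA on its chromosomal binding sites: DnaA exchanges at the
replication origin on a timescale of seconds, individual molecules arrest
on chromosomal sites for only a few hundred milliseconds, and in *E. coli*
the protein shuttles between opposite chromosome regions within one to two
seconds. The package quantifies all three observations from standard
live-cell measurements: FRAP recovery curves, single-molecule trajectories,
and paired region-intensity time series.

## 1. FRAP

### Model

Recovery of fluorescence in a bleached region that exchanges with a large
pool by first-order binding kinetics follows the single-exponential model

$$ f(t) = A\,\bigl(1 - e^{-k_r t}\bigr), $$

with recovery level $A$ and recovery rate $k_r$ (1/s). The half-time is
$t_{1/2} = \ln 2 / k_r$, stored exactly as this ratio so the identity
holds to machine precision. The single-exponential form is appropriate in
the reaction-dominant regime (binding turnover much slower than diffusion
across the bleached spot); pure-diffusion and full reaction–diffusion
models are deliberately out of scope.

### Normalization

Two schemes are implemented, differing in the reference channel:

* **Single normalization** divides the background-subtracted ROI by a
  background-subtracted *unbleached control cell*, cancelling acquisition
  bleaching, then rescales to the pre-bleach mean.
* **Double normalization** divides by the *whole bleached cell* instead,
  which additionally corrects for the fluorescence destroyed by the bleach
  pulse. Under this scheme, full exchange recovers the trace to 1, so the
  fitted plateau $A$ is the mobile fraction and $1-A$ (clamped to
  $[0,1]$) the immobile, non-exchanging fraction. The package reports
  immobile fractions only from double-normalized fits.

Whether the control channel should itself be background-subtracted is not
standardized; the package subtracts background from both channels (the
symmetric choice) and exposes `subtract_background_from_control` for the
asymmetric convention.

### Clustering and full-scale normalization

Individual-cell traces are noisy, so cells are grouped before fitting:
traces are sorted by pre-bleach intensity and partitioned into consecutive
groups of three ("similar intensities" operationalized as adjacency after
sorting — the natural deterministic reading when no similarity metric is
given). Each trace is full-scale normalized,

$$ v' = \frac{v - \min_{\text{post}} v}{\overline{v}_{\text{pre}} -
\min_{\text{post}} v}, $$

mapping the post-bleach minimum to 0 and the pre-bleach mean to 1 so that
different bleach depths align, then averaged pointwise within the group.
A remainder group is kept if it still contains at least two traces. Note
one consequence of the scheme: with additive noise the post-bleach
*minimum* is biased low, which slightly inflates the apparent recovery
speed; across the simulation conditions used in the tests this biases the
mean half-time a few percent below truth, well inside the tolerances
asserted.

### Fitting

The fit runs on post-bleach points only, with $t = 0$ at the first
post-bleach frame (the origin convention must be fixed somewhere; this is
the convention under which the bleach-depth point is part of the fitted
span). Levenberg-Marquardt least squares (via minpack.lm) is initialized
from $A_0$ = mean of the last quartile of the trace and
$k_0 = \ln 2 / t$ where $t$ is the linear-interpolated time of first
crossing $A_0/2$ — both direct readings of the curve, so convergence is
robust without user-supplied starts. Group comparisons use the
pooled-variance Student's t-test (Welch's version behind a flag).

### Bleach-frame detection

When not supplied, the bleach frame is detected as the largest
single-frame fractional drop of the ROI channel. In a real protocol it is
known; the detector exists so that plain CSV exports carry enough
information.

## 2. Single-molecule tracking: diffusion

### MSD estimation

For free 2D Brownian motion the mean squared displacement is
$\mathrm{MSD}(\tau) = 4D\tau$. Per-track time-averaged MSD curves (exact
frame spacing only — pairs spanning detection gaps are excluded) are
combined into an ensemble curve by weighting each track's value at each
lag with its pair count, and a straight line through the origin is fitted
to the first 4 lags, again weighted by total pair counts. Four lags is as
much as tracks averaging ~6 frames can support; the estimator divides the
fitted slope by 4. The standard error comes from a seeded bootstrap over
tracks (200 resamples) — resampling tracks, not steps, respects the
within-track correlation of time-averaged MSDs. An optional free intercept
can absorb static localization error; the default forces the origin
because the simulators' default localization error is zero and real
intercepts trade off against the shortest (most informative) lags.

### Step-size mixture decomposition

Molecular sub-populations with distinct mobility leave a characteristic
signature in the per-frame displacement distribution: a mixture of
zero-mean normals whose variances are $2 d_k \Delta t$. The x- and y-
displacements are pooled (both are independent draws from the same
marginal for isotropic diffusion, doubling the effective sample size —
verified unbiased in the tests), and the mixture is fitted by
maximum-likelihood EM on the *raw* step values. Fitting raw values rather
than binned histogram counts avoids a bin-width nuisance parameter;
histograms remain a display device. The zero-mean constraint is imposed
throughout: Brownian steps have mean zero, and freeing the means would let
a component chase drift artifacts.

EM details: responsibilities and variance updates in closed form, 10
restarts from seeded jittered initializations (the first restart is
deterministic), convergence on relative log-likelihood change below
1e-8, variances floored at 1e-12 to avoid collapse onto a single point.
Components are always reported sorted by $d$, so initialization labels
never leak into results. For a single component the ML solution
$\hat\sigma^2 = \overline{x^2}$ is used directly. Model order can be
compared with `compare_mixture_orders()` (log-likelihood, BIC, AIC; a
mixture of $K$ zero-mean components has $2K-1$ free parameters).

Whether component variances should be shared across datasets fitted
together ("simultaneous fit") is ambiguous in common practice; the package
fits per dataset, which keeps datasets independent and is what the
recovery tests exercise. Note also that the whole-data MSD estimate
($D^* \approx 0.68\,\mu m^2/s$ in the motivating system) legitimately
exceeds the mobile mixture component ($0.51$): the two estimators weight
the static population differently, and no reconciliation is attempted.

## 3. Single-molecule tracking: residence times

### Static-interval detection

A trapping event is the maximal run of consecutive frames during which the
trajectory stays within a threshold radius (default 230 nm, a typical
resolution limit) of an *anchor* — one of the trajectory's own points, not
a centroid, since a bound molecule's true position is best represented by
an observed localization. Every point is tried as an anchor and its run
extended forward and backward in time; runs shorter than `min_frames`
(default 3) are discarded; and a non-overlapping set is selected greedily
by decreasing length with deterministic tie-breaks (earlier start, then
earlier anchor). Greedy longest-first is the decomposition that keeps the
longest genuine arrests intact, is order-independent given the
tie-breaks, and reproduces hand-traceable examples. Frame gaps break
intervals: a gap hides unobserved motion.

Durations are reported as (number of frames) × Δt, in milliseconds.

### Truncation bias and its correction

The ≥3-frame filter and frame quantization bias the raw mean duration.
For an exponential dwell with mean $\tau$ observed on a frame grid of
spacing $\Delta t$ with uniform phase, the number of covered frames $K$
has $P(K \ge j) \propto q^{j-1}$ with $q = e^{-\Delta t/\tau}$, so
conditioning on $K \ge m$ gives
$E[\text{duration}] = \Delta t\,(m + q/(1-q))$.
`correct_residence_truncation()` inverts this relation. The correction
removes the dominant (filter) bias; edge censoring by track ends
(photobleaching) and contamination by mobile molecules remain, which is
why the recovery test demands 15% accuracy rather than exactness, and why
reported residence times on real data remain *underestimates* of true
binding times.

### The false-positive model

A freely diffusing molecule occasionally produces a qualifying static run
by chance. The analytic model makes this tractable with a *moving-circle*
relaxation: each single-frame displacement is compared with $r_{max}$
independently, giving the per-frame stopping probability

$$ p = 1 - e^{-r_{max}^2 / (4 D \Delta t)}, $$

and the probability that a track of length $n$ contains at least $m$
consecutive static frames is approximated by grouping one run of $m$ and
counting arrangements:

$$ P(n) = \sum_{r=m}^{n} \binom{n-m+1}{n-r} p^r (1-p)^{n-r}. $$

Two approximations are at work, and the tests quantify both against
independent oracles (exhaustive $2^n$ enumeration and a run-length
dynamic program):

* The combinatorial formula is **exact for $n \le m+1$ and undercounts
  for longer tracks** (it counts arrangements, not all strings containing
  a run).
* The moving circle is **more permissive than anchored detection**, which
  makes the analytic rate an overestimate of the detector's behavior — the
  direction usually quoted. For short tracks ($n \le 6$ at the motivating
  parameter values) this relaxation dominates and the analytic rate indeed
  exceeds the exact moving-circle probability of the corresponding jump
  sequence; from $n = 7$ the combinatorial undercount outweighs it. Both
  regimes are asserted in the test suite rather than hidden; averaged over
  a photobleaching-limited (geometric, mean 5.7 frames) length
  distribution the two rates agree to a few tenths of a percentage point.

The Monte-Carlo mode of `false_positive_rate()` simulates free
displacement sequences under the same moving-circle criterion, providing
the independent check. Which $D$ and which track-length distribution to
plug in are left as explicit inputs — the defensible default for $D$ is
the mobile-component estimate from the mixture fit. The formula's $n$ is
interpreted as the track length in frames as conventionally written; a
`"jumps"` convention (evaluate at $n-1$ Bernoulli trials) is selectable.

### Heat maps

Trajectory heat maps distinguish arrests from crossings: each point adds a
unit-amplitude Gaussian bell (sd 80 nm) to a temperature field damped by
0.8 per frame, and the map shows the pointwise maximum over time. A
molecule arrested for $k$ frames builds a peak of
$(1-0.8^k)/(1-0.8)$ (geometric series, asserted to 1e-9), while a fast
crossing never exceeds ~1. Grid spacing (20 nm), mask sd and damping are
package defaults chosen to make a 3-frame arrest visually distinct from a
crossing at typical acquisition settings; all three are exposed as
parameters since no standard values exist.

## 4. Oscillation analysis

Two region intensities are divided framewise by the whole-cell intensity
(removing any decay common to all channels, e.g. photobleaching) and
summarized by Pearson's correlation: coordinated shuttling between the
regions gives $r \to -1$; a spatially fixed marker gives $r \approx 0$
with $|r| < 3/\sqrt{n}$ under independent noise. No detrending beyond the
whole-cell normalization is applied, matching common practice. Spearman's
rank correlation is available for heavy-tailed intensities, and
`estimate_period()` offers an exploratory period readout (twice the lag
of the first autocorrelation minimum of the difference signal) — labeled
exploratory because periodicity judgments on real traces are made by
inspection.

## 5. The simulators and what the tests show

Every analysis stage is validated against seeded generators that produce
data with exactly the statistical structure the stage assumes:

* `simulate_brownian_tracks()`: per-axis Gaussian steps of variance
  $2D\Delta t$; components assigned per molecule by weight, or two-state
  static/mobile switching with exponential dwells simulated in continuous
  time (a frame spanning a switch gets the time-weighted variance, and
  every drawn dwell is logged as ground truth). Track lengths default to
  geometric (mean 5.7, minimum 2) because photobleaching yields geometric
  survival; localization error defaults to 0 because no standard value
  exists — both are configurable. No cell-boundary confinement by default:
  confinement distorts the MSD only at lags longer than the short lags
  these analyses use. An optional rod-shaped boundary (rectangle with
  semicircular caps) is available behind a flag; it keeps points inside by
  resampling out-of-bounds increments, a pragmatic rule sufficient for its
  exploratory purpose.
* `simulate_frap_trace()`: pre-bleach plateau, instantaneous drop by the
  bleach depth (diffusion during the pulse ignored), exponential recovery
  of the mobile share, acquisition-bleaching decay on all channels,
  additive Gaussian noise. By default the ROI is treated as a negligible
  share of the fluorophore pool (`roi_share = 0`), so the whole-cell
  channel is conserved; a positive share switches on finite-pool
  book-keeping. Default bleach depth is 1, under which the
  single-normalized trace *is* $A(1-e^{-k_r t})$.
* `simulate_oscillation_trace()`: a conserved total shuttling
  sinusoidally between two regions, independent additive noise per
  region. The whole-cell channel is emitted noise-free: dividing both
  regions by a common noisy denominator would fabricate positive
  correlation unrelated to exchange. Noise magnitudes have no published
  reference values; defaults are placeholders and every test states the
  level it uses.

The simulation study conditions mirror the motivating measurements: 41 ms
frames (24.5 Hz) and 4 ms frames (250 Hz) for the fast control, tracks of
geometric mean length 5.7, diffusion coefficients 0.027/0.51 (20/80
split), whole-data $D^*$ 0.68 and fast-control 3.3 μm²/s, FRAP half-times
around 2.5 s with a ~10% immobile pool, dwell means of roughly 200 ms and
a 2 s oscillation period. Problem sizes in the tests (e.g. 32 FRAP traces,
1,000 tracks for MSD recovery, 20,000 steps for mixture recovery, 500
switching tracks for residence recovery) are the package's choices to make
each estimate's sampling error comfortably smaller than the asserted
tolerance.

**What passing tests show:** the estimators recover known ground truth
under the assumed generating models, at realistic sample sizes, with the
documented biases corrected or bounded. **What they do not show:** that
real microscopy obeys those models. Real data add localization error,
confinement within the nucleoid and cell boundary, blinking and
photophysics, detection and linking errors, and drift — none of which the
generators emulate by default. Estimates on real data inherit those
caveats, most importantly that residence times are photobleaching-limited
underestimates.

## 6. Numerical choices, degenerate inputs and limitations

* `run_probability()` accumulates terms in log space (`lchoose`), stable
  to $n \sim 10^4$; $p \in \{0, 1\}$ and $n < m$ short-circuit exactly.
* `stop_probability(0, \cdot)` returns 1 (an immobile molecule never
  leaves); negative inputs are domain errors, not NaNs.
* EM non-convergence after all restarts is returned flagged
  (`converged = FALSE`), never silently.
* Degenerate FRAP inputs (non-positive control or whole-cell channel,
  too few post-bleach points, unequal trace lengths in a cluster) are
  errors naming the offending frame or condition; a zero-variance
  comparison of identical half-time groups returns $p = 1$ by convention.
* `fit_recovery()` reports a boundary warning when the rate estimate hits
  its lower bound.
* Readers never silently drop rows: malformed cells are errors naming row
  and column, missing optional channels are filled with documented
  defaults under a warning, and gap counts are recorded.
* The KS comparison attaches a warning below 5 intervals per group; its
  asymptotic p-values run slightly conservative, which the calibration
  tests account for.
* Heat-map grids above $10^7$ cells are refused with a suggestion to
  coarsen the spacing.

The package's command-line entry point (`inst/cli/oriturn.R`) is a thin
wrapper over the exported functions for shell-based batch use; the R API
is the primary interface.
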