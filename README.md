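# oriturn

Quantifying how fast DNA-binding proteins exchange on their chromosomal
binding sites, from live-cell fluorescence data. The motivating system is
the bacterial replication initiator **DnaA**, which binds the replication
origin (*oriC*) yet turns over in seconds — a property that matters for
how cells avoid premature replication initiation. The package is for
microscopists and quantitative biologists who have FRAP recovery curves,
single-molecule trajectories, or two-region intensity series, and want
the standard turnover statistics computed reproducibly.

## What it computes

**FRAP.** Background subtraction; single (control-cell) or double
(whole-cell) normalization; grouping of cells with similar intensities
into clusters of three with full-scale normalization; least-squares fit of
the single-exponential recovery model

    f(t) = A (1 − e^(−k_r t)),    t_1/2 = ln 2 / k_r

with the recovery level *A* interpreted (under double normalization) as
the mobile fraction, so `1 − A` is the immobile, non-exchanging pool; and
pooled-variance Student's t-tests between groups of half-times.

**Single-molecule tracking.**

* Apparent diffusion coefficients *D\** from pair-count-weighted ensemble
  MSD fits through the origin (`MSD(τ) = 4Dτ` for free 2D motion), with
  bootstrap-over-tracks standard errors.
* Decomposition of the frame-to-frame displacement distribution into
  static and mobile sub-populations by a zero-mean Gaussian mixture with
  variances `2 d_k Δt`, fitted by seeded EM on raw steps; the component
  weights are the population fractions.
* Static-interval (residence time) detection: maximal runs of consecutive
  frames within a 230 nm threshold radius of a trajectory point, a
  greedy non-overlapping decomposition, duration CDFs and two-sample
  Kolmogorov–Smirnov comparisons, plus a closed-form correction for the
  minimum-length truncation bias.
* An analytic false-positive model for free molecules mistaken as static:
  per-frame stopping probability `p = 1 − exp(−r_max² / (4 D Δt))` and a
  combinatorial run probability, cross-checked by a Monte-Carlo mode.
* Trajectory heat maps with damped heat accumulation that make trapping
  events visually distinct from crossings.

**Oscillation.** Whole-cell-normalized intensities of two regions and
their Pearson correlation: anti-phase shuttling of molecules between the
regions drives *r* toward −1.

Seeded simulators (`simulate_brownian_tracks()`, `simulate_frap_trace()`,
`simulate_oscillation_trace()`) generate trajectories and traces with
exactly the structure the analyses assume, so every stage is testable
against known ground truth.

## Worked example

```r
library(oriturn)

# --- FRAP: nine synthetic cells, true half-time 2.5 s, 10% immobile pool
cfg <- function(i) sim_config(seed = i, frame_interval = 0.041)
traces <- lapply(1:9, function(i)
  simulate_frap_trace(mobile_level = 0.9, k_r = log(2) / 2.5,
                      noise_sd = 0.03, n_pre = 10, n_post = 488,
                      config = cfg(i)))
clusters <- cluster_traces(lapply(traces, single_normalize), cluster_size = 3)
fits <- lapply(clusters, fit_recovery)
fits[[1]]
#> <frap_fit> A = 0.897, k_r = 0.2827 1/s, t_half = 2.452 s, immobile = 10.3%
summarize_halftimes(fits)
#> mean t_half = 2.38 +/- 0.05 s over 3 clusters

# --- SMT: a 20/80 static/mobile population, 41 ms frames
tracks <- simulate_brownian_tracks(
  diffusion_model(c(0.027, 0.51), weight = c(0.2, 0.8)),
  n_tracks = 1000,
  sim_config(seed = 42, frame_interval = 0.041,
             track_length_law = list(distribution = "geometric",
                                     mean = 5.7, min = 3)))
fit_msd(tracks)
#> <diffusion_estimate> D* = 0.410 +/- 0.014 um^2/s (1000 tracks, 4 lags)
fit_step_mixture(extract_steps(tracks))
#> <mixture_fit> 2 components over 9670 steps (logL = 3038.1)
#>   d = 0.0278 um^2/s, weight = 23.3%
#>   d = 0.5270 um^2/s, weight = 76.7%
```

Reading the numbers: the first cluster's fit recovers the generating
parameters (half-time 2.45 s vs the true 2.5 s; immobile fraction 10.3%
vs the true 10%). The ensemble MSD estimate, 0.41 μm²/s, is the
population-weighted average mobility (0.2·0.027 + 0.8·0.51 = 0.41) — it
cannot see the sub-populations. The mixture fit resolves them: diffusion
coefficients 0.028 and 0.53 μm²/s with a 23/77 split, close to the
generating 0.027/0.51 at 20/80.

Trajectory CSVs from any tracking program can be analyzed the same way
via `read_tracks_csv()` (header `track_id,frame,x_um,y_um`; a
`--pixel-size` style argument converts pixel units). A thin command-line
wrapper for batch use ships in `inst/cli/oriturn.R`.

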