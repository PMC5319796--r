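#' Configuration for static-interval (trapping) detection
#'
#' @param radius Threshold radius in micrometers within which a track is
#'   considered to stay put; default 0.23 (the 230 nm resolution limit of a
#'   conventional setup).
#' @param min_frames Minimum static-interval length in frames (default 3;
#'   shorter runs are dominated by slowly diffusing mobile molecules).
#' @param frame_interval Frame interval in seconds.
#' @return An object of class `residence_config`.
#' @export
residence_config <- function(radius = 0.23, min_frames = 3L,
                             frame_interval = 0.041) {
  stopifnot_scalar(radius, "radius", 0, strict_lower = TRUE)
  stopifnot_scalar(min_frames, "min_frames", 2)
  stopifnot_scalar(frame_interval, "frame_interval", 0, strict_lower = TRUE)
  structure(list(radius = radius, min_frames = as.integer(min_frames),
                 frame_interval = frame_interval),
            class = "residence_config")
}

# maximal anchored runs within one gap-free segment of a track
anchored_runs <- function(x, y, frames, radius) {
  n <- length(x)
  r2 <- radius^2
  out <- vector("list", n)
  for (a in seq_len(n)) {
    ok <- (x - x[a])^2 + (y - y[a])^2 <= r2
    lo <- a; while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
    hi <- a; while (hi < n && ok[hi + 1L]) hi <- hi + 1L
    out[[a]] <- c(lo, hi, a)
  }
  do.call(rbind, out)
}

#' Detect static intervals within a trajectory
#'
#' Decomposes a track into non-overlapping trapping events. Every
#' trajectory point serves as a candidate anchor; the maximal run of
#' consecutive frames (no gaps) whose points all lie within `radius` of
#' that anchor is extended forward and backward in time. Runs shorter than
#' `min_frames` are discarded; from the surviving candidates a
#' non-overlapping set is chosen greedily by decreasing length (ties:
#' earlier start, then earlier anchor index). Frame gaps break intervals,
#' since a gap hides unobserved motion.
#'
#' @param track Data frame with columns `frame`, `x`, `y` (one trajectory),
#'   or a single-track [track_set()].
#' @param config A [residence_config()].
#' @return Data frame with one row per selected interval: `track_id`,
#'   `anchor_x`, `anchor_y`, `start_frame`, `end_frame` (inclusive),
#'   `n_frames`, `duration` (seconds, `n_frames * frame_interval`), sorted
#'   by `start_frame`. Zero rows when nothing qualifies.
#' @export
find_static_intervals <- function(track, config) {
  stopifnot(inherits(config, "residence_config"))
  if (inherits(track, "track_set")) track <- track$tracks
  track <- track[order(track$frame), , drop = FALSE]
  id <- if ("track_id" %in% names(track)) track$track_id[1] else NA
  dt <- config$frame_interval
  empty <- data.frame(track_id = id[0], anchor_x = numeric(0),
                      anchor_y = numeric(0), start_frame = integer(0),
                      end_frame = integer(0), n_frames = integer(0),
                      duration = numeric(0))
  if (nrow(track) < config$min_frames) return(empty)

  # split at frame gaps: intervals may not span unobserved frames
  seg_id <- cumsum(c(1L, diff(track$frame) != 1L))
  cands <- do.call(rbind, lapply(split(track, seg_id), function(seg) {
    if (nrow(seg) < config$min_frames) return(NULL)
    runs <- anchored_runs(seg$x, seg$y, seg$frame, config$radius)
    len <- runs[, 2] - runs[, 1] + 1L
    keep <- len >= config$min_frames
    if (!any(keep)) return(NULL)
    data.frame(start = seg$frame[runs[keep, 1]],
               end = seg$frame[runs[keep, 2]],
               len = len[keep],
               anchor_frame = seg$frame[runs[keep, 3]],
               anchor_x = seg$x[runs[keep, 3]],
               anchor_y = seg$y[runs[keep, 3]])
  }))
  if (is.null(cands) || !nrow(cands)) return(empty)

  cands <- cands[order(-cands$len, cands$start, cands$anchor_frame), ,
                 drop = FALSE]
  taken <- logical(max(cands$end) - min(cands$start) + 1L)
  offset <- min(cands$start) - 1L
  sel <- logical(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    span <- (cands$start[i] - offset):(cands$end[i] - offset)
    if (!any(taken[span])) {
      taken[span] <- TRUE
      sel[i] <- TRUE
    }
  }
  chosen <- cands[sel, , drop = FALSE]
  chosen <- chosen[order(chosen$start), , drop = FALSE]
  data.frame(track_id = id,
             anchor_x = chosen$anchor_x, anchor_y = chosen$anchor_y,
             start_frame = as.integer(chosen$start),
             end_frame = as.integer(chosen$end),
             n_frames = as.integer(chosen$len),
             duration = chosen$len * dt,
             row.names = NULL)
}

#' Residence-time summary over a track set
#'
#' Pools static intervals from all tracks with at least `min_track_frames`
#' observed frames, and reports the mean residence time (milliseconds, to
#' match the conventional reporting unit) together with the empirical CDF
#' of interval durations. Restricting to long tracks (e.g.
#' `min_track_frames = 10`) reduces the bias from tracks bleaching before
#' a dwell is over.
#'
#' Reported values are raw: photobleaching truncates dwells, so they
#' underestimate the true binding time.
#'
#' @param tracks A [track_set()].
#' @param config A [residence_config()].
#' @param min_track_frames Minimum observed frames for a track to enter
#'   the pool (default 0, all tracks).
#' @return An object of class `residence_summary` with `intervals`,
#'   `mean_residence` (ms), `n_intervals`, `cdf` (data frame `time` in
#'   seconds, `cumulative_probability`), `units`. An empty pool yields an
#'   empty summary (flagged with `n_intervals = 0`), not an error.
#' @export
residence_summary <- function(tracks, config, min_track_frames = 0L) {
  stopifnot(inherits(tracks, "track_set"),
            inherits(config, "residence_config"))
  per_track <- split_tracks(tracks)
  keep <- vapply(per_track, nrow, integer(1)) >= min_track_frames
  ints <- do.call(rbind, lapply(per_track[keep], find_static_intervals,
                                config = config))
  if (is.null(ints) || !nrow(ints)) {
    return(structure(list(intervals = NULL, mean_residence = NA_real_,
                          n_intervals = 0L, cdf = NULL,
                          units = "ms"), class = "residence_summary"))
  }
  rownames(ints) <- NULL
  durs <- sort(ints$duration)
  cdf <- data.frame(time = durs,
                    cumulative_probability = seq_along(durs) / length(durs))
  structure(list(intervals = ints,
                 mean_residence = mean(durs) * 1000,
                 n_intervals = nrow(ints),
                 cdf = cdf,
                 units = "ms"),
            class = "residence_summary")
}

#' @export
print.residence_summary <- function(x, ...) {
  if (x$n_intervals == 0L) cat("<residence_summary> no static intervals\n")
  else cat(sprintf("<residence_summary> %d intervals, mean residence %.0f ms\n",
                   x$n_intervals, x$mean_residence))
  invisible(x)
}

#' Truncation-corrected mean dwell time
#'
#' The raw mean residence time is biased by the minimum-length filter and
#' by frame quantization. For an exponentially distributed dwell with mean
#' `tau`, sampled on a frame grid of spacing `dt` with uniform phase, the
#' number of covered frames `K` satisfies `P(K >= j) = c * q^(j-1)` with
#' `q = exp(-dt / tau)`; conditioning on `K >= m` (the `min_frames`
#' filter) and using the memorylessness of the geometric tail gives
#' `E[duration | detected] = dt * (m + q / (1 - q))`. This function
#' inverts that relation: with `r = mean_duration / dt - m`, the estimate
#' is `tau_hat = -dt / log(r / (1 + r))`.
#'
#' The correction assumes exponential dwells and ignores edge censoring by
#' track ends and false positives from mobile molecules, so it removes the
#' dominant (filter) bias, not every bias.
#'
#' @param summary A non-empty `residence_summary`, or a mean duration in
#'   seconds.
#' @param config The [residence_config()] used for detection.
#' @return Estimated mean dwell time in milliseconds.
#' @export
correct_residence_truncation <- function(summary, config) {
  stopifnot(inherits(config, "residence_config"))
  mean_dur <- if (inherits(summary, "residence_summary")) {
    if (summary$n_intervals == 0L) stop("empty summary", call. = FALSE)
    summary$mean_residence / 1000
  } else as.numeric(summary)
  r <- mean_dur / config$frame_interval - config$min_frames
  if (r <= 0)
    stop("mean duration at or below the detection floor; cannot invert",
         call. = FALSE)
  1000 * -config$frame_interval / log(r / (1 + r))
}

#' Compare two residence-time distributions
#'
#' Two-sample Kolmogorov-Smirnov test on the pooled interval durations of
#' two summaries.
#'
#' @param a,b Non-empty `residence_summary` objects.
#' @return List with `ks_statistic`, `p_value` and `warning` (non-`NULL`
#'   when either sample has fewer than 5 intervals, where the asymptotic p
#'   value is unreliable).
#' @export
residence_cdf_compare <- function(a, b) {
  stopifnot(inherits(a, "residence_summary"),
            inherits(b, "residence_summary"))
  if (a$n_intervals == 0L || b$n_intervals == 0L)
    stop("both summaries must contain intervals", call. = FALSE)
  da <- a$intervals$duration; db <- b$intervals$duration
  wmsg <- if (length(da) < 5L || length(db) < 5L)
    "fewer than 5 intervals in a group: asymptotic p value unreliable"
  kt <- suppressWarnings(ks.test(da, db))
  list(ks_statistic = unname(kt$statistic), p_value = kt$p.value,
       warning = wmsg)
}

#' Single-frame stopping probability of a diffusing molecule
#'
#' Probability that a molecule with diffusion constant `d` moves less than
#' `r_max` within one frame interval: `1 - exp(-r_max^2 / (4 * d * dt))`.
#' An immobile molecule (`d = 0`) never leaves, so the probability is 1.
#'
#' @param d Diffusion coefficient in um^2/s (>= 0).
#' @param dt Frame interval in seconds (> 0).
#' @param r_max Threshold radius in micrometers (>= 0).
#' @return Probability in [0, 1].
#' @export
stop_probability <- function(d, dt, r_max) {
  if (any(d < 0) || any(dt <= 0) || any(r_max < 0))
    stop("domain error: need d >= 0, dt > 0, r_max >= 0", call. = FALSE)
  ifelse(d == 0, 1, 1 - exp(-r_max^2 / (4 * d * dt)))
}

#' Probability that a track contains a static run
#'
#' Evaluates the combinatorial approximation for the probability that a
#' track of length `n` contains at least `min_run` consecutive static
#' frames, each frame being static independently with probability `p`:
#' the sum over `r = min_run..n` of
#' `choose(n - min_run + 1, n - r) * p^r * (1-p)^(n-r)`,
#' where the binomial coefficient counts the arrangements of the non-static
#' frames once one run of `min_run` static frames is grouped together.
#'
#' The formula is exact for `n <= min_run + 1` and undercounts slightly for
#' longer tracks (it counts configurations, not all strings containing a
#' run); the package's tests document this against exhaustive enumeration.
#' Terms are accumulated in log space, so the sum is stable up to
#' `n` of order 1e4.
#'
#' @param n Track length (frames). Lengths below `min_run` return 0.
#' @param p Per-frame static probability in [0, 1].
#' @param min_run Minimum run length (default 3).
#' @param convention `"frames"` (default): `n` is the track length in
#'   frames, exactly as the formula is usually written. `"jumps"`: the
#'   Bernoulli trials are the `n - 1` displacements of an `n`-frame track,
#'   so the formula is evaluated at `n - 1`.
#' @return Probability in [0, 1].
#' @export
run_probability <- function(n, p, min_run = 3L,
                            convention = c("frames", "jumps")) {
  convention <- match.arg(convention)
  stopifnot_scalar(p, "p", 0, 1)
  if (length(n) > 1L)
    return(vapply(n, run_probability, numeric(1), p = p, min_run = min_run,
                  convention = convention))
  if (convention == "jumps") n <- n - 1L
  if (n < min_run) return(0)
  if (p == 0) return(0)
  if (p == 1) return(1)
  r <- min_run:n
  sum(exp(lchoose(n - min_run + 1, n - r) +
          r * log(p) + (n - r) * log1p(-p)))
}

#' False-positive rate of static-interval detection for free molecules
#'
#' Estimates how often a freely diffusing molecule would be counted as
#' static. The analytic mode averages [run_probability()] at the
#' single-frame stopping probability [stop_probability()] over the
#' observed track-length distribution; it rests on a moving-circle
#' approximation (each displacement judged against `r_max` independently),
#' which makes the calculation tractable. The Monte-Carlo mode simulates
#' free Brownian displacement sequences of the given lengths under the
#' same moving-circle criterion (a run of at least `min_frames`
#' consecutive displacements shorter than the radius) and provides an
#' independent check of the combinatorial formula.
#'
#' Which diffusion coefficient and track-length distribution to use are
#' deliberately exposed as inputs: a sensible default for `d` is the
#' mobile-component estimate from [fit_step_mixture()].
#'
#' @param track_lengths Integer vector of track lengths in frames
#'   (non-empty).
#' @param d Diffusion coefficient of the free population in um^2/s.
#' @param config A [residence_config()].
#' @param method `"analytic"` (default) or `"monte-carlo"`.
#' @param n_tracks_mc Number of simulated tracks in Monte-Carlo mode
#'   (lengths resampled from `track_lengths`; default 20000).
#' @param seed Seed for the Monte-Carlo mode.
#' @param convention Passed to [run_probability()].
#' @return An object of class `false_positive_model` with fields `p` (the
#'   single-frame stopping probability) and `rate` (expected fraction of
#'   tracks containing a qualifying static run), plus `method`.
#' @export
false_positive_rate <- function(track_lengths, d, config,
                                method = c("analytic", "monte-carlo"),
                                n_tracks_mc = 20000L, seed = 1L,
                                convention = c("frames", "jumps")) {
  method <- match.arg(method)
  convention <- match.arg(convention)
  stopifnot(length(track_lengths) >= 1L,
            inherits(config, "residence_config"))
  p <- stop_probability(d, config$frame_interval, config$radius)
  rate <- if (method == "analytic") {
    mean(run_probability(track_lengths, p, min_run = config$min_frames,
                         convention = convention))
  } else {
    step_sd <- sqrt(2 * d * config$frame_interval)
    minr <- config$min_frames
    with_seed(seed, {
      lens <- sample(track_lengths, n_tracks_mc, replace = TRUE)
      hits <- vapply(lens, function(n) {
        if (n - 1L < minr) return(FALSE)
        jump <- sqrt(rnorm(n - 1L, 0, step_sd)^2 +
                     rnorm(n - 1L, 0, step_sd)^2)
        rl <- rle(jump < config$radius)
        any(rl$values & rl$lengths >= minr)
      }, logical(1))
      mean(hits)
    })
  }
  structure(list(p = p, rate = rate, method = method,
                 d = d, min_frames = config$min_frames,
                 radius = config$radius),
            class = "false_positive_model")
}

#' @export
print.false_positive_model <- function(x, ...) {
  cat(sprintf("<false_positive_model> p = %.3f, rate = %.1f%% (%s)\n",
              x$p, 100 * x$rate, x$method))
  invisible(x)
}

#' Trajectory heat map with cooling
#'
#' Each trajectory point emits a unit-amplitude isotropic Gaussian bell of
#' heat; the running temperature field is damped by `damping` before the
#' next bell is added (`T_t = damping * T_{t-1} + G_t`), and the output is
#' the pointwise maximum over time. Trapping events accumulate heat
#' (approaching the geometric-series limit `1 / (1 - damping)` for a long
#' arrest), while a fast-crossing track never exceeds about 1, which is
#' what distinguishes real arrests from crossings.
#'
#' @param track Data frame with columns `x`, `y` (one trajectory), or a
#'   single-track [track_set()].
#' @param grid_spacing Raster spacing in micrometers (default 0.02).
#' @param mask_sd Standard deviation of the Gaussian heat mask in
#'   micrometers (default 0.08).
#' @param damping Damping factor in (0, 1) applied per frame (default
#'   0.8).
#' @return An object of class `heat_map` with `x`, `y` (grid coordinates),
#'   `temperatures` (matrix, rows indexed by `x`), and the parameters.
#' @export
heat_map <- function(track, grid_spacing = 0.02, mask_sd = 0.08,
                     damping = 0.8) {
  if (inherits(track, "track_set")) track <- track$tracks
  stopifnot(nrow(track) >= 1L)
  stopifnot_scalar(damping, "damping", 0, 1)
  pad <- 3 * mask_sd
  gx <- seq(min(track$x) - pad, max(track$x) + pad, by = grid_spacing)
  gy <- seq(min(track$y) - pad, max(track$y) + pad, by = grid_spacing)
  if (as.numeric(length(gx)) * as.numeric(length(gy)) > 1e7)
    stop("grid exceeds 1e7 cells; use a coarser grid_spacing", call. = FALSE)
  temp <- maxmap <- matrix(0, length(gx), length(gy))
  inv2s2 <- 1 / (2 * mask_sd^2)
  for (i in seq_len(nrow(track))) {
    bell <- exp(-(gx - track$x[i])^2 * inv2s2) %o%
            exp(-(gy - track$y[i])^2 * inv2s2)
    temp <- damping * temp + bell
    maxmap <- pmax(maxmap, temp)
  }
  structure(list(x = gx, y = gy, temperatures = maxmap,
                 grid_spacing = grid_spacing, mask_sd = mask_sd,
                 damping = damping),
            class = "heat_map")
}

#' @export
print.heat_map <- function(x, ...) {
  cat(sprintf("<heat_map> %d x %d grid, peak temperature %.3f\n",
              length(x$x), length(x$y), max(x$temperatures)))
  invisible(x)
}

#' @export
plot.heat_map <- function(x, ...) {
  image(x$x, x$y, x$temperatures, asp = 1, xlab = "x [um]", ylab = "y [um]",
        col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  invisible(x)
}
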