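#' Simulation configuration
#'
#' Bundles the acquisition parameters shared by all simulators: the frame
#' interval, the per-axis localization error, the track-length law and the
#' RNG seed. Identical configurations (including the seed) produce
#' bit-identical simulator output.
#'
#' @param seed Integer RNG seed.
#' @param frame_interval Frame interval in seconds (e.g. 0.041 for 24.5 Hz
#'   acquisition, 0.004 for 250 Hz).
#' @param localization_error_sd Per-axis localization error standard
#'   deviation in micrometers, added independently to every coordinate.
#'   Default 0.
#' @param track_length_law List with elements `distribution` (`"fixed"` or
#'   `"geometric"`), `mean` (mean track length in frames) and `min`
#'   (minimum length, at least 2). Photobleaching-limited track survival is
#'   geometric, the default.
#' @param confinement Optional rod-shaped confinement, a list with `length`
#'   and `width` in micrometers (rectangle with semicircular caps, centered
#'   at the origin). `NULL` (default) disables confinement.
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, frame_interval = 0.041)
#' @export
sim_config <- function(seed,
                       frame_interval,
                       localization_error_sd = 0,
                       track_length_law = list(distribution = "geometric",
                                               mean = 5.7, min = 2),
                       confinement = NULL) {
  stopifnot_scalar(frame_interval, "frame_interval", 0, strict_lower = TRUE)
  stopifnot_scalar(localization_error_sd, "localization_error_sd", 0)
  law <- track_length_law
  if (is.null(law$distribution) ||
      !law$distribution %in% c("fixed", "geometric"))
    stop("track_length_law$distribution must be \"fixed\" or \"geometric\"",
         call. = FALSE)
  law$min <- law$min %||% 2
  stopifnot_scalar(law$min, "track_length_law$min", 2)
  stopifnot_scalar(law$mean, "track_length_law$mean", law$min)
  if (!is.null(confinement)) {
    stopifnot_scalar(confinement$length, "confinement$length", 0,
                     strict_lower = TRUE)
    stopifnot_scalar(confinement$width, "confinement$width", 0,
                     strict_lower = TRUE)
  }
  structure(list(seed = as.integer(seed),
                 frame_interval = frame_interval,
                 localization_error_sd = localization_error_sd,
                 track_length_law = law,
                 confinement = confinement),
            class = "sim_config")
}

#' Diffusion model for trajectory simulation
#'
#' Describes the mobility of the simulated molecules as a mixture of
#' Brownian components, optionally with static/mobile state switching.
#'
#' @param d Numeric vector of diffusion coefficients in um^2/s, one per
#'   component.
#' @param weight Numeric vector of component weights summing to 1. Defaults
#'   to a single component of weight 1 when `d` has length 1.
#' @param switching Optional list with `mean_static_dwell` and
#'   `mean_mobile_dwell` (seconds). Requires exactly two components; the
#'   slower one is the static state. When present, each molecule alternates
#'   between the two states with exponentially distributed dwell times
#'   instead of keeping one component for its whole track.
#' @return An object of class `diffusion_model`.
#' @examples
#' one <- diffusion_model(0.68)
#' two <- diffusion_model(c(0.027, 0.51), c(0.2, 0.8))
#' @export
diffusion_model <- function(d, weight = NULL, switching = NULL) {
  if (length(d) == 0L) stop("empty component list", call. = FALSE)
  if (any(!is.finite(d)) || any(d < 0))
    stop("every diffusion coefficient must be finite and >= 0", call. = FALSE)
  if (is.null(weight)) {
    if (length(d) != 1L)
      stop("`weight` is required for more than one component", call. = FALSE)
    weight <- 1
  }
  if (length(weight) != length(d))
    stop("`d` and `weight` must have the same length", call. = FALSE)
  if (any(weight < 0) || abs(sum(weight) - 1) > 1e-9)
    stop("weights must be non-negative and sum to 1 (within 1e-9)",
         call. = FALSE)
  if (!is.null(switching)) {
    if (length(d) != 2L)
      stop("switching requires exactly two components (static, mobile)",
           call. = FALSE)
    stopifnot_scalar(switching$mean_static_dwell, "mean_static_dwell", 0,
                     strict_lower = TRUE)
    stopifnot_scalar(switching$mean_mobile_dwell, "mean_mobile_dwell", 0,
                     strict_lower = TRUE)
  }
  structure(list(components = data.frame(d = d, weight = weight),
                 switching = switching),
            class = "diffusion_model")
}

# Draw track lengths (in frames) according to the configured law.
draw_track_lengths <- function(n, law) {
  if (law$distribution == "fixed") {
    rep.int(max(law$min, round(law$mean)), n)
  } else {
    # geometric survival: length = min + Geom with mean (mean - min)
    excess <- law$mean - law$min
    if (excess <= 0) rep.int(law$min, n)
    else law$min + rgeom(n, prob = 1 / (excess + 1))
  }
}

inside_rod <- function(x, y, len, width) {
  r <- width / 2
  hx <- pmax(abs(x) - (len / 2 - r), 0)
  hx^2 + y^2 <= r^2
}

#' Simulate 2D Brownian trajectories
#'
#' Generates single-molecule tracks whose per-axis frame-to-frame
#' displacements are draws from Normal(0, 2 * D * dt) for the molecule's
#' diffusive component, plus independent localization error on every
#' coordinate. Without switching, each molecule is assigned one component
#' for its lifetime according to the component weights; with switching,
#' molecules alternate between the static and mobile states with
#' exponential dwell times (simulated in continuous time, so a frame
#' spanning a state change gets the time-weighted mixture variance).
#'
#' @param model A [diffusion_model()].
#' @param n_tracks Number of tracks to simulate (>= 1).
#' @param config A [sim_config()].
#' @return A [track_set()]. When the model switches states, the attribute
#'   `"dwell_log"` records every completed dwell (columns `track_id`,
#'   `state`, `duration` in seconds) drawn by the generator, which is the
#'   ground truth for residence-time recovery tests.
#' @examples
#' ts <- simulate_brownian_tracks(diffusion_model(0.68), 10,
#'                                sim_config(1, 0.041))
#' @export
simulate_brownian_tracks <- function(model, n_tracks, config) {
  if (!inherits(model, "diffusion_model"))
    stop("invalid model: use diffusion_model()", call. = FALSE)
  stopifnot_scalar(n_tracks, "n_tracks", 1)
  stopifnot(inherits(config, "sim_config"))
  dt <- config$frame_interval

  with_seed(config$seed, {
    lens <- draw_track_lengths(n_tracks, config$track_length_law)
    comp <- model$components
    dwell_log <- NULL

    if (is.null(model$switching)) {
      which_comp <- sample.int(nrow(comp), n_tracks, replace = TRUE,
                               prob = comp$weight)
      step_sd <- sqrt(2 * comp$d[which_comp] * dt)
      n_steps <- lens - 1L
      sds <- rep.int(step_sd, n_steps)
      dx <- rnorm(sum(n_steps), 0, sds)
      dy <- rnorm(sum(n_steps), 0, sds)
      track_of_step <- rep.int(seq_len(n_tracks), n_steps)
      x <- unlist(lapply(split(dx, track_of_step), function(s) cumsum(c(0, s))),
                  use.names = FALSE)
      y <- unlist(lapply(split(dy, track_of_step), function(s) cumsum(c(0, s))),
                  use.names = FALSE)
    } else {
      # continuous-time two-state alternation; component 1 = static
      ord <- order(comp$d)
      d_static <- comp$d[ord[1]]; d_mobile <- comp$d[ord[2]]
      tau <- c(model$switching$mean_static_dwell,
               model$switching$mean_mobile_dwell)
      p_static <- tau[1] / sum(tau)
      x <- y <- numeric(sum(lens))
      logs <- vector("list", n_tracks)
      pos <- 1L
      for (i in seq_len(n_tracks)) {
        n <- lens[i]
        state <- if (runif(1) < p_static) 1L else 2L
        t_rem <- rexp(1, 1 / tau[state])
        # every drawn dwell is logged in full: it is the generator's ground
        # truth, independent of how frames later quantize it
        durs <- t_rem; states <- state
        frac_static <- numeric(n - 1L)   # share of each frame in static state
        for (s in seq_len(n - 1L)) {
          left <- dt; f_static <- 0
          while (t_rem < left) {
            if (state == 1L) f_static <- f_static + t_rem / dt
            left <- left - t_rem
            state <- 3L - state
            t_rem <- rexp(1, 1 / tau[state])
            durs <- c(durs, t_rem); states <- c(states, state)
          }
          if (state == 1L) f_static <- f_static + left / dt
          t_rem <- t_rem - left
          frac_static[s] <- f_static
        }
        var_step <- 2 * dt * (frac_static * d_static +
                              (1 - frac_static) * d_mobile)
        sx <- cumsum(c(0, rnorm(n - 1L, 0, sqrt(var_step))))
        sy <- cumsum(c(0, rnorm(n - 1L, 0, sqrt(var_step))))
        x[pos:(pos + n - 1L)] <- sx
        y[pos:(pos + n - 1L)] <- sy
        pos <- pos + n
        if (length(durs))
          logs[[i]] <- data.frame(track_id = i,
                                  state = c("static", "mobile")[states],
                                  duration = durs)
      }
      dwell_log <- do.call(rbind, logs[!vapply(logs, is.null, TRUE)])
      track_of_step <- NULL
    }

    tracks <- data.frame(
      track_id = rep.int(seq_len(n_tracks), lens),
      frame = unlist(lapply(lens, function(n) seq_len(n) - 1L),
                     use.names = FALSE),
      x = x, y = y)

    if (!is.null(config$confinement)) {
      # keep steps inside the rod by resampling out-of-bounds increments
      cl <- config$confinement
      tracks <- do.call(rbind, lapply(split(tracks, tracks$track_id),
        function(tr) {
          for (k in seq_len(nrow(tr))[-1]) {
            tries <- 0L
            while (!inside_rod(tr$x[k], tr$y[k], cl$length, cl$width) &&
                   tries < 100L) {
              stepx <- rnorm(1, 0, abs(tr$x[k] - tr$x[k - 1]) + 1e-12)
              tr$x[k] <- tr$x[k - 1] + stepx * sign(rnorm(1))
              tr$y[k] <- tr$y[k - 1] +
                rnorm(1, 0, abs(tr$y[k] - tr$y[k - 1]) + 1e-12)
              tries <- tries + 1L
            }
          }
          tr
        }))
      rownames(tracks) <- NULL
    }

    if (config$localization_error_sd > 0) {
      tracks$x <- tracks$x + rnorm(nrow(tracks), 0,
                                   config$localization_error_sd)
      tracks$y <- tracks$y + rnorm(nrow(tracks), 0,
                                   config$localization_error_sd)
    }

    out <- track_set(tracks, frame_interval = dt)
    attr(out, "dwell_log") <- dwell_log
    out
  })
}

#' Simulate a FRAP recovery trace
#'
#' Produces a four-channel intensity time series (ROI, background, control
#' cell, whole cell) following the single-exponential recovery model: a
#' pre-bleach plateau at 1, an instantaneous drop by `bleach_depth` at the
#' bleach frame, and recovery of the mobile share along
#' `mobile_level * (1 - exp(-k_r * t))`. All signal channels are multiplied
#' by `exp(-acquisition_bleach_rate * t)` (the control and whole-cell
#' channels carry the same decay, which is what the normalization schemes
#' exploit), and independent Gaussian noise of sd `noise_sd` is added to
#' every channel.
#'
#' With the default `roi_share = 0` the bleached region is treated as a
#' negligible share of the fluorophore pool, so the whole-cell channel is
#' conserved and full recovery of the mobile fraction reaches exactly
#' `1 - bleach_depth * (1 - mobile_level)`. A positive `roi_share` models a
#' finite pool: the whole-cell channel then drops by
#' `roi_share * bleach_depth` at the bleach and the mobile pool is depleted
#' accordingly.
#'
#' @param mobile_level Fraction of molecules that exchange (0..1); `1 -
#'   mobile_level` is the non-exchanging (immobile) pool.
#' @param k_r Recovery rate in 1/s (> 0). Half-time is `log(2) / k_r`.
#' @param bleach_depth Fraction of ROI signal destroyed by the bleach pulse
#'   (default 1, a complete bleach).
#' @param acquisition_bleach_rate Exponential acquisition-bleaching rate in
#'   1/s applied to all signal channels (default 0).
#' @param noise_sd Additive Gaussian noise sd, in units of the pre-bleach
#'   ROI intensity (default 0).
#' @param n_pre Number of pre-bleach frames (>= 1).
#' @param n_post Number of post-bleach frames (>= 3).
#' @param config A [sim_config()] (supplies frame interval and seed).
#' @param roi_share Share of total cell fluorescence inside the ROI
#'   (default 0, see above).
#' @param background_level Constant background added to every measured
#'   channel and emitted as the background channel (default 0).
#' @return A [frap_trace()].
#' @examples
#' cfg <- sim_config(1, 0.041)
#' tr <- simulate_frap_trace(0.9, log(2) / 2.5, n_pre = 10, n_post = 200,
#'                           config = cfg)
#' @export
simulate_frap_trace <- function(mobile_level, k_r,
                                bleach_depth = 1,
                                acquisition_bleach_rate = 0,
                                noise_sd = 0,
                                n_pre, n_post,
                                config,
                                roi_share = 0,
                                background_level = 0) {
  stopifnot_scalar(mobile_level, "mobile_level", 0, 1)
  stopifnot_scalar(k_r, "k_r", 0, strict_lower = TRUE)
  stopifnot_scalar(bleach_depth, "bleach_depth", 0, 1)
  stopifnot_scalar(roi_share, "roi_share", 0, 1)
  stopifnot(inherits(config, "sim_config"))
  if (n_pre < 1 || n_post < 3)
    stop("insufficient trace: need n_pre >= 1 and n_post >= 3", call. = FALSE)

  dt <- config$frame_interval
  n <- n_pre + n_post
  times <- (seq_len(n) - 1) * dt
  bleach_index <- n_pre + 1L          # first post-bleach frame
  u <- times - times[bleach_index]    # time since bleach
  m <- mobile_level; b <- bleach_depth; s <- roi_share

  roi <- rep.int(1, n)
  post <- seq.int(bleach_index, n)
  # finite-pool recovery: plateau (1-m)(1-b) + m(1-s*b); at u=0 equals 1-b
  roi[post] <- (1 - m) * (1 - b) + m * (1 - s * b) -
    m * b * (1 - s) * exp(-k_r * u[post])

  whole <- rep.int(1, n)
  whole[post] <- 1 - s * b
  control <- rep.int(1, n)

  decay <- exp(-acquisition_bleach_rate * times)
  with_seed(config$seed, {
    noise <- function(v) v + rnorm(n, 0, noise_sd)
    frap_trace(times = times,
               roi = noise(roi * decay + background_level),
               background = noise(rep.int(background_level, n)),
               control_cell = noise(control * decay + background_level),
               whole_cell = noise(whole * decay + background_level),
               bleach_index = bleach_index)
  })
}

#' Simulate an anti-phase two-region oscillation trace
#'
#' Generates paired region intensities in which signal shuttles between the
#' two regions while the total is conserved:
#' `I1 = baseline + amplitude * sin(2*pi*t / period) + noise` and
#' `I2 = 2*baseline - I1_clean + noise`.
#'
#' @param period Oscillation period in seconds (> 2 frame intervals).
#' @param amplitude Oscillation amplitude as a fraction of `baseline`
#'   (must not exceed it, otherwise intensities would go negative).
#' @param noise_sd Additive Gaussian noise sd on each channel.
#' @param n_frames Number of frames.
#' @param config A [sim_config()].
#' @param baseline Mean region intensity (default 1).
#' @return An [oscillation_trace()].
#' @export
simulate_oscillation_trace <- function(period, amplitude, noise_sd,
                                       n_frames, config, baseline = 1) {
  stopifnot(inherits(config, "sim_config"))
  dt <- config$frame_interval
  if (period <= 2 * dt)
    stop("period must exceed two frame intervals", call. = FALSE)
  if (amplitude > baseline)
    stop("negative intensity: amplitude exceeds baseline", call. = FALSE)
  stopifnot_scalar(n_frames, "n_frames", 5)
  times <- (seq_len(n_frames) - 1) * dt
  clean1 <- baseline + amplitude * sin(2 * pi * times / period)
  clean2 <- 2 * baseline - clean1
  # the whole-cell channel is emitted noise-free: dividing two regions by a
  # common noisy denominator would induce a spurious positive correlation
  # unrelated to molecule exchange
  with_seed(config$seed, {
    oscillation_trace(times = times,
                      area1 = clean1 + rnorm(n_frames, 0, noise_sd),
                      area2 = clean2 + rnorm(n_frames, 0, noise_sd),
                      whole_cell = rep(2 * baseline, n_frames))
  })
}
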