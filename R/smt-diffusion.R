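#' Extract frame-to-frame displacements
#'
#' One sample per pair of consecutive frames; pairs spanning a frame gap
#' are omitted (their number is available as attribute `n_gap_skipped`).
#'
#' @param tracks A [track_set()].
#' @return A data frame of class `step_sample` with columns `track_id`,
#'   `dx`, `dy` (micrometers) and attributes `frame_interval` and
#'   `n_gap_skipped`.
#' @export
extract_steps <- function(tracks) {
  stopifnot(inherits(tracks, "track_set"))
  df <- tracks$tracks
  same <- df$track_id == c(df$track_id[-1], NA)
  dfr <- c(diff(df$frame), NA)
  take <- which(same & dfr == 1L)
  skipped <- sum(same & dfr > 1L, na.rm = TRUE)
  out <- data.frame(track_id = df$track_id[take],
                    dx = df$x[take + 1L] - df$x[take],
                    dy = df$y[take + 1L] - df$y[take])
  attr(out, "frame_interval") <- tracks$frame_interval
  attr(out, "n_gap_skipped") <- skipped
  class(out) <- c("step_sample", "data.frame")
  out
}

#' Time-averaged MSD curve of one trajectory
#'
#' For each lag `1..max_lag` (in frames), averages the squared displacement
#' over all ordered point pairs separated by exactly that many frames
#' (gap-aware: pairs must have the exact frame spacing).
#'
#' @param track Data frame with columns `frame`, `x`, `y` (one trajectory),
#'   or a [track_set()] holding a single track.
#' @param max_lag Maximum lag in frames (must be below the track length).
#' @param frame_interval Frame interval in seconds (taken from the
#'   `track_set` when one is supplied).
#' @return A data frame of class `msd_curve` with columns `lag` (seconds),
#'   `msd` (um^2) and `n_pairs`.
#' @export
msd_curve <- function(track, max_lag, frame_interval = NULL) {
  if (inherits(track, "track_set")) {
    frame_interval <- frame_interval %||% track$frame_interval
    track <- track$tracks
    if (length(unique(track$track_id)) != 1L)
      stop("msd_curve() expects a single trajectory", call. = FALSE)
  }
  if (is.null(frame_interval))
    stop("`frame_interval` required", call. = FALSE)
  n <- nrow(track)
  if (max_lag >= n) stop("max_lag must be below the track length",
                         call. = FALSE)
  msd <- npairs <- numeric(max_lag)
  fr <- track$frame
  for (L in seq_len(max_lag)) {
    # pairs at exact frame spacing L
    idx <- match(fr + L, fr)
    ok <- which(!is.na(idx))
    npairs[L] <- length(ok)
    msd[L] <- if (length(ok))
      mean((track$x[idx[ok]] - track$x[ok])^2 +
           (track$y[idx[ok]] - track$y[ok])^2) else NA_real_
  }
  structure(data.frame(lag = seq_len(max_lag) * frame_interval,
                       msd = msd, n_pairs = npairs),
            class = c("msd_curve", "data.frame"))
}

#' Ensemble diffusion coefficient from MSD curves
#'
#' Combines per-track MSD curves into an ensemble curve (weighted mean per
#' lag with the pair counts as weights), fits a straight line through the
#' origin to the first `lags_used` lags — each lag weighted by its total
#' pair count — and reports `D* = slope / 4` for free 2D diffusion. The
#' standard error comes from a seeded bootstrap over tracks.
#'
#' @param tracks A [track_set()], or a list of `msd_curve` objects.
#' @param lags_used Number of lags entering the fit (default 4; short
#'   tracks cannot support more).
#' @param n_boot Bootstrap resamples over tracks (default 200).
#' @param seed Seed for the bootstrap.
#' @param intercept Fit a free intercept to absorb localization error
#'   instead of forcing the line through the origin (default `FALSE`).
#' @return An object of class `diffusion_estimate` with `d_star`, `sem`,
#'   `n_tracks`, `lags_used`.
#' @export
fit_msd <- function(tracks, lags_used = 4L, n_boot = 200L, seed = 1L,
                    intercept = FALSE) {
  stopifnot(lags_used >= 2L)
  if (inherits(tracks, "track_set")) {
    dt <- tracks$frame_interval
    curves <- lapply(split_tracks(tracks), function(tr) {
      if (nrow(tr) <= 2L) return(NULL)
      msd_curve(tr, max_lag = min(lags_used, nrow(tr) - 1L),
                frame_interval = dt)
    })
    curves <- curves[!vapply(curves, is.null, TRUE)]
  } else {
    curves <- tracks
  }
  if (!length(curves))
    stop("insufficient data: no track supports the requested lags",
         call. = FALSE)
  usable <- vapply(curves, function(cv) any(cv$n_pairs[
    seq_len(min(lags_used, nrow(cv)))] > 0), TRUE)
  curves <- curves[usable]
  reach <- vapply(curves, function(cv)
    nrow(cv) >= lags_used && cv$n_pairs[lags_used] > 0, TRUE)
  if (!length(curves) || !any(reach))
    stop("insufficient data: all tracks shorter than lags_used + 1",
         call. = FALSE)

  est_from <- function(cvs) {
    lag_s <- cvs[[which.max(vapply(cvs, nrow, 1L))]]$lag[seq_len(lags_used)]
    wsum <- vsum <- numeric(lags_used)
    for (cv in cvs) {
      k <- min(nrow(cv), lags_used)
      w <- cv$n_pairs[seq_len(k)]
      m <- cv$msd[seq_len(k)]
      ok <- which(w > 0)
      wsum[ok] <- wsum[ok] + w[ok]
      vsum[ok] <- vsum[ok] + w[ok] * m[ok]
    }
    has <- wsum > 0
    m_ens <- vsum[has] / wsum[has]
    tau <- lag_s[has]; w <- wsum[has]
    if (intercept) {
      fit <- stats::lm.wfit(cbind(1, tau), m_ens, w)
      fit$coefficients[2] / 4
    } else {
      sum(w * m_ens * tau) / sum(w * tau^2) / 4
    }
  }

  d_star <- est_from(curves)
  n_tr <- length(curves)
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    est_from(curves[sample.int(n_tr, n_tr, replace = TRUE)])
  }, numeric(1)))
  structure(list(d_star = d_star, sem = sd(boots), n_tracks = n_tr,
                 lags_used = as.integer(lags_used)),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("<diffusion_estimate> D* = %.3f +/- %.3f um^2/s (%d tracks, %d lags)\n",
              x$d_star, x$sem, x$n_tracks, x$lags_used))
  invisible(x)
}

# log-density of a zero-mean normal, vectorized over components
mixture_loglik <- function(x, sigma2, weight) {
  dens <- vapply(seq_along(sigma2), function(k)
    weight[k] * dnorm(x, 0, sqrt(sigma2[k])), numeric(length(x)))
  if (is.null(dim(dens))) dens <- matrix(dens, nrow = length(x))
  sum(log(rowSums(dens)))
}

#' Zero-mean Gaussian mixture decomposition of step sizes
#'
#' Pools the per-axis displacements (x and y treated as independent draws,
#' doubling the effective sample size) and fits a mixture of zero-mean
#' normal densities by maximum likelihood (EM), with component variances
#' parameterized as `sigma_k^2 = 2 * d_k * dt`. The weights are the areas
#' under the component curves: for a two-component fit they are the static
#' and mobile population fractions. Multiple seeded restarts protect
#' against local optima; components are always reported in ascending order
#' of `d`, so the result does not depend on initialization labels.
#'
#' The fit uses the raw step values, not binned histograms: binning would
#' introduce an arbitrary bin-width parameter. (Histograms remain useful
#' for display.)
#'
#' @param steps A `step_sample` from [extract_steps()], or a numeric vector
#'   of pooled per-axis displacements.
#' @param n_components Number of mixture components (default 2).
#' @param frame_interval Frame interval in seconds (taken from the
#'   `step_sample` attribute when available).
#' @param n_restarts Seeded EM restarts (default 10).
#' @param seed Seed controlling the restarts.
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @return An object of class `mixture_fit` with a `components` data frame
#'   (`d` in um^2/s, `weight`), `log_likelihood`, `n_steps`, `converged`.
#' @export
fit_step_mixture <- function(steps, n_components = 2L,
                             frame_interval = NULL,
                             n_restarts = 10L, seed = 1L,
                             max_iter = 500L, tol = 1e-8) {
  if (inherits(steps, "step_sample")) {
    frame_interval <- frame_interval %||% attr(steps, "frame_interval")
    x <- c(steps$dx, steps$dy)
  } else {
    x <- as.numeric(steps)
  }
  if (is.null(frame_interval))
    stop("`frame_interval` required", call. = FALSE)
  dt <- frame_interval
  K <- as.integer(n_components)
  if (length(x) < 10L * K)
    stop(sprintf("need at least %d steps for %d components", 10L * K, K),
         call. = FALSE)

  if (K == 1L) {
    s2 <- mean(x^2)   # ML estimate for a single zero-mean normal
    return(structure(list(
      components = data.frame(d = s2 / (2 * dt), weight = 1),
      log_likelihood = mixture_loglik(x, s2, 1),
      n_steps = length(x), converged = TRUE,
      frame_interval = dt), class = "mixture_fit"))
  }

  em_once <- function(sigma2, weight) {
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      dens <- vapply(seq_len(K), function(k)
        weight[k] * dnorm(x, 0, sqrt(sigma2[k])), numeric(length(x)))
      tot <- rowSums(dens)
      tot[tot == 0] <- .Machine$double.xmin
      ll <- sum(log(tot))
      resp <- dens / tot
      nk <- colSums(resp)
      weight <- nk / length(x)
      sigma2 <- pmax(colSums(resp * x^2) / nk, 1e-12)
      if (is.finite(ll) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
        converged <- TRUE
        break
      }
      ll_old <- ll
    }
    list(sigma2 = sigma2, weight = weight, ll = ll, converged = converged)
  }

  best <- with_seed(seed, {
    v <- mean(x^2)
    # spread initial variances across the observed scale; jitter restarts
    inits <- lapply(seq_len(n_restarts), function(r) {
      spread <- exp(seq(log(0.05), log(2), length.out = K))
      jitter <- exp(rnorm(K, 0, if (r == 1L) 0 else 0.5))
      list(sigma2 = v * spread * jitter, weight = rep(1 / K, K))
    })
    fits <- lapply(inits, function(ini) em_once(ini$sigma2, ini$weight))
    fits[[which.max(vapply(fits, `[[`, numeric(1), "ll"))]]
  })

  ord <- order(best$sigma2)
  structure(list(
    components = data.frame(d = best$sigma2[ord] / (2 * dt),
                            weight = best$weight[ord]),
    log_likelihood = best$ll,
    n_steps = length(x),
    converged = best$converged,
    frame_interval = dt), class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> %d components over %d steps (logL = %.1f%s)\n",
              nrow(x$components), x$n_steps, x$log_likelihood,
              if (x$converged) "" else ", NOT converged"))
  with(x$components, for (i in seq_along(d))
    cat(sprintf("  d = %.4f um^2/s, weight = %.1f%%\n",
                d[i], 100 * weight[i])))
  invisible(x)
}

#' Model selection across mixture orders
#'
#' Fits step-size mixtures of several orders and reports log-likelihood,
#' BIC and AIC per order, so a 1- vs 2- vs 3-component decision can be
#' made (a mixture of `K` zero-mean components has `2K - 1` free
#' parameters).
#'
#' @inheritParams fit_step_mixture
#' @param orders Integer vector of component counts to compare.
#' @return Data frame with one row per order (`order`, `log_likelihood`,
#'   `bic`, `aic`, `converged`) and the fits as attribute `"fits"`.
#' @export
compare_mixture_orders <- function(steps, orders = 1:3,
                                   frame_interval = NULL, ...) {
  stopifnot(length(orders) >= 1L)
  fits <- lapply(orders, function(K)
    fit_step_mixture(steps, n_components = K,
                     frame_interval = frame_interval, ...))
  n <- fits[[1]]$n_steps
  ll <- vapply(fits, `[[`, numeric(1), "log_likelihood")
  npar <- 2 * orders - 1
  out <- data.frame(order = orders,
                    log_likelihood = ll,
                    bic = -2 * ll + npar * log(n),
                    aic = -2 * ll + 2 * npar,
                    converged = vapply(fits, `[[`, logical(1), "converged"))
  attr(out, "fits") <- fits
  out
}
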