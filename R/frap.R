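new_normalized_trace <- function(times, values, mode, prebleach_level,
                                 n_pre, n_traces = 1L) {
  structure(list(times = times, values = values,
                 normalization_mode = mode,
                 prebleach_level = prebleach_level,
                 n_pre = n_pre, n_traces = n_traces),
            class = "normalized_trace")
}

#' @export
print.normalized_trace <- function(x, ...) {
  cat(sprintf(
    "<normalized_trace> %s normalization, %d frames (%d pre-bleach)\n",
    x$normalization_mode, length(x$times), x$n_pre))
  invisible(x)
}

normalize_frap <- function(trace, denom, mode,
                           subtract_background_from_denominator = TRUE) {
  bg <- trace$background
  den <- if (subtract_background_from_denominator) denom - bg else denom
  if (any(den <= 0))
    stop(sprintf("degenerate %s channel: non-positive value at frame %d",
                 mode, which(den <= 0)[1]), call. = FALSE)
  ratio <- (trace$roi - bg) / den
  pre <- seq_len(trace$bleach_index - 1L)
  pre_mean <- mean(ratio[pre])
  if (!is.finite(pre_mean) || pre_mean <= 0)
    stop("degenerate pre-bleach level", call. = FALSE)
  new_normalized_trace(
    times = trace$times - trace$times[trace$bleach_index],
    values = ratio / pre_mean,
    mode = mode,
    prebleach_level = mean(trace$roi[pre] - bg[pre]),
    n_pre = length(pre))
}

#' Single (control-cell) normalization of a FRAP trace
#'
#' Corrects for acquisition bleaching by dividing the background-subtracted
#' ROI signal by the background-subtracted intensity of an unbleached
#' control cell, then normalizes to the pre-bleach mean of that ratio.
#' Times are shifted so the first post-bleach frame is at t = 0.
#'
#' @param trace A [frap_trace()].
#' @param subtract_background_from_control Whether the control channel is
#'   background-subtracted as well (default `TRUE`; the symmetric choice).
#' @return A `normalized_trace` whose pre-bleach mean is 1.
#' @export
single_normalize <- function(trace, subtract_background_from_control = TRUE) {
  stopifnot(inherits(trace, "frap_trace"))
  normalize_frap(trace, trace$control_cell, "single",
                 subtract_background_from_control)
}

#' Double (whole-cell) normalization of a FRAP trace
#'
#' Divides the background-subtracted ROI signal by the background-
#' subtracted whole-cell intensity and normalizes to the pre-bleach mean of
#' that ratio. This corrects for both acquisition bleaching and the
#' fluorescence destroyed by the bleach pulse itself, so the recovery level
#' `A` of a subsequent [fit_recovery()] is interpretable as the mobile
#' fraction and `1 - A` as the immobile (non-exchanging) fraction.
#'
#' @inheritParams single_normalize
#' @return A `normalized_trace` whose pre-bleach mean is 1.
#' @export
double_normalize <- function(trace, subtract_background_from_control = TRUE) {
  stopifnot(inherits(trace, "frap_trace"))
  normalize_frap(trace, trace$whole_cell, "double",
                 subtract_background_from_control)
}

full_scale_normalize <- function(nt) {
  post <- nt$times >= 0
  pre_mean <- mean(nt$values[!post])
  v_min <- min(nt$values[post])
  span <- pre_mean - v_min
  if (span <= 0) stop("full-scale normalization needs pre-bleach > post-bleach minimum",
                      call. = FALSE)
  nt$values <- (nt$values - v_min) / span
  nt
}

#' Group normalized traces into intensity-matched clusters
#'
#' To stabilize fitting, traces are sorted by pre-bleach intensity,
#' partitioned into consecutive groups of `cluster_size` ("similar
#' intensities" operationalized as adjacency after sorting), full-scale
#' normalized (post-bleach minimum to 0, pre-bleach mean to 1, correcting
#' for different bleach depths) and averaged pointwise within each group.
#' A remainder group is kept when it still holds at least two traces,
#' otherwise dropped with a message.
#'
#' @param traces List of `normalized_trace` objects of equal length and
#'   identical time grids.
#' @param cluster_size Traces per cluster (default 3).
#' @return List of averaged `normalized_trace` objects, one per cluster,
#'   each carrying `n_traces`.
#' @export
cluster_traces <- function(traces, cluster_size = 3L) {
  stopifnot(length(traces) >= cluster_size)
  lens <- vapply(traces, function(t) length(t$times), integer(1))
  if (length(unique(lens)) != 1L)
    stop("alignment error: traces have unequal length (resampling is not attempted)",
         call. = FALSE)
  ord <- order(vapply(traces, `[[`, numeric(1), "prebleach_level"))
  traces <- lapply(traces[ord], full_scale_normalize)
  n <- length(traces)
  groups <- split(seq_len(n), ceiling(seq_len(n) / cluster_size))
  keep <- lengths(groups) >= 2L
  if (any(!keep))
    message(sprintf("dropping %d leftover trace(s) (cluster below 2)",
                    sum(lengths(groups)[!keep])))
  groups <- groups[keep]
  lapply(groups, function(idx) {
    vals <- rowMeans(vapply(traces[idx], `[[`,
                            numeric(lens[1]), "values"))
    out <- traces[[idx[1]]]
    out$values <- vals
    out$prebleach_level <- mean(vapply(traces[idx], `[[`, numeric(1),
                                       "prebleach_level"))
    out$n_traces <- length(idx)
    out
  })
}

#' Fit the single-exponential recovery model
#'
#' Least-squares fit of `f(t) = A * (1 - exp(-k_r * t))` to the post-bleach
#' points (t >= 0) of a normalized trace, by Levenberg-Marquardt. The fit
#' is initialized from the last-quartile mean (`A0`) and from the time at
#' which the trace first crosses `A0 / 2` by linear interpolation
#' (`k0 = log(2) / t_half_guess`). The recovery half-time is
#' `t_half = log(2) / k_r` and, for double-normalized data, `1 - A` clamped
#' to [0, 1] is the immobile fraction.
#'
#' @param trace A `normalized_trace` with at least 4 post-bleach points.
#' @return An object of class `frap_fit` with fields `A`, `k_r`, `t_half`,
#'   `immobile_fraction`, `n_traces`, `residual_sse`.
#' @export
fit_recovery <- function(trace) {
  stopifnot(inherits(trace, "normalized_trace"))
  post <- trace$times >= 0
  t <- trace$times[post]
  v <- trace$values[post]
  if (length(t) < 4L)
    stop("need at least 4 post-bleach points", call. = FALSE)

  a0 <- mean(v[t >= quantile(t, 0.75)])
  if (!is.finite(a0) || a0 <= 0) a0 <- max(v) / 2
  above <- which(v >= a0 / 2)
  t_half0 <- if (length(above) && above[1] > 1) {
    i <- above[1]
    approx(v[(i - 1):i], t[(i - 1):i], xout = a0 / 2, ties = "ordered")$y
  } else if (length(above)) t[pmin(2L, length(t))] else max(t) / 2
  if (!is.finite(t_half0) || t_half0 <= 0) t_half0 <- max(t) / 4
  k0 <- log(2) / t_half0

  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ A * (1 - exp(-k * t)),
                      start = list(A = a0, k = k0),
                      lower = c(A = 0, k = 1e-8),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop(sprintf(
        "recovery fit did not converge (start A=%.3g, k=%.3g; %d points, range [%.3g, %.3g]): %s",
        a0, k0, length(v), min(v), max(v), conditionMessage(e)),
        call. = FALSE))
  est <- coef(fit)
  if (est[["k"]] <= 2e-8)
    warning("recovery rate at parameter bound; fit unreliable", call. = FALSE)
  a <- est[["A"]]; k <- est[["k"]]
  structure(list(A = a,
                 k_r = k,
                 t_half = log(2) / k,
                 immobile_fraction = min(max(1 - a, 0), 1),
                 n_traces = trace$n_traces %||% 1L,
                 residual_sse = sum(residuals(fit)^2),
                 normalization_mode = trace$normalization_mode),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "<frap_fit> A = %.3f, k_r = %.4f 1/s, t_half = %.3f s, immobile = %.1f%%\n",
    x$A, x$k_r, x$t_half, 100 * x$immobile_fraction))
  invisible(x)
}

#' Mean and standard error of recovery half-times
#'
#' @param fits List of `frap_fit` objects (>= 2), typically one per
#'   cluster.
#' @return List with `mean` and `sem` (seconds); SEM is sd / sqrt(n) over
#'   the cluster half-times.
#' @export
summarize_halftimes <- function(fits) {
  stopifnot(length(fits) >= 2L)
  th <- vapply(fits, `[[`, numeric(1), "t_half")
  list(mean = mean(th), sem = sd(th) / sqrt(length(th)), n = length(th))
}

#' Compare two groups of recovery half-times
#'
#' Two-sided two-sample Student's t-test (pooled variance by default, to
#' match the classical test; Welch's correction behind `welch = TRUE`).
#'
#' @param group_a,group_b Numeric vectors of half-times in seconds (each
#'   >= 2 values).
#' @param welch Use Welch's unequal-variance t-test instead.
#' @return An object of class `halftime_comparison` with means, SEMs, the
#'   t statistic and the p value.
#' @export
compare_halftimes <- function(group_a, group_b, welch = FALSE) {
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  if (sd(group_a) == 0 && sd(group_b) == 0 &&
      mean(group_a) == mean(group_b)) {
    tt <- list(statistic = c(t = 0), p.value = 1)  # degenerate: identical
  } else {
    tt <- t.test(group_a, group_b, var.equal = !welch)
  }
  structure(list(mean_a = mean(group_a), mean_b = mean(group_b),
                 sem_a = sd(group_a) / sqrt(length(group_a)),
                 sem_b = sd(group_b) / sqrt(length(group_b)),
                 t_statistic = unname(tt$statistic),
                 p_value = tt$p.value),
            class = "halftime_comparison")
}

#' @export
print.halftime_comparison <- function(x, ...) {
  cat(sprintf(
    "<halftime_comparison> %.2f +/- %.2f s vs %.2f +/- %.2f s, t = %.2f, p = %.3g\n",
    x$mean_a, x$sem_a, x$mean_b, x$sem_b, x$t_statistic, x$p_value))
  invisible(x)
}
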