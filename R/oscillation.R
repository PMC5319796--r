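#' Normalize two region intensities to whole-cell signal
#'
#' Divides each region's intensity framewise by the whole-cell intensity,
#' which cancels any decay (e.g. photobleaching) common to all channels.
#'
#' @param trace An [oscillation_trace()].
#' @return List with `series1` and `series2`.
#' @export
normalize_areas <- function(trace) {
  stopifnot(inherits(trace, "oscillation_trace"))
  bad <- which(trace$whole_cell <= 0)
  if (length(bad))
    stop(sprintf("degenerate trace: non-positive whole-cell value at frame %d",
                 bad[1]), call. = FALSE)
  list(series1 = trace$area1 / trace$whole_cell,
       series2 = trace$area2 / trace$whole_cell)
}

#' Correlation between two whole-cell-normalized region intensities
#'
#' Quantifies anti-phase intensity exchange between two regions of one
#' cell: coordinated shuttling of molecules gives a strongly negative
#' correlation, while a spatially fixed marker gives a correlation near
#' zero. Pearson's r is the default; Spearman's rank correlation is
#' available for heavy-tailed intensities.
#'
#' @param trace An [oscillation_trace()] with at least 5 frames.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return An object of class `oscillation_result` with
#'   `normalized_area1`, `normalized_area2`, `correlation`, `n_frames`.
#' @export
area_correlation <- function(trace, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(trace, "oscillation_trace"))
  if (length(trace$times) < 5L)
    stop("need at least 5 frames", call. = FALSE)
  s <- normalize_areas(trace)
  if (sd(s$series1) == 0 || sd(s$series2) == 0)
    stop("undefined correlation: a normalized series has zero variance",
         call. = FALSE)
  structure(list(normalized_area1 = s$series1,
                 normalized_area2 = s$series2,
                 correlation = cor(s$series1, s$series2, method = method),
                 n_frames = length(trace$times)),
            class = "oscillation_result")
}

#' @export
print.oscillation_result <- function(x, ...) {
  cat(sprintf("<oscillation_result> r = %.3f over %d frames\n",
              x$correlation, x$n_frames))
  invisible(x)
}

#' Exploratory oscillation period estimate
#'
#' Reports twice the lag of the first minimum of the autocorrelation of
#' the difference between the two normalized series. This is an
#' exploratory aid only — a visual check of the traces remains the
#' authoritative way to judge periodicity.
#'
#' @param trace An [oscillation_trace()].
#' @return Estimated period in seconds, or `NA` when no interior
#'   autocorrelation minimum exists.
#' @export
estimate_period <- function(trace) {
  stopifnot(inherits(trace, "oscillation_trace"))
  s <- normalize_areas(trace)
  diffsig <- s$series1 - s$series2
  n <- length(diffsig)
  ac <- acf(diffsig, lag.max = n - 2L, plot = FALSE)$acf[, 1, 1]
  mins <- which(diff(sign(diff(ac))) > 0) + 1L   # local minima (lag index)
  if (!length(mins)) return(NA_real_)
  dt <- mean(diff(trace$times))
  2 * (mins[1] - 1L) * dt
}
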