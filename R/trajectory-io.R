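#' Trajectory set container
#'
#' A `track_set` holds time-ordered 2D single-molecule localizations for
#' many tracks at a common frame interval. The underlying table has columns
#' `track_id`, `frame` (0-based integer index), `x`, `y` (micrometers).
#' Frame indices must be strictly increasing within a track; gaps (missing
#' frames) are permitted and are handled explicitly downstream (a gap
#' breaks static intervals and excludes the spanning step pair).
#'
#' @param tracks Data frame with columns `track_id`, `frame`, `x`, `y`.
#' @param frame_interval Frame interval in seconds.
#' @param pixel_size Optional pixel calibration in micrometers (metadata
#'   only; coordinates are always stored in micrometers).
#' @return An object of class `track_set`.
#' @export
track_set <- function(tracks, frame_interval, pixel_size = NA_real_) {
  stopifnot(is.data.frame(tracks),
            all(c("track_id", "frame", "x", "y") %in% names(tracks)))
  stopifnot_scalar(frame_interval, "frame_interval", 0, strict_lower = TRUE)
  if (nrow(tracks)) {
    if (any(!is.finite(tracks$x)) || any(!is.finite(tracks$y)))
      stop("all coordinates must be finite", call. = FALSE)
    tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
    rownames(tracks) <- NULL
    dup <- duplicated(tracks[c("track_id", "frame")])
    if (any(dup))
      stop(sprintf("duplicate (track, frame) pair at row %d",
                   which(dup)[1]), call. = FALSE)
  }
  structure(list(tracks = tracks, frame_interval = frame_interval,
                 pixel_size = pixel_size),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  n <- length(unique(x$tracks$track_id))
  cat(sprintf("<track_set> %d tracks, %d localizations, dt = %g s\n",
              n, nrow(x$tracks), x$frame_interval))
  invisible(x)
}

#' @export
length.track_set <- function(x) length(unique(x$tracks$track_id))

# split into per-track data frames (ordered by frame)
split_tracks <- function(ts) {
  split(ts$tracks, ts$tracks$track_id)
}

#' FRAP intensity trace container
#'
#' Measured channels of one bleach-recovery experiment: the bleached region
#' of interest, the image background, an unbleached control cell and the
#' whole bleached cell. `bleach_index` is the index (1-based) of the first
#' post-bleach frame.
#'
#' @param times Acquisition times in seconds, strictly increasing.
#' @param roi,background,control_cell,whole_cell Intensity vectors of equal
#'   length.
#' @param bleach_index Index of the first post-bleach frame. Must leave at
#'   least 1 pre-bleach and 3 post-bleach points.
#' @return An object of class `frap_trace`.
#' @export
frap_trace <- function(times, roi, background, control_cell, whole_cell,
                       bleach_index) {
  n <- length(times)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  for (nm in c("roi", "background", "control_cell", "whole_cell"))
    if (length(get(nm)) != n)
      stop(sprintf("`%s` must match the length of `times`", nm),
           call. = FALSE)
  bleach_index <- as.integer(bleach_index)
  if (bleach_index < 2L || bleach_index > n - 2L)
    stop("bleach_index must leave >= 1 pre-bleach and >= 3 post-bleach points",
         call. = FALSE)
  structure(list(times = times, roi = roi, background = background,
                 control_cell = control_cell, whole_cell = whole_cell,
                 bleach_index = bleach_index),
            class = "frap_trace")
}

#' @export
print.frap_trace <- function(x, ...) {
  cat(sprintf("<frap_trace> %d frames (%d pre-bleach), t = [%g, %g] s\n",
              length(x$times), x$bleach_index - 1L,
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Two-region oscillation trace container
#'
#' @param times Acquisition times in seconds, strictly increasing.
#' @param area1,area2 Region intensity vectors.
#' @param whole_cell Whole-cell intensity vector used for normalization.
#' @return An object of class `oscillation_trace`.
#' @export
oscillation_trace <- function(times, area1, area2, whole_cell) {
  n <- length(times)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (length(area1) != n || length(area2) != n || length(whole_cell) != n)
    stop("all channels must match the length of `times`", call. = FALSE)
  structure(list(times = times, area1 = area1, area2 = area2,
                 whole_cell = whole_cell),
            class = "oscillation_trace")
}

#' Read a trajectory CSV
#'
#' The dialect is comma-separated UTF-8 with header
#' `track_id,frame,x_um,y_um`, 0-based frame indices and coordinates in
#' micrometers. Metadata comment lines of the form `# key=value` before the
#' header may carry `frame_interval` (seconds) and `pixel_size`
#' (micrometers). Files with coordinates in pixel units can be converted on
#' read via `pixel_size`.
#'
#' Native tracker formats (MTrackJ `.mdf`, u-track `.mat`, TrackMate XML)
#' are not parsed; export from those programs to this four-column CSV (most
#' offer a spreadsheet export) and supply `frame_interval` either as a
#' metadata line or through `dt`.
#'
#' @param path Path to the CSV file.
#' @param dt Frame interval in seconds; overrides any metadata line.
#' @param pixel_size If given, coordinates in the file are taken to be in
#'   pixels and are multiplied by this calibration (micrometers per pixel).
#' @return A [track_set()].
#' @export
read_tracks_csv <- function(path, dt = NULL, pixel_size = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  meta <- read_meta_comments(path)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("track_id", "frame", "x_um", "y_um")
  if (!all(req %in% names(df)))
    stop(sprintf("trajectory CSV must have columns %s",
                 paste(req, collapse = ", ")), call. = FALSE)
  dt <- dt %||% meta$frame_interval
  if (is.null(dt))
    stop("frame_interval missing: supply `dt` or a '# frame_interval=' line",
         call. = FALSE)
  px <- pixel_size %||% meta$pixel_size %||% NA_real_
  scale <- if (!is.null(pixel_size)) pixel_size else 1
  if (nrow(df)) {
    for (col in c("frame", "x_um", "y_um")) {
      v <- suppressWarnings(as.numeric(df[[col]]))
      if (any(is.na(v)))
        stop(sprintf("malformed value in column `%s`, row %d of %s",
                     col, which(is.na(v))[1], path), call. = FALSE)
      df[[col]] <- v
    }
    # frames must increase in file order within each track: a duplicated
    # (track, frame) pair gives diff 0, a shuffled export a negative diff
    nondec <- ave(df$frame, df$track_id, FUN = function(f) c(1, diff(f)))
    if (any(nondec <= 0))
      stop(sprintf("non-monotone or duplicated frame at row %d",
                   which(nondec <= 0)[1]), call. = FALSE)
  }
  track_set(data.frame(track_id = df$track_id, frame = as.integer(df$frame),
                       x = df$x_um * scale, y = df$y_um * scale),
            frame_interval = as.numeric(dt), pixel_size = px)
}

read_meta_comments <- function(path) {
  lines <- readLines(path, n = 50L, warn = FALSE)
  lines <- lines[startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(sub("^#\\s*", "", ln), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2L) out[[trimws(kv[1])]] <- as.numeric(trimws(kv[2]))
  }
  out
}

#' Write a trajectory CSV
#'
#' Inverse of [read_tracks_csv()]: emits the metadata comment lines
#' followed by the `track_id,frame,x_um,y_um` table, so that a write/read
#' round trip reproduces the [track_set()] exactly.
#'
#' @param tracks A [track_set()].
#' @param path Output path.
#' @export
write_tracks_csv <- function(tracks, path) {
  stopifnot(inherits(tracks, "track_set"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# frame_interval=%.17g", tracks$frame_interval), con)
  if (!is.na(tracks$pixel_size))
    writeLines(sprintf("# pixel_size=%.17g", tracks$pixel_size), con)
  df <- tracks$tracks
  out <- data.frame(track_id = df$track_id, frame = df$frame,
                    x_um = df$x, y_um = df$y)
  write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

read_trace_table <- function(path, required, optional_fill) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  for (col in required)
    if (!col %in% names(df))
      stop(sprintf("column `%s` missing from %s", col, path), call. = FALSE)
  for (col in names(optional_fill)) {
    if (!col %in% names(df)) {
      warning(sprintf("column `%s` missing from %s; filled with %g",
                      col, path, optional_fill[[col]]), call. = FALSE)
      df[[col]] <- optional_fill[[col]]
    }
  }
  for (col in c(required, names(optional_fill))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(is.na(v)))
      stop(sprintf("malformed numeric cell in column `%s`, row %d of %s",
                   col, which(is.na(v))[1], path), call. = FALSE)
    df[[col]] <- v
  }
  df
}

#' Read a FRAP trace CSV
#'
#' Expects columns `time` and `roi`; optional columns `background`
#' (filled with zeros when absent) and `control_cell` / `whole_cell`
#' (filled with ones), each absence flagged with a warning. The bleach
#' frame is taken from `bleach_index` (1-based index of the first
#' post-bleach frame), from a `# bleach_index=` metadata line, or detected
#' with [detect_bleach_index()] when neither is given.
#'
#' @param path Path to the CSV file.
#' @param bleach_index Optional explicit bleach index.
#' @return A [frap_trace()].
#' @export
read_frap_csv <- function(path, bleach_index = NULL) {
  df <- read_trace_table(path, c("time", "roi"),
                         list(background = 0, control_cell = 1,
                              whole_cell = 1))
  meta <- read_meta_comments(path)
  bi <- bleach_index %||% meta$bleach_index %||%
    detect_bleach_index(df$roi)
  if (nrow(df) - bi < 3L)
    stop("insufficient data: fewer than 4 post-bleach rows", call. = FALSE)
  frap_trace(df$time, df$roi, df$background, df$control_cell, df$whole_cell,
             bleach_index = bi)
}

#' Detect the bleach frame of a FRAP trace
#'
#' Returns the index of the first post-bleach frame, identified as the
#' frame following the largest single-frame fractional drop of the ROI
#' channel.
#'
#' @param roi ROI intensity vector.
#' @return Integer index.
#' @export
detect_bleach_index <- function(roi) {
  drops <- -diff(roi) / pmax(abs(head(roi, -1)), .Machine$double.eps)
  which.max(drops) + 1L
}

#' Read a two-region oscillation trace CSV
#'
#' Expects columns `time`, `area1`, `area2` and `whole_cell`.
#'
#' @param path Path to the CSV file.
#' @return An [oscillation_trace()].
#' @export
read_oscillation_csv <- function(path) {
  df <- read_trace_table(path, c("time", "area1", "area2", "whole_cell"),
                         list())
  oscillation_trace(df$time, df$area1, df$area2, df$whole_cell)
}

#' Serialize analysis results to JSON
#'
#' Writes any of the package's fit/result objects (or a list of them) as
#' JSON with deterministic key order and field names matching the object
#' fields. Units are included where the object carries them.
#'
#' @param results A result object or list of result objects.
#' @param path Output path.
#' @export
write_results_json <- function(results, path) {
  jsonlite::write_json(results_payload(results), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(NULL)
}

results_payload <- function(x) {
  if (is.list(x) && is.null(attr(x, "class"))) {
    lapply(x, results_payload)
  } else if (inherits(x, c("frap_fit", "halftime_comparison",
                           "diffusion_estimate", "mixture_fit",
                           "residence_summary", "false_positive_model",
                           "oscillation_result"))) {
    out <- unclass(x)
    out$.type <- class(x)[1]
    out
  } else {
    x
  }
}

#' Read back results written by [write_results_json()]
#'
#' @param path Path to the JSON file.
#' @return A list; entries that were package result objects regain their
#'   class from the stored `.type` field.
#' @export
read_results_json <- function(path) {
  restore <- function(x) {
    if (is.list(x) && !is.null(x$.type)) {
      cls <- x$.type; x$.type <- NULL
      x <- lapply(x, function(el)
        if (is.list(el) && is.null(el$.type) && length(el) &&
            all(vapply(el, is.numeric, TRUE)) &&
            all(lengths(el) == 1L)) as.data.frame(el) else el)
      return(structure(x, class = cls))
    }
    if (is.list(x)) return(lapply(x, restore))
    x
  }
  restore(jsonlite::read_json(path, simplifyVector = TRUE,
                              simplifyDataFrame = TRUE))
}
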