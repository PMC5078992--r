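# Track container and plain-CSV I/O.
#
# CSV schema (exact): header `track_id,condition,frame,x_um,y_um`, one row
# per localization, coordinates in um written with 6 decimals, frame
# 0-based. The frame interval and provenance live in a sidecar JSON
# (`<name>.meta.json`), not per-row, to avoid float drift.

TRACK_COLUMNS <- c("track_id", "condition", "frame", "x_um", "y_um")

#' Construct a validated set of single-particle tracks
#'
#' A `track_set` holds one data.frame of localizations (columns `track_id`,
#' `condition`, `frame`, `x_um`, `y_um`), the shared frame interval, and
#' free-form provenance metadata. Validation enforces the container
#' invariants: each track has at least 2 points with strictly increasing
#' frames, no duplicated (track_id, frame) pairs, finite positions.
#'
#' @param data data.frame with the columns above; rows are sorted by
#'   track_id then frame.
#' @param frame_interval Frame interval in seconds shared by all tracks.
#' @param metadata Named list of provenance (seed, source, filter history).
#' @return An object of class `track_set`.
#' @export
track_set <- function(data, frame_interval, metadata = list()) {
  stopifnot(is.data.frame(data), is.numeric(frame_interval),
            length(frame_interval) == 1L, frame_interval > 0,
            is.list(metadata))
  missing_cols <- setdiff(TRACK_COLUMNS, names(data))
  if (length(missing_cols))
    stop("track table is missing columns: ", paste(missing_cols, collapse = ", "))
  data <- data[TRACK_COLUMNS]
  data$track_id <- as.character(data$track_id)
  data$condition <- as.character(data$condition)
  data$frame <- as.integer(data$frame)
  data$x_um <- as.numeric(data$x_um)
  data$y_um <- as.numeric(data$y_um)
  if (nrow(data)) {
    if (anyNA(data$frame)) stop("non-integer frame values in track table")
    if (!all(is.finite(data$x_um)) || !all(is.finite(data$y_um)))
      stop("non-finite positions in track table")
    data <- data[order(data$track_id, data$frame), , drop = FALSE]
    rownames(data) <- NULL
    dup <- duplicated(data[c("track_id", "frame")])
    if (any(dup))
      stop("duplicated (track_id, frame) pairs in track(s): ",
           paste(unique(data$track_id[dup]), collapse = ", "))
    n_pts <- table(data$track_id)
    short <- names(n_pts)[n_pts < 2]
    if (length(short))
      stop("track(s) with fewer than 2 points: ",
           paste(short, collapse = ", "))
    # frames strictly increasing within track is implied by sort + no dup
  }
  structure(list(data = data, frame_interval = frame_interval,
                 metadata = metadata),
            class = "track_set")
}

#' Number of tracks in a track set
#' @param ts A [track_set()].
#' @return Integer count.
#' @export
n_tracks <- function(ts) {
  stopifnot(inherits(ts, "track_set"))
  length(unique(ts$data$track_id))
}

#' Per-track point counts
#' @param ts A [track_set()].
#' @return Named integer vector (names are track_ids, in sorted order).
#' @export
track_lengths <- function(ts) {
  stopifnot(inherits(ts, "track_set"))
  if (!nrow(ts$data)) return(stats::setNames(integer(), character()))
  tab <- table(ts$data$track_id)
  stats::setNames(as.integer(tab), names(tab))
}

#' Times (seconds) for a frame vector
#' @param ts A [track_set()].
#' @return Numeric vector `frame * frame_interval` aligned with `ts$data`.
#' @export
track_times <- function(ts) {
  stopifnot(inherits(ts, "track_set"))
  ts$data$frame * ts$frame_interval
}

#' @export
print.track_set <- function(x, ...) {
  lens <- track_lengths(x)
  cat(sprintf("<track_set> %d tracks, %d localizations, frame interval %g s\n",
              length(lens), nrow(x$data), x$frame_interval))
  if (length(lens))
    cat(sprintf("  track lengths: %d-%d points (median %g)\n",
                min(lens), max(lens), stats::median(lens)))
  invisible(x)
}

#' Read tracks from CSV (with optional metadata sidecar)
#'
#' Reads the documented track CSV. Malformed input (missing columns,
#' duplicate (track_id, frame) pairs, non-finite positions, tracks with < 2
#' points) is rejected with an error naming the offending tracks, never
#' coerced. If `<path>.meta.json` exists its `frame_interval` is used unless
#' one is given explicitly.
#'
#' @param path CSV file path.
#' @param frame_interval Frame interval in seconds; optional if a sidecar
#'   provides it.
#' @return A [track_set()].
#' @export
read_tracks <- function(path, frame_interval = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- list()
  side <- sidecar_path(path)
  if (file.exists(side)) meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(frame_interval)) frame_interval <- meta$frame_interval
  if (is.null(frame_interval))
    stop("frame_interval not given and no metadata sidecar found for ", path)
  df <- utils::read.csv(path, colClasses = c(track_id = "character",
                                             condition = "character"),
                        check.names = TRUE)
  meta$source <- path
  track_set(df, frame_interval = as.numeric(frame_interval), metadata = meta)
}

sidecar_path <- function(path) {
  sub("\\.csv$", "", path) |> paste0(".meta.json")
}

#' Write tracks to CSV plus a metadata sidecar
#'
#' Deterministic output: rows ordered by track_id then frame, coordinates
#' formatted with 6 decimals. Metadata (frame_interval, seed, filter
#' history, ...) is serialized to `<path stem>.meta.json`.
#'
#' @param ts A [track_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(ts, path) {
  stopifnot(inherits(ts, "track_set"))
  d <- ts$data
  lines <- c(paste(TRACK_COLUMNS, collapse = ","),
             if (nrow(d)) sprintf("%s,%s,%d,%.6f,%.6f",
                                  d$track_id, d$condition, d$frame,
                                  d$x_um, d$y_um))
  writeLines(lines, path)
  meta <- ts$metadata
  meta$frame_interval <- ts$frame_interval
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Keep only tracks whose point count lies in a window
#'
#' The analysis considers tracks persisting for 4-12 time points; this
#' filter retains exactly the tracks with point counts in
#' `[min_points, max_points]` and records the operation (with in/out counts)
#' in the metadata filter history.
#'
#' @param ts A [track_set()].
#' @param min_points Minimum points per track (>= 2), default 4.
#' @param max_points Maximum points per track, default 12; `Inf` allowed.
#' @return A filtered [track_set()].
#' @export
filter_by_length <- function(ts, min_points = 4L, max_points = 12L) {
  stopifnot(inherits(ts, "track_set"))
  if (min_points < 2) stop("min_points must be >= 2")
  if (min_points > max_points) stop("min_points must be <= max_points")
  lens <- track_lengths(ts)
  keep_ids <- names(lens)[lens >= min_points & lens <= max_points]
  out <- ts$data[ts$data$track_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  meta <- ts$metadata
  meta$filter_history <- c(meta$filter_history, list(list(
    filter = "filter_by_length", min_points = min_points,
    max_points = if (is.finite(max_points)) max_points else "Inf",
    tracks_in = length(lens), tracks_out = length(keep_ids))))
  track_set(out, frame_interval = ts$frame_interval, metadata = meta)
}

# split a track_set's rows by track, returning a list of data.frames;
# used by the estimators. Order: sorted track_id.
split_tracks <- function(ts) {
  split(ts$data, ts$data$track_id)
}
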