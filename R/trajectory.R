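#' Construct a trajectory table
#'
#' A `trajectory_table` holds per-frame centroid positions for every
#' individual in a group recording, in millimetres with the arena centre at
#' the origin. It is the common input to interaction detection and the
#' occupancy heat map. Missing detections are kept as `NA` coordinates so
#' downstream stages can treat them explicitly (no silent imputation).
#'
#' @param data A data.frame with columns `fly_id`, `frame`, `x`, `y` and
#'   optionally `heading` (radians) and `body_length` (mm). Coordinates must
#'   already be in mm relative to the arena centre; [read_tracking()] applies
#'   the calibration for you.
#' @param arena An [arena_spec()].
#' @return An object of class `trajectory_table` with fields `data`,
#'   `arena`, `n_frames` (frames span the half-open range `[0, n_frames)`)
#'   and `roster` (sorted unique fly ids).
#' @export
trajectory_table <- function(data, arena = arena_spec()) {
  stopifnot(is.data.frame(data))
  if (!is_arena_spec(arena)) stop("`arena` must be an arena_spec", call. = FALSE)
  required <- c("fly_id", "frame", "x", "y")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    stop("trajectory data is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(data) == 0L)
    stop("trajectory data has no rows", call. = FALSE)
  data$fly_id <- as.character(data$fly_id)
  data$frame <- as.integer(data$frame)
  if (anyNA(data$frame) || any(data$frame < 0L))
    stop("`frame` must be a non-negative integer for every row", call. = FALSE)
  if (anyDuplicated(data[c("fly_id", "frame")]))
    stop("duplicate (fly_id, frame) pairs in trajectory data", call. = FALSE)
  keep <- intersect(c("fly_id", "frame", "x", "y", "heading", "body_length"),
                    names(data))
  data <- data[order(data$fly_id, data$frame), keep, drop = FALSE]
  rownames(data) <- NULL
  structure(
    list(data = data, arena = arena,
         n_frames = max(data$frame) + 1L,
         roster = sort(unique(data$fly_id))),
    class = "trajectory_table")
}

#' @export
print.trajectory_table <- function(x, ...) {
  cat(sprintf("<trajectory_table> %d flies x %d frames (%.1f s at %g fps)\n",
              length(x$roster), x$n_frames, x$n_frames / x$arena$fps,
              x$arena$fps))
  invisible(x)
}

#' Read a tracker export into a trajectory table
#'
#' Reads a delimited text export of per-frame, per-individual positions
#' (e.g. from FlyTracker after conversion to CSV) and applies the arena
#' calibration: raw coordinates are divided by `px_per_mm` (when present)
#' and re-centred on the arena centre, so all downstream thresholds can be
#' metric. Rows with non-finite coordinates are retained as missing
#' detections.
#'
#' @param path Path to a delimited text file with a header naming at least
#'   `fly_id`, `frame`, `x`, `y` (aliases `id` and `t` are accepted).
#' @param arena An [arena_spec()] describing geometry and calibration.
#' @param sep Field separator (default `","`).
#' @return A [trajectory_table()].
#' @export
read_tracking <- function(path, arena = arena_spec(), sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("empty tracking file: ", path, call. = FALSE)
  names(raw)[names(raw) == "id"] <- "fly_id"
  names(raw)[names(raw) == "t"] <- "frame"
  required <- c("fly_id", "frame", "x", "y")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("tracking file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  scale <- if (is.null(arena$px_per_mm)) 1 else arena$px_per_mm
  raw$x <- suppressWarnings(as.numeric(raw$x)) / scale - arena$center_x / scale
  raw$y <- suppressWarnings(as.numeric(raw$y)) / scale - arena$center_y / scale
  if ("body_length" %in% names(raw))
    raw$body_length <- suppressWarnings(as.numeric(raw$body_length)) / scale
  raw$x[!is.finite(raw$x)] <- NA_real_
  raw$y[!is.finite(raw$y)] <- NA_real_
  # internal table is centred; centre offset already applied above
  centred <- arena
  centred$center_x <- 0
  centred$center_y <- 0
  trajectory_table(raw, centred)
}

#' Write a trajectory table to CSV
#'
#' Writes the table in the same layout [read_tracking()] consumes
#' (`fly_id,frame,x,y[,heading,body_length]`, coordinates in mm, arena
#' centre at the origin), so a write/read round trip reproduces the table.
#'
#' @param traj A [trajectory_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory_table"))
  if (length(traj$roster) == 0L || nrow(traj$data) == 0L)
    stop("nothing to write: empty trajectory table", call. = FALSE)
  utils::write.csv(traj$data, path, row.names = FALSE, quote = FALSE,
                   na = "NA")
  invisible(path)
}

#' Validate a trajectory table
#'
#' Reports (without modifying the input) the data-quality problems that
#' matter for interaction detection: frames where a fly has no detection,
#' points outside the arena disc (beyond the radius plus one body length of
#' tolerance), and rows with missing coordinates.
#'
#' @param traj A [trajectory_table()].
#' @param body_length_mm Tolerance added to the arena radius when flagging
#'   out-of-arena points (default 2 mm, one fly body length).
#' @return A list with `missing_frames_per_fly` (named integer vector:
#'   frames in `[0, n_frames)` with no row or an `NA` coordinate),
#'   `n_out_of_arena`, `n_missing_coord`, and `clean` (`TRUE` when all
#'   counts are zero).
#' @export
validate_trajectories <- function(traj, body_length_mm = 2) {
  stopifnot(inherits(traj, "trajectory_table"))
  d <- traj$data
  miss <- vapply(traj$roster, function(id) {
    rows <- d[d$fly_id == id, ]
    present <- rows$frame[is.finite(rows$x) & is.finite(rows$y)]
    traj$n_frames - length(unique(present))
  }, integer(1))
  r <- sqrt(d$x^2 + d$y^2)
  n_out <- sum(r > traj$arena$radius_mm + body_length_mm, na.rm = TRUE)
  n_na <- sum(!is.finite(d$x) | !is.finite(d$y))
  list(missing_frames_per_fly = miss,
       n_out_of_arena = as.integer(n_out),
       n_missing_coord = as.integer(n_na),
       clean = all(miss == 0L) && n_out == 0L && n_na == 0L)
}

# frames x flies position matrices; absent frames become NA
position_matrices <- function(traj) {
  n <- traj$n_frames
  ids <- traj$roster
  X <- matrix(NA_real_, n, length(ids), dimnames = list(NULL, ids))
  Y <- X
  d <- traj$data
  i <- match(d$fly_id, ids)
  idx <- cbind(d$frame + 1L, i)
  X[idx] <- d$x
  Y[idx] <- d$y
  list(x = X, y = Y)
}

#' Per-frame distance between two flies
#'
#' Euclidean centroid-to-centroid distance in mm for every frame of the
#' recording; `NA` where either fly is missing. This is the series the
#' interaction criterion (within two body lengths for at least 0.5 s)
#' is evaluated on.
#'
#' @param traj A [trajectory_table()].
#' @param a,b Two distinct fly ids from the roster.
#' @return Numeric vector of length `n_frames`; entry `f + 1` is the
#'   distance at frame `f`.
#' @export
pairwise_distance_series <- function(traj, a, b) {
  stopifnot(inherits(traj, "trajectory_table"))
  a <- as.character(a); b <- as.character(b)
  if (identical(a, b))
    stop("`a` and `b` must be two different flies", call. = FALSE)
  bad <- setdiff(c(a, b), traj$roster)
  if (length(bad))
    stop("unknown fly id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  pm <- position_matrices(traj)
  sqrt((pm$x[, a] - pm$x[, b])^2 + (pm$y[, a] - pm$y[, b])^2)
}

#' Linearly interpolate short tracking gaps
#'
#' Optional gap repair for tracking dropouts: fills runs of at most
#' `max_gap` consecutive missing frames per fly by linear interpolation
#' between the flanking detections. Off by default throughout the pipeline;
#' gaps at the start or end of a track are left missing.
#'
#' @param traj A [trajectory_table()].
#' @param max_gap Longest run of missing frames to fill (default 3).
#' @return A new [trajectory_table()] with gaps filled.
#' @export
interpolate_gaps <- function(traj, max_gap = 3) {
  stopifnot(inherits(traj, "trajectory_table"))
  pm <- position_matrices(traj)
  frames <- seq_len(traj$n_frames) - 1L
  out <- do.call(rbind, lapply(traj$roster, function(id) {
    x <- pm$x[, id]; y <- pm$y[, id]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) >= 2L) {
      gap_id <- rle(!ok)
      ends <- cumsum(gap_id$lengths)
      starts <- ends - gap_id$lengths + 1L
      for (k in seq_along(gap_id$lengths)) {
        if (!gap_id$values[k] || gap_id$lengths[k] > max_gap) next
        if (starts[k] == 1L || ends[k] == length(x)) next
        span <- starts[k]:ends[k]
        x[span] <- stats::approx(frames[ok], x[ok], xout = frames[span])$y
        y[span] <- stats::approx(frames[ok], y[ok], xout = frames[span])$y
      }
    }
    keep <- is.finite(x) & is.finite(y)
    data.frame(fly_id = id, frame = frames[keep], x = x[keep], y = y[keep],
               stringsAsFactors = FALSE)
  }))
  extra <- intersect(c("heading", "body_length"), names(traj$data))
  if (length(extra)) {
    out <- merge(out, traj$data[c("fly_id", "frame", extra)],
                 by = c("fly_id", "frame"), all.x = TRUE)
  }
  trajectory_table(out, traj$arena)
}
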