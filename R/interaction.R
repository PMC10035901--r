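#' Interaction criteria
#'
#' The proximity criterion that turns trajectories into social
#' interactions: two flies count as interacting while their centroids stay
#' within `distance_threshold_bl` body lengths of each other (the default
#' two body lengths of 2 mm each, i.e. 4 mm), and an episode is kept only
#' if it lasts at least `min_duration_s` seconds (default 0.5 s, applied
#' inclusively, so 12 frames at 24 fps qualify).
#'
#' @param distance_threshold_bl Distance threshold in body lengths
#'   (default 2).
#' @param body_length_mm One body length in mm (default 2). When the
#'   trajectory table carries a per-fly `body_length` column, the mean of
#'   the two flies' body lengths is used instead for that pair.
#' @param min_duration_s Minimum episode duration in seconds (default 0.5).
#' @param gap_tolerance_frames Separations of at most this many frames
#'   between two above-threshold excursions are bridged before the duration
#'   test (default 0: no bridging). Missing detections always break
#'   episodes regardless of this setting.
#' @return An object of class `interaction_criteria`.
#' @export
interaction_criteria <- function(distance_threshold_bl = 2,
                                 body_length_mm = 2,
                                 min_duration_s = 0.5,
                                 gap_tolerance_frames = 0L) {
  if (distance_threshold_bl <= 0 || body_length_mm <= 0 || min_duration_s <= 0)
    stop("thresholds must be positive", call. = FALSE)
  if (gap_tolerance_frames < 0)
    stop("`gap_tolerance_frames` must be >= 0", call. = FALSE)
  structure(
    list(distance_threshold_bl = distance_threshold_bl,
         body_length_mm = body_length_mm,
         min_duration_s = min_duration_s,
         gap_tolerance_frames = as.integer(gap_tolerance_frames)),
    class = "interaction_criteria")
}

empty_events <- function(fps) {
  ev <- data.frame(fly_a = character(), fly_b = character(),
                   start_frame = integer(), end_frame = integer(),
                   duration_s = numeric(), stringsAsFactors = FALSE)
  attr(ev, "fps") <- fps
  class(ev) <- c("interaction_events", "data.frame")
  ev
}

# runs of TRUE in a logical mask (NA treated as hard breaks), optionally
# bridging FALSE (but never NA) gaps of <= gap frames; returns matrix of
# half-open [start, end) 0-based frame ranges
contact_runs <- function(mask, gap) {
  state <- ifelse(is.na(mask), 2L, as.integer(mask)) # 0 apart, 1 close, 2 missing
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L
  if (!any(keep)) return(matrix(integer(), ncol = 2))
  runs <- cbind(starts[keep], ends[keep])
  if (gap > 0 && nrow(runs) > 1) {
    # bridge only if all frames in between are 0 (apart), none missing
    merged <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      gap_span <- (merged[nrow(merged), 2] + 1L):(runs[i, 1] - 1L)
      gap_len <- runs[i, 1] - merged[nrow(merged), 2] - 1L
      if (gap_len <= gap && all(state[gap_span] == 0L)) {
        merged[nrow(merged), 2] <- runs[i, 2]
      } else {
        merged <- rbind(merged, runs[i, , drop = FALSE])
      }
    }
    runs <- merged
  }
  # to 0-based half-open
  cbind(runs[, 1] - 1L, runs[, 2])
}

#' Detect pairwise interaction events
#'
#' Scans every unordered pair of flies for maximal runs of frames in which
#' the pair is within the distance threshold, bridges sub-tolerance gaps
#' when requested, and emits each run whose duration reaches
#' `min_duration_s` as one interaction event. Frames where either fly is
#' missing terminate runs.
#'
#' @param traj A [trajectory_table()] with at least two flies.
#' @param criteria An [interaction_criteria()].
#' @return A data.frame of class `interaction_events` with columns
#'   `fly_a`, `fly_b` (with `fly_a < fly_b`), `start_frame`, `end_frame`
#'   (half-open, 0-based) and `duration_s`, sorted by
#'   `(fly_a, fly_b, start_frame)`; the frame rate travels along as
#'   attribute `fps`.
#' @export
detect_events <- function(traj, criteria = interaction_criteria()) {
  stopifnot(inherits(traj, "trajectory_table"))
  if (!inherits(criteria, "interaction_criteria"))
    stop("`criteria` must be an interaction_criteria", call. = FALSE)
  ids <- traj$roster
  if (length(ids) < 2L)
    stop("need at least two flies to detect interactions", call. = FALSE)
  fps <- traj$arena$fps
  pm <- position_matrices(traj)
  bl <- rep(criteria$body_length_mm, length(ids))
  names(bl) <- ids
  if ("body_length" %in% names(traj$data)) {
    per_fly <- tapply(traj$data$body_length, traj$data$fly_id,
                      function(v) mean(v, na.rm = TRUE))
    ok <- is.finite(per_fly)
    bl[names(per_fly)[ok]] <- per_fly[ok]
  }
  min_frames <- ceiling(criteria$min_duration_s * fps - 1e-9)
  out <- vector("list", length(ids) * (length(ids) - 1L) / 2L)
  k <- 0L
  for (i in seq_len(length(ids) - 1L)) {
    dx_i <- pm$x[, i]; dy_i <- pm$y[, i]
    for (j in (i + 1L):length(ids)) {
      thr <- criteria$distance_threshold_bl * mean(c(bl[i], bl[j]))
      d <- sqrt((dx_i - pm$x[, j])^2 + (dy_i - pm$y[, j])^2)
      runs <- contact_runs(d <= thr, criteria$gap_tolerance_frames)
      if (nrow(runs) == 0) next
      len <- runs[, 2] - runs[, 1]
      runs <- runs[len >= min_frames, , drop = FALSE]
      if (nrow(runs) == 0) next
      k <- k + 1L
      out[[k]] <- data.frame(
        fly_a = ids[i], fly_b = ids[j],
        start_frame = as.integer(runs[, 1]), end_frame = as.integer(runs[, 2]),
        duration_s = (runs[, 2] - runs[, 1]) / fps,
        stringsAsFactors = FALSE)
    }
  }
  if (k == 0L) return(empty_events(fps))
  ev <- do.call(rbind, out[seq_len(k)])
  ev <- ev[order(ev$fly_a, ev$fly_b, ev$start_frame), ]
  rownames(ev) <- NULL
  attr(ev, "fps") <- fps
  class(ev) <- c("interaction_events", "data.frame")
  ev
}

#' Merge events separated by short gaps
#'
#' Fuses, per pair, consecutive events whose separation is at most
#' `gap_tolerance_frames` frames, recomputing durations. Idempotent;
#' tolerance 0 returns the input unchanged.
#'
#' @param events An `interaction_events` data.frame (sorted per pair, as
#'   produced by [detect_events()]).
#' @param gap_tolerance_frames Largest separation (in frames) to fuse.
#' @return An `interaction_events` data.frame.
#' @export
merge_events <- function(events, gap_tolerance_frames) {
  if (gap_tolerance_frames < 0)
    stop("`gap_tolerance_frames` must be >= 0", call. = FALSE)
  fps <- attr(events, "fps")
  if (nrow(events) == 0L || gap_tolerance_frames == 0L) return(events)
  key <- paste(events$fly_a, events$fly_b, sep = "\r")
  pieces <- lapply(split(events, key), function(e) {
    e <- e[order(e$start_frame), ]
    cur <- 1L
    for (i in seq_len(nrow(e))[-1]) {
      if (e$start_frame[i] - e$end_frame[cur] <= gap_tolerance_frames) {
        e$end_frame[cur] <- max(e$end_frame[cur], e$end_frame[i])
        e$start_frame[i] <- NA_integer_
      } else cur <- i
    }
    e <- e[!is.na(e$start_frame), ]
    e$duration_s <- (e$end_frame - e$start_frame) / fps
    e
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$fly_a, out$fly_b, out$start_frame), ]
  rownames(out) <- NULL
  attr(out, "fps") <- fps
  class(out) <- c("interaction_events", "data.frame")
  out
}

#' Summarise events per pair
#'
#' Collapses the event list into the two quantities that become SIN edge
#' weights: the number of interaction events per pair and their total
#' duration in seconds.
#'
#' @param events An `interaction_events` data.frame.
#' @return A list with `pairs` (data.frame `fly_a,fly_b,n_events,
#'   total_duration_s`) and `totals` (`n_events`, `total_duration_s` summed
#'   over all pairs).
#' @export
events_summary <- function(events) {
  if (nrow(events) == 0L) {
    return(list(pairs = data.frame(fly_a = character(), fly_b = character(),
                                   n_events = integer(),
                                   total_duration_s = numeric(),
                                   stringsAsFactors = FALSE),
                totals = list(n_events = 0L, total_duration_s = 0)))
  }
  agg <- stats::aggregate(
    cbind(n_events = rep(1L, nrow(events)), total_duration_s = events$duration_s),
    by = list(fly_a = events$fly_a, fly_b = events$fly_b), FUN = sum)
  agg <- agg[order(agg$fly_a, agg$fly_b), ]
  rownames(agg) <- NULL
  agg$n_events <- as.integer(agg$n_events)
  list(pairs = agg,
       totals = list(n_events = sum(agg$n_events),
                     total_duration_s = sum(agg$total_duration_s)))
}

#' Write / read interaction events as CSV
#'
#' @param events An `interaction_events` data.frame.
#' @param path Output path.
#' @return `path` invisibly for the writer; an `interaction_events`
#'   data.frame for the reader.
#' @export
write_events <- function(events, path) {
  fps <- attr(events, "fps")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fps=%g", fps), con)
  utils::write.csv(as.data.frame(events), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  first <- readLines(path, n = 1L)
  fps <- if (grepl("^# fps=", first)) as.numeric(sub("^# fps=", "", first)) else NA_real_
  ev <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  ev$fly_a <- as.character(ev$fly_a)
  ev$fly_b <- as.character(ev$fly_b)
  attr(ev, "fps") <- fps
  class(ev) <- c("interaction_events", "data.frame")
  ev
}
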