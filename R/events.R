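#' Severity levels
#'
#' Fall severity is graded from how long the fall posture persists — a
#' proxy for the subject being unable to get up. Two ordered levels:
#' `MODERATE < SEVERE`.
#' @format Character vector of length 2, in increasing order.
#' @export
SEVERITY_LEVELS <- c("MODERATE", "SEVERE")

#' Event tracker configuration
#'
#' Debounce and severity parameters for [track_events]. Per-frame labels
#' flicker (single-frame pose-estimation glitches), so an event only opens
#' after `onset_frames` consecutive fall labels and only closes after
#' `release_frames` consecutive `NORMAL` labels.
#'
#' @param onset_frames consecutive fall-labeled frames required to confirm
#'   an onset (default 3).
#' @param release_frames consecutive `NORMAL` frames required to close an
#'   event (default 5).
#' @param severe_after_s duration in seconds at or beyond which an event is
#'   graded `SEVERE` rather than `MODERATE` (default 8).
#' @return A list of class `tracker_config`.
#' @export
tracker_config <- function(onset_frames = 3, release_frames = 5,
                           severe_after_s = 8) {
  stopifnot(onset_frames >= 1, release_frames >= 1, severe_after_s > 0)
  structure(list(onset_frames = as.integer(onset_frames),
                 release_frames = as.integer(release_frames),
                 severe_after_s = severe_after_s),
            class = "tracker_config")
}

#' Aggregate per-frame labels into fall events
#'
#' A state machine over the label stream. An event opens at the first frame
#' of a run of at least `onset_frames` fall labels (`t_start` is that
#' frame's timestamp). It closes at the last fall-labeled frame before a
#' run of at least `release_frames` consecutive `NORMAL` labels, or at the
#' end of the sequence (`t_end` is that last fall frame's timestamp).
#' `UNKNOWN` frames inside an open event are continuation: occlusion during
#' a fall neither ends the event nor counts toward release; outside an
#' event they break an onset run. The event's direction is the modal
#' `FALL_*` label over its fall frames (ties to the earliest observed), and
#' `severity` is `SEVERE` iff `duration >= severe_after_s`.
#'
#' @param labels factor or character vector of posture labels
#'   ([POSTURE_LEVELS]).
#' @param timestamps numeric vector, seconds, strictly increasing, same
#'   length as `labels`.
#' @param config a [tracker_config].
#' @return `data.frame` with columns `direction`, `t_start`, `t_end`,
#'   `duration`, `severity`; zero rows when no event qualifies. Events are
#'   time-ordered and non-overlapping.
#' @export
track_events <- function(labels, timestamps, config = tracker_config()) {
  labels <- as.character(labels)
  if (length(labels) != length(timestamps))
    stop("labels and timestamps must have the same length")
  if (length(timestamps) > 1 && any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing")
  bad <- setdiff(unique(labels), POSTURE_LEVELS)
  if (length(bad))
    stop("unknown posture labels: ", paste(bad, collapse = ", "))

  empty <- data.frame(direction = character(0), t_start = numeric(0),
                      t_end = numeric(0), duration = numeric(0),
                      severity = character(0))
  events <- list()
  open <- FALSE
  fall_run <- 0L; run_start <- NA_integer_
  normal_run <- 0L; last_fall <- NA_integer_
  fall_idx <- integer(0)

  close_event <- function() {
    idx <- fall_idx
    dirs <- labels[idx]
    counts <- table(factor(dirs, levels = unique(dirs)))  # unique() = order observed
    direction <- names(counts)[which.max(counts)]         # tie -> earliest observed
    t_start <- timestamps[run_start]
    t_end <- timestamps[last_fall]
    duration <- t_end - t_start
    data.frame(direction = direction, t_start = t_start, t_end = t_end,
               duration = duration,
               severity = if (duration >= config$severe_after_s) "SEVERE"
                          else "MODERATE")
  }

  for (i in seq_along(labels)) {
    is_fall <- labels[i] %in% FALL_DIRECTIONS
    if (!open) {
      if (is_fall) {
        if (fall_run == 0L) run_start <- i
        fall_run <- fall_run + 1L
        if (fall_run >= config$onset_frames) {
          open <- TRUE
          fall_idx <- seq.int(run_start, i)
          last_fall <- i
          normal_run <- 0L
        }
      } else {
        fall_run <- 0L
      }
    } else {
      if (is_fall) {
        normal_run <- 0L
        last_fall <- i
        fall_idx <- c(fall_idx, i)
      } else if (labels[i] == "NORMAL") {
        normal_run <- normal_run + 1L
        if (normal_run >= config$release_frames) {
          events[[length(events) + 1L]] <- close_event()
          open <- FALSE; fall_run <- 0L; fall_idx <- integer(0)
        }
      } # UNKNOWN: continuation, resets nothing but the release run
      if (open && labels[i] == "UNKNOWN") normal_run <- 0L
    }
  }
  if (open) events[[length(events) + 1L]] <- close_event()
  if (!length(events)) return(empty)
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}

#' Write / read the fall-event log (JSONL)
#'
#' One JSON object per event with the fixed field order
#' `direction, t_start, t_end, duration, severity, source` — byte-identical
#' output for identical inputs, and round-trip readable.
#'
#' @param events event table from [track_events].
#' @param metadata named list; its `source` entry (if any) is recorded with
#'   every event, otherwise `"unknown"`.
#' @param path file path.
#' @return `write_event_log` returns `path` invisibly; `read_event_log`
#'   returns an event `data.frame` with a `source` column appended.
#' @export
write_event_log <- function(events, metadata = list(), path) {
  src <- if (!is.null(metadata$source)) as.character(metadata$source)
         else "unknown"
  lines <- character(nrow(events))
  for (i in seq_len(nrow(events))) {
    lines[i] <- jsonlite::toJSON(
      list(direction = jsonlite::unbox(events$direction[i]),
           t_start = jsonlite::unbox(events$t_start[i]),
           t_end = jsonlite::unbox(events$t_end[i]),
           duration = jsonlite::unbox(events$duration[i]),
           severity = jsonlite::unbox(events$severity[i]),
           source = jsonlite::unbox(src)),
      digits = I(17))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(direction = character(0), t_start = numeric(0),
                      t_end = numeric(0), duration = numeric(0),
                      severity = character(0), source = character(0)))
  rows <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    data.frame(direction = x$direction, t_start = x$t_start,
               t_end = x$t_end, duration = x$duration,
               severity = x$severity, source = x$source)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
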