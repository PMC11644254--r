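#' Construct a pose sequence
#'
#' A `pose_sequence` is the package's in-memory container for a BODY_25
#' keypoint stream: an `n x 25 x 3` array (`x`, `y`, `confidence` in the
#' third margin), one strictly increasing timestamp per frame, and free-form
#' metadata. Coordinates are in the image frame: origin top-left, `x` grows
#' rightward, `y` grows downward. A keypoint with confidence 0 is missing;
#' its coordinates are stored as 0 and carry no meaning (the upstream
#' OpenPose convention).
#'
#' @param keypoints numeric array `n x 25 x 3`.
#' @param timestamps numeric vector of length `n`, seconds, strictly
#'   increasing, all finite and non-negative.
#' @param metadata named list of free-form sequence metadata (source, fps,
#'   scenario id, ...).
#' @return An object of class `pose_sequence`.
#' @export
pose_sequence <- function(keypoints, timestamps, metadata = list()) {
  keypoints <- as_kp_array(keypoints)
  n <- dim(keypoints)[1]
  timestamps <- as.numeric(timestamps)
  if (length(timestamps) != n)
    stop("length(timestamps) must equal the number of frames")
  if (n > 0) {
    if (any(!is.finite(timestamps)) || any(timestamps < 0))
      stop("timestamps must be finite and non-negative")
    if (n > 1 && any(diff(timestamps) <= 0))
      stop("timestamps must be strictly increasing")
  }
  conf <- keypoints[, , 3, drop = FALSE]
  if (n > 0 && (any(conf < 0) || any(conf > 1)))
    stop("confidences must lie in [0, 1]")
  xy <- keypoints[, , 1:2, drop = FALSE]
  bad <- conf > 0 & !is.finite(xy[, , 1, drop = FALSE] + xy[, , 2, drop = FALSE])
  if (any(bad))
    stop("keypoints with confidence > 0 must have finite coordinates")
  structure(list(keypoints = keypoints, timestamps = timestamps,
                 metadata = metadata),
            class = "pose_sequence")
}

as_kp_array <- function(keypoints) {
  if (is.matrix(keypoints)) # single frame
    keypoints <- array(keypoints, c(1L, dim(keypoints)))
  if (!is.array(keypoints) || length(dim(keypoints)) != 3 ||
      dim(keypoints)[2] != 25 || dim(keypoints)[3] != 3)
    stop("keypoints must be an n x 25 x 3 array")
  storage.mode(keypoints) <- "double"
  keypoints
}

#' @export
print.pose_sequence <- function(x, ...) {
  cat(sprintf("<pose_sequence> %d frames", n_frames(x)))
  if (n_frames(x) > 0)
    cat(sprintf(", t = [%g, %g] s", x$timestamps[1],
                x$timestamps[n_frames(x)]))
  if (length(x$metadata))
    cat(" |", paste(names(x$metadata), unlist(lapply(x$metadata, format)),
                    sep = "=", collapse = " "))
  cat("\n")
  invisible(x)
}

#' @rdname pose_sequence
#' @param seq a `pose_sequence`.
#' @export
n_frames <- function(seq) dim(seq$keypoints)[1]

#' Extract one frame's keypoint matrix
#'
#' @param seq a `pose_sequence`.
#' @param i frame index (1-based).
#' @return `25 x 3` numeric matrix with rownames from [BODY25] and columns
#'   `x`, `y`, `confidence`.
#' @export
frame_keypoints <- function(seq, i) {
  kp <- seq$keypoints[i, , ]
  dimnames(kp) <- list(names(BODY25), c("x", "y", "confidence"))
  kp
}

missing_frame <- function() matrix(0, 25, 3)

#' Read OpenPose per-frame JSON files
#'
#' Parses the standard OpenPose output dialect (version >= 1.3): one JSON
#' file per frame with a top-level `"people"` array, each person carrying
#' `"pose_keypoints_2d"` as 75 floats (25 keypoints times x, y, confidence).
#' Frame order is the order of `paths`; OpenPose writes no timestamps, so
#' they are synthesized as `frame_index / fps`.
#'
#' When a frame contains several people exactly one is kept, chosen by
#' `person_policy`. The only policy currently implemented is
#' `"mean_confidence"`: the person with the highest mean keypoint confidence
#' wins, ties going to the first listed — deterministic and independent of
#' any face-tracking stack. A frame with zero people becomes 25 missing
#' keypoints.
#'
#' @param paths character vector of file paths, in frame order.
#' @param fps frames per second used to synthesize timestamps (default 10).
#' @param person_policy person selection policy; `"mean_confidence"`.
#' @return A [pose_sequence] with one frame per input file.
#' @export
read_openpose_json <- function(paths, fps = 10,
                               person_policy = "mean_confidence") {
  person_policy <- match.arg(person_policy, "mean_confidence")
  stopifnot(is.numeric(fps), fps > 0)
  n <- length(paths)
  kp <- array(0, c(n, 25, 3))
  for (i in seq_len(n)) {
    doc <- tryCatch(jsonlite::fromJSON(paths[i], simplifyVector = FALSE),
                    error = function(e)
                      stop(sprintf("malformed OpenPose JSON in '%s': %s",
                                   paths[i], conditionMessage(e)),
                           call. = FALSE))
    people <- doc$people
    if (is.null(people) || length(people) == 0) {
      kp[i, , ] <- missing_frame()
      next
    }
    frames <- lapply(people, function(p) {
      v <- as.numeric(unlist(p$pose_keypoints_2d))
      if (length(v) %% 75 != 0 || length(v) != 75)
        stop(sprintf(
          "'%s': pose_keypoints_2d has %d values, expected 75 per person",
          paths[i], length(v)), call. = FALSE)
      matrix(v, 25, 3, byrow = TRUE)
    })
    best <- which.max(vapply(frames, function(m) mean(m[, 3]), 0))
    kp[i, , ] <- frames[[best]]
  }
  pose_sequence(kp, timestamps = (seq_len(n) - 1) / fps,
                metadata = list(source = "openpose_json", fps = fps))
}

#' Write / read the package JSONL sequence format
#'
#' The package's own on-disk format for pose sequences: line 1 is the
#' metadata object; every following line is one frame,
#' `{"t": <seconds>, "kp": [[x, y, confidence] x 25]}`. Serialization is
#' decimal-faithful (17 significant digits), so `read(write(seq))`
#' reproduces every coordinate, confidence and timestamp exactly.
#'
#' @param seq a [pose_sequence].
#' @param path file path.
#' @return `write_sequence_jsonl` returns `path` invisibly;
#'   `read_sequence_jsonl` returns a [pose_sequence].
#' @export
write_sequence_jsonl <- function(seq, path) {
  stopifnot(inherits(seq, "pose_sequence"))
  meta <- seq$metadata
  if (is.null(names(meta))) names(meta) <- character(length(meta))
  header <- jsonlite::toJSON(meta, auto_unbox = TRUE, digits = I(17))
  lines <- character(n_frames(seq))
  for (i in seq_len(n_frames(seq))) {
    lines[i] <- jsonlite::toJSON(
      list(t = jsonlite::unbox(seq$timestamps[i]),
           kp = unname(seq$keypoints[i, , ])),
      digits = I(17))
  }
  writeLines(c(header, lines), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_sequence_jsonl
#' @export
read_sequence_jsonl <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1)
    stop(sprintf("'%s': empty file, expected a metadata header line", path))
  meta <- jsonlite::fromJSON(lines[1], simplifyVector = FALSE)
  n <- length(lines) - 1L
  kp <- array(0, c(n, 25, 3))
  ts <- numeric(n)
  for (i in seq_len(n)) {
    rec <- jsonlite::fromJSON(lines[i + 1L], simplifyVector = TRUE)
    if (is.null(rec$t) || is.null(rec$kp))
      stop(sprintf("'%s' line %d: frame record needs fields 't' and 'kp'",
                   path, i + 1L))
    m <- rec$kp
    if (!is.matrix(m) || nrow(m) != 25 || ncol(m) != 3)
      stop(sprintf("'%s' line %d: 'kp' must be 25 x 3", path, i + 1L))
    ts[i] <- rec$t
    kp[i, , ] <- m
  }
  pose_sequence(kp, ts, metadata = meta)
}
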