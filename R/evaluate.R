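#' Classification accuracy
#'
#' The fraction of frames whose predicted label exactly matches the truth
#' label: correct instances over total instances tested. `UNKNOWN`
#' predictions simply never match a fall truth, so abstention counts as
#' incorrect.
#'
#' @param predicted,truth label vectors or factors of equal positive
#'   length.
#' @return Fraction in `[0, 1]`.
#' @export
accuracy <- function(predicted, truth) {
  if (length(predicted) == 0 || length(predicted) != length(truth))
    stop("predicted and truth must be non-empty and of equal length")
  mean(as.character(predicted) == as.character(truth))
}

#' Confusion matrix report
#'
#' Full 6 x 6 confusion matrix over [POSTURE_LEVELS] (rows = truth,
#' columns = predicted), with per-class and overall accuracy. Off-diagonal
#' mass shows which directions get confused — e.g. forward falls read as
#' backward when the face is lost.
#'
#' @inheritParams accuracy
#' @return Object of class `fall_eval`: list with `confusion` (6 x 6
#'   integer matrix), `overall` accuracy, `per_class` named vector
#'   (`NA` for classes absent from `truth`), and `n`.
#' @export
confusion <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  p <- as_posture_factor(predicted)
  t_ <- as_posture_factor(truth)
  if (anyNA(p) || anyNA(t_)) stop("labels outside POSTURE_LEVELS")
  m <- table(truth = t_, predicted = p)
  cm <- matrix(as.integer(m), 6, 6,
               dimnames = list(truth = POSTURE_LEVELS,
                               predicted = POSTURE_LEVELS))
  per_class <- diag(cm) / rowSums(cm)
  structure(list(confusion = cm,
                 overall = if (length(truth)) sum(diag(cm)) / length(truth)
                           else NA_real_,
                 per_class = per_class, n = length(truth)),
            class = "fall_eval")
}

#' @export
print.fall_eval <- function(x, ...) {
  cat(sprintf("<fall_eval> n = %d, overall accuracy = %.4f\n", x$n,
              x$overall))
  print(x$confusion)
  invisible(x)
}

#' Run the method-comparison benchmark
#'
#' For every combination of scenario preset, fall direction and detector
#' method: generates `n_sequences` labeled sequences (per-sequence seeds
#' `seed + 0, seed + 1, ...`, so the same corrupted inputs are scored by
#' every method), corrupts them per the preset, classifies them, and scores
#' per-frame direction accuracy restricted to the lying phase (frames whose
#' truth is a fall label) — transition frames are excluded unless
#' `include_transition` is set. Fully deterministic given `seed`.
#'
#' @param methods detector methods to compare (subset of
#'   [DETECTOR_METHODS]).
#' @param presets scenario presets (see [scenario_presets]).
#' @param directions fall directions to simulate (subset of
#'   [FALL_DIRECTIONS]).
#' @param n_sequences sequences per (preset, direction) cell.
#' @param seed base integer seed.
#' @param config baseline [classifier_config]; its `method` field is
#'   overridden per benchmark row.
#' @param include_transition score all frames, not only the lying phase.
#' @return `data.frame` with one row per (preset, direction, method):
#'   `preset`, `direction`, `method`, `n_sequences`, `n_frames` (frames
#'   scored), `accuracy`.
#' @export
run_benchmark <- function(methods = DETECTOR_METHODS,
                          presets = "clean",
                          directions = FALL_DIRECTIONS,
                          n_sequences = 10,
                          seed = 1,
                          config = classifier_config(),
                          include_transition = FALSE) {
  methods <- match.arg(methods, DETECTOR_METHODS, several.ok = TRUE)
  presets <- match.arg(presets, scenario_presets(), several.ok = TRUE)
  directions <- match.arg(directions, c("NONE", FALL_DIRECTIONS),
                          several.ok = TRUE)
  stopifnot(n_sequences >= 1)
  rows <- list()
  for (preset in presets) {
    for (direction in directions) {
      specs <- lapply(seq_len(n_sequences) - 1L, function(k)
        scenario_preset(preset, direction = direction, seed = seed + k))
      lseqs <- lapply(specs, function(sp)
        apply_noise_and_dropout(generate_sequence(sp), sp))
      for (method in methods) {
        cfg <- config
        cfg$method <- method
        pred <- unlist(lapply(lseqs, function(ls)
          as.character(classify_sequence(ls$sequence, cfg))))
        tru <- unlist(lapply(lseqs, function(ls) as.character(ls$truth)))
        mask <- if (include_transition) rep(TRUE, length(tru))
                else tru != "NORMAL"
        acc <- if (any(mask)) accuracy(pred[mask], tru[mask]) else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          preset = preset, direction = direction, method = method,
          n_sequences = n_sequences, n_frames = sum(mask), accuracy = acc)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
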