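#' Brightness-normalization parameters
#'
#' Parameters of the percentile-clipped min-max brightness normalization.
#' Pixels outside the `[p_low, p_high]` percentile band are treated as
#' outliers and clipped; the surviving range is stretched to
#' `[out_min, out_max]`. The output bounds default inside (not onto)
#' `[0, 255]` to avoid saturating the 8-bit range.
#'
#' @param p_low lower percentile in `[0, 100)` (default 1).
#' @param p_high upper percentile in `(0, 100]` (default 99).
#' @param out_min,out_max output 8-bit levels, `0 <= out_min < out_max <=
#'   255` (defaults 10 and 245).
#' @return A list of class `normalization_params`.
#' @export
normalization_params <- function(p_low = 1, p_high = 99,
                                 out_min = 10, out_max = 245) {
  stopifnot(p_low >= 0, p_low < 100, p_high > 0, p_high <= 100,
            p_low < p_high,
            out_min >= 0, out_max <= 255, out_min < out_max)
  structure(list(p_low = p_low, p_high = p_high,
                 out_min = out_min, out_max = out_max),
            class = "normalization_params")
}

#' Percentile-clipped min-max brightness normalization
#'
#' For each channel independently: let `lo` and `hi` be the `p_low` and
#' `p_high` percentile values of the channel (linear interpolation between
#' order statistics, i.e. `quantile(type = 7)`). Every pixel is clipped to
#' `[lo, hi]` and mapped affinely so that `lo -> out_min` and
#' `hi -> out_max`, then rounded half-up to an integer level. A constant
#' channel (`hi == lo`) maps entirely to `out_min`. Output values are
#' therefore always inside `[out_min, out_max]`, pixel rank order within a
#' channel is preserved, and shape and channel count are unchanged.
#'
#' This is the automatic brightness-rescue step for dim or overexposed
#' scenes: stretching the informative pixel range restores contrast around
#' the face so the upstream pose estimator stops losing above-the-neck
#' keypoints.
#'
#' @param image numeric matrix (grayscale) or `h x w x channels` array of
#'   pixel values (8-bit scale, 0..255).
#' @param params a [normalization_params].
#' @return Image of identical shape with integer-valued pixels in
#'   `[out_min, out_max]`.
#' @export
normalize_brightness <- function(image, params = normalization_params()) {
  if (length(image) == 0) stop("empty image")
  stopifnot(is.numeric(image))
  norm_channel <- function(ch) {
    q <- stats::quantile(ch, c(params$p_low, params$p_high) / 100,
                         names = FALSE, type = 7)
    lo <- q[1]; hi <- q[2]
    if (hi <= lo) {
      ch[] <- params$out_min
      return(ch)
    }
    x <- pmin(pmax(ch, lo), hi)
    y <- (x - lo) / (hi - lo) * (params$out_max - params$out_min) +
      params$out_min
    floor(y + 0.5)  # round half-up
  }
  d <- dim(image)
  if (is.null(d) || length(d) == 2) return(norm_channel(image))
  if (length(d) == 3) {
    out <- image
    for (k in seq_len(d[3])) out[, , k] <- norm_channel(image[, , k])
    return(out)
  }
  stop("image must be a matrix or a 3-d array")
}

#' Read / write plain ASCII PNM images (P2 / P3)
#'
#' Minimal text-based image I/O for the brightness normalizer: grayscale
#' (`P2`) and RGB (`P3`) plain PNM with maxval 255. Chosen because it is a
#' text format any image tool can convert to or from; this package does not
#' link against a PNG/JPEG codec.
#'
#' @param path file path.
#' @param image numeric matrix (written as `P2`) or `h x w x 3` array
#'   (written as `P3`), integer values in 0..255.
#' @return `read_pnm` returns a matrix or `h x w x 3` array; `write_pnm`
#'   returns `path` invisibly.
#' @export
read_pnm <- function(path) {
  tokens <- scan(path, what = character(), quiet = TRUE,
                 comment.char = "#")
  magic <- tokens[1]
  if (!magic %in% c("P2", "P3"))
    stop(sprintf("'%s': unsupported PNM magic '%s' (plain P2/P3 only)",
                 path, magic))
  hdr <- as.numeric(tokens[2:4])
  w <- hdr[1]; h <- hdr[2]; maxval <- hdr[3]
  if (maxval != 255) stop(sprintf("'%s': only maxval 255 supported", path))
  vals <- as.numeric(tokens[-(1:4)])
  if (magic == "P2") {
    if (length(vals) != w * h)
      stop(sprintf("'%s': expected %d pixel values, found %d",
                   path, w * h, length(vals)))
    return(matrix(vals, nrow = h, ncol = w, byrow = TRUE))
  }
  if (length(vals) != 3 * w * h)
    stop(sprintf("'%s': expected %d pixel values, found %d",
                 path, 3 * w * h, length(vals)))
  px <- matrix(vals, ncol = 3, byrow = TRUE)  # row-major, RGB interleaved
  out <- array(0, c(h, w, 3))
  for (k in 1:3) out[, , k] <- matrix(px[, k], nrow = h, byrow = TRUE)
  out
}

#' @rdname read_pnm
#' @export
write_pnm <- function(image, path) {
  stopifnot(is.numeric(image))
  d <- dim(image)
  con <- file(path, "w")
  on.exit(close(con))
  if (is.null(d) || length(d) == 2) {
    m <- if (is.null(d)) matrix(image, nrow = 1) else image
    writeLines(c("P2", sprintf("%d %d", ncol(m), nrow(m)), "255"), con)
    apply(m, 1, function(r)
      writeLines(paste(as.integer(round(r)), collapse = " "), con))
  } else if (length(d) == 3 && d[3] == 3) {
    writeLines(c("P3", sprintf("%d %d", d[2], d[1]), "255"), con)
    for (i in seq_len(d[1])) {
      row <- as.integer(round(t(image[i, , ])))  # RGB interleaved
      writeLines(paste(row, collapse = " "), con)
    }
  } else stop("image must be a matrix or h x w x 3 array")
  invisible(path)
}
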