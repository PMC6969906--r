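#' Psychometric parameters of the synthetic responder
#'
#' The synthetic patient judges a frame 'bad' (distorted) when the maximum
#' displacement of any point of the frame's pattern under the lesion map
#' reaches `threshold_delta` pixels. Optional response noise: with
#' probability `lapse_rate` the deterministic bit is flipped; with
#' probability `guess_rate` it is replaced by a fair coin. Both default to 0
#' so that simulated tests are fully deterministic.
#'
#' @param threshold_delta Detection threshold in pixels (>= 0). Default 2 px,
#'   a conservative suprathreshold criterion; see the methods vignette for
#'   the displacement scale of cap lesions and the idealized-observer
#'   alternative.
#' @param lapse_rate,guess_rate Probabilities in `[0, 1]`.
#' @param seed Optional integer seed consumed by [run_test()] when any noise
#'   rate is positive.
#' @return A list of class `vd_psychometric`.
#' @export
psychometric_params <- function(threshold_delta = 2, lapse_rate = 0,
                                guess_rate = 0, seed = NULL) {
  stopifnot_scalar(threshold_delta, "threshold_delta", lower = 0)
  stopifnot_scalar(lapse_rate, "lapse_rate", lower = 0, upper = 1)
  stopifnot_scalar(guess_rate, "guess_rate", lower = 0, upper = 1)
  if (!is.null(seed)) stopifnot_scalar(seed, "seed")
  structure(list(threshold_delta = threshold_delta, lapse_rate = lapse_rate,
                 guess_rate = guess_rate,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "vd_psychometric")
}

# Resample every segment of a polyline so consecutive samples are <= max_step
# apart. Returns an N x 2 matrix of sample points.
sample_polyline <- function(pts, max_step) {
  out <- list(pts[1L, , drop = FALSE])
  for (s in seq_len(nrow(pts) - 1L)) {
    a <- pts[s, ]; b <- pts[s + 1L, ]
    len <- sqrt(sum((b - a)^2))
    k <- max(1L, ceiling(len / max_step))
    t <- seq_len(k) / k
    out[[length(out) + 1L]] <- cbind(a[1L] + t * (b[1L] - a[1L]),
                                     a[2L] + t * (b[2L] - a[2L]))
  }
  do.call(rbind, out)
}

# Does segment a-b come within `radius` of centre `c0`? (point-segment distance)
segment_hits_disk <- function(a, b, c0, radius) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- if (len2 == 0) 0 else max(0, min(1, sum((c0 - a) * ab) / len2))
  q <- a + t * ab
  sqrt(sum((q - c0)^2)) < radius
}

#' Distort a frame as perceived through lesions
#'
#' Applies the forward lesion map to the frame's polylines, producing a
#' polyline approximation of the curved percept. Segments that intersect a
#' support disk are resampled so consecutive samples are at most `max_step`
#' pixels apart before mapping; segments wholly outside every support disk
#' are passed through untouched.
#'
#' @param frame A `vd_frame`.
#' @param lesions A `vd_lesion` or list of them (may be empty).
#' @param max_step Resampling step in pixels (> 0). The default 1 px keeps
#'   the polyline approximation error sub-pixel given the map's bounded
#'   curvature.
#' @return A `vd_frame` with the same canvas, index, and styles.
#' @export
distort_frame <- function(frame, lesions, max_step = 1) {
  stopifnot(inherits(frame, "vd_frame"))
  stopifnot_scalar(max_step, "max_step")
  if (max_step <= 0) stop("max_step must be > 0")
  lesions <- as_lesion_list(lesions)
  if (!length(lesions)) return(frame)
  frame$elements <- lapply(frame$elements, function(el) {
    pts <- el$points
    out <- pts[1L, , drop = FALSE]
    for (s in seq_len(nrow(pts) - 1L)) {
      a <- pts[s, ]; b <- pts[s + 1L, ]
      hit <- any(vapply(lesions, function(l)
        segment_hits_disk(a, b, c(l$x0, l$y0), l$D / 2), logical(1)))
      seg <- if (hit) sample_polyline(rbind(a, b), max_step)[-1L, , drop = FALSE]
      else matrix(b, 1L)
      out <- rbind(out, seg)
    }
    el$points <- forward_map(out, lesions)
    el
  })
  frame
}

#' Distort a raster image as perceived through lesions
#'
#' Inverse warping: each output pixel centre `p` is looked up at
#' `inverse_map(p)` in the input (so the percept has no holes). Pixels
#' outside every support disk are copied bit-exactly; sample positions
#' falling outside the canvas clamp to the border.
#'
#' @param image A numeric matrix (`m x n`) or array (`m x n x ch`,
#'   1 to 4 channels), as returned by [png::readPNG()].
#' @param lesions A `vd_lesion` or list of them (may be empty).
#' @param interpolation `"bilinear"` (default) or `"nearest"`.
#' @return The warped image, same dimensions and channel count.
#' @export
distort_raster <- function(image, lesions,
                           interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  dm <- dim(image)
  if (is.null(dm) || length(dm) < 2L || length(dm) > 3L)
    stop("image must be an m x n matrix or m x n x ch array")
  ch <- if (length(dm) == 3L) dm[3L] else 1L
  if (ch < 1L || ch > 4L) stop("unsupported channel count: ", ch)
  lesions <- as_lesion_list(lesions)
  if (!length(lesions) || all(vapply(lesions, function(l) l$D, 0) == 0))
    return(image)
  m <- dm[1L]; n <- dm[2L]
  xs <- rep(seq_len(n) - 1, each = m)
  ys <- rep(seq_len(m) - 1, times = n)
  src <- inverse_map(cbind(xs, ys), lesions)
  moved <- which(src[, 1L] != xs | src[, 2L] != ys)
  if (!length(moved)) return(image)
  sx <- pmin(pmax(src[moved, 1L], 0), n - 1)
  sy <- pmin(pmax(src[moved, 2L], 0), m - 1)
  out <- image
  img3 <- if (ch == 1L && length(dm) == 2L) array(image, c(m, n, 1L)) else image
  out3 <- img3
  if (interpolation == "nearest") {
    ii <- cbind(round(sy) + 1, round(sx) + 1)
    for (k in seq_len(ch)) {
      band <- img3[, , k]
      ob <- out3[, , k]
      ob[moved] <- band[ii]
      out3[, , k] <- ob
    }
  } else {
    x0 <- floor(sx); y0 <- floor(sy)
    x1 <- pmin(x0 + 1, n - 1); y1 <- pmin(y0 + 1, m - 1)
    fx <- sx - x0; fy <- sy - y0
    i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x1 + 1)
    i10 <- cbind(y1 + 1, x0 + 1); i11 <- cbind(y1 + 1, x1 + 1)
    for (k in seq_len(ch)) {
      band <- img3[, , k]
      val <- band[i00] * (1 - fx) * (1 - fy) + band[i01] * fx * (1 - fy) +
        band[i10] * (1 - fx) * fy + band[i11] * fx * fy
      # locally constant neighbourhoods pass through bit-exactly
      eq <- band[i00] == band[i01] & band[i00] == band[i10] &
        band[i00] == band[i11]
      val[eq] <- band[i00][eq]
      ob <- out3[, , k]
      ob[moved] <- val
      out3[, , k] <- ob
    }
  }
  if (ch == 1L && length(dm) == 2L) out3[, , 1L] else out3
}

#' Simulate one good/bad response to a frame
#'
#' Deterministic core: the response is 'bad' (0) iff the maximum
#' [displacement_magnitude()] over the frame's sampled pattern points is at
#' least `params$threshold_delta`; otherwise 'good' (1). If
#' `params$lapse_rate > 0` the bit is then flipped with that probability; if
#' `params$guess_rate > 0` it is replaced by a fair coin with that
#' probability (noise draws consume the current RNG stream; see
#' [run_test()] for seeding).
#'
#' @param frame A `vd_frame`.
#' @param lesions A `vd_lesion` or list of them (may be empty).
#' @param params A `vd_psychometric` (see [psychometric_params()]).
#' @param max_step Pattern sampling step in pixels.
#' @return `1L` ('good') or `0L` ('bad').
#' @export
simulate_response <- function(frame, lesions, params = psychometric_params(),
                              max_step = 1) {
  stopifnot(inherits(frame, "vd_frame"), inherits(params, "vd_psychometric"))
  lesions <- as_lesion_list(lesions)
  bad <- FALSE
  if (length(lesions) && length(frame$elements)) {
    for (el in frame$elements) {
      pts <- sample_polyline(el$points, max_step)
      if (max(displacement_magnitude(pts, lesions)) >= params$threshold_delta) {
        bad <- TRUE
        break
      }
    }
  }
  bit <- if (bad) 0L else 1L
  if (params$lapse_rate > 0 && stats::runif(1) < params$lapse_rate)
    bit <- 1L - bit
  if (params$guess_rate > 0 && stats::runif(1) < params$guess_rate)
    bit <- if (stats::runif(1) < 0.5) 1L else 0L
  bit
}

#' Run a visual-distortion test on a synthetic patient
#'
#' Presents each frame in order to the synthetic responder and records the
#' good/bad bits with synthetic timestamps at `1 / rate_r` intervals. With
#' `lapse_rate = guess_rate = 0` the log is fully deterministic; otherwise
#' `params$seed` (when set) seeds the noise draws.
#'
#' @param test A `vd_test`.
#' @param lesions A `vd_lesion` or list of them (may be empty).
#' @param params A `vd_psychometric`.
#' @param max_step Pattern sampling step in pixels.
#' @return An object of class `vd_response_log`: list with `test_name`,
#'   `bits` (integer vector, 1 = 'good', 0 = 'bad') and `timestamps_ms`.
#' @export
run_test <- function(test, lesions, params = psychometric_params(),
                     max_step = 1) {
  stopifnot(inherits(test, "vd_test"))
  if (!is.null(params$seed) &&
      (params$lapse_rate > 0 || params$guess_rate > 0))
    set.seed(params$seed)
  bits <- vapply(test$frames, simulate_response, integer(1),
                 lesions = lesions, params = params, max_step = max_step)
  structure(
    list(test_name = test$name, bits = bits,
         timestamps_ms = seq_along(bits) * 1000 / test$rate_r),
    class = "vd_response_log"
  )
}

#' @export
print.vd_response_log <- function(x, ...) {
  cat(sprintf("<vd_response_log '%s'> %d responses, %d 'bad'\n",
              x$test_name, length(x$bits), sum(x$bits == 0L)))
  invisible(x)
}

#' Read and write response logs as JSON
#'
#' The interchange form is `{test_name, bits, timestamps_ms}` with bits
#' coded 1 = 'good', 0 = 'bad'.
#'
#' @param log A `vd_response_log`.
#' @param path File path.
#' @return `read_response_log` returns a `vd_response_log`;
#'   `write_response_log` returns `path` invisibly.
#' @export
write_response_log <- function(log, path) {
  stopifnot(inherits(log, "vd_response_log"))
  jsonlite::write_json(unclass(log), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_response_log
#' @export
read_response_log <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(rec$bits %in% c(0L, 1L))) stop("response bits must be 0 or 1")
  structure(list(test_name = rec$test_name, bits = as.integer(rec$bits),
                 timestamps_ms = as.numeric(rec$timestamps_ms)),
            class = "vd_response_log")
}
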