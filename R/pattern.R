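#' Construct a polyline element
#'
#' @param points An N x 2 matrix (or length-2 vector pair list) of vertices,
#'   N >= 2, finite coordinates in pixels.
#' @param stroke_width Stroke width in pixels (>= 1).
#' @param color Stroke colour as a hex string, e.g. `"#000000"`.
#' @return A list of class `vd_polyline`.
#' @export
make_polyline <- function(points, stroke_width = 1, color = "#000000") {
  pts <- as_points(points)
  if (nrow(pts) < 2L) stop("a polyline needs at least 2 points")
  stopifnot_scalar(stroke_width, "stroke_width", lower = 1)
  if (!grepl("^#[0-9a-fA-F]{6}$", color))
    stop("color must be a hex string like '#000000'")
  structure(list(points = pts, stroke_width = as.numeric(stroke_width),
                 color = tolower(color)),
            class = "vd_polyline")
}

#' Construct a test frame
#'
#' A frame is one pattern of straight lines shown to the patient, indexed
#' within a test, on an `m x n` canvas.
#'
#' @param elements List of `vd_polyline` (may be empty).
#' @param canvas Canvas shape `c(m, n)` (rows, columns).
#' @param index 1-based frame index within its test.
#' @return A list of class `vd_frame`.
#' @export
make_frame <- function(elements = list(), canvas, index = 1L) {
  canvas <- as_canvas(canvas)
  if (inherits(elements, "vd_polyline")) elements <- list(elements)
  if (!all(vapply(elements, inherits, logical(1), "vd_polyline")))
    stop("elements must be vd_polyline objects")
  stopifnot_scalar(index, "index", lower = 1)
  structure(list(index = as.integer(index), elements = elements,
                 canvas = canvas),
            class = "vd_frame")
}

#' @export
print.vd_frame <- function(x, ...) {
  cat(sprintf("<vd_frame %d> %d element(s) on %d x %d canvas\n",
              x$index, length(x$elements), x$canvas[1L], x$canvas[2L]))
  invisible(x)
}

#' Single full-width straight-line frame
#'
#' The elementary stimulus of the test: one horizontal or vertical line
#' spanning the whole canvas at a given offset.
#'
#' @param orientation `"horizontal"` or `"vertical"`.
#' @param offset Perpendicular offset in pixels: the y position of a
#'   horizontal line (must satisfy `0 <= offset < m`) or the x position of a
#'   vertical line (`0 <= offset < n`).
#' @param canvas Canvas shape `c(m, n)`.
#' @param stroke_width,color Line style, as in [make_polyline()].
#' @param index Frame index.
#' @return A `vd_frame` with one 2-point polyline: e.g.
#'   `make_line_frame("horizontal", 400, c(800, 800))` runs from `(0, 400)`
#'   to `(799, 400)`.
#' @export
make_line_frame <- function(orientation = c("horizontal", "vertical"),
                            offset, canvas, stroke_width = 1,
                            color = "#000000", index = 1L) {
  orientation <- match.arg(orientation)
  canvas <- as_canvas(canvas)
  m <- canvas[1L]; n <- canvas[2L]
  extent <- if (orientation == "horizontal") m else n
  stopifnot_scalar(offset, "offset")
  if (offset < 0 || offset >= extent)
    stop(sprintf("offset %g outside canvas: must be in [0, %d)", offset, extent))
  pts <- if (orientation == "horizontal")
    rbind(c(0, offset), c(n - 1, offset))
  else
    rbind(c(offset, 0), c(offset, m - 1))
  make_frame(list(make_polyline(pts, stroke_width, color)), canvas, index)
}

#' Assemble a visual-distortion test from frames
#'
#' @param frames Ordered list of `vd_frame` sharing one canvas; indices are
#'   rewritten to 1..N.
#' @param name Test name.
#' @param duration_t Total test duration in seconds (> 0); defaults to
#'   `N / rate_r`.
#' @param rate_r Presentation rate in frames per second (> 0).
#' @return A list of class `vd_test`.
#' @export
make_test <- function(frames, name = "vdtest", duration_t = NULL, rate_r = 1) {
  if (!length(frames)) stop("a test needs at least one frame")
  if (!all(vapply(frames, inherits, logical(1), "vd_frame")))
    stop("frames must be vd_frame objects")
  canv <- frames[[1L]]$canvas
  for (f in frames) if (!identical(f$canvas, canv))
    stop("all frames in a test must share one canvas")
  stopifnot_scalar(rate_r, "rate_r")
  if (rate_r <= 0) stop("rate_r must be > 0")
  if (is.null(duration_t)) duration_t <- length(frames) / rate_r
  stopifnot_scalar(duration_t, "duration_t")
  if (duration_t <= 0) stop("duration_t must be > 0")
  for (i in seq_along(frames)) frames[[i]]$index <- i
  structure(list(name = name, frames = frames, canvas = canv,
                 duration_t = as.numeric(duration_t),
                 rate_r = as.numeric(rate_r)),
            class = "vd_test")
}

#' @export
print.vd_test <- function(x, ...) {
  cat(sprintf("<vd_test '%s'> %d frames on %d x %d canvas, %.3g s at %.3g fps\n",
              x$name, length(x$frames), x$canvas[1L], x$canvas[2L],
              x$duration_t, x$rate_r))
  invisible(x)
}

#' Generate a line-grid visual-distortion test
#'
#' The standard fixture test: one frame per horizontal line at offsets
#' `0, spacing, 2 spacing, ...` down the canvas, followed by one frame per
#' vertical line across it, so every canvas pixel lies within `spacing / 2`
#' of some frame's line. Frame count is `ceiling(m / spacing) +
#' ceiling(n / spacing)`; an 800 x 800 canvas at spacing 10 gives 160 frames.
#'
#' @param canvas Canvas shape `c(m, n)`.
#' @param spacing Line spacing in pixels (> 0). A spacing at or beyond the
#'   canvas extent degenerates to a single line per orientation, with a
#'   warning.
#' @param duration_t,rate_r Timing metadata, as in [make_test()].
#' @param stroke_width,color Line style.
#' @param name Test name.
#' @return A `vd_test`, horizontal frames first (ascending offset), then
#'   vertical frames (ascending offset).
#' @export
generate_grid_test <- function(canvas, spacing, duration_t = NULL, rate_r = 1,
                               stroke_width = 1, color = "#000000",
                               name = "line-grid") {
  canvas <- as_canvas(canvas)
  stopifnot_scalar(spacing, "spacing")
  if (spacing <= 0) stop("spacing must be > 0")
  m <- canvas[1L]; n <- canvas[2L]
  if (spacing >= m || spacing >= n)
    warning("spacing >= canvas extent: single line per orientation")
  off_h <- seq(0, m - 1, by = spacing)
  off_v <- seq(0, n - 1, by = spacing)
  frames <- c(
    lapply(off_h, function(o)
      make_line_frame("horizontal", o, canvas, stroke_width, color)),
    lapply(off_v, function(o)
      make_line_frame("vertical", o, canvas, stroke_width, color))
  )
  make_test(frames, name = name, duration_t = duration_t, rate_r = rate_r)
}

#' Rasterize a frame into a binary matrix
#'
#' Renders the frame's polylines into the binary pattern matrix `F` used by
#' the heatmap collapse: entry 1 marks a pattern pixel, 0 background. Lines
#' are traversed with an integer midpoint (DDA) walk, one pixel per
#' major-axis step, with no anti-aliasing, so the result is exactly binary;
#' stroke width `w` is drawn as `w` parallel single-pixel traversals offset
#' along the minor axis. Geometry falling outside the canvas is clipped, not
#' an error.
#'
#' @param frame A `vd_frame`.
#' @return An `m x n` integer matrix with entries in `{0, 1}` (row = y,
#'   column = x; pixel `(x, y)` is entry `[y + 1, x + 1]`).
#' @export
rasterize_frame <- function(frame) {
  stopifnot(inherits(frame, "vd_frame"))
  m <- frame$canvas[1L]; n <- frame$canvas[2L]
  F <- matrix(0L, m, n)
  for (el in frame$elements) {
    w <- max(1L, as.integer(round(el$stroke_width)))
    offs <- seq_len(w) - 1L - (w - 1L) %/% 2L
    pts <- el$points
    for (s in seq_len(nrow(pts) - 1L)) {
      x0 <- pts[s, 1L]; y0 <- pts[s, 2L]
      x1 <- pts[s + 1L, 1L]; y1 <- pts[s + 1L, 2L]
      steps <- max(abs(round(x1) - round(x0)), abs(round(y1) - round(y0))) + 1L
      xs <- round(seq(x0, x1, length.out = steps))
      ys <- round(seq(y0, y1, length.out = steps))
      horiz_major <- abs(x1 - x0) >= abs(y1 - y0)
      for (o in offs) {
        px <- if (horiz_major) xs else xs + o
        py <- if (horiz_major) ys + o else ys
        keep <- px >= 0 & px < n & py >= 0 & py < m
        if (any(keep)) F[cbind(py[keep] + 1L, px[keep] + 1L)] <- 1L
      }
    }
  }
  F
}

#' Export a frame matrix as CSV
#'
#' @param F A binary matrix from [rasterize_frame()].
#' @param path Output CSV path (m rows x n columns, no headers).
#' @return `path`, invisibly.
#' @export
write_frame_matrix_csv <- function(F, path) {
  utils::write.table(F, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
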