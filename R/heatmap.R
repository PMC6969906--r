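#' Collapse frame matrices over a response log
#'
#' Accumulates the binary pattern matrices of all frames the patient judged
#' distorted: `C = sum_i (1 - R_i) * F_i`, where `R_i = 1` codes 'good' and
#' `R_i = 0` codes 'bad'. Each entry of `C` counts the distorted patterns
#' that meet in that pixel.
#'
#' `collapse_matrices()` takes a pre-rasterized list of frame matrices;
#' `collapse_responses()` rasterizes a [vd_test][make_test()]'s frames on the
#' fly (only the 'bad' ones), which avoids holding all `N` matrices at once.
#'
#' @param frames List of equal-shape binary matrices (see
#'   [rasterize_frame()]).
#' @param test A `vd_test`.
#' @param log A `vd_response_log` with one bit per frame.
#' @return The accumulation matrix `C` (nonnegative integer matrix).
#' @export
collapse_matrices <- function(frames, log) {
  stopifnot(inherits(log, "vd_response_log"))
  if (length(frames) != length(log$bits))
    stop("length mismatch: ", length(frames), " frames vs ",
         length(log$bits), " response bits")
  if (!length(frames)) stop("no frames to collapse")
  shp <- dim(frames[[1L]])
  C <- matrix(0L, shp[1L], shp[2L])
  for (i in seq_along(frames)) {
    if (!identical(dim(frames[[i]]), shp))
      stop("frame ", i, " has mismatched shape")
    if (log$bits[i] == 0L) C <- C + frames[[i]]
  }
  C
}

#' @rdname collapse_matrices
#' @export
collapse_responses <- function(test, log) {
  stopifnot(inherits(test, "vd_test"), inherits(log, "vd_response_log"))
  if (length(test$frames) != length(log$bits))
    stop("length mismatch: ", length(test$frames), " frames vs ",
         length(log$bits), " response bits")
  C <- matrix(0L, test$canvas[1L], test$canvas[2L])
  for (i in seq_along(test$frames))
    if (log$bits[i] == 0L) C <- C + rasterize_frame(test$frames[[i]])
  C
}

#' Normalize an accumulation matrix to a heatmap
#'
#' Centred, clamped, max-scaled normalization: subtract the matrix mean,
#' clamp negatives to zero, and divide by the maximum so the result lies in
#' `[0, 1]` with maximum exactly 1 whenever any entry survives clamping. (A
#' z-score's division by the standard deviation would cancel in the final
#' max-scaling, so it is omitted.) An all-constant input, including all-zero,
#' yields an all-zero heatmap.
#'
#' @param C Nonnegative matrix from [collapse_responses()].
#' @return The normalized heatmap `H`, same shape, values in `[0, 1]`.
#' @export
normalize_heatmap <- function(C) {
  if (any(C < 0)) stop("C must be nonnegative")
  H <- pmax(C - mean(C), 0)
  mx <- max(H)
  if (mx > 0) H <- H / mx
  H
}

#' Distortion percentage and summary statistics of a heatmap
#'
#' Counts the heat pixels `N` (entries of `H` strictly above `theta`) and
#' reports the distortion percentage `eta = 100 * N / M` where `M = m * n`
#' is the total pixel count (e.g. `M = 800 * 800` for the default canvas),
#' together with the heat centroid and effective radius when any heat pixel
#' exists.
#'
#' @param H Normalized heatmap from [normalize_heatmap()].
#' @param theta Heat-pixel threshold in `[0, 1)`; default 0 (any strictly
#'   positive value counts).
#' @return A list of class `vd_heatmap_stats`: `N_heat`, `M_total`, `eta`,
#'   `centroid` (`c(x, y)` or `NULL`), `effective_radius`
#'   (`sqrt(N_heat / pi)` pixels).
#' @export
distortion_percentage <- function(H, theta = 0) {
  stopifnot_scalar(theta, "theta", lower = 0)
  if (theta >= 1) stop("theta must be in [0, 1)")
  N <- sum(H > theta)
  M <- length(H)
  centroid <- if (N > 0) estimate_lesion(H, theta)$centroid else NULL
  structure(list(N_heat = as.integer(N), M_total = as.integer(M),
                 eta = 100 * N / M, centroid = centroid,
                 effective_radius = sqrt(N / pi)),
            class = "vd_heatmap_stats")
}

#' @export
print.vd_heatmap_stats <- function(x, ...) {
  cat(sprintf("<vd_heatmap_stats> eta = %.4g%% (%d / %d heat pixels), effective radius %.4g px\n",
              x$eta, x$N_heat, x$M_total, x$effective_radius))
  if (!is.null(x$centroid))
    cat(sprintf("  centroid (%.2f, %.2f)\n", x$centroid[1L], x$centroid[2L]))
  invisible(x)
}

#' Estimate lesion location and extent from a heatmap
#'
#' The centroid is the `H`-weighted mean pixel position over heat pixels
#' (`H > theta`); the effective radius is that of a disk with the heat-pixel
#' area, `sqrt(N_heat / pi)`.
#'
#' For line-grid tests, `theta = 0.5` restricts the weight to pixels where at
#' least two distorted patterns meet (the intersections of 'bad' horizontal
#' and vertical lines), which localizes the lesion centre; with `theta = 0`
#' the full-length bad lines pull the centroid toward the canvas centre.
#'
#' @param H Normalized heatmap.
#' @param theta Heat-pixel threshold in `[0, 1)`.
#' @return List with `centroid` (`c(x, y)`, pixels, 0-based),
#'   `effective_radius`, and `N_heat`. Errors if no pixel exceeds `theta`
#'   (advising a lower threshold).
#' @export
estimate_lesion <- function(H, theta = 0) {
  stopifnot_scalar(theta, "theta", lower = 0)
  sel <- H > theta
  N <- sum(sel)
  if (N == 0)
    stop("no heat pixels above theta = ", theta, "; lower theta")
  m <- nrow(H); n <- ncol(H)
  xs <- rep(seq_len(n) - 1, each = m)
  ys <- rep(seq_len(m) - 1, times = n)
  w <- H[sel]
  centroid <- c(x = sum(w * xs[sel]) / sum(w),
                y = sum(w * ys[sel]) / sum(w))
  list(centroid = centroid, effective_radius = sqrt(N / pi),
       N_heat = as.integer(N))
}

#' Render a heatmap as circles
#'
#' Tiles the canvas into `cell x cell` pixel blocks; each block whose mean
#' heat value `v` is positive is drawn as a circle at the block centre with
#' radius `(cell / 2) * v` and opacity `v`. `cell = 1` renders one circle per
#' pixel; the default 10 gives the conventional summary rendering.
#'
#' @param H Normalized heatmap.
#' @param cell Block size in pixels (>= 1).
#' @param path Output path ending in `.svg` or `.png`.
#' @param color Circle colour (hex) for SVG output.
#' @return `path`, invisibly. The PNG rendering is a grayscale image where
#'   each pixel carries the maximum opacity of the circles covering it.
#' @export
render_heatmap <- function(H, cell = 10, path, color = "#d62728") {
  stopifnot_scalar(cell, "cell", lower = 1)
  cell <- as.integer(cell)
  m <- nrow(H); n <- ncol(H)
  blocks <- heatmap_blocks(H, cell)
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") {
    doc <- xml2::xml_new_root(
      "svg", xmlns = "http://www.w3.org/2000/svg", version = "1.1",
      width = as.character(n), height = as.character(m),
      viewBox = sprintf("0 0 %d %d", n, m))
    if (nrow(blocks))
      for (i in seq_len(nrow(blocks)))
        xml2::xml_add_child(doc, "circle",
                            cx = sprintf("%.9g", blocks$cx[i]),
                            cy = sprintf("%.9g", blocks$cy[i]),
                            r = sprintf("%.9g", blocks$r[i]),
                            fill = color,
                            `fill-opacity` = sprintf("%.6g", blocks$v[i]))
    xml2::write_xml(doc, path)
  } else if (ext == "png") {
    img <- matrix(0, m, n)
    if (nrow(blocks)) {
      for (i in seq_len(nrow(blocks))) {
        r <- blocks$r[i]
        x0 <- max(0, floor(blocks$cx[i] - r)); x1 <- min(n - 1, ceiling(blocks$cx[i] + r))
        y0 <- max(0, floor(blocks$cy[i] - r)); y1 <- min(m - 1, ceiling(blocks$cy[i] + r))
        if (x1 < x0 || y1 < y0) next
        xs <- x0:x1; ys <- y0:y1
        dx2 <- outer(rep(1, length(ys)), (xs - blocks$cx[i])^2)
        dy2 <- outer((ys - blocks$cy[i])^2, rep(1, length(xs)))
        hit <- dx2 + dy2 <= r^2
        sub <- img[ys + 1, xs + 1, drop = FALSE]
        sub[hit] <- pmax(sub[hit], blocks$v[i])
        img[ys + 1, xs + 1] <- sub
      }
    }
    png::writePNG(img, path)
  } else {
    stop("unsupported render format '", ext, "' (use .svg or .png)")
  }
  invisible(path)
}

# per-block means and circle geometry; returns a data.frame of positive blocks
heatmap_blocks <- function(H, cell) {
  m <- nrow(H); n <- ncol(H)
  by <- seq(1L, m, by = cell)
  bx <- seq(1L, n, by = cell)
  out <- list()
  for (r0 in by) for (c0 in bx) {
    rows <- r0:min(r0 + cell - 1L, m)
    cols <- c0:min(c0 + cell - 1L, n)
    v <- mean(H[rows, cols])
    if (v > 0) {
      out[[length(out) + 1L]] <- data.frame(
        cx = (c0 - 1) + (length(cols) - 1) / 2,
        cy = (r0 - 1) + (length(rows) - 1) / 2,
        r = (cell / 2) * v, v = v)
    }
  }
  if (!length(out)) return(data.frame(cx = numeric(0), cy = numeric(0),
                                      r = numeric(0), v = numeric(0)))
  do.call(rbind, out)
}

#' Export heatmap matrices
#'
#' `write_heatmap_csv` writes `C` or `H` as a plain CSV matrix (m rows x n
#' columns); `write_heatmap_png` writes a lossless PNG (16-bit grayscale,
#' values scaled by the matrix maximum).
#'
#' @param M Matrix (`C` or `H`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_heatmap_csv <- function(M, path) {
  utils::write.table(M, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_heatmap_csv
#' @export
write_heatmap_png <- function(M, path) {
  mx <- max(M)
  img <- if (mx > 0) M / mx else M
  png::writePNG(img, path)
  invisible(path)
}

#' Heatmap statistics as JSON
#'
#' @param stats A `vd_heatmap_stats` from [distortion_percentage()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_heatmap_stats <- function(stats, path) {
  stopifnot(inherits(stats, "vd_heatmap_stats"))
  rec <- list(N_heat = stats$N_heat, M_total = stats$M_total, eta = stats$eta,
              centroid = if (is.null(stats$centroid)) NULL else
                list(x = unname(stats$centroid[1L]),
                     y = unname(stats$centroid[2L])),
              effective_radius = stats$effective_radius)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
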