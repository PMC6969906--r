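#' Forward displacement map of a CSR lesion
#'
#' Maps stimulus positions to the positions at which a patient with the given
#' lesion(s) perceives them. For a single lesion with centre `c`, sphere
#' radius `R`, base diameter `D` and cap half-angle `beta = asin(D/(2R))`,
#' a point at radial distance `L1 = ||p - c||` inside the support disk
#' (`L1 < D/2`) is moved outward along its ray to
#' `L2 = R * sin(2 * beta * L1 / D)`; every point with `L1 >= D/2` is a fixed
#' point. The in-plane direction angle about the lesion centre is preserved.
#' The map is continuous, fixes the centre and the support boundary, and for
#' the half sphere (`D = 2R`) reduces to `L2 = R * sin(pi * L1 / (2 R))`.
#'
#' With multiple lesions the maps are composed sequentially in list order;
#' for lesions with disjoint support disks this equals independent
#' application.
#'
#' @param p A point `c(x, y)` or an N x 2 matrix of points (pixels).
#' @param lesions A `vd_lesion` or list of them (see [make_lesion()]).
#' @return Points in the same shape as `p` (a length-2 vector in, a vector
#'   out; a matrix in, a matrix out).
#' @seealso [inverse_map()], [displacement_magnitude()], [build_field()]
#' @examples
#' les <- make_lesion(400, 400, R = 250, variant = "half_sphere")
#' forward_map(c(400 + 250 / 3, 400), les)  # -> (525, 400): L2 = 250 sin(pi/6)
#' @export
forward_map <- function(p, lesions) {
  map_points(p, lesions, .forward_one)
}

#' Inverse displacement map of a CSR lesion
#'
#' Exact inverse of [forward_map()]: a perceived point at radial distance
#' `L2 < D/2` from the lesion centre came from stimulus distance
#' `L1 = (D / (2 beta)) * asin(L2 / R)`; points with `L2 >= D/2` are fixed.
#' For composed lesions the single-lesion inverses are applied in reverse
#' list order. The `asin` argument is clamped to `[-1, 1]` when it exceeds 1
#' by at most `1e-9`; larger excursions raise an error.
#'
#' @inheritParams forward_map
#' @return Points in the same shape as `p`.
#' @export
inverse_map <- function(p, lesions) {
  lesions <- rev(as_lesion_list(lesions))
  map_points(p, lesions, .inverse_one, .prelisted = TRUE)
}

#' Displacement magnitude of the lesion map
#'
#' `||forward_map(p) - p||`: how far (in pixels) the percept of a stimulus at
#' `p` is displaced. Zero at the lesion centre and everywhere outside the
#' support disk(s).
#'
#' @inheritParams forward_map
#' @return A numeric vector, one value per point.
#' @export
displacement_magnitude <- function(p, lesions) {
  pts <- as_points(p)
  out <- forward_map(pts, lesions)
  sqrt(rowSums((out - pts)^2))
}

# shared driver: applies fn(points, lesion) for each lesion in order
map_points <- function(p, lesions, fn, .prelisted = FALSE) {
  vec_in <- is.null(dim(p))
  pts <- as_points(p)
  if (!.prelisted) lesions <- as_lesion_list(lesions)
  for (les in lesions) pts <- fn(pts, les)
  if (vec_in) c(x = unname(pts[1L, 1L]), y = unname(pts[1L, 2L])) else pts
}

.forward_one <- function(pts, les) {
  s <- les$D / 2
  if (s <= 0) return(pts)
  dx <- pts[, 1L] - les$x0
  dy <- pts[, 2L] - les$y0
  L1 <- sqrt(dx * dx + dy * dy)
  idx <- which(L1 > 0 & L1 < s)
  if (length(idx)) {
    L2 <- les$R * sin(2 * les$beta * L1[idx] / les$D)
    k <- L2 / L1[idx]
    pts[idx, 1L] <- les$x0 + dx[idx] * k
    pts[idx, 2L] <- les$y0 + dy[idx] * k
  }
  pts
}

.inverse_one <- function(pts, les) {
  s <- les$D / 2
  if (s <= 0) return(pts)
  dx <- pts[, 1L] - les$x0
  dy <- pts[, 2L] - les$y0
  L2 <- sqrt(dx * dx + dy * dy)
  idx <- which(L2 > 0 & L2 < s)
  if (length(idx)) {
    arg <- L2[idx] / les$R
    if (any(arg > 1 + 1e-9))
      stop("inverse_map: asin argument exceeds 1 beyond tolerance (corrupt geometry?)")
    arg <- pmin(arg, 1)
    L1 <- (les$D / (2 * les$beta)) * asin(arg)
    k <- L1 / L2[idx]
    pts[idx, 1L] <- les$x0 + dx[idx] * k
    pts[idx, 2L] <- les$y0 + dy[idx] * k
  }
  pts
}

#' Sample the composed forward map over a pixel grid
#'
#' Evaluates the composed forward map of `lesions` at every pixel centre of
#' an `m x n` canvas and returns the per-pixel displacement components. Pixel
#' `(row r, col c)` (1-based in R) has centre `(x, y) = (c - 1, r - 1)`.
#'
#' @param shape Canvas shape `c(m, n)` (rows, columns).
#' @param lesions A `vd_lesion` or list of them; may be empty.
#' @return A list of class `vd_field` with `dx` and `dy` (`m x n` matrices,
#'   pixels) and `shape`. Displacement is exactly zero outside every
#'   lesion's support disk. Lesions whose support disks overlap are allowed;
#'   a warning is issued because sequential composition is order-dependent
#'   there.
#' @export
build_field <- function(shape, lesions) {
  shape <- as_canvas(shape)
  m <- shape[1L]; n <- shape[2L]
  lesions <- as_lesion_list(lesions)
  warn_on_overlap(lesions)
  dx <- matrix(0, m, n)
  dy <- matrix(0, m, n)
  if (length(lesions)) {
    # restrict work to the union of support bounding boxes
    xs <- rep(seq_len(n) - 1, each = m)
    ys <- rep(seq_len(m) - 1, times = n)
    active <- rep(FALSE, m * n)
    for (les in lesions) {
      s <- les$D / 2
      if (s <= 0) next
      active <- active |
        ((xs - les$x0)^2 + (ys - les$y0)^2 < s^2)
    }
    if (any(active)) {
      pts <- cbind(xs[active], ys[active])
      out <- forward_map(pts, lesions)
      dx[active] <- out[, 1L] - pts[, 1L]
      dy[active] <- out[, 2L] - pts[, 2L]
    }
  }
  structure(list(dx = dx, dy = dy, shape = shape), class = "vd_field")
}

warn_on_overlap <- function(lesions) {
  k <- length(lesions)
  if (k < 2L) return(invisible(FALSE))
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    a <- lesions[[i]]; b <- lesions[[j]]
    d <- sqrt((a$x0 - b$x0)^2 + (a$y0 - b$y0)^2)
    if (d < a$D / 2 + b$D / 2) {
      warning("lesion support disks overlap; composition is applied in list order")
      return(invisible(TRUE))
    }
  }
  invisible(FALSE)
}

#' Export a displacement field as CSV
#'
#' Writes the two displacement bands of a [build_field()] result as two CSV
#' matrices (`m` rows x `n` columns, row = y), `<stem>_dx.csv` and
#' `<stem>_dy.csv`.
#'
#' @param field A `vd_field`.
#' @param stem Output path stem (no extension).
#' @return The two file paths, invisibly.
#' @export
write_field_csv <- function(field, stem) {
  stopifnot(inherits(field, "vd_field"))
  paths <- paste0(stem, c("_dx.csv", "_dy.csv"))
  utils::write.table(field$dx, paths[1L], sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(field$dy, paths[2L], sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(paths)
}
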