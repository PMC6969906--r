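# internal helpers shared across modules

# Coerce a point or set of points to an N x 2 numeric matrix (columns x, y).
# Accepts a length-2 vector, an N x 2 matrix, or a data.frame with x/y columns.
as_points <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p[, c("x", "y")])
  if (is.null(dim(p))) {
    if (length(p) != 2L) stop("a point must have exactly 2 coordinates (x, y)")
    p <- matrix(as.numeric(p), nrow = 1L)
  } else {
    p <- matrix(as.numeric(p), nrow = nrow(p))
  }
  if (ncol(p) != 2L) stop("points must be an N x 2 matrix with columns (x, y)")
  if (!all(is.finite(p))) stop("point coordinates must be finite")
  colnames(p) <- c("x", "y")
  p
}

# Validate a canvas spec c(m, n) = (rows, columns).
as_canvas <- function(canvas) {
  if (length(canvas) != 2L || !all(is.finite(canvas)) || any(canvas < 1))
    stop("canvas must be c(m, n) with m, n >= 1")
  as.integer(canvas)
}

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (length(x) != 1L || !is.finite(x))
    stop(sprintf("%s must be a single finite number", name))
  if (x < lower || x > upper)
    stop(sprintf("%s must be in [%s, %s], got %s", name, lower, upper, x))
  invisible(x)
}
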