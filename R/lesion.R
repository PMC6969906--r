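#' Define a CSR lesion (spherical or spherical-cap cavity)
#'
#' A central serous chorioretinopathy (CSR) cavity is modelled as a spherical
#' cap of base diameter `D` cut from a sphere of radius `R`, centred at canvas
#' position `(x0, y0)`. Retinal sensing points that were uniformly spaced on
#' the flat base are stretched uniformly along the cap's arc, which displaces
#' the perceived position of every stimulus landing inside the cap base (the
#' *support disk* of radius `D/2`). The cap half-angle is
#' `beta = asin(D / (2 R))`; the half-sphere variant is the special case
#' `D = 2 R` (`beta = pi/2`).
#'
#' @param x0,y0 Lesion centre on the canvas, in pixels (x rightward, y
#'   downward, origin at the top-left pixel centre, 0-based).
#' @param R Sphere radius in pixels; must be positive.
#' @param D Cavity base diameter in pixels, `0 <= D <= 2 R`. May be omitted
#'   for `variant = "half_sphere"`, where it is forced to `2 R`.
#' @param variant `"cap"` (default) or `"half_sphere"`.
#' @return An object of class `vd_lesion`: a list with fields `x0`, `y0`,
#'   `R`, `D`, `variant` and the derived cap half-angle `beta` (radians).
#' @examples
#' make_lesion(400, 400, R = 250, variant = "half_sphere") # D forced to 500
#' make_lesion(400, 400, R = 250, D = 125)                 # beta = asin(0.25)
#' @export
make_lesion <- function(x0, y0, R, D = NULL, variant = c("cap", "half_sphere")) {
  variant <- match.arg(variant)
  stopifnot_scalar(x0, "x0")
  stopifnot_scalar(y0, "y0")
  stopifnot_scalar(R, "R")
  if (R <= 0) stop("R must be > 0, got ", R)
  if (variant == "half_sphere") {
    if (!is.null(D) && abs(D - 2 * R) > 1e-9)
      stop("half_sphere requires D = 2R (got D = ", D, ", 2R = ", 2 * R, ")")
    D <- 2 * R
  }
  if (is.null(D)) stop("D is required for variant = 'cap'")
  stopifnot_scalar(D, "D")
  if (D < 0) stop("D must be >= 0, got ", D)
  if (D > 2 * R) stop("D must be <= 2R (got D = ", D, ", 2R = ", 2 * R, ")")
  structure(
    list(x0 = as.numeric(x0), y0 = as.numeric(y0), R = as.numeric(R),
         D = as.numeric(D), variant = variant,
         beta = asin(D / (2 * R))),
    class = "vd_lesion"
  )
}

#' @export
print.vd_lesion <- function(x, ...) {
  cat(sprintf(
    "<vd_lesion %s> centre (%g, %g), R = %g px, D = %g px, beta = %.4f rad, support radius %g px\n",
    x$variant, x$x0, x$y0, x$R, x$D, x$beta, x$D / 2))
  invisible(x)
}

is_lesion <- function(x) inherits(x, "vd_lesion")

# Normalise a lesion or list of lesions to a plain list of vd_lesion objects.
as_lesion_list <- function(lesions) {
  if (is.null(lesions)) return(list())
  if (is_lesion(lesions)) return(list(lesions))
  if (!is.list(lesions) || !all(vapply(lesions, is_lesion, logical(1))))
    stop("lesions must be a vd_lesion or a list of vd_lesion objects")
  lesions
}

#' Read and write lesion configurations as JSON
#'
#' A lesion configuration is a JSON object `{x0, y0, R, D, variant}`, or a
#' JSON array of such objects for multi-lesion scenes.
#'
#' @param lesions A `vd_lesion` or list of them.
#' @param path File path.
#' @return `read_lesions` returns a list of `vd_lesion`; `write_lesions`
#'   returns `path` invisibly.
#' @export
write_lesions <- function(lesions, path) {
  lesions <- as_lesion_list(lesions)
  recs <- lapply(lesions, function(l)
    list(x0 = l$x0, y0 = l$y0, R = l$R, D = l$D, variant = l$variant))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lesions
#' @export
read_lesions <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(recs$x0)) recs <- list(recs)  # single object
  lapply(recs, function(r) {
    make_lesion(r$x0, r$y0, r$R, D = r$D,
                variant = if (is.null(r$variant)) "cap" else r$variant)
  })
}
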