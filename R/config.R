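#' Read a run configuration
#'
#' A run configuration is a single JSON object driving the command-line
#' interface:
#'
#' ```json
#' {
#'   "canvas": [800, 800],
#'   "spacing": 10,
#'   "lesions": [{"x0": 300, "y0": 420, "R": 250, "D": 125, "variant": "cap"}],
#'   "psychometric": {"threshold_delta": 2, "lapse_rate": 0, "guess_rate": 0},
#'   "theta": 0,
#'   "output_dir": "out",
#'   "seed": 1
#' }
#' ```
#'
#' Missing fields take the defaults above (no lesions, canvas 800 x 800).
#'
#' @param path JSON config path.
#' @return A validated list of class `vd_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  as_run_config(raw)
}

as_run_config <- function(raw) {
  canvas <- if (is.null(raw$canvas)) c(800L, 800L) else
    as_canvas(unlist(raw$canvas))
  spacing <- if (is.null(raw$spacing)) 10 else raw$spacing
  stopifnot_scalar(spacing, "spacing")
  if (spacing <= 0) stop("spacing must be > 0")
  lesions <- lapply(raw$lesions %||% list(), function(r)
    make_lesion(r$x0, r$y0, r$R, D = r$D,
                variant = if (is.null(r$variant)) "cap" else r$variant))
  ps <- raw$psychometric %||% list()
  psy <- psychometric_params(
    threshold_delta = ps$threshold_delta %||% 2,
    lapse_rate = ps$lapse_rate %||% 0,
    guess_rate = ps$guess_rate %||% 0,
    seed = ps$seed %||% raw$seed)
  theta <- raw$theta %||% 0
  stopifnot_scalar(theta, "theta", lower = 0)
  structure(list(canvas = canvas, spacing = as.numeric(spacing),
                 lesions = lesions, psychometric = psy,
                 theta = as.numeric(theta),
                 output_dir = raw$output_dir %||% ".",
                 seed = if (is.null(raw$seed)) NULL else as.integer(raw$seed)),
            class = "vd_run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable hash of a config for output-manifest provenance
config_hash <- function(config) {
  js <- jsonlite::toJSON(
    list(canvas = as.integer(config$canvas), spacing = config$spacing,
         lesions = lapply(config$lesions, function(l)
           list(x0 = l$x0, y0 = l$y0, R = l$R, D = l$D, variant = l$variant)),
         psychometric = unclass(config$psychometric),
         theta = config$theta, seed = config$seed),
    auto_unbox = TRUE, digits = NA)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}
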