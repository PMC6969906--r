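#' Write a frame as an SVG file
#'
#' Emits SVG 1.1 with a `viewBox` of `"0 0 n m"` matching the canvas (user
#' units = pixels) and one `<polyline>` per element (`fill="none"`, stroke
#' colour and width from the element style).
#'
#' @param frame A `vd_frame`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_svg()]
#' @export
write_svg <- function(frame, path) {
  stopifnot(inherits(frame, "vd_frame"))
  m <- frame$canvas[1L]; n <- frame$canvas[2L]
  doc <- xml2::xml_new_root(
    "svg", xmlns = "http://www.w3.org/2000/svg", version = "1.1",
    width = as.character(n), height = as.character(m),
    viewBox = sprintf("0 0 %d %d", n, m)
  )
  for (el in frame$elements) {
    pts <- paste(sprintf("%.9g,%.9g", el$points[, 1L], el$points[, 2L]),
                 collapse = " ")
    xml2::xml_add_child(doc, "polyline", points = pts, fill = "none",
                        stroke = el$color,
                        `stroke-width` = sprintf("%.9g", el$stroke_width))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a frame from an SVG file
#'
#' Parses the restricted SVG dialect written by [write_svg()]: `<line>`,
#' `<polyline>`, and `<path>` with absolute `M`/`L` commands, optionally
#' inside `<g>` groups carrying only `translate(tx, ty)` transforms. Any
#' other element (circles, rects, text, filters, ...) or transform is
#' rejected with an error naming it. The canvas is taken from the `viewBox`.
#'
#' @param path SVG file path.
#' @param index Frame index to assign.
#' @return A `vd_frame`. Round-trips with [write_svg()] to within 1e-6 px.
#' @export
read_svg <- function(path, index = 1L) {
  doc <- xml2::read_xml(path)
  root <- xml2::xml_name(doc)
  if (root != "svg") stop("not an SVG document: root <", root, ">")
  vb <- xml2::xml_attr(doc, "viewBox")
  if (is.na(vb)) stop("SVG lacks a viewBox attribute")
  vb <- as.numeric(strsplit(trimws(vb), "[ ,]+")[[1L]])
  if (length(vb) != 4L || any(vb[1:2] != 0))
    stop("unsupported viewBox (must be '0 0 n m')")
  canvas <- c(vb[4L], vb[3L])  # (m, n)
  elements <- parse_svg_children(doc, tx = 0, ty = 0)
  make_frame(elements, canvas, index)
}

parse_svg_children <- function(node, tx, ty) {
  out <- list()
  for (child in xml2::xml_children(node)) {
    nm <- xml2::xml_name(child)
    if (nm %in% c("title", "desc", "metadata", "defs")) next
    ctx <- c(tx, ty)
    tr <- xml2::xml_attr(child, "transform")
    if (!is.na(tr)) {
      mt <- regmatches(tr, regexec(
        "^\\s*translate\\(\\s*(-?[0-9.eE+]+)[ ,]+(-?[0-9.eE+]+)\\s*\\)\\s*$", tr))[[1L]]
      if (length(mt) != 3L)
        stop("unsupported SVG transform '", tr, "' (only translate is supported)")
      ctx <- ctx + as.numeric(mt[2:3])
    }
    if (nm == "g") {
      out <- c(out, parse_svg_children(child, ctx[1L], ctx[2L]))
      next
    }
    pts <- switch(nm,
      line = {
        a <- function(at) as.numeric(xml2::xml_attr(child, at))
        rbind(c(a("x1"), a("y1")), c(a("x2"), a("y2")))
      },
      polyline = {
        raw <- xml2::xml_attr(child, "points")
        v <- as.numeric(strsplit(trimws(raw), "[ ,]+")[[1L]])
        matrix(v, ncol = 2L, byrow = TRUE)
      },
      path = parse_path_d(xml2::xml_attr(child, "d")),
      stop("unsupported SVG element <", nm, ">")
    )
    pts[, 1L] <- pts[, 1L] + ctx[1L]
    pts[, 2L] <- pts[, 2L] + ctx[2L]
    sw <- xml2::xml_attr(child, "stroke-width")
    col <- xml2::xml_attr(child, "stroke")
    out <- c(out, list(make_polyline(
      pts,
      stroke_width = if (is.na(sw)) 1 else as.numeric(sw),
      color = if (is.na(col)) "#000000" else col)))
  }
  out
}

# absolute M/L path commands only
parse_path_d <- function(d) {
  if (is.na(d)) stop("<path> without 'd' attribute")
  toks <- strsplit(trimws(d), "(?<=[A-Za-z])|(?=[A-Za-z])|[ ,]+", perl = TRUE)[[1L]]
  toks <- toks[nzchar(toks)]
  pts <- NULL
  i <- 1L
  cmd <- ""
  while (i <= length(toks)) {
    if (grepl("^[A-Za-z]$", toks[i])) {
      cmd <- toks[i]
      if (!cmd %in% c("M", "L"))
        stop("unsupported <path> command '", cmd, "' (only absolute M/L)")
      i <- i + 1L
    }
    if (i + 1L > length(toks)) stop("malformed <path> data")
    pts <- rbind(pts, as.numeric(toks[i:(i + 1L)]))
    i <- i + 2L
  }
  pts
}

#' Write and read a test manifest
#'
#' A test manifest is a JSON file `{name, canvas, duration_t, rate_r,
#' frames: [...]}` with one SVG file per frame (`<name>_frame_0001.svg`, ...)
#' next to the manifest.
#'
#' @param test A `vd_test`.
#' @param dir Output directory (created if needed).
#' @param manifest Manifest path.
#' @return `write_test_manifest` returns the manifest path invisibly;
#'   `read_test_manifest` returns a `vd_test`.
#' @export
write_test_manifest <- function(test, dir) {
  stopifnot(inherits(test, "vd_test"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("%s_frame_%04d.svg", test$name, seq_along(test$frames))
  for (i in seq_along(test$frames))
    write_svg(test$frames[[i]], file.path(dir, files[i]))
  manifest <- file.path(dir, paste0(test$name, "_manifest.json"))
  jsonlite::write_json(
    list(name = test$name,
         canvas = as.integer(test$canvas),
         duration_t = test$duration_t,
         rate_r = test$rate_r,
         frames = files),
    manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' @rdname write_test_manifest
#' @export
read_test_manifest <- function(manifest) {
  meta <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  dir <- dirname(manifest)
  frames <- lapply(seq_along(meta$frames), function(i)
    read_svg(file.path(dir, meta$frames[i]), index = i))
  make_test(frames, name = meta$name, duration_t = meta$duration_t,
            rate_r = meta$rate_r)
}
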