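#' Read a 3-column ASCII SAXS curve
#'
#' Parses the conventional `.dat` layout: whitespace-separated numeric
#' columns q \[inverse Angstrom\], I and (optionally) sigma, with comment
#' lines prefixed by `#`. Comments are preserved as the `"comments"`
#' attribute and re-emitted by [writeSAXSDat()].
#'
#' @param path file path.
#' @return A [SAXSCurve-class]; 2-column files yield a curve without sigma.
#' @examples
#' f <- tempfile(fileext = ".dat")
#' writeSAXSDat(saxsCurve(c(0.01, 0.02), c(2, 1)), f)
#' readSAXSDat(f)
#' @export
readSAXSDat <- function(path) {
  lines <- readLines(path, warn = FALSE)
  isComment <- grepl("^\\s*#", lines)
  isBlank <- grepl("^\\s*$", lines)
  dataLines <- which(!isComment & !isBlank)
  if (!length(dataLines)) stop("parse error: no data rows in ", path)
  rows <- lapply(dataLines, function(i) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals) || !length(vals) %in% c(2L, 3L))
      stop("parse error at line ", i, ": expected 2-3 numeric columns, got '",
           lines[i], "'")
    vals
  })
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1L)
    stop("parse error: inconsistent column counts in ", path)
  m <- do.call(rbind, rows)
  curve <- saxsCurve(m[, 1L], m[, 2L],
                     sigma = if (ncols == 3L) m[, 3L] else numeric())
  attr(curve, "comments") <- sub("^\\s*#\\s?", "", lines[isComment])
  curve
}

#' Write a SAXS curve as 3-column ASCII
#'
#' @param curve a [SAXSCurve-class].
#' @param path output path.
#' @param comments header comment lines (written with a `#` prefix); when
#'   NULL, any `"comments"` attribute of the curve is used.
#' @return `path`, invisibly. Values round-trip at 6 significant figures.
#' @examples
#' f <- tempfile(fileext = ".dat")
#' writeSAXSDat(saxsCurve(c(0.01, 0.02), c(2, 1)), f, comments = "model")
#' @export
writeSAXSDat <- function(curve, path, comments = NULL) {
  stopifnot(is(curve, "SAXSCurve"))
  if (is.null(comments)) comments <- attr(curve, "comments")
  hdr <- if (length(comments)) paste0("# ", comments) else character()
  cols <- cbind(curve@q, curve@I)
  if (length(curve@sigma)) cols <- cbind(cols, curve@sigma)
  body <- apply(cols, 1L, function(v)
    paste(formatC(v, format = "g", digits = 6), collapse = "  "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a grayscale micrograph from TIFF or PNG
#'
#' Multi-channel images are averaged to grayscale.
#'
#' @param path image path (`.tif`, `.tiff` or `.png`).
#' @param pixelSize nm per pixel calibration.
#' @param polarity ridge polarity of the image.
#' @return A [Micrograph-class].
#' @export
readMicrographImage <- function(path, pixelSize,
                                polarity = c("DARK_RIDGES",
                                             "BRIGHT_RIDGES")) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3L) img <- apply(img, c(1L, 2L), mean)
  micrograph(img, pixelSize, match.arg(polarity))
}

#' Write a micrograph as 32-bit float TIFF or PNG
#'
#' Intensities are rescaled to \[0, 1\] before writing (both formats store
#' values in that range); the rescaling is affine, so ridge polarity and
#' relative contrast — everything the quantification pipeline uses after
#' its own standardization — survive a write/read round trip.
#'
#' @param image a [Micrograph-class].
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
writeMicrographImage <- function(image, path) {
  stopifnot(is(image, "Micrograph"))
  ext <- tolower(tools::file_ext(path))
  px <- image@pixels
  rng <- range(px)
  scaled <- if (diff(rng) > 0) (px - rng[1L]) / diff(rng) else px * 0
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(scaled, path, bits.per.sample = 32L)
  } else if (ext == "png") {
    png::writePNG(scaled, path)
  } else stop("unsupported image format: ", ext)
  invisible(path)
}
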