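# Raster and boundary I/O: PNG/JPEG images in, masks as PNG, boundaries
# as CSV vertex lists or GeoJSON polygon records.

#' Read a clinical photograph as an RGB array
#'
#' Decodes an 8-bit PNG or JPEG into an H x W x 3 numeric array on the
#' 0-255 scale. Grayscale images are replicated across channels; an alpha
#' channel is dropped.
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return H x W x 3 numeric array, values in \[0, 255\].
#' @export
readLesionImage <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE))
      stop("reading JPEG requires the jpeg package")
    jpeg::readJPEG(path)
  } else stop("unsupported image format: .", ext)
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3L), c(dim(raw), 3L))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  raw * 255
}

#' Write an RGB array as PNG
#'
#' @param image H x W x 3 numeric array on the 0-255 scale.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeLesionImage <- function(image, path) {
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(path)
}

#' Write a region mask as a 0/255 PNG
#'
#' @param mask Logical H x W matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeMaskPNG <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a 0/255 PNG as a logical mask
#'
#' @param path PNG path.
#' @return Logical H x W matrix.
#' @export
readMaskPNG <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m > 0.5
}

#' Boundary import/export
#'
#' CSV vertex lists have columns `x`, `y` (0-based pixel centers);
#' GeoJSON files hold one `Polygon` feature whose outer ring repeats the
#' first vertex at the end, per the GeoJSON convention.
#'
#' @param boundary A [ClosedBoundary][ClosedBoundary-class].
#' @param path File path.
#' @return Readers return a [ClosedBoundary][ClosedBoundary-class];
#'   writers return `path` invisibly.
#' @name boundaryIO
NULL

#' @rdname boundaryIO
#' @export
writeBoundaryCSV <- function(boundary, path) {
  utils::write.csv(as.data.frame(boundary@vertices), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname boundaryIO
#' @export
readBoundaryCSV <- function(path) {
  df <- utils::read.csv(path)
  closedBoundary(as.matrix(df[, c("x", "y")]))
}

#' @rdname boundaryIO
#' @export
writeBoundaryGeoJSON <- function(boundary, path) {
  v <- boundary@vertices
  ring <- rbind(v, v[1L, ])
  obj <- list(type = "Feature",
              geometry = list(type = "Polygon",
                              coordinates = list(unname(
                                lapply(seq_len(nrow(ring)),
                                       function(i) as.numeric(ring[i, ]))))),
              properties = list(coordinate_system =
                                  "pixel centers, 0-based, y down"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname boundaryIO
#' @export
readBoundaryGeoJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ring <- obj$geometry$coordinates[1, , ]
  closedBoundary(ring)
}
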