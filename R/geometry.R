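# Polygon primitives (shoelace area, perimeter, centroid, diameter,
# simplicity), scale calibration and physical geometry features.

.polygonArea <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

.polygonPerimeter <- function(v) {
  dx <- diff(c(v[, 1], v[1, 1])); dy <- diff(c(v[, 2], v[1, 2]))
  sum(sqrt(dx^2 + dy^2))
}

# area centroid (signed shoelace weights); falls back to the vertex mean
# for degenerate (near-zero-area) rings
.polygonCentroid <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

.maxPairDist <- function(v) {
  max(stats::dist(v))
}

# proper-crossing test between all non-adjacent edge pairs (even-odd
# polygons); vectorized over pairs
.isSimplePolygon <- function(v) {
  n <- nrow(v)
  if (n < 4L) return(TRUE)
  p1 <- v
  p2 <- v[c(2:n, 1L), , drop = FALSE]
  idx <- utils::combn(n, 2L)
  i <- idx[1, ]; j <- idx[2, ]
  adj <- (j - i == 1L) | (i == 1L & j == n)
  i <- i[!adj]; j <- j[!adj]
  if (!length(i)) return(TRUE)
  o <- function(ax, ay, bx, by, cx, cy)
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  a1x <- p1[i, 1]; a1y <- p1[i, 2]; a2x <- p2[i, 1]; a2y <- p2[i, 2]
  b1x <- p1[j, 1]; b1y <- p1[j, 2]; b2x <- p2[j, 1]; b2y <- p2[j, 2]
  d1 <- o(a1x, a1y, a2x, a2y, b1x, b1y)
  d2 <- o(a1x, a1y, a2x, a2y, b2x, b2y)
  d3 <- o(b1x, b1y, b2x, b2y, a1x, a1y)
  d4 <- o(b1x, b1y, b2x, b2y, a2x, a2y)
  cross <- (d1 * d2 < 0) & (d3 * d4 < 0)
  !any(cross)
}

#' Construct a ClosedBoundary from vertex coordinates
#'
#' @param vertices Numeric matrix (or 2-column object) of `x`, `y` pixel
#'   coordinates, in order around the lesion.
#' @return A validated [ClosedBoundary][ClosedBoundary-class].
#' @export
closedBoundary <- function(vertices) {
  v <- as.matrix(vertices)
  storage.mode(v) <- "double"
  # drop an explicitly repeated closing vertex and consecutive duplicates
  if (nrow(v) > 1L && all(abs(v[nrow(v), ] - v[1L, ]) < 1e-12))
    v <- v[-nrow(v), , drop = FALSE]
  keep <- c(TRUE, rowSums(abs(diff(v))) > 1e-12)
  v <- v[keep, , drop = FALSE]
  colnames(v) <- c("x", "y")
  new("ClosedBoundary", vertices = v)
}

#' Calibrate physical scale from two ruler points
#'
#' Given two image points marking a known physical distance on a ruler
#' photographed next to the lesion, returns the centimeters-per-pixel
#' calibration.
#'
#' @param p1,p2 Numeric `(x, y)` pixel coordinates; must differ.
#' @param knownCm Physical distance between them in cm, > 0.
#' @return A [ScaleCalibration][ScaleCalibration-class].
#' @export
#' @examples
#' calibrateScale(c(0, 0), c(100, 0), 1)   # 0.01 cm/px
calibrateScale <- function(p1, p2, knownCm) {
  stopifnot(length(p1) == 2L, length(p2) == 2L,
            all(is.finite(c(p1, p2, knownCm))))
  if (knownCm <= 0) stop("knownCm must be positive")
  d <- sqrt(sum((as.numeric(p1) - as.numeric(p2))^2))
  if (d == 0) stop("ruler points must not coincide")
  new("ScaleCalibration", cmPerPixel = knownCm / d)
}

#' Physical geometry of a lesion boundary
#'
#' Surface is the shoelace polygon area scaled by `cmPerPixel^2`;
#' perimeter is the edge-length sum scaled by `cmPerPixel`; maximal
#' diameter is the largest pairwise vertex distance (exhaustive).
#'
#' @param boundary A [ClosedBoundary][ClosedBoundary-class].
#' @param scale A [ScaleCalibration][ScaleCalibration-class].
#' @return A [GeometryFeatures][GeometryFeatures-class].
#' @export
#' @examples
#' sq <- closedBoundary(cbind(c(0, 100, 100, 0), c(0, 0, 100, 100)))
#' geometryFeatures(sq, calibrateScale(c(0, 0), c(100, 0), 1))
geometryFeatures <- function(boundary, scale) {
  stopifnot(is(boundary, "ClosedBoundary"), is(scale, "ScaleCalibration"))
  v <- boundary@vertices
  s <- scale@cmPerPixel
  new("GeometryFeatures",
      maxDiameterCm = .maxPairDist(v) * s,
      surfaceCm2 = .polygonArea(v) * s^2,
      perimeterCm = .polygonPerimeter(v) * s)
}
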