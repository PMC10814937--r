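# Lesion border determination: manual point-and-spline mode, automatic
# color-distance segmentation, rasterization, and the surrounding
# normal-skin band.

#' Close operator-placed border points with a periodic quadratic spline
#'
#' Fits a closed (periodic) quadratic B-spline whose coefficients minimize
#' the mean squared distance to the input points, then samples it into a
#' polygon. With one control point per input point the least-squares fit
#' passes through the points (zero residual), so the sampled boundary is a
#' smooth closed curve through the operator's clicks.
#'
#' @param points Numeric matrix (n x 2) of `(x, y)` border points in
#'   order around the lesion; at least 4 non-collinear points.
#' @param nOut Number of polygon vertices to sample (default 200).
#' @return A [ClosedBoundary][ClosedBoundary-class].
#' @export
#' @examples
#' th <- 2 * pi * (0:11) / 12
#' b <- closeBoundary(cbind(100 + 50 * cos(th), 100 + 50 * sin(th)))
#' b
closeBoundary <- function(points, nOut = 200L) {
  p <- as.matrix(points)
  storage.mode(p) <- "double"
  if (ncol(p) != 2L || anyNA(p) || !all(is.finite(p)))
    stop("points must be a finite n x 2 matrix")
  if (nrow(p) > 1L && all(abs(p[nrow(p), ] - p[1L, ]) < 1e-12))
    p <- p[-nrow(p), , drop = FALSE]
  n <- nrow(p)
  if (n < 4L)
    stop(errorCondition("need at least 4 border points",
                        class = c("lesioncolor_boundary_error", "error",
                                  "condition")))
  ctr <- colMeans(p)
  sv <- svd(sweep(p, 2, ctr))$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop(errorCondition("border points are collinear",
                        class = c("lesioncolor_boundary_error", "error",
                                  "condition")))
  # Periodic uniform quadratic B-spline: segment i, local t in [0,1]:
  #   C_i(t) = ((1-t)^2 P_{i-1} + (-2t^2+2t+1) P_i + t^2 P_{i+1}) / 2
  # Data point i is placed at the segment midpoint t = 1/2, giving the
  # cyclic collocation system (P_{i-1} + 6 P_i + P_{i+1}) / 8 = D_i.
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    A[i, ((i - 2L) %% n) + 1L] <- A[i, ((i - 2L) %% n) + 1L] + 1 / 8
    A[i, ((i - 1L) %% n) + 1L] <- A[i, ((i - 1L) %% n) + 1L] + 6 / 8
    A[i, (i %% n) + 1L] <- A[i, (i %% n) + 1L] + 1 / 8
  }
  ctrl <- qr.solve(A, p)
  u <- seq(0, n, length.out = nOut + 1L)[-(nOut + 1L)]
  seg <- pmin(floor(u), n - 1L)
  t <- u - seg
  Pm <- ctrl[((seg - 1L) %% n) + 1L, , drop = FALSE]
  P0 <- ctrl[(seg %% n) + 1L, , drop = FALSE]
  Pp <- ctrl[((seg + 1L) %% n) + 1L, , drop = FALSE]
  w <- cbind((1 - t)^2, -2 * t^2 + 2 * t + 1, t^2) / 2
  out <- w[, 1] * Pm + w[, 2] * P0 + w[, 3] * Pp
  closedBoundary(out)
}

#' Mean squared distance from points to a boundary polygon
#'
#' Point-to-segment distances against every polygon edge; used to verify
#' the least-squares property of [closeBoundary()].
#'
#' @param boundary A [ClosedBoundary][ClosedBoundary-class].
#' @param points n x 2 matrix of `(x, y)` points.
#' @return Mean of squared minimal distances.
#' @export
boundaryResidual <- function(boundary, points) {
  v <- boundary@vertices
  w <- v[c(2:nrow(v), 1L), , drop = FALSE]
  p <- as.matrix(points)
  d2 <- vapply(seq_len(nrow(p)), function(k) {
    px <- p[k, 1]; py <- p[k, 2]
    ex <- w[, 1] - v[, 1]; ey <- w[, 2] - v[, 2]
    len2 <- ex^2 + ey^2
    t <- pmin(pmax(((px - v[, 1]) * ex + (py - v[, 2]) * ey) /
                     pmax(len2, 1e-300), 0), 1)
    min((v[, 1] + t * ex - px)^2 + (v[, 2] + t * ey - py)^2)
  }, numeric(1))
  mean(d2)
}

#' Rasterize a boundary into a region mask
#'
#' Pixel-center containment with the even-odd rule: pixel (row r, col c),
#' 1-based, has center (x, y) = (c - 1, r - 1).
#'
#' @param boundary A [ClosedBoundary][ClosedBoundary-class].
#' @param dim Image dimensions `c(H, W)`, or an H x W x 3 image array.
#' @return Logical H x W matrix.
#' @export
boundaryMask <- function(boundary, dim) {
  d <- .imageDim(dim)
  v <- boundary@vertices
  H <- d[1]; W <- d[2]
  cols <- max(1L, floor(min(v[, 1])) + 1L):min(W, ceiling(max(v[, 1])) + 1L)
  rows <- max(1L, floor(min(v[, 2])) + 1L):min(H, ceiling(max(v[, 2])) + 1L)
  mask <- matrix(FALSE, H, W)
  if (!length(cols) || !length(rows)) return(mask)
  g <- expand.grid(r = rows, c = cols)
  inside <- pracma::inpolygon(g$c - 1, g$r - 1, v[, 1], v[, 2],
                              boundary = TRUE)
  mask[cbind(g$r, g$c)] <- inside
  mask
}

.imageDim <- function(dim) {
  if (is.array(dim) && length(base::dim(dim)) == 3L) return(base::dim(dim)[1:2])
  if (is.matrix(dim)) return(base::dim(dim))
  stopifnot(is.numeric(dim), length(dim) >= 2L)
  as.integer(dim[1:2])
}

#' Scale a boundary about its area centroid
#'
#' @param boundary A [ClosedBoundary][ClosedBoundary-class].
#' @param factor Positive similarity factor.
#' @return A scaled [ClosedBoundary][ClosedBoundary-class].
#' @export
scaleBoundary <- function(boundary, factor) {
  stopifnot(is.finite(factor), factor > 0)
  v <- boundary@vertices
  ctr <- .polygonCentroid(v)
  closedBoundary(sweep(sweep(v, 2, ctr), 2, rep(factor, 2), "*") +
                   matrix(ctr, nrow(v), 2, byrow = TRUE))
}

#' Surrounding normal-skin band of a lesion
#'
#' Enlarges the lesion border by a similarity transform about its area
#' centroid (default factor 1.25, i.e. "+25%") and takes the pixels that
#' are inside the enlarged border but outside the original one. This band
#' serves as the normal-skin reference region. If the enlarged border
#' extends past the image frame the band is clipped to the frame and a
#' warning is recorded.
#'
#' @param boundary A [ClosedBoundary][ClosedBoundary-class].
#' @param dim Image dimensions `c(H, W)` or an image array.
#' @param factor Enlargement factor, must be > 1 (default 1.25).
#' @return Logical H x W band mask, disjoint from the lesion mask.
#' @export
normalSkinBand <- function(boundary, dim, factor = 1.25) {
  if (!is.finite(factor) || factor <= 1)
    stop("band factor must be > 1 (factor = 1 gives an empty band)")
  d <- .imageDim(dim)
  scaled <- scaleBoundary(boundary, factor)
  sv <- scaled@vertices
  if (min(sv[, 1]) < 0 || min(sv[, 2]) < 0 ||
      max(sv[, 1]) > d[2] - 1 || max(sv[, 2]) > d[1] - 1)
    warning(warningCondition(
      "enlarged border exceeds the image frame; band clipped",
      class = c("lesioncolor_band_clipped", "warning", "condition")))
  boundaryMask(scaled, d) & !boundaryMask(boundary, d)
}

#' Automatic lesion segmentation
#'
#' Assumes the image contains one dominant lesion on surrounding skin.
#' The image is converted to CIELab; each pixel's Euclidean Lab distance
#' from the median color of the image-border pixels (taken as surrounding
#' skin) is thresholded by Otsu's method; the thresholded mask is closed
#' morphologically (disc brush), the largest connected component is kept,
#' and its outer contour is returned as a polygon. A component smaller
#' than `minArea` raises a segmentation-failure condition inviting manual
#' delineation with [closeBoundary()].
#'
#' @param image H x W x 3 RGB array on the 0-255 scale.
#' @param closingRadius Disc radius (px) of the morphological closing
#'   (default 5).
#' @param minArea Minimum component area in pixels (default 100).
#' @param maxVertices Contour subsampling cap (default 400).
#' @return A [ClosedBoundary][ClosedBoundary-class] tracing the lesion.
#' @export
#' @examples
#' syn <- generateLesionImage(syntheticLesionSpec(seed = 7))
#' b <- autoSegment(syn$image)
#' b
autoSegment <- function(image, closingRadius = 5L, minArea = 100L,
                        maxVertices = 400L) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("image must be an H x W x 3 array")
  H <- dim(image)[1]; W <- dim(image)[2]
  px <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
              as.vector(image[, , 3]))
  lab <- rgbToLab(px)
  border <- c(which(row(matrix(0, H, W)) %in% c(1L, H)),
              which(col(matrix(0, H, W)) %in% c(1L, W)))
  ref <- apply(lab[unique(border), , drop = FALSE], 2, stats::median)
  d <- sqrt((lab[, 1] - ref[1])^2 + (lab[, 2] - ref[2])^2 +
              (lab[, 3] - ref[3])^2)
  dmat <- matrix(d, H, W)
  rng <- max(d)
  fail <- function(msg)
    stop(errorCondition(paste0(msg, "; consider manual delineation via ",
                               "closeBoundary()"),
                        class = c("lesioncolor_segmentation_failure", "error",
                                  "condition")))
  if (rng < 1e-9) fail("image is uniform, no lesion found")
  thr <- EBImage::otsu(EBImage::Image(t(dmat / rng)), range = c(0, 1))
  mask <- dmat / rng > thr
  brush <- EBImage::makeBrush(2L * as.integer(closingRadius) + 1L, "disc")
  closed <- EBImage::closing(EBImage::Image(t(mask)), brush)
  labels <- EBImage::bwlabel(closed)
  tab <- tabulate(as.integer(labels))
  if (!length(tab) || max(tab) < minArea)
    fail(sprintf("no connected component of at least %d px", minArea))
  biggest <- which.max(tab)
  comp <- labels == biggest
  contour <- EBImage::ocontour(comp)[[1]]  # 0-based (x, y)
  if (nrow(contour) > maxVertices) {
    idx <- unique(round(seq(1L, nrow(contour), length.out = maxVertices)))
    contour <- contour[idx, , drop = FALSE]
  }
  closedBoundary(contour)
}
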