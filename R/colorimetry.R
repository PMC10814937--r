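# sRGB <-> CIELab conversion (IEC 61966-2-1 transfer, D65 2-degree observer),
# the Individual Typology Angle, and per-channel region histograms.

# sRGB (linear) -> XYZ, D65 reference white
.M_RGB2XYZ <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                       0.2126729, 0.7151522, 0.0721750,
                       0.0193339, 0.1191920, 0.9503041),
                     nrow = 3, byrow = TRUE)
.M_XYZ2RGB <- solve(.M_RGB2XYZ)
.WHITE_D65 <- c(X = 0.95047, Y = 1.00000, Z = 1.08883)

.srgbToLinear <- function(u) ifelse(u <= 0.04045, u / 12.92,
                                    ((u + 0.055) / 1.055)^2.4)
.linearToSrgb <- function(u) ifelse(u <= 0.0031308, 12.92 * u,
                                    1.055 * u^(1 / 2.4) - 0.055)

# CIE f() and inverse, with the linear segment below (6/29)^3
.labF <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}
.labFinv <- function(f) {
  d <- 6 / 29
  ifelse(f > d, f^3, 3 * d^2 * (f - 4 / 29))
}

.asColorMatrix <- function(x, what, lo, hi) {
  if (is.null(dim(x))) {
    if (length(x) %% 3L != 0L)
      stop(sprintf("%s input must have 3 components per color", what))
    x <- matrix(x, ncol = 3, byrow = length(x) > 3)
  }
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop(sprintf("%s input must have 3 columns", what))
  if (anyNA(x) || !all(is.finite(x)))
    stop(sprintf("%s input must be finite", what))
  if (!missing(lo) && (any(x < lo) || any(x > hi)))
    stop(sprintf("%s components must lie in [%g, %g]", what, lo, hi))
  x
}

#' Convert sRGB colors to CIELab
#'
#' Standard colorimetric conversion: 8-bit sRGB values are linearized with
#' the IEC 61966-2-1 transfer function, mapped to CIE XYZ (D65 white,
#' 2-degree observer) and then to CIELab. The inverse is [labToRgb()];
#' the round trip is accurate to well under 0.5 intensity units per
#' channel for in-gamut colors.
#'
#' @param rgb Numeric of length 3 (`red`, `green`, `blue` in \[0, 255\]) or
#'   an n x 3 matrix of such rows.
#' @return Named numeric `(L, a, b)`, or an n x 3 matrix with those
#'   columns when `rgb` is a matrix.
#' @export
#' @examples
#' rgbToLab(c(255, 255, 255))  # D65 white: L = 100, neutral axis
#' rgbToLab(c(188, 60, 86))
rgbToLab <- function(rgb) {
  m <- .asColorMatrix(rgb, "RGB", 0, 255)
  lin <- .srgbToLinear(m / 255)
  xyz <- lin %*% t(.M_RGB2XYZ)
  fx <- .labF(sweep(xyz, 2, .WHITE_D65, "/"))
  # the published matrix/white constants leave Y/Yn off 1 by ~4e-8 at
  # white; clamp so L stays within [0, 100] exactly
  lab <- cbind(L = pmin(pmax(116 * fx[, 2] - 16, 0), 100),
               a = 500 * (fx[, 1] - fx[, 2]),
               b = 200 * (fx[, 2] - fx[, 3]))
  if (is.null(dim(rgb)) && length(rgb) == 3L) lab[1, ] else lab
}

#' Convert CIELab colors to sRGB
#'
#' Inverse of [rgbToLab()]. Out-of-gamut results are clipped to
#' \[0, 255\].
#'
#' @param lab Numeric of length 3 (`L` in \[0, 100\], `a`, `b`) or an
#'   n x 3 matrix of such rows.
#' @return Named numeric `(red, green, blue)` in \[0, 255\], or an n x 3
#'   matrix when `lab` is a matrix.
#' @export
labToRgb <- function(lab) {
  m <- .asColorMatrix(lab, "Lab")
  if (any(m[, 1] < -1e-9) || any(m[, 1] > 100 + 1e-9))
    stop("L must lie in [0, 100]")
  fy <- (m[, 1] + 16) / 116
  fx <- fy + m[, 2] / 500
  fz <- fy - m[, 3] / 200
  xyz <- sweep(.labFinv(cbind(fx, fy, fz)), 2, .WHITE_D65, "*")
  lin <- xyz %*% t(.M_XYZ2RGB)
  out <- 255 * .linearToSrgb(pmin(pmax(lin, 0), 1))
  out <- pmin(pmax(out, 0), 255)
  colnames(out) <- c("red", "green", "blue")
  if (is.null(dim(lab)) && length(lab) == 3L) out[1, ] else out
}

#' Individual Typology Angle from CIELab coordinates
#'
#' `ITA = arctan((L - 50) / b) * 180 / pi`, in degrees. Higher values
#' correspond to lighter color; the angle is used here as an index of the
#' color shift a lesion induces relative to surrounding skin. For
#' `b = 0` the formula is undefined and the limiting convention is used:
#' +90 when `L > 50`, -90 when `L < 50`, and 0 at `L = 50`.
#'
#' @param L Lightness in \[0, 100\] (vectorized).
#' @param b CIELab blue-yellow coordinate (vectorized; positive = yellow,
#'   the CIE convention).
#' @return ITA in degrees, in \[-90, 90\].
#' @export
#' @examples
#' itaFromLab(65.79, 25.28)  # 31.99
#' itaFromLab(50, 10)        # 0
itaFromLab <- function(L, b) {
  if (anyNA(L) || anyNA(b) || !all(is.finite(L)) || !all(is.finite(b)))
    stop("L and b must be finite")
  if (any(L < -1e-9) || any(L > 100 + 1e-9))
    stop("L must lie in [0, 100]")
  as.vector(ifelse(b == 0,
                   ifelse(L > 50, 90, ifelse(L < 50, -90, 0)),
                   atan((L - 50) / b) * 180 / pi))
}

#' Construct a ColorSummary
#'
#' @param rgb Mean RGB triple in \[0, 255\].
#' @param lab Mean CIELab triple; defaults to `rgbToLab(rgb)`.
#' @param ita ITA in degrees; defaults to `itaFromLab(lab[1], lab[3])`.
#' @return A [ColorSummary][ColorSummary-class].
#' @export
#' @examples
#' colorSummary(c(188, 60, 86))
colorSummary <- function(rgb, lab = rgbToLab(rgb),
                         ita = itaFromLab(lab[[1]], lab[[3]])) {
  rgb <- as.numeric(rgb); lab <- as.numeric(lab)
  names(rgb) <- c("red", "green", "blue")
  names(lab) <- c("L", "a", "b")
  new("ColorSummary", rgb = rgb, lab = lab, ita = as.numeric(ita))
}

#' Per-channel intensity histograms of a masked region
#'
#' Tallies the red, green and blue 8-bit intensities of the pixels
#' selected by `mask` into 256 bins each. Non-integer intensities are
#' rounded to the nearest integer before binning.
#'
#' @param image RGB raster: an H x W x 3 numeric array on the 0-255 scale
#'   (see [readLesionImage()]).
#' @param mask Logical H x W matrix selecting the region; must be
#'   nonempty.
#' @return Named list of three [ChannelHistogram][ChannelHistogram-class]
#'   objects (`red`, `green`, `blue`). For each, `sum(counts)` equals the
#'   number of pixels in the mask.
#' @export
#' @examples
#' img <- array(rep(c(10, 20, 30), each = 12), dim = c(3, 4, 3))
#' h <- regionHistograms(img, matrix(TRUE, 3, 4))
#' which(h$green@counts > 0) - 1  # all 12 pixels at intensity 20
regionHistograms <- function(image, mask) {
  .checkImageMask(image, mask)
  if (!any(mask))
    stop(errorCondition("mask selects no pixels",
                        class = c("lesioncolor_empty_mask", "error", "condition")))
  out <- lapply(seq_len(3L), function(ch) {
    v <- round(image[, , ch][mask])
    v <- pmin(pmax(v, 0), 255)
    new("ChannelHistogram", channel = c("red", "green", "blue")[ch],
        counts = tabulate(as.integer(v) + 1L, nbins = 256L))
  })
  names(out) <- c("red", "green", "blue")
  out
}

.checkImageMask <- function(image, mask) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("image must be an H x W x 3 array")
  if (!is.matrix(mask) || !is.logical(mask))
    stop("mask must be a logical matrix")
  if (!all(dim(mask) == dim(image)[1:2]))
    stop("mask dimensions must match the image")
  invisible(TRUE)
}

#' Write channel histograms as CSV
#'
#' One file per channel or a single combined file, with columns
#' `bin` (0-255) and `count` (plus `channel` in combined mode).
#'
#' @param histograms Result of [regionHistograms()].
#' @param path Output CSV path.
#' @param combined If `TRUE` (default) write one file with a `channel`
#'   column; otherwise write `<stem>_<channel>.csv` files next to `path`.
#' @return Invisibly, the paths written.
#' @export
writeHistogramCSV <- function(histograms, path, combined = TRUE) {
  stopifnot(all(c("red", "green", "blue") %in% names(histograms)))
  if (combined) {
    df <- do.call(rbind, lapply(names(histograms), function(nm)
      data.frame(channel = nm, bin = 0:255,
                 count = histograms[[nm]]@counts)))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  stem <- sub("\\.csv$", "", path)
  paths <- vapply(names(histograms), function(nm) {
    p <- sprintf("%s_%s.csv", stem, nm)
    utils::write.csv(data.frame(bin = 0:255,
                                count = histograms[[nm]]@counts),
                     p, row.names = FALSE, quote = FALSE)
    p
  }, character(1))
  invisible(paths)
}
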