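# Per-region color summaries and per-patient feature assembly: 7 lesion
# parameters, 7 normal-skin parameters, 7 lesion-minus-normal differences.

#' Summarize the color of a masked image region
#'
#' Computes the region's seven color parameters. RGB means are per-channel
#' pixel means. By default the Lab means are obtained by converting every
#' pixel to CIELab and averaging (`labMode = "perpixel"`, the perceptually
#' standard choice); `labMode = "meanrgb"` instead converts the mean RGB
#' triple. The region ITA is, by default, the ITA of the mean L and mean b
#' (`itaMode = "meanlab"`); `itaMode = "perpixel"` averages per-pixel ITA
#' values instead.
#'
#' Optionally, specular-highlight pixels (top luminance quantile) can be
#' excluded before averaging; this is off by default since flash
#' reflections were found not to alter regional means materially.
#'
#' @param image H x W x 3 RGB array on the 0-255 scale.
#' @param mask Logical H x W region mask, nonempty.
#' @param labMode `"perpixel"` (default) or `"meanrgb"`.
#' @param itaMode `"meanlab"` (default) or `"perpixel"`.
#' @param excludeHighlights If `TRUE`, drop pixels whose Lab lightness
#'   exceeds the `highlightQuantile` quantile of the region.
#' @param highlightQuantile Luminance quantile for highlight exclusion
#'   (default 0.99).
#' @return A [ColorSummary][ColorSummary-class].
#' @export
#' @examples
#' img <- array(rep(c(188, 60, 86), each = 25), dim = c(5, 5, 3))
#' summarizeRegion(img, matrix(TRUE, 5, 5))
summarizeRegion <- function(image, mask,
                            labMode = c("perpixel", "meanrgb"),
                            itaMode = c("meanlab", "perpixel"),
                            excludeHighlights = FALSE,
                            highlightQuantile = 0.99) {
  labMode <- match.arg(labMode)
  itaMode <- match.arg(itaMode)
  .checkImageMask(image, mask)
  if (!any(mask))
    stop(errorCondition("mask selects no pixels",
                        class = c("lesioncolor_empty_mask", "error",
                                  "condition")))
  px <- cbind(image[, , 1][mask], image[, , 2][mask], image[, , 3][mask])
  lab <- rgbToLab(px)
  if (excludeHighlights && nrow(px) > 1L) {
    cut <- stats::quantile(lab[, 1], highlightQuantile, names = FALSE)
    keep <- lab[, 1] <= cut
    if (any(keep)) {
      px <- px[keep, , drop = FALSE]
      lab <- lab[keep, , drop = FALSE]
    }
  }
  rgbMean <- colMeans(px)
  labMean <- if (labMode == "perpixel") colMeans(lab) else
    rgbToLab(rgbMean)
  itaVal <- if (itaMode == "meanlab") itaFromLab(labMean[1], labMean[3]) else
    mean(itaFromLab(lab[, 1], lab[, 3]))
  colorSummary(rgbMean, labMean, itaVal)
}

#' Extract a full patient record from an image and lesion boundary
#'
#' Assembles the 21 per-patient variables: the seven color parameters of
#' the lesion interior, the same seven for the surrounding normal-skin
#' band ([normalSkinBand()], default +25%), and their lesion-minus-normal
#' differences (the ITA difference is the difference of the two ITAs, not
#' the ITA of differences). When a scale calibration is supplied the
#' lesion's physical geometry is attached.
#'
#' @param image H x W x 3 RGB array on the 0-255 scale.
#' @param boundary Lesion [ClosedBoundary][ClosedBoundary-class].
#' @param diagnosis One of [diagnosisLevels()].
#' @param patientId Identifier string.
#' @param scale Optional [ScaleCalibration][ScaleCalibration-class].
#' @param bandFactor Normal-skin band enlargement factor (default 1.25).
#' @param ... Passed to [summarizeRegion()] (`labMode`, `itaMode`,
#'   highlight options).
#' @return A [PatientRecord][PatientRecord-class].
#' @export
extractPatient <- function(image, boundary, diagnosis, patientId = "P1",
                           scale = NULL, bandFactor = 1.25, ...) {
  lesionMask <- boundaryMask(boundary, image)
  band <- normalSkinBand(boundary, image, bandFactor)
  lesion <- summarizeRegion(image, lesionMask, ...)
  normal <- summarizeRegion(image, band, ...)
  delta <- parameterVector(lesion) - parameterVector(normal)
  geom <- if (!is.null(scale)) geometryFeatures(boundary, scale) else NULL
  new("PatientRecord", patientId = as.character(patientId),
      diagnosis = diagnosis, lesion = lesion, normal = normal,
      delta = delta, geometry = geom)
}

#' Assemble a LesionCohort
#'
#' Either from a `data.frame` with the fixture layout (`patient_id`,
#' `diagnosis`, and the seven parameters) or from a list of
#' [PatientRecord][PatientRecord-class] objects, in which case
#' `normal_`/`delta_` columns are populated where available.
#'
#' @param x A `data.frame` or a list of `PatientRecord`s.
#' @return A [LesionCohort][LesionCohort-class].
#' @export
lesionCohort <- function(x) {
  if (is.data.frame(x)) {
    x$patient_id <- as.character(x$patient_id)
    x$diagnosis <- as.character(x$diagnosis)
    return(new("LesionCohort", records = x))
  }
  stopifnot(is.list(x), length(x) > 0L,
            all(vapply(x, is, logical(1), "PatientRecord")))
  rows <- lapply(x, function(r) {
    out <- data.frame(patient_id = r@patientId, diagnosis = r@diagnosis)
    out <- cbind(out, as.data.frame(as.list(parameterVector(r@lesion))))
    if (!is.null(r@normal)) {
      nv <- parameterVector(r@normal)
      names(nv) <- paste0("normal_", names(nv))
      out <- cbind(out, as.data.frame(as.list(nv)))
    }
    if (!is.null(r@delta)) {
      dv <- r@delta
      names(dv) <- paste0("delta_", colorParameters())
      out <- cbind(out, as.data.frame(as.list(dv)))
    }
    if (!is.null(r@geometry))
      out <- cbind(out, data.frame(
        max_diameter_cm = r@geometry@maxDiameterCm,
        surface_cm2 = r@geometry@surfaceCm2,
        perimeter_cm = r@geometry@perimeterCm))
    out
  })
  common <- Reduce(intersect, lapply(rows, names))
  new("LesionCohort",
      records = do.call(rbind, lapply(rows, function(r) r[common])))
}

#' Write a cohort feature table as CSV
#'
#' Numeric columns are rendered with exactly two decimals, mirroring the
#' printed cohort table layout.
#'
#' @param cohort A [LesionCohort][LesionCohort-class].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
writeFeatureTable <- function(cohort, path) {
  df <- cohort@records
  out <- df
  for (nm in names(out))
    if (is.numeric(out[[nm]])) out[[nm]] <- sprintf("%.2f", out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
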