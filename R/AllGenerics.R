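# Generics, accessors and show methods.

#' @name accessors
#' @title Accessors for LesionColor classes
#' @description Small accessor generics: `rgbMeans()`, `labMeans()` and
#'   `ita()` read the three components of a [ColorSummary][ColorSummary-class];
#'   `vertices()` returns the vertex matrix of a
#'   [ClosedBoundary][ClosedBoundary-class]; `cmPerPixel()` the scale of a
#'   [ScaleCalibration][ScaleCalibration-class]; `records()` the underlying
#'   `data.frame` of a [LesionCohort][LesionCohort-class]; `nPatients()` its
#'   row count; `diagnoses()` its diagnosis column.
#' @param object An object of the appropriate class.
#' @return The slot value (see Description).
NULL

#' @rdname accessors
#' @export
setGeneric("rgbMeans", function(object) standardGeneric("rgbMeans"))
#' @rdname accessors
#' @export
setGeneric("labMeans", function(object) standardGeneric("labMeans"))
#' @rdname accessors
#' @export
setGeneric("ita", function(object) standardGeneric("ita"))
#' @rdname accessors
#' @export
setGeneric("vertices", function(object) standardGeneric("vertices"))
#' @rdname accessors
#' @export
setGeneric("cmPerPixel", function(object) standardGeneric("cmPerPixel"))
#' @rdname accessors
#' @export
setGeneric("records", function(object) standardGeneric("records"))
#' @rdname accessors
#' @export
setGeneric("nPatients", function(object) standardGeneric("nPatients"))
#' @rdname accessors
#' @export
setGeneric("diagnoses", function(object) standardGeneric("diagnoses"))

#' @rdname accessors
setMethod("rgbMeans", "ColorSummary", function(object) object@rgb)
#' @rdname accessors
setMethod("labMeans", "ColorSummary", function(object) object@lab)
#' @rdname accessors
setMethod("ita", "ColorSummary", function(object) object@ita)
#' @rdname accessors
setMethod("vertices", "ClosedBoundary", function(object) object@vertices)
#' @rdname accessors
setMethod("cmPerPixel", "ScaleCalibration", function(object) object@cmPerPixel)
#' @rdname accessors
setMethod("records", "LesionCohort", function(object) object@records)
#' @rdname accessors
setMethod("nPatients", "LesionCohort", function(object) nrow(object@records))
#' @rdname accessors
setMethod("diagnoses", "LesionCohort", function(object) object@records$diagnosis)

#' Seven-parameter vector of a ColorSummary
#'
#' @param object A [ColorSummary][ColorSummary-class].
#' @return Named numeric of length 7 (`red, green, blue, L, a, b, ITA`).
#' @export
setGeneric("parameterVector",
           function(object) standardGeneric("parameterVector"))

#' @rdname parameterVector
setMethod("parameterVector", "ColorSummary", function(object) {
  out <- c(object@rgb, object@lab, object@ita)
  names(out) <- colorParameters()
  out
})

setMethod("show", "ColorSummary", function(object) {
  cat("ColorSummary\n")
  cat(sprintf("  RGB: (%.2f, %.2f, %.2f)\n",
              object@rgb[1], object@rgb[2], object@rgb[3]))
  cat(sprintf("  Lab: (%.2f, %.2f, %.2f)\n",
              object@lab[1], object@lab[2], object@lab[3]))
  cat(sprintf("  ITA: %.2f deg\n", object@ita))
})

setMethod("show", "ClosedBoundary", function(object) {
  v <- object@vertices
  cat(sprintf("ClosedBoundary with %d vertices\n", nrow(v)))
  cat(sprintf("  area: %.1f px^2, perimeter: %.1f px\n",
              .polygonArea(v), .polygonPerimeter(v)))
})

setMethod("show", "ScaleCalibration", function(object) {
  cat(sprintf("ScaleCalibration: %.6g cm/pixel\n", object@cmPerPixel))
})

setMethod("show", "GeometryFeatures", function(object) {
  cat("GeometryFeatures\n")
  cat(sprintf("  Maximal diameter: %.2f cm\n", object@maxDiameterCm))
  cat(sprintf("  Surface: %.2f cm^2\n", object@surfaceCm2))
  cat(sprintf("  Perimeter: %.2f cm\n", object@perimeterCm))
})

setMethod("show", "PatientRecord", function(object) {
  cat(sprintf("PatientRecord %s (%s)\n", object@patientId, object@diagnosis))
  p <- parameterVector(object@lesion)
  cat("  lesion: ", paste(sprintf("%s=%.2f", names(p), p), collapse = " "),
      "\n", sep = "")
  if (!is.null(object@normal)) {
    q <- parameterVector(object@normal)
    cat("  normal: ", paste(sprintf("%s=%.2f", names(q), q), collapse = " "),
        "\n", sep = "")
  }
  if (!is.null(object@delta))
    cat("  delta:  ", paste(sprintf("%s=%+.2f", names(object@delta),
                                    object@delta), collapse = " "),
        "\n", sep = "")
  if (!is.null(object@geometry))
    cat(sprintf("  geometry: d=%.2f cm, A=%.2f cm^2, P=%.2f cm\n",
                object@geometry@maxDiameterCm, object@geometry@surfaceCm2,
                object@geometry@perimeterCm))
})

setMethod("show", "LesionCohort", function(object) {
  df <- object@records
  cat(sprintf("LesionCohort with %d patients\n", nrow(df)))
  tab <- table(factor(df$diagnosis, levels = diagnosisLevels()))
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
      "\n", sep = "")
  extra <- setdiff(names(df), c("patient_id", "diagnosis", colorParameters()))
  if (length(extra))
    cat("  extra columns: ", paste(extra, collapse = ", "), "\n", sep = "")
})

setMethod("show", "MWUResult", function(object) {
  cat(sprintf("Mann-Whitney U test%s (n1 = %d, n2 = %d)\n",
              if (is.na(object@parameter)) "" else
                sprintf(" [%s]", object@parameter),
              object@n1, object@n2))
  cat(sprintf("  U = %g, W = %g, Z = %s\n", object@U, object@W,
              if (is.na(object@Z)) "NA" else sprintf("%.3f", object@Z)))
  cat(sprintf("  Asymp. Sig. (2-tailed): %s\n",
              if (is.na(object@pAsymp)) "NA" else sprintf("%.3f", object@pAsymp)))
  cat(sprintf("  Exact Sig. (2*(1-tailed Sig.)): %.3f\n", object@pExact))
})

setMethod("show", "ConfusionReport", function(object) {
  r <- object@rule
  cat(sprintf("ConfusionReport: %s %s %.4g -> %s (negative: %s)\n",
              r@parameter,
              if (r@direction == "above_is_positive") ">=" else "<=",
              r@threshold, r@positiveClass, object@negativeClass))
  cat(sprintf("  counts: TP=%d FP=%d TN=%d FN=%d\n",
              object@tp, object@fp, object@tn, object@fn))
  m <- confusionMetrics(object)
  lab <- c(sensitivity = "sensitivity", specificity = "specificity",
           accuracy = "accuracy", ppv = "PPV", npv = "NPV")
  for (nm in names(lab))
    cat(sprintf("  %-12s %s\n", paste0(lab[[nm]], ":"),
                if (is.na(m[[nm]])) "undefined" else sprintf("%.2f%%", m[[nm]])))
})

setMethod("show", "SyntheticLesionSpec", function(object) {
  cat(sprintf("SyntheticLesionSpec %dx%d px, seed %d\n",
              object@width, object@height, object@seed))
  cat(sprintf("  lesion RGB (%g, %g, %g) sd %s; skin RGB (%g, %g, %g) sd %s\n",
              object@lesion[1], object@lesion[2], object@lesion[3],
              paste(object@lesionSd, collapse = "/"),
              object@background[1], object@background[2], object@background[3],
              paste(object@backgroundSd, collapse = "/")))
  cat(sprintf("  ellipse center (%g, %g), semi-axes (%g, %g), rotation %g deg\n",
              object@center[1], object@center[2],
              object@axes[1], object@axes[2], object@rotation))
  if (!is.null(object@highlight)) cat("  with specular highlight\n")
  if (!is.null(object@ruler)) cat("  with ruler marks\n")
})

setMethod("show", "SyntheticCohortSpec", function(object) {
  cat(sprintf("SyntheticCohortSpec, seed %d\n", object@seed))
  for (nm in names(object@groups))
    cat(sprintf("  %s: n = %d\n", nm, object@groups[[nm]]$n))
})
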