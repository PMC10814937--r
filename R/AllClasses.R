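# Central S4 classes. Coordinates are 0-based pixel centers, x right, y down.

#' Diagnosis vocabulary
#'
#' The closed set of diagnosis labels used throughout the package:
#' Merkel cell carcinoma (`MCC`), cherry angioma (`CHERRY`), basal/squamous
#' cell carcinoma (`BCC/SCC`) and hemangioma (`HEMANGIOMA`).
#'
#' @return Character vector of the four diagnosis labels.
#' @export
#' @examples
#' diagnosisLevels()
diagnosisLevels <- function() c("MCC", "CHERRY", "BCC/SCC", "HEMANGIOMA")

#' Color parameter names
#'
#' The seven per-region color parameters: mean red, green, blue channel
#' intensities, mean CIELab `L`, `a`, `b`, and the Individual Typology
#' Angle `ITA` in degrees.
#'
#' @return Character vector of the seven parameter names.
#' @export
colorParameters <- function() c("red", "green", "blue", "L", "a", "b", "ITA")

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' ColorSummary: mean color of one image region
#'
#' Holds the seven color parameters of a region: mean RGB channel
#' intensities (0-255 scale), mean CIELab coordinates, and the Individual
#' Typology Angle (degrees).
#'
#' @slot rgb Named numeric of length 3 (`red`, `green`, `blue`), each in
#'   \[0, 255\].
#' @slot lab Named numeric of length 3 (`L`, `a`, `b`); `L` in \[0, 100\].
#' @slot ita Numeric scalar, degrees in \[-90, 90\].
#' @export
setClass("ColorSummary",
         representation(rgb = "numeric", lab = "numeric", ita = "numeric"))

setValidity("ColorSummary", function(object) {
  msg <- character()
  if (length(object@rgb) != 3L || anyNA(object@rgb) || !all(is.finite(object@rgb)))
    msg <- c(msg, "rgb must be 3 finite values")
  else if (any(object@rgb < -1e-9) || any(object@rgb > 255 + 1e-9))
    msg <- c(msg, "rgb components must lie in [0, 255]")
  if (length(object@lab) != 3L || anyNA(object@lab) || !all(is.finite(object@lab)))
    msg <- c(msg, "lab must be 3 finite values")
  else if (object@lab[1] < -1e-6 || object@lab[1] > 100 + 1e-6)
    msg <- c(msg, "L must lie in [0, 100]")
  if (length(object@ita) != 1L || !is.finite(object@ita) ||
      object@ita < -90 - 1e-9 || object@ita > 90 + 1e-9)
    msg <- c(msg, "ita must be a finite angle in [-90, 90] degrees")
  if (length(msg)) msg else TRUE
})

#' ChannelHistogram: 256-bin intensity histogram of one RGB channel
#'
#' @slot channel One of `"red"`, `"green"`, `"blue"`.
#' @slot counts Integer vector of length 256 (bins 0-255), nonnegative;
#'   the counts sum to the number of pixels in the tallied region.
#' @export
setClass("ChannelHistogram",
         representation(channel = "character", counts = "integer"))

setValidity("ChannelHistogram", function(object) {
  msg <- character()
  if (!(length(object@channel) == 1L &&
        object@channel %in% c("red", "green", "blue")))
    msg <- c(msg, "channel must be one of red/green/blue")
  if (length(object@counts) != 256L || anyNA(object@counts) ||
      any(object@counts < 0L))
    msg <- c(msg, "counts must be 256 nonnegative integers")
  if (length(msg)) msg else TRUE
})

#' ClosedBoundary: simple closed polygon delineating a lesion
#'
#' Vertices are in pixel coordinates (x right, y down, origin at the
#' top-left pixel center, 0-based). The polygon is implicitly closed: the
#' last vertex connects back to the first.
#'
#' @slot vertices Numeric matrix with columns `x`, `y`, at least 3 rows;
#'   the polygon must be simple (non-self-intersecting) and enclose
#'   positive area.
#' @export
setClass("ClosedBoundary", representation(vertices = "matrix"))

setValidity("ClosedBoundary", function(object) {
  v <- object@vertices
  if (!is.numeric(v) || ncol(v) != 2L)
    return("vertices must be a numeric matrix with columns x, y")
  if (nrow(v) < 3L) return("a closed boundary needs at least 3 vertices")
  if (anyNA(v) || !all(is.finite(v))) return("vertices must be finite")
  if (.polygonArea(v) <= 0) return("enclosed area must be positive")
  # O(n^2) pairwise segment test; skipped for very dense contours where the
  # generating algorithms guarantee a simple chain.
  if (nrow(v) <= 800L && !.isSimplePolygon(v))
    return("polygon must be simple (non-self-intersecting)")
  TRUE
})

#' ScaleCalibration: physical scale of an image
#'
#' @slot cmPerPixel Positive finite scalar, centimeters per pixel.
#' @export
setClass("ScaleCalibration", representation(cmPerPixel = "numeric"))

setValidity("ScaleCalibration", function(object) {
  s <- object@cmPerPixel
  if (length(s) != 1L || !is.finite(s) || s <= 0)
    return("cmPerPixel must be a single positive finite number")
  TRUE
})

#' GeometryFeatures: physical geometry of a lesion boundary
#'
#' @slot maxDiameterCm Maximum pairwise vertex distance, cm.
#' @slot surfaceCm2 Enclosed (shoelace) area, cm^2.
#' @slot perimeterCm Edge-length sum, cm.
#' @export
setClass("GeometryFeatures",
         representation(maxDiameterCm = "numeric", surfaceCm2 = "numeric",
                        perimeterCm = "numeric"))

setValidity("GeometryFeatures", function(object) {
  d <- object@maxDiameterCm; a <- object@surfaceCm2; p <- object@perimeterCm
  if (any(!is.finite(c(d, a, p))) || any(c(d, a, p) <= 0))
    return("all geometry features must be positive and finite")
  if (d > p / 2 * (1 + 1e-9))
    return("max diameter cannot exceed half the perimeter")
  if (4 * pi * a > p^2 * (1 + 1e-9))
    return("isoperimetric inequality violated (4*pi*A <= P^2)")
  TRUE
})

setClassUnion("ColorSummaryOrNULL", c("ColorSummary", "NULL"))
setClassUnion("GeometryFeaturesOrNULL", c("GeometryFeatures", "NULL"))

#' PatientRecord: the color variables of one patient
#'
#' Carries the lesion-region color summary, and — when a full image was
#' analyzed — the surrounding normal-skin summary, the lesion-minus-normal
#' differences, and the lesion geometry.
#'
#' @slot patientId Opaque identifier.
#' @slot diagnosis One of [diagnosisLevels()].
#' @slot lesion [ColorSummary][ColorSummary-class] of the lesion interior.
#' @slot normal Optional [ColorSummary][ColorSummary-class] of the
#'   surrounding normal-skin band.
#' @slot delta Optional named numeric of length 7 (lesion minus normal,
#'   componentwise; the ITA delta is the difference of the two ITAs).
#' @slot geometry Optional [GeometryFeatures][GeometryFeatures-class].
#' @export
setClass("PatientRecord",
         representation(patientId = "character", diagnosis = "character",
                        lesion = "ColorSummary",
                        normal = "ColorSummaryOrNULL",
                        delta = "numericOrNULL",
                        geometry = "GeometryFeaturesOrNULL"))

setValidity("PatientRecord", function(object) {
  msg <- character()
  if (!(length(object@diagnosis) == 1L &&
        object@diagnosis %in% diagnosisLevels()))
    msg <- c(msg, sprintf("diagnosis must be one of: %s",
                          paste(diagnosisLevels(), collapse = ", ")))
  if (!is.null(object@delta)) {
    if (length(object@delta) != 7L || anyNA(object@delta))
      msg <- c(msg, "delta must be 7 finite values")
    if (is.null(object@normal))
      msg <- c(msg, "delta requires a normal-skin summary")
  }
  if (length(msg)) msg else TRUE
})

#' LesionCohort: a table of per-patient color features
#'
#' A cohort of patients, one row each, with the seven lesion color
#' parameters and optionally `normal_`- and `delta_`-prefixed columns for
#' the surrounding skin and the lesion-minus-normal differences.
#'
#' @slot records A `data.frame` with columns `patient_id`, `diagnosis`
#'   (values from [diagnosisLevels()]), and the seven parameters
#'   `red, green, blue, L, a, b, ITA`.
#' @seealso [loadStudyFixture()], [generateCohort()], [groupMeans()],
#'   [comparisonTable()], [applyRule()]
#' @export
setClass("LesionCohort", representation(records = "data.frame"))

setValidity("LesionCohort", function(object) {
  df <- object@records
  need <- c("patient_id", "diagnosis", colorParameters())
  miss <- setdiff(need, names(df))
  if (length(miss))
    return(sprintf("missing columns: %s", paste(miss, collapse = ", ")))
  if (nrow(df) < 1L) return("cohort must contain at least one record")
  if (!all(df$diagnosis %in% diagnosisLevels()))
    return("diagnosis values outside the closed vocabulary")
  num <- as.matrix(df[colorParameters()])
  if (anyNA(num) || !all(is.finite(num)))
    return("color parameters must be finite")
  rgbm <- as.matrix(df[c("red", "green", "blue")])
  if (any(rgbm < -1e-9) || any(rgbm > 255 + 1e-9))
    return("RGB means must lie in [0, 255]")
  if (any(df$L < -1e-6) || any(df$L > 100 + 1e-6))
    return("L must lie in [0, 100]")
  TRUE
})

#' ThresholdRule: a single-parameter diagnostic rule
#'
#' @slot parameter One of [colorParameters()].
#' @slot threshold Decision threshold on that parameter.
#' @slot direction `"above_is_positive"` (value >= threshold calls the
#'   positive class) or `"below_is_positive"` (value <= threshold does).
#' @slot positiveClass Diagnosis treated as the positive (disease) class.
#' @export
setClass("ThresholdRule",
         representation(parameter = "character", threshold = "numeric",
                        direction = "character", positiveClass = "character"))

setValidity("ThresholdRule", function(object) {
  msg <- character()
  if (!(length(object@parameter) == 1L &&
        object@parameter %in% colorParameters()))
    msg <- c(msg, "parameter must be one of the 7 color parameters")
  if (length(object@threshold) != 1L || !is.finite(object@threshold))
    msg <- c(msg, "threshold must be a finite scalar")
  if (!(length(object@direction) == 1L &&
        object@direction %in% c("above_is_positive", "below_is_positive")))
    msg <- c(msg, "direction must be above_is_positive or below_is_positive")
  if (!(length(object@positiveClass) == 1L &&
        object@positiveClass %in% diagnosisLevels()))
    msg <- c(msg, "positiveClass must be a known diagnosis")
  if (length(msg)) msg else TRUE
})

#' ConfusionReport: confusion-matrix counts of a threshold rule
#'
#' Raw counts are stored; the derived percentages (sensitivity,
#' specificity, accuracy, PPV, NPV) are computed by [confusionMetrics()]
#' at full precision, with undefined ratios reported as `NA` rather than
#' silently zero.
#'
#' @slot rule The [ThresholdRule][ThresholdRule-class] that was applied.
#' @slot negativeClass Diagnosis treated as the negative class.
#' @slot tp,fp,tn,fn Nonnegative integer counts.
#' @export
setClass("ConfusionReport",
         representation(rule = "ThresholdRule", negativeClass = "character",
                        tp = "integer", fp = "integer",
                        tn = "integer", fn = "integer"))

setValidity("ConfusionReport", function(object) {
  cnt <- c(object@tp, object@fp, object@tn, object@fn)
  if (length(cnt) != 4L || anyNA(cnt) || any(cnt < 0L))
    return("tp, fp, tn, fn must be nonnegative integers")
  TRUE
})

#' MWUResult: one Mann-Whitney U comparison, SPSS conventions
#'
#' @slot parameter Name of the compared variable (may be `NA`).
#' @slot n1,n2 Group sizes.
#' @slot U Smaller of the two U statistics (half-integers under ties).
#' @slot W Smaller of the two rank sums.
#' @slot Z Tie-corrected normal approximation statistic, signed so that
#'   `Z = (U - n1*n2/2) / sigma` (always <= 0); `NA` when all pooled
#'   values are identical.
#' @slot pAsymp Two-tailed asymptotic significance (no continuity
#'   correction).
#' @slot pExact Exact significance reported as 2 x the one-tailed
#'   probability `P(U' <= U)` under the tie-free null distribution,
#'   capped at 1.
#' @export
setClass("MWUResult",
         representation(parameter = "character",
                        n1 = "integer", n2 = "integer",
                        U = "numeric", W = "numeric", Z = "numeric",
                        pAsymp = "numeric", pExact = "numeric"))

setValidity("MWUResult", function(object) {
  msg <- character()
  n1 <- object@n1; n2 <- object@n2
  if (n1 < 1L || n2 < 1L) msg <- c(msg, "both groups must be nonempty")
  if (!is.finite(object@U) || object@U < -1e-9 ||
      object@U > n1 * n2 / 2 + 1e-9)
    msg <- c(msg, "U must lie in [0, n1*n2/2]")
  for (p in c(object@pAsymp, object@pExact))
    if (!is.na(p) && (p < 0 || p > 1))
      msg <- c(msg, "p-values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' SyntheticLesionSpec: parameters of a synthetic lesion photograph
#'
#' Describes a noisy skin-colored field containing one elliptical lesion
#' of a different mean color, optionally with a central specular highlight
#' (emulating a camera flash on a vaulted lesion) and a pair of ruler tick
#' marks a known physical distance apart.
#'
#' @slot width,height Image size in pixels.
#' @slot background,lesion Mean RGB triples (0-255).
#' @slot backgroundSd,lesionSd Per-channel Gaussian noise sd (scalar or
#'   length 3), >= 0.
#' @slot center,axes Ellipse center (x, y) and semi-axes (a, b) in pixels.
#' @slot rotation Ellipse rotation, degrees counterclockwise in (x, y).
#' @slot highlight `NULL` or `list(center = c(x, y), radius, boost)`.
#' @slot ruler `NULL` or `list(p1 = c(x, y), p2 = c(x, y), cm)`.
#' @slot seed Integer RNG seed; generation is fully deterministic given it.
#' @export
setClass("SyntheticLesionSpec",
         representation(width = "integer", height = "integer",
                        background = "numeric", backgroundSd = "numeric",
                        lesion = "numeric", lesionSd = "numeric",
                        center = "numeric", axes = "numeric",
                        rotation = "numeric",
                        highlight = "ANY", ruler = "ANY", seed = "integer"))

setValidity("SyntheticLesionSpec", function(object) {
  msg <- character()
  if (object@width < 8L || object@height < 8L)
    msg <- c(msg, "image must be at least 8x8 pixels")
  for (nm in c("background", "lesion")) {
    v <- slot(object, nm)
    if (length(v) != 3L || any(!is.finite(v)) || any(v < 0) || any(v > 255))
      msg <- c(msg, sprintf("%s must be an RGB triple in [0, 255]", nm))
  }
  for (nm in c("backgroundSd", "lesionSd")) {
    v <- slot(object, nm)
    if (!length(v) %in% c(1L, 3L) || any(!is.finite(v)) || any(v < 0))
      msg <- c(msg, sprintf("%s must be nonnegative (length 1 or 3)", nm))
  }
  if (length(object@axes) != 2L || any(object@axes <= 0))
    msg <- c(msg, "ellipse semi-axes must be positive")
  if (length(object@center) != 2L || any(!is.finite(object@center)))
    msg <- c(msg, "ellipse center must be finite (x, y)")
  # lesion must be at least partially inside the frame
  if (!length(msg)) {
    th <- seq(0, 2 * pi, length.out = 181L)
    rot <- object@rotation * pi / 180
    ex <- object@center[1] + object@axes[1] * cos(th) * cos(rot) -
      object@axes[2] * sin(th) * sin(rot)
    ey <- object@center[2] + object@axes[1] * cos(th) * sin(rot) +
      object@axes[2] * sin(th) * cos(rot)
    inside <- ex >= 0 & ex <= object@width - 1 & ey >= 0 & ey <= object@height - 1
    cinside <- all(object@center >= 0) && object@center[1] <= object@width - 1 &&
      object@center[2] <= object@height - 1
    if (!any(inside) && !cinside)
      msg <- c(msg, "lesion lies entirely outside the image frame")
  }
  if (length(msg)) msg else TRUE
})

#' SyntheticCohortSpec: parameters of a synthetic feature cohort
#'
#' Per diagnosis group: a sample size, a 7-vector of parameter means
#' (red, green, blue, L, a, b, ITA) and a 7x7 covariance matrix. Records
#' are multivariate-normal draws; the ITA column is then recomputed from
#' the sampled L and b so every record satisfies the ITA identity.
#'
#' @slot groups Named list (names from [diagnosisLevels()]), each element
#'   `list(n, mean, cov)` with `n >= 1`, `mean` length 7 and `cov` a
#'   symmetric positive semi-definite 7x7 matrix.
#' @slot seed Integer RNG seed.
#' @export
setClass("SyntheticCohortSpec",
         representation(groups = "list", seed = "integer"))

setValidity("SyntheticCohortSpec", function(object) {
  g <- object@groups
  if (!length(g) || is.null(names(g)) || !all(names(g) %in% diagnosisLevels()))
    return("groups must be a named list keyed by diagnosis labels")
  for (nm in names(g)) {
    el <- g[[nm]]
    if (!all(c("n", "mean", "cov") %in% names(el)))
      return(sprintf("group %s needs n, mean and cov", nm))
    if (el$n < 1L) return("group sizes must be >= 1")
    if (length(el$mean) != 7L || anyNA(el$mean))
      return("group means must be 7 finite values")
    cv <- el$cov
    if (!is.matrix(cv) || !all(dim(cv) == c(7L, 7L)))
      return("cov must be a 7x7 matrix")
    if (max(abs(cv - t(cv))) > 1e-8 * (1 + max(abs(cv))))
      return("cov must be symmetric")
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(1, abs(ev[1])))
      return("cov must be positive semi-definite")
  }
  TRUE
})
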