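# Single-parameter threshold diagnosis between two lesion classes.

#' Construct a threshold diagnostic rule
#'
#' @param parameter One of [colorParameters()].
#' @param threshold Decision threshold.
#' @param direction `"above_is_positive"` (default; a value greater than
#'   or equal to the threshold calls the positive class) or
#'   `"below_is_positive"`. A value exactly at the threshold is always
#'   called positive.
#' @param positiveClass Diagnosis treated as positive (default `"MCC"`).
#' @return A [ThresholdRule][ThresholdRule-class].
#' @export
#' @examples
#' thresholdRule("a", 37)  # the a* >= 37 rule for MCC
thresholdRule <- function(parameter, threshold,
                          direction = c("above_is_positive",
                                        "below_is_positive"),
                          positiveClass = "MCC") {
  direction <- match.arg(direction)
  new("ThresholdRule", parameter = parameter,
      threshold = as.numeric(threshold), direction = direction,
      positiveClass = positiveClass)
}

#' Apply a threshold rule to a cohort
#'
#' Restricts the cohort to the rule's positive class and the given
#' negative class, classifies each record by comparing its value of the
#' rule's parameter with the threshold, and tallies the confusion matrix.
#'
#' @param cohort A [LesionCohort][LesionCohort-class].
#' @param rule A [ThresholdRule][ThresholdRule-class].
#' @param negativeClass Diagnosis treated as negative.
#' @return A [ConfusionReport][ConfusionReport-class].
#' @seealso [confusionMetrics()], [writeConfusionJSON()]
#' @export
#' @examples
#' applyRule(loadStudyFixture(), thresholdRule("a", 37), "HEMANGIOMA")
applyRule <- function(cohort, rule, negativeClass) {
  stopifnot(is(cohort, "LesionCohort"), is(rule, "ThresholdRule"))
  if (!negativeClass %in% diagnosisLevels())
    stop("negativeClass must be a known diagnosis")
  df <- cohort@records
  pos <- df[df$diagnosis == rule@positiveClass, , drop = FALSE]
  neg <- df[df$diagnosis == negativeClass, , drop = FALSE]
  if (!nrow(pos) || !nrow(neg))
    stop(errorCondition(
      sprintf("both classes must be present (%s: %d, %s: %d)",
              rule@positiveClass, nrow(pos), negativeClass, nrow(neg)),
      class = c("lesioncolor_empty_class", "error", "condition")))
  callPos <- function(v)
    if (rule@direction == "above_is_positive") v >= rule@threshold else
      v <= rule@threshold
  posCalls <- callPos(pos[[rule@parameter]])
  negCalls <- callPos(neg[[rule@parameter]])
  new("ConfusionReport", rule = rule, negativeClass = negativeClass,
      tp = sum(posCalls), fp = sum(negCalls),
      tn = sum(!negCalls), fn = sum(!posCalls))
}

#' Confusion-matrix metrics at full precision
#'
#' Sensitivity, specificity, accuracy, PPV and NPV as percentages. A
#' metric whose denominator is zero is `NA` (flagged via the `"undefined"`
#' attribute), never silently zero.
#'
#' @param report A [ConfusionReport][ConfusionReport-class].
#' @return Named numeric of length 5 with attribute `undefined` naming any
#'   metrics that could not be computed.
#' @export
confusionMetrics <- function(report) {
  stopifnot(is(report, "ConfusionReport"))
  tp <- report@tp; fp <- report@fp; tn <- report@tn; fn <- report@fn
  safe <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  out <- c(sensitivity = safe(tp, tp + fn),
           specificity = safe(tn, tn + fp),
           accuracy = safe(tp + tn, tp + fp + tn + fn),
           ppv = safe(tp, tp + fp),
           npv = safe(tn, tn + fn))
  attr(out, "undefined") <- names(out)[is.na(out)]
  out
}

#' Display strings for confusion metrics
#'
#' Full-precision values rendered for reporting: percentages to two
#' decimals, plus a one-decimal truncated form (clinical reports often
#' truncate, e.g. 8/12 shown as 66.6%).
#'
#' @param report A [ConfusionReport][ConfusionReport-class].
#' @return A `data.frame` with columns `metric`, `value`, `display`
#'   (two-decimal) and `truncated1` (one decimal, truncated toward zero).
#' @export
displayMetrics <- function(report) {
  m <- confusionMetrics(report)
  data.frame(metric = names(m), value = as.numeric(m),
             display = ifelse(is.na(m), "undefined",
                              sprintf("%.2f%%", m)),
             truncated1 = ifelse(is.na(m), "undefined",
                                 sprintf("%.1f%%", trunc(m * 10) / 10)))
}

#' Write a confusion report as JSON
#'
#' Serializes the rule, the raw counts, and the metrics (full precision
#' and display strings).
#'
#' @param report A [ConfusionReport][ConfusionReport-class].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
writeConfusionJSON <- function(report, path) {
  r <- report@rule
  m <- confusionMetrics(report)
  d <- displayMetrics(report)
  obj <- list(
    rule = list(parameter = r@parameter, threshold = r@threshold,
                direction = r@direction, positive_class = r@positiveClass,
                negative_class = report@negativeClass),
    counts = list(tp = report@tp, fp = report@fp,
                  tn = report@tn, fn = report@fn),
    metrics = as.list(m),
    display = stats::setNames(as.list(d$display), d$metric))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Scan all thresholds for the best separation of two classes
#'
#' Considers every midpoint between adjacent sorted distinct values of the
#' parameter (plus one threshold below the minimum and one above the
#' maximum), in both directions, and returns the rule maximizing
#' sensitivity + specificity (Youden-style). Ties are broken toward the
#' smallest threshold with `"above_is_positive"` preferred, so the result
#' is deterministic.
#'
#' @param cohort A [LesionCohort][LesionCohort-class].
#' @param parameter One of [colorParameters()].
#' @param classA Positive class.
#' @param classB Negative class.
#' @return A list: `rule` (the best [ThresholdRule][ThresholdRule-class]),
#'   `report` (its [ConfusionReport][ConfusionReport-class]), `youden`
#'   (sensitivity + specificity, percent), and `perfect` (`TRUE` when a
#'   threshold separates the classes completely).
#' @export
#' @examples
#' separationScan(loadStudyFixture(), "a", "MCC", "BCC/SCC")$perfect
separationScan <- function(cohort, parameter, classA, classB) {
  stopifnot(is(cohort, "LesionCohort"),
            parameter %in% colorParameters())
  df <- cohort@records
  vals <- sort(unique(df[[parameter]][df$diagnosis %in% c(classA, classB)]))
  if (!length(vals))
    stop(errorCondition("no records in either class",
                        class = c("lesioncolor_empty_class", "error",
                                  "condition")))
  gap <- if (length(vals) > 1) min(diff(vals)) else 1
  cand <- c(vals[1] - gap / 2,
            if (length(vals) > 1) (vals[-length(vals)] + vals[-1]) / 2,
            vals[length(vals)] + gap / 2)
  best <- NULL
  for (dir in c("above_is_positive", "below_is_positive")) {
    for (th in cand) {
      rule <- thresholdRule(parameter, th, dir, positiveClass = classA)
      rep <- applyRule(cohort, rule, classB)
      m <- confusionMetrics(rep)
      score <- m[["sensitivity"]] + m[["specificity"]]
      if (is.null(best) || score > best$youden + 1e-12)
        best <- list(rule = rule, report = rep, youden = score)
    }
  }
  best$perfect <- isTRUE(all.equal(best$youden, 200))
  best
}
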