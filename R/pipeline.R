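# End-to-end pipeline runner behind the command-line interface.
# Configuration is a plain named list (or a YAML file of one); CLI flags
# override file values. Every run is deterministic given its seed.

.pipelineError <- function(msg, class = "lesioncolor_input_error")
  stop(errorCondition(msg, class = c(class, "error", "condition")))

.defaultConfig <- function() list(
  mode = NULL, input = NULL, out = NULL, boundary = NULL,
  band_factor = 1.25, seed = 1L,
  lab_mode = "perpixel", ita_mode = "meanlab",
  closing_radius = 5L, min_area = 100L,
  cm_per_pixel = NULL, ruler = NULL,
  comparisons = list(c("MCC", "CHERRY"), c("MCC", "BCC/SCC"),
                     c("MCC", "HEMANGIOMA")),
  rule = list(parameter = "a", threshold = 37,
              direction = "above_is_positive",
              positive_class = "MCC", negative_class = "HEMANGIOMA"),
  simulate = list())

#' Run the analysis pipeline
#'
#' One entry point for the five pipeline modes:
#' \describe{
#'   \item{`analyze-image`}{segment (or read) a lesion boundary in a
#'     photograph, extract the 21 color variables and geometry, and write
#'     the feature table, per-channel histograms, boundary and masks.}
#'   \item{`compare-groups`}{group means plus Mann-Whitney comparison
#'     tables (CSV and Markdown) for a feature table (default: the
#'     packaged study cohort).}
#'   \item{`classify`}{apply a threshold rule and write a JSON confusion
#'     report.}
#'   \item{`simulate`}{write a synthetic image bundle (image, ground-truth
#'     mask and boundary) and a synthetic cohort CSV.}
#'   \item{`fixtures`}{export the packaged cohort table.}
#' }
#'
#' @param config Named list, or path to a YAML file of one. Recognized
#'   keys: `mode` (required), `out` (output directory, required),
#'   `input`, `boundary` (CSV of operator-placed points), `band_factor`,
#'   `seed`, `lab_mode`, `ita_mode`, `closing_radius`, `min_area`,
#'   `cm_per_pixel` or `ruler` (`list(p1, p2, cm)`), `comparisons`
#'   (list of label pairs), `rule` (threshold-rule fields), `simulate`
#'   (overrides for [syntheticLesionSpec()]).
#' @param overrides Named list merged over `config` (CLI flags).
#' @return Invisibly, a named list of the files written.
#' @export
#' @examples
#' out <- tempfile(); dir.create(out)
#' runPipeline(list(mode = "compare-groups", out = out))
runPipeline <- function(config = list(), overrides = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) .pipelineError(paste("config not found:", config))
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(.defaultConfig(), config)
  cfg <- utils::modifyList(cfg, overrides)
  if (is.null(cfg$mode) ||
      !cfg$mode %in% c("analyze-image", "compare-groups", "classify",
                       "simulate", "fixtures"))
    .pipelineError("mode must be one of analyze-image, compare-groups, classify, simulate, fixtures")
  if (is.null(cfg$out)) .pipelineError("out (output directory) is required")
  if (!is.finite(as.numeric(cfg$band_factor)) || cfg$band_factor <= 1)
    .pipelineError("band_factor must be > 1")
  # validate inputs before creating any output
  if (cfg$mode == "analyze-image") {
    if (is.null(cfg$input)) .pipelineError("analyze-image needs input")
    if (!file.exists(cfg$input))
      .pipelineError(paste("input not found:", cfg$input))
    if (!is.null(cfg$boundary) && !file.exists(cfg$boundary))
      .pipelineError(paste("boundary file not found:", cfg$boundary))
  }
  if (cfg$mode %in% c("compare-groups", "classify") &&
      !is.null(cfg$input) && !identical(cfg$input, "fixture") &&
      !file.exists(cfg$input))
    .pipelineError(paste("input not found:", cfg$input))
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(cfg$seed))
  written <- switch(cfg$mode,
                    "analyze-image" = .runAnalyzeImage(cfg),
                    "compare-groups" = .runCompareGroups(cfg),
                    "classify" = .runClassify(cfg),
                    "simulate" = .runSimulate(cfg),
                    "fixtures" = .runFixtures(cfg))
  logPath <- file.path(cfg$out, "run_log.yaml")
  yaml::write_yaml(list(mode = cfg$mode, seed = as.integer(cfg$seed),
                        parameters = cfg[setdiff(names(cfg),
                                                 c("mode", "seed"))],
                        outputs = written), logPath)
  invisible(c(written, list(log = logPath)))
}

.loadCohortInput <- function(cfg) {
  if (is.null(cfg$input) || identical(cfg$input, "fixture"))
    loadStudyFixture()
  else
    lesionCohort(utils::read.csv(cfg$input, stringsAsFactors = FALSE))
}

.runAnalyzeImage <- function(cfg) {
  img <- readLesionImage(cfg$input)
  boundary <- if (!is.null(cfg$boundary)) {
    pts <- utils::read.csv(cfg$boundary)
    closeBoundary(as.matrix(pts[, c("x", "y")]))
  } else {
    autoSegment(img, closingRadius = cfg$closing_radius,
                minArea = cfg$min_area)
  }
  scale <- if (!is.null(cfg$cm_per_pixel))
    new("ScaleCalibration", cmPerPixel = as.numeric(cfg$cm_per_pixel))
  else if (!is.null(cfg$ruler))
    calibrateScale(as.numeric(cfg$ruler$p1), as.numeric(cfg$ruler$p2),
                   as.numeric(cfg$ruler$cm))
  rec <- extractPatient(img, boundary, diagnosis = cfg$diagnosis %||% "MCC",
                        patientId = cfg$patient_id %||% "P1", scale = scale,
                        bandFactor = cfg$band_factor,
                        labMode = cfg$lab_mode, itaMode = cfg$ita_mode)
  lesionMask <- boundaryMask(boundary, img)
  hist <- regionHistograms(img, lesionMask)
  paths <- list(
    features = file.path(cfg$out, "features.csv"),
    histograms = file.path(cfg$out, "histograms.csv"),
    boundary = file.path(cfg$out, "boundary.csv"),
    lesion_mask = file.path(cfg$out, "lesion_mask.png"),
    band_mask = file.path(cfg$out, "band_mask.png"))
  writeFeatureTable(lesionCohort(list(rec)), paths$features)
  writeHistogramCSV(hist, paths$histograms)
  writeBoundaryCSV(boundary, paths$boundary)
  writeMaskPNG(lesionMask, paths$lesion_mask)
  writeMaskPNG(normalSkinBand(boundary, img, cfg$band_factor),
               paths$band_mask)
  paths
}

.runCompareGroups <- function(cfg) {
  cohort <- .loadCohortInput(cfg)
  paths <- list(group_means = file.path(cfg$out, "group_means.csv"))
  writeGroupMeans(groupMeans(cohort), paths$group_means)
  for (cmp in cfg$comparisons) {
    tab <- comparisonTable(cohort, cmp[[1]], cmp[[2]])
    stem <- sprintf("comparison_%s_vs_%s",
                    gsub("/", "", cmp[[1]]), gsub("/", "", cmp[[2]]))
    paths[[stem]] <- file.path(cfg$out, paste0(stem, ".csv"))
    writeComparisonTable(tab, paths[[stem]], "csv")
    writeComparisonTable(tab, file.path(cfg$out, paste0(stem, ".md")),
                         "markdown")
  }
  paths
}

.runClassify <- function(cfg) {
  cohort <- .loadCohortInput(cfg)
  r <- cfg$rule
  rule <- thresholdRule(r$parameter, r$threshold, r$direction,
                        r$positive_class)
  report <- applyRule(cohort, rule, r$negative_class)
  path <- file.path(cfg$out, "classification.json")
  writeConfusionJSON(report, path)
  list(classification = path)
}

.runSimulate <- function(cfg) {
  simArgs <- cfg$simulate
  simArgs$seed <- simArgs$seed %||% cfg$seed
  spec <- do.call(syntheticLesionSpec, simArgs)
  syn <- generateLesionImage(spec)
  cohort <- generateCohort(syntheticCohortSpec(seed = as.integer(cfg$seed)))
  paths <- list(image = file.path(cfg$out, "synthetic_image.png"),
                lesion_mask = file.path(cfg$out, "synthetic_lesion_mask.png"),
                boundary = file.path(cfg$out, "synthetic_boundary.csv"),
                cohort = file.path(cfg$out, "synthetic_cohort.csv"))
  writeLesionImage(syn$image, paths$image)
  writeMaskPNG(syn$lesionMask, paths$lesion_mask)
  writeBoundaryCSV(syn$boundary, paths$boundary)
  utils::write.csv(records(cohort), paths$cohort, row.names = FALSE,
                   quote = FALSE)
  paths
}

.runFixtures <- function(cfg) {
  src <- system.file("extdata", "table1_cohort.csv",
                     package = "LesionColor", mustWork = TRUE)
  dst <- file.path(cfg$out, "table1_cohort.csv")
  file.copy(src, dst, overwrite = TRUE)
  list(fixture = dst)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
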