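# The packaged 46-patient cohort feature table (verbatim transcription of
# the published per-patient results: 7 lesion color parameters each for
# 11 MCC, 11 cherry angioma, 12 BCC/SCC and 12 hemangioma patients).
# Note: only the lesion-region values were published per patient, so
# fixture records carry lesion summaries only.

# md5 pin of inst/extdata/table1_cohort.csv; the loader refuses a
# modified file.
.FIXTURE_MD5 <- "92d9c13f46f34a6a8b3c8bb92036dd6d"

.readFixtureFile <- function(path, md5 = .FIXTURE_MD5) {
  if (!file.exists(path)) stop("fixture file not found: ", path)
  got <- unname(tools::md5sum(path))
  if (!identical(got, md5))
    stop(errorCondition(
      sprintf("fixture checksum mismatch (%s): file corrupted or modified",
              got),
      class = c("lesioncolor_fixture_checksum", "error", "condition")))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lesionCohort(df)
}

#' Load the packaged study cohort
#'
#' Returns the 46-patient feature table shipped with the package: 11
#' cherry angioma, 11 MCC, 12 BCC/SCC and 12 hemangioma records, each
#' with the seven lesion color parameters (red, green, blue, L, a, b,
#' ITA). The file is checksum-pinned; a modified copy is refused.
#'
#' @return A [LesionCohort][LesionCohort-class] of 46 records.
#' @export
#' @examples
#' fx <- loadStudyFixture()
#' table(diagnoses(fx))
loadStudyFixture <- function() {
  path <- system.file("extdata", "table1_cohort.csv",
                      package = "LesionColor", mustWork = TRUE)
  .readFixtureFile(path)
}
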