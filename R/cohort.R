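# Group descriptives and Mann-Whitney U comparisons following the
# conventions of mainstream statistical packages' nonparametric-test
# reports: U = min(U1, U2), W = the smaller rank sum, tie-corrected Z
# without continuity correction, and exact significance reported as
# 2 x the one-tailed probability from the tie-free null distribution.

#' Per-diagnosis group means of the seven color parameters
#'
#' @param cohort A [LesionCohort][LesionCohort-class].
#' @return A `data.frame` with one row per diagnosis present (in
#'   [diagnosisLevels()] order): `diagnosis`, `n`, and the seven parameter
#'   means at full precision. Round at serialization time
#'   ([writeGroupMeans()]).
#' @export
#' @examples
#' groupMeans(loadStudyFixture())
groupMeans <- function(cohort) {
  stopifnot(is(cohort, "LesionCohort"))
  df <- cohort@records
  if (!nrow(df)) stop("cohort is empty")
  present <- intersect(diagnosisLevels(), unique(df$diagnosis))
  out <- do.call(rbind, lapply(present, function(g) {
    sub <- df[df$diagnosis == g, colorParameters(), drop = FALSE]
    cbind(data.frame(diagnosis = g, n = nrow(sub)),
          as.data.frame(as.list(colMeans(sub))))
  }))
  rownames(out) <- NULL
  out
}

#' Write group means as CSV, rounded to two decimals
#'
#' @param means Result of [groupMeans()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
writeGroupMeans <- function(means, path) {
  out <- means
  for (nm in colorParameters()) out[[nm]] <- sprintf("%.2f", out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# cache of exact null distributions keyed by "n1,n2"
.mwCache <- new.env(parent = emptyenv())

#' Exact null distribution of the Mann-Whitney U statistic
#'
#' Counts, for every attainable value `u = 0, ..., n1*n2`, the number of
#' ways to choose which `n1` of the `n1 + n2` ranks belong to the first
#' sample such that its U statistic equals `u` (dynamic programming over
#' ranks; ties are ignored, i.e. the classical tie-free distribution).
#'
#' @param n1,n2 Group sizes.
#' @return Numeric vector of length `n1*n2 + 1`; entry `u + 1` is the
#'   count for `U = u`. The counts sum to `choose(n1 + n2, n1)`.
#' @export
mwExactDistribution <- function(n1, n2) {
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  stopifnot(n1 >= 1L, n2 >= 1L)
  key <- paste(n1, n2, sep = ",")
  if (!is.null(.mwCache[[key]])) return(.mwCache[[key]])
  N <- n1 + n2
  maxS <- n1 * n2  # U ranges over 0..n1*n2 after shifting by n1(n1+1)/2
  # ways[k + 1, s + 1]: subsets of size k of the ranks processed so far
  # whose rank sum, shifted by k(k+1)/2 at completion, leads to U = s.
  # Process ranks 1..N; track raw rank sums, shift at the end.
  maxRaw <- sum((n2 + 1):N)
  ways <- matrix(0, n1 + 1L, maxRaw + 1L)
  ways[1L, 1L] <- 1
  for (r in seq_len(N)) {
    kmax <- min(r, n1)
    for (k in kmax:1) {
      src <- ways[k, ]
      if (any(src != 0)) {
        shifted <- c(rep(0, r), src)[seq_len(maxRaw + 1L)]
        ways[k + 1L, ] <- ways[k + 1L, ] + shifted
      }
    }
  }
  raw <- ways[n1 + 1L, ]
  minRaw <- n1 * (n1 + 1L) / 2
  counts <- raw[(minRaw + 1L):(minRaw + maxS + 1L)]
  .mwCache[[key]] <- counts
  counts
}

#' Mann-Whitney U test of two samples
#'
#' Midranks are used for ties. Reports `U = min(U1, U2)`, `W` = the
#' smaller of the two rank sums, the tie-corrected normal approximation
#' `Z = (U - n1*n2/2) / sigma_tie` (no continuity correction; always
#' <= 0 by construction), the two-tailed asymptotic significance
#' `2 * (1 - Phi(|Z|))`, and the exact significance `2 * P(U' <= U)`
#' computed from the tie-free null distribution
#' ([mwExactDistribution()]), capped at 1.
#'
#' When every pooled value is identical the normal approximation is
#' undefined: `Z` and the asymptotic p are `NA` (with a warning) and the
#' exact p is 1.
#'
#' @param x,y Numeric samples (each nonempty).
#' @param parameter Optional variable name carried into the result.
#' @return An [MWUResult][MWUResult-class].
#' @export
#' @examples
#' f <- records(loadStudyFixture())
#' mannWhitney(f$a[f$diagnosis == "MCC"], f$a[f$diagnosis == "BCC/SCC"])
mannWhitney <- function(x, y, parameter = NA_character_) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y) || anyNA(x) || anyNA(y))
    stop("both samples must be nonempty and free of NA")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))  # midranks
  R1 <- sum(r[seq_len(n1)]); R2 <- sum(r) - R1
  U1 <- R1 - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  U <- min(U1, U2)
  W <- min(R1, R2)
  tieTab <- table(r)
  tieSum <- sum(tieTab^3 - tieTab)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tieSum / (N * (N - 1)))
  if (sigma2 <= 0) {
    warning(warningCondition(
      "all pooled values identical; Z undefined",
      class = c("lesioncolor_degenerate_test", "warning", "condition")))
    Z <- NA_real_; pAsymp <- NA_real_; pExact <- 1
  } else {
    Z <- (U - n1 * n2 / 2) / sqrt(sigma2)
    pAsymp <- 2 * stats::pnorm(-abs(Z))
    counts <- mwExactDistribution(n1, n2)
    pOne <- sum(counts[seq_len(floor(U) + 1L)]) / sum(counts)
    pExact <- min(1, 2 * pOne)
  }
  new("MWUResult", parameter = parameter,
      n1 = as.integer(n1), n2 = as.integer(n2),
      U = U, W = W, Z = Z, pAsymp = pAsymp, pExact = pExact)
}

#' Per-parameter Mann-Whitney comparison of two diagnosis groups
#'
#' Runs [mannWhitney()] on each of the seven color parameters for the two
#' named groups, in the standard column order (red, green, blue, L, a, b,
#' ITA).
#'
#' @param cohort A [LesionCohort][LesionCohort-class].
#' @param groupA,groupB Diagnosis labels; both must be present.
#' @return Named list of seven [MWUResult][MWUResult-class] objects, with
#'   attributes `groupA`/`groupB`.
#' @export
#' @examples
#' tab <- comparisonTable(loadStudyFixture(), "MCC", "HEMANGIOMA")
#' tab$red
comparisonTable <- function(cohort, groupA, groupB) {
  stopifnot(is(cohort, "LesionCohort"))
  df <- cohort@records
  a <- df[df$diagnosis == groupA, , drop = FALSE]
  b <- df[df$diagnosis == groupB, , drop = FALSE]
  if (!nrow(a) || !nrow(b))
    stop(sprintf("both groups must be nonempty (%s: %d, %s: %d)",
                 groupA, nrow(a), groupB, nrow(b)))
  out <- lapply(colorParameters(), function(p)
    withCallingHandlers(
      mannWhitney(a[[p]], b[[p]], parameter = p),
      lesioncolor_degenerate_test = function(w) invokeRestart("muffleWarning")))
  names(out) <- colorParameters()
  attr(out, "groupA") <- groupA
  attr(out, "groupB") <- groupB
  class(out) <- "mwuComparison"
  out
}

.comparisonFrame <- function(tab) {
  fmt <- function(v, d) ifelse(is.na(v), "", formatC(v, format = "f",
                                                     digits = d))
  num <- function(v) ifelse(v == floor(v), sprintf("%d", as.integer(v)),
                            sprintf("%.1f", v))
  rows <- list(
    "Mann-Whitney U" = vapply(tab, function(r) num(r@U), character(1)),
    "Wilcoxon W" = vapply(tab, function(r) num(r@W), character(1)),
    "Z" = vapply(tab, function(r) fmt(r@Z, 3), character(1)),
    "Asymp. Sig. (2-tailed)" =
      vapply(tab, function(r) fmt(r@pAsymp, 3), character(1)),
    "Exact Sig. (2*(1-tailed Sig.))" =
      vapply(tab, function(r) fmt(r@pExact, 3), character(1)))
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("Red", "Green", "Blue", "L", "a", "b", "ITA")
  cbind(data.frame(statistic = names(rows)), df)
}

#' Write a Mann-Whitney comparison table
#'
#' Mirrors the report layout: one row per statistic (U, W, Z, asymptotic
#' and exact significance), one column per color parameter.
#'
#' @param tab Result of [comparisonTable()].
#' @param path Output path.
#' @param format `"csv"` (default) or `"markdown"`.
#' @return Invisibly, `path`.
#' @export
writeComparisonTable <- function(tab, path, format = c("csv", "markdown")) {
  format <- match.arg(format)
  df <- .comparisonFrame(tab)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    body <- apply(df, 1, function(r)
      paste0("| ", paste(r, collapse = " | "), " |"))
    writeLines(c(sprintf("**%s vs %s**", attr(tab, "groupA"),
                         attr(tab, "groupB")), "", hdr, sep, body), path)
  }
  invisible(path)
}

#' @export
print.mwuComparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney comparison: %s vs %s\n",
              attr(x, "groupA"), attr(x, "groupB")))
  print(.comparisonFrame(x), row.names = FALSE)
  invisible(x)
}
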