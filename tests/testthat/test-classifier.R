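test_that("the a* >= 37 rule on the packaged cohort gives the published metrics", {
  rep <- applyRule(loadStudyFixture(), thresholdRule("a", 37), "HEMANGIOMA")
  expect_identical(c(rep@tp, rep@fp, rep@tn, rep@fn), c(9L, 4L, 8L, 2L))
  m <- confusionMetrics(rep)
  expect_equal(unname(m["sensitivity"]), 900 / 11)
  expect_equal(unname(m["specificity"]), 200 / 3)
  expect_equal(unname(m["accuracy"]), 1700 / 23)
  expect_equal(unname(m["ppv"]), 900 / 13)
  expect_equal(unname(m["npv"]), 80)
  # report-style rendering: integer rounding and one-decimal truncation
  expect_identical(round(unname(m["sensitivity"])), 82)
  d <- displayMetrics(rep)
  expect_identical(d$truncated1[d$metric == "specificity"], "66.6%")
})

test_that("perfectly separated groups score 100 on every metric", {
  df <- data.frame(patient_id = as.character(1:10),
                   diagnosis = rep(c("MCC", "HEMANGIOMA"), each = 5),
                   red = 150, green = 80, blue = 90, L = 45,
                   a = c(51:55, 11:15), b = 10, ITA = 0)
  df$ITA <- itaFromLab(df$L, df$b)
  rep <- applyRule(lesionCohort(df), thresholdRule("a", 37), "HEMANGIOMA")
  m <- confusionMetrics(rep)
  expect_equal(as.numeric(m), rep(100, 5))
})

test_that("metrics equal a direct tally on random labelings", {
  set.seed(83)
  for (i in 1:10) {
    n <- 20
    df <- data.frame(patient_id = as.character(seq_len(n)),
                     diagnosis = sample(c("MCC", "CHERRY"), n, TRUE),
                     red = 150, green = 80, blue = 90, L = 45,
                     a = round(runif(n, 10, 60), 1), b = 10, ITA = 0)
    df$ITA <- itaFromLab(df$L, df$b)
    if (!all(c("MCC", "CHERRY") %in% df$diagnosis)) next
    th <- runif(1, 15, 55)
    rep <- applyRule(lesionCohort(df), thresholdRule("a", th), "CHERRY")
    ref <- oracleConfusion(df$a, df$diagnosis, "MCC", th, above = TRUE)
    expect_identical(c(rep@tp, rep@fp, rep@tn, rep@fn), unname(ref))
  }
})

test_that("metrics are invariant under record order permutation", {
  set.seed(89)
  df <- records(loadStudyFixture())
  rule <- thresholdRule("a", 37)
  a <- confusionMetrics(applyRule(lesionCohort(df), rule, "HEMANGIOMA"))
  b <- confusionMetrics(applyRule(lesionCohort(df[sample(nrow(df)), ]),
                                  rule, "HEMANGIOMA"))
  expect_equal(a, b)
})

test_that("flipping the direction swaps sensitivity and specificity", {
  df <- records(loadStudyFixture())
  sub <- df[df$diagnosis %in% c("MCC", "HEMANGIOMA"), ]
  # strictly-between threshold so >= and <= partition identically
  up <- applyRule(lesionCohort(sub), thresholdRule("a", 37), "HEMANGIOMA")
  swapped <- sub
  swapped$diagnosis <- ifelse(sub$diagnosis == "MCC", "HEMANGIOMA", "MCC")
  down <- applyRule(lesionCohort(swapped),
                    thresholdRule("a", 37, "below_is_positive"),
                    "HEMANGIOMA")
  mu <- confusionMetrics(up); md <- confusionMetrics(down)
  expect_equal(unname(mu["sensitivity"]), unname(md["specificity"]))
  expect_equal(unname(mu["specificity"]), unname(md["sensitivity"]))
})

test_that("undefined ratios are flagged, never silently zero", {
  df <- data.frame(patient_id = as.character(1:4),
                   diagnosis = rep(c("MCC", "CHERRY"), each = 2),
                   red = 150, green = 80, blue = 90, L = 45,
                   a = c(50, 55, 60, 45), b = 10, ITA = 0)
  df$ITA <- itaFromLab(df$L, df$b)
  rep <- applyRule(lesionCohort(df), thresholdRule("a", 5), "CHERRY")
  m <- confusionMetrics(rep)  # nobody called negative
  expect_true(is.na(m["npv"]))
  expect_true("npv" %in% attr(m, "undefined"))
})

test_that("an empty class is rejected", {
  df <- records(loadStudyFixture())
  mccOnly <- lesionCohort(df[df$diagnosis == "MCC", ])
  expect_error(applyRule(mccOnly, thresholdRule("a", 37), "HEMANGIOMA"),
               class = "lesioncolor_empty_class")
})

test_that("the threshold scan finds the exhaustive optimum", {
  fx <- loadStudyFixture()
  df <- records(fx)
  for (par in c("a", "b", "red")) {
    for (cls in list(c("MCC", "BCC/SCC"), c("MCC", "CHERRY"))) {
      scan <- separationScan(fx, par, cls[1], cls[2])
      sub <- df[df$diagnosis %in% cls, ]
      ref <- oracleBestSeparation(sub[[par]], sub$diagnosis, cls[1])
      expect_equal(scan$youden, ref)
      # the scan's optimum dominates any fixed rule
      fixed <- confusionMetrics(applyRule(fx, thresholdRule(par, 37,
                                                            positiveClass = cls[1]),
                                          cls[2]))
      expect_gte(scan$youden + 1e-9,
                 fixed[["sensitivity"]] + fixed[["specificity"]])
    }
  }
})

test_that("the a* scan for MCC vs BCC/SCC matches the exhaustive optimum", {
  # the cohort's printed a* ranges overlap (one MCC value of 24.66 sits
  # below the BCC/SCC maximum of 34.09), so no threshold reaches 100/100;
  # the scan must still find the exhaustive optimum
  fx <- loadStudyFixture()
  df <- records(fx)
  expect_lt(min(df$a[df$diagnosis == "MCC"]),
            max(df$a[df$diagnosis == "BCC/SCC"]))
  scan <- separationScan(fx, "a", "MCC", "BCC/SCC")
  expect_false(scan$perfect)
  sub <- df[df$diagnosis %in% c("MCC", "BCC/SCC"), ]
  expect_equal(scan$youden,
               oracleBestSeparation(sub$a, sub$diagnosis, "MCC"))
})

test_that("disjoint synthetic ranges are flagged as perfectly separable", {
  df <- data.frame(patient_id = as.character(1:12),
                   diagnosis = rep(c("MCC", "HEMANGIOMA"), each = 6),
                   red = 150, green = 80, blue = 90, L = 45,
                   a = c(40:45, 10:15), b = 10, ITA = 0)
  df$ITA <- itaFromLab(df$L, df$b)
  scan <- separationScan(lesionCohort(df), "a", "MCC", "HEMANGIOMA")
  expect_true(scan$perfect)
})

test_that("confusion JSON serializes rule, counts and both precisions", {
  rep <- applyRule(loadStudyFixture(), thresholdRule("a", 37), "HEMANGIOMA")
  p <- withr::local_tempfile(fileext = ".json")
  writeConfusionJSON(rep, p)
  obj <- jsonlite::read_json(p)
  expect_equal(obj$counts$tp, 9)
  expect_equal(obj$metrics$specificity, 200 / 3, tolerance = 1e-12)
  expect_equal(obj$rule$threshold, 37)
})
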