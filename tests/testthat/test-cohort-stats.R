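test_that("group means reproduce the packaged cohort's published summary", {
  gm <- groupMeans(loadStudyFixture())
  mcc <- gm[gm$diagnosis == "MCC", ]
  expect_identical(mcc$n, 11L)
  expect_equal(mcc$red, 184.38, tolerance = 0.005)
  hem <- gm[gm$diagnosis == "HEMANGIOMA", ]
  expect_identical(hem$n, 12L)
  expect_equal(hem$ITA, -35.33, tolerance = 0.005)
})

test_that("a single-record group's means equal that record", {
  df <- records(loadStudyFixture())[12, ]
  gm <- groupMeans(lesionCohort(df))
  expect_equal(gm$red, df$red)
  expect_equal(gm$ITA, df$ITA)
})

test_that("U statistics reproduce published comparisons of the cohort", {
  f <- records(loadStudyFixture())
  a <- mannWhitney(f$a[f$diagnosis == "MCC"],
                   f$a[f$diagnosis == "BCC/SCC"])
  expect_equal(a@U, 7)
  r <- mannWhitney(f$red[f$diagnosis == "MCC"],
                   f$red[f$diagnosis == "HEMANGIOMA"])
  expect_equal(r@U, 17)
  expect_lte(abs(r@pExact - 0.002), 5e-4)
  expect_lte(abs(r@Z - (-3.016)), 5e-4)
  expect_equal(r@W, 95)
})

test_that("identical samples give the central U and exact p of 1", {
  x <- c(3.2, 7.7, 1.4, 9.9, 5.5)
  res <- mannWhitney(x, x)
  expect_equal(res@U, 25 / 2)
  expect_equal(res@pExact, 1)
})

test_that("U1 + U2 = n1*n2 and W is consistent with the smaller rank sum", {
  set.seed(61)
  for (i in 1:25) {
    n1 <- sample(2:12, 1); n2 <- sample(2:12, 1)
    x <- round(rnorm(n1, sd = 3), 1); y <- round(rnorm(n2, 1, 3), 1)
    res <- mannWhitney(x, y)
    r <- rank(c(x, y))
    R1 <- sum(r[seq_len(n1)]); R2 <- sum(r) - R1
    U1 <- R1 - n1 * (n1 + 1) / 2
    expect_equal(res@U, min(U1, n1 * n2 - U1))
    expect_equal(res@W, min(R1, R2))
    # W = U' + m(m+1)/2 where m is the size of the smaller-rank-sum group
    m <- if (R1 <= R2) n1 else n2
    Uw <- if (R1 <= R2) U1 else n1 * n2 - U1
    expect_equal(res@W, Uw + m * (m + 1) / 2)
  }
})

test_that("exact null distribution matches brute-force enumeration up to N = 10", {
  for (n1 in 1:5) for (n2 in n1:(10 - n1)) {
    dp <- mwExactDistribution(n1, n2)
    expect_identical(dp, as.numeric(oracleMWDistribution(n1, n2)))
    expect_equal(sum(dp), choose(n1 + n2, n1))
    # symmetry of the null distribution about n1*n2/2
    expect_identical(dp, rev(dp))
  }
})

test_that("exact p at n1 = n2 = 4 equals enumeration over all 70 splits", {
  set.seed(67)
  for (i in 1:10) {
    x <- rnorm(4); y <- rnorm(4, 0.5)
    res <- mannWhitney(x, y)
    sets <- combn(8, 4)
    r <- rank(c(x, y))
    uAll <- apply(sets, 2, function(s) sum(r[s])) - 10
    pOne <- mean(uAll <= res@U)
    expect_equal(res@pExact, min(1, 2 * pOne))
  }
})

test_that("tie-free results agree with the standard exact test", {
  set.seed(71)
  for (i in 1:10) {
    x <- rnorm(7); y <- rnorm(9, 0.8)
    res <- mannWhitney(x, y)
    wt <- wilcox.test(x, y, exact = TRUE)
    expect_equal(min(wt$statistic, 63 - wt$statistic), res@U)
    # the reported exact p is 2 * one tail; for the symmetric tie-free
    # null this coincides with the two-sided exact p
    expect_equal(res@pExact, wt$p.value, tolerance = 1e-10)
  }
})

test_that("an all-tied comparison degrades gracefully", {
  expect_warning(res <- mannWhitney(rep(4, 5), rep(4, 6)),
                 class = "lesioncolor_degenerate_test")
  expect_true(is.na(res@Z))
  expect_equal(res@pExact, 1)
})

test_that("comparison tables carry the published cells for the cohort", {
  fx <- loadStudyFixture()
  t4 <- comparisonTable(fx, "MCC", "BCC/SCC")
  expect_equal(t4$green@U, 32)
  expect_lte(abs(t4$green@pExact - 0.037), 5e-4)
  t5 <- comparisonTable(fx, "MCC", "HEMANGIOMA")
  expect_lte(abs(t5$red@pExact - 0.002), 5e-4)
  expect_lte(abs(t5$ITA@pExact - 0.009), 5e-4)
})

test_that("comparing a group against itself is null across parameters", {
  fx <- loadStudyFixture()
  tab <- comparisonTable(fx, "CHERRY", "CHERRY")
  for (p in colorParameters()) {
    expect_equal(tab[[p]]@pExact, 1)
    expect_equal(tab[[p]]@U, 11^2 / 2)
  }
})

test_that("comparison against an absent group fails", {
  df <- records(loadStudyFixture())
  sub <- lesionCohort(df[df$diagnosis == "MCC", ])
  expect_error(comparisonTable(sub, "MCC", "CHERRY"), "nonempty")
})

test_that("table writers mirror the report layout", {
  fx <- loadStudyFixture()
  tab <- comparisonTable(fx, "MCC", "HEMANGIOMA")
  p <- withr::local_tempfile(fileext = ".csv")
  writeComparisonTable(tab, p, "csv")
  df <- read.csv(p, check.names = FALSE, colClasses = "character")
  expect_identical(df$statistic,
                   c("Mann-Whitney U", "Wilcoxon W", "Z",
                     "Asymp. Sig. (2-tailed)",
                     "Exact Sig. (2*(1-tailed Sig.))"))
  expect_identical(df$Red[1], "17")
  expect_identical(df$ITA[5], "0.009")
  md <- withr::local_tempfile(fileext = ".md")
  writeComparisonTable(tab, md, "markdown")
  expect_true(any(grepl("^\\| Mann-Whitney U \\|", readLines(md))))
})
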