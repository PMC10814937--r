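test_that("image generation is byte-identical for a repeated seed", {
  a <- generateLesionImage(syntheticLesionSpec(seed = 101))
  b <- generateLesionImage(syntheticLesionSpec(seed = 101))
  expect_identical(a$image, b$image)
  expect_identical(a$lesionMask, b$lesionMask)
  c <- generateLesionImage(syntheticLesionSpec(seed = 102))
  expect_false(identical(a$image, c$image))
})

test_that("zero noise reproduces the spec means exactly", {
  spec <- syntheticLesionSpec(backgroundSd = 0, lesionSd = 0, seed = 1)
  syn <- generateLesionImage(spec)
  for (ch in 1:3) {
    plane <- syn$image[, , ch]
    expect_true(all(plane[syn$lesionMask] == c(180, 70, 90)[ch]))
    expect_true(all(plane[syn$skinMask] == c(220, 180, 160)[ch]))
  }
})

test_that("lesion and skin masks partition the frame; boundary matches mask", {
  syn <- generateLesionImage(syntheticLesionSpec(seed = 3))
  expect_true(all(xor(syn$lesionMask, syn$skinMask)))
  rast <- boundaryMask(syn$boundary, syn$image)
  expect_gte(diceCoefficient(rast, syn$lesionMask), 0.99)
})

test_that("highlight and ruler options change the image as specified", {
  hl <- list(center = c(127.5, 127.5), radius = 10, boost = 60)
  rl <- list(p1 = c(10, 240), p2 = c(110, 240), cm = 1)
  spec <- syntheticLesionSpec(backgroundSd = 0, lesionSd = 0,
                              highlight = hl, ruler = rl, seed = 5)
  syn <- generateLesionImage(spec)
  # boosted disk at the lesion center (0-based (127.5, 127.5) -> rows 124:132)
  expect_true(all(syn$image[128, 124:132, 1] == 240))
  expect_equal(cmPerPixel(syn$scale), 0.01)
  # tick marks are dark
  expect_true(all(syn$image[241, 10:12, ] == 40))
})

test_that("a lesion entirely outside the frame is rejected", {
  expect_error(syntheticLesionSpec(center = c(600, 600), axes = c(20, 10)),
               "outside")
})

test_that("synthetic cohorts recover their group means at n = 500", {
  fx <- records(loadStudyFixture())
  groups <- lapply(setNames(nm = c("MCC", "HEMANGIOMA")), function(g) {
    sub <- as.matrix(fx[fx$diagnosis == g, colorParameters()])
    list(n = 500L, mean = colMeans(sub),
         cov = diag(apply(sub, 2, var), 7, 7))
  })
  cohort <- generateCohort(syntheticCohortSpec(groups, seed = 11))
  expect_identical(nPatients(cohort), 1000L)
  df <- records(cohort)
  for (g in names(groups)) {
    got <- colMeans(as.matrix(df[df$diagnosis == g, colorParameters()]))
    se <- setNames(sqrt(diag(groups[[g]]$cov) / 500), colorParameters())
    # ITA is recomputed from sampled L, b, so compare the six raw params
    for (p in colorParameters()[1:6])
      expect_lt(abs(got[[p]] - groups[[g]]$mean[[p]]), 3 * se[[p]] + 1e-9)
  }
})

test_that("zero covariance collapses every record onto the group mean", {
  mu <- c(red = 180, green = 80, blue = 95, L = 48, a = 42, b = 13.5,
          ITA = 0)
  groups <- list(MCC = list(n = 5L, mean = mu, cov = matrix(0, 7, 7)))
  cohort <- generateCohort(syntheticCohortSpec(groups, seed = 13))
  df <- records(cohort)
  expect_true(all(df$red == 180))
  expect_equal(df$ITA, rep(itaFromLab(48, 13.5), 5))
})

test_that("a non-PSD covariance is rejected", {
  cv <- diag(7); cv[1, 1] <- -2
  groups <- list(MCC = list(n = 3L, mean = rep(50, 7), cov = cv))
  expect_error(syntheticCohortSpec(groups, seed = 1), "semi-definite")
})

test_that("generated cohorts keep the ITA identity", {
  cohort <- generateCohort(syntheticCohortSpec(seed = 17))
  df <- records(cohort)
  expect_equal(df$ITA, itaFromLab(df$L, df$b), tolerance = 1e-12)
})

test_that("the packaged cohort loads verbatim", {
  fx <- loadStudyFixture()
  df <- records(fx)
  expect_identical(nrow(df), 46L)
  expect_identical(as.vector(table(factor(df$diagnosis,
                                          levels = diagnosisLevels()))),
                   c(11L, 11L, 12L, 12L))
  expect_identical(df$patient_id[1], "1")
  expect_equal(df$red[1], 195.36)
  expect_identical(df$diagnosis[1], "CHERRY")
  expect_equal(df$ITA[12], -18.56)
})

test_that("a tampered fixture file is refused", {
  src <- system.file("extdata", "table1_cohort.csv", package = "LesionColor")
  tmp <- withr::local_tempfile(fileext = ".csv")
  lines <- readLines(src)
  lines[2] <- sub("195.36", "295.36", lines[2], fixed = TRUE)
  writeLines(lines, tmp)
  expect_error(LesionColor:::.readFixtureFile(tmp),
               class = "lesioncolor_fixture_checksum")
})

test_that("two identical groups reject at about the nominal 5% rate", {
  # exact test at n1 = n2 = 8, where the attainable two-sided level of
  # the discrete null is 0.0499; 2000 seeded replicates
  set.seed(1)
  reps <- 2000L
  hits <- 0L
  for (i in seq_len(reps)) {
    res <- mannWhitney(rnorm(8), rnorm(8))
    if (res@pExact < 0.05) hits <- hits + 1L
  }
  rate <- hits / reps
  ciHalf <- 1.96 * sqrt(0.05 * 0.95 / reps)
  expect_gt(rate, 0.05 - ciHalf)
  expect_lt(rate, 0.05 + ciHalf)
})
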