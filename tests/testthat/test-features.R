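test_that("a uniform region summarizes to its exact color", {
  img <- uniformImage(c(188, 60, 86), 12, 12)
  s <- summarizeRegion(img, matrix(TRUE, 12, 12))
  expect_equal(unname(rgbMeans(s)), c(188, 60, 86))
  expect_equal(unname(labMeans(s)), unname(rgbToLab(c(188, 60, 86))),
               tolerance = 1e-9)
  expect_equal(ita(s), itaFromLab(labMeans(s)[1], labMeans(s)[3]))
})

test_that("a black-and-white pair averages to mid gray", {
  img <- uniformImage(c(0, 0, 0), 1, 2)
  img[1, 2, ] <- 255
  s <- summarizeRegion(img, matrix(TRUE, 1, 2))
  expect_equal(unname(rgbMeans(s)), rep(127.5, 3))
  # per-pixel Lab mean of black and white: L = 50, neutral axis
  expect_equal(unname(labMeans(s)[1]), 50, tolerance = 1e-3)
})

test_that("noisy region means recover generator parameters within CLT bounds", {
  spec <- syntheticLesionSpec(seed = 19)
  syn <- generateLesionImage(spec)
  n <- sum(syn$lesionMask)
  expect_gt(n, 1e4)
  s <- summarizeRegion(syn$image, syn$lesionMask)
  # 8-bit quantization adds ~1/12 variance; 3 SE of the generator sd
  bound <- 3 * 5 / sqrt(n) + 0.05
  expect_true(all(abs(rgbMeans(s) - c(180, 70, 90)) < bound + 0.15))
})

test_that("region summaries are permutation-invariant over pixels", {
  set.seed(41)
  img <- array(runif(75, 0, 255), dim = c(5, 5, 3))
  mask <- matrix(runif(25) < 0.6, 5, 5)
  mask[1] <- TRUE
  s1 <- summarizeRegion(img, mask)
  # permute pixel positions consistently across channels
  perm <- sample(25)
  img2 <- array(0, dim = c(5, 5, 3))
  for (ch in 1:3) img2[, , ch] <- matrix(img[, , ch][perm], 5, 5)
  mask2 <- matrix(mask[perm], 5, 5)
  s2 <- summarizeRegion(img2, mask2)
  expect_equal(parameterVector(s1), parameterVector(s2), tolerance = 1e-12)
})

test_that("lab averaging mode switch behaves as documented", {
  set.seed(43)
  img <- array(runif(300, 0, 255), dim = c(10, 10, 3))
  mask <- matrix(TRUE, 10, 10)
  sPer <- summarizeRegion(img, mask, labMode = "perpixel")
  sMean <- summarizeRegion(img, mask, labMode = "meanrgb")
  expect_equal(unname(labMeans(sMean)),
               unname(rgbToLab(rgbMeans(sMean))), tolerance = 1e-9)
  # on a heterogeneous region the two differ (Lab is nonlinear in RGB)
  expect_gt(max(abs(labMeans(sPer) - labMeans(sMean))), 0.1)
})

test_that("patient extraction: deltas follow the generator's sign pattern", {
  syn <- generateLesionImage(syntheticLesionSpec(seed = 23))
  rec <- extractPatient(syn$image, syn$boundary, "MCC", "S1",
                        scale = calibrateScale(c(0, 0), c(100, 0), 1))
  d <- rec@delta
  # lesion (180,70,90) darker/redder than skin (220,180,160)
  expect_lt(d[["red"]], 0)
  expect_lt(d[["green"]], 0)
  expect_lt(d[["blue"]], 0)
  # green shows the largest channel decrease for this red-purple lesion
  expect_lt(d[["green"]], d[["red"]])
  expect_lt(d[["green"]], d[["blue"]])
  expect_identical(unname(d),
                   unname(parameterVector(rec@lesion) -
                            parameterVector(rec@normal)))
  expect_s4_class(rec@geometry, "GeometryFeatures")
})

test_that("lesion colored like the skin gives near-zero deltas", {
  spec <- syntheticLesionSpec(lesion = c(220, 180, 160),
                              background = c(220, 180, 160), seed = 29)
  syn <- generateLesionImage(spec)
  rec <- extractPatient(syn$image, syn$boundary, "CHERRY")
  expect_true(all(abs(rec@delta) < 1))
})

test_that("swapping lesion and normal masks negates every delta", {
  syn <- generateLesionImage(syntheticLesionSpec(seed = 31))
  lesionMask <- boundaryMask(syn$boundary, syn$image)
  band <- normalSkinBand(syn$boundary, syn$image, 1.25)
  a <- summarizeRegion(syn$image, lesionMask)
  b <- summarizeRegion(syn$image, band)
  expect_equal(parameterVector(a) - parameterVector(b),
               -(parameterVector(b) - parameterVector(a)))
  expect_equal(unname((parameterVector(a) - parameterVector(b)) +
                        (parameterVector(b) - parameterVector(a))),
               rep(0, 7))
})

test_that("fixture rows satisfy the ITA identity within reporting tolerance", {
  df <- records(loadStudyFixture())
  recomputed <- itaFromLab(df$L, df$b)
  expect_lt(max(abs(recomputed - df$ITA)), 0.15)
})

test_that("the feature table writer renders two decimals", {
  syn <- generateLesionImage(syntheticLesionSpec(seed = 37))
  rec <- extractPatient(syn$image, syn$boundary, "MCC", "W1")
  p <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(lesionCohort(list(rec)), p)
  df <- read.csv(p, colClasses = "character")
  expect_true(all(grepl("^-?[0-9]+\\.[0-9]{2}$", df$red)))
  expect_true(all(c("normal_L", "delta_ITA") %in% names(df)))
})
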