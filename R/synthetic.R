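# Synthetic data: lesion photographs with ground truth, and feature
# cohorts drawn per diagnosis group.

#' Construct a synthetic-lesion image specification
#'
#' Defaults emulate the study's photographs at desk scale: a 256 x 256
#' field of noisy skin-colored pixels (RGB (220, 180, 160), per-channel
#' Gaussian sd 5) containing one rotated elliptical lesion of a redder,
#' darker mean color (RGB (180, 70, 90), sd 5) with semi-axes (70, 50) px.
#' A central specular highlight (flash reflection on a vaulted lesion) and
#' a pair of ruler tick marks can be added.
#'
#' @param width,height Image size in pixels.
#' @param background,backgroundSd Skin mean RGB triple and noise sd.
#' @param lesion,lesionSd Lesion mean RGB triple and noise sd.
#' @param center,axes,rotation Ellipse center `(x, y)`, semi-axes
#'   `(a, b)` in px, rotation in degrees.
#' @param highlight `NULL` or `list(center = c(x, y), radius, boost)`:
#'   pixels within `radius` of `center` get `boost` added to every
#'   channel.
#' @param ruler `NULL` or `list(p1 = c(x, y), p2 = c(x, y), cm)`: dark
#'   tick marks at `p1`, `p2`, a known `cm` apart.
#' @param seed Integer RNG seed.
#' @return A validated
#'   [SyntheticLesionSpec][SyntheticLesionSpec-class].
#' @export
syntheticLesionSpec <- function(width = 256L, height = 256L,
                                background = c(220, 180, 160),
                                backgroundSd = 5,
                                lesion = c(180, 70, 90), lesionSd = 5,
                                center = c(127.5, 127.5),
                                axes = c(70, 50), rotation = 20,
                                highlight = NULL, ruler = NULL,
                                seed = 1L) {
  new("SyntheticLesionSpec",
      width = as.integer(width), height = as.integer(height),
      background = as.numeric(background),
      backgroundSd = as.numeric(backgroundSd),
      lesion = as.numeric(lesion), lesionSd = as.numeric(lesionSd),
      center = as.numeric(center), axes = as.numeric(axes),
      rotation = as.numeric(rotation),
      highlight = highlight, ruler = ruler, seed = as.integer(seed))
}

.ellipseMask <- function(spec) {
  H <- spec@height; W <- spec@width
  x <- matrix(rep(0:(W - 1L), each = H), H, W)
  y <- matrix(rep(0:(H - 1L), times = W), H, W)
  rot <- spec@rotation * pi / 180
  dx <- x - spec@center[1]; dy <- y - spec@center[2]
  u <- dx * cos(rot) + dy * sin(rot)
  v <- -dx * sin(rot) + dy * cos(rot)
  (u / spec@axes[1])^2 + (v / spec@axes[2])^2 <= 1
}

.ellipseBoundary <- function(spec, n = 360L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  rot <- spec@rotation * pi / 180
  x <- spec@center[1] + spec@axes[1] * cos(th) * cos(rot) -
    spec@axes[2] * sin(th) * sin(rot)
  y <- spec@center[2] + spec@axes[1] * cos(th) * sin(rot) +
    spec@axes[2] * sin(th) * cos(rot)
  closedBoundary(cbind(x, y))
}

# run expr with a locally seeded RNG, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic lesion photograph with ground truth
#'
#' Pixel colors are the region mean (skin or lesion) plus independent
#' per-channel Gaussian noise, rounded to 8-bit and clipped to
#' \[0, 255\]. Fully deterministic given the spec's seed.
#'
#' @param spec A [SyntheticLesionSpec][SyntheticLesionSpec-class].
#' @return A list: `image` (H x W x 3 array, 0-255), `boundary` (exact
#'   elliptical [ClosedBoundary][ClosedBoundary-class]), `lesionMask` and
#'   `skinMask` (logical H x W ground-truth masks), and `scale`
#'   (a [ScaleCalibration][ScaleCalibration-class] from the ruler marks,
#'   or `NULL` when no ruler was drawn).
#' @export
#' @examples
#' syn <- generateLesionImage(syntheticLesionSpec(seed = 42))
#' dim(syn$image)
generateLesionImage <- function(spec) {
  stopifnot(is(spec, "SyntheticLesionSpec"))
  validObject(spec)
  H <- spec@height; W <- spec@width
  inside <- .ellipseMask(spec)
  bgSd <- rep(spec@backgroundSd, length.out = 3L)
  leSd <- rep(spec@lesionSd, length.out = 3L)
  img <- .withSeed(spec@seed, {
    out <- array(0, dim = c(H, W, 3L))
    for (ch in 1:3) {
      plane <- matrix(spec@background[ch], H, W)
      plane[inside] <- spec@lesion[ch]
      sdPlane <- matrix(bgSd[ch], H, W)
      sdPlane[inside] <- leSd[ch]
      noise <- matrix(stats::rnorm(H * W), H, W) * sdPlane
      out[, , ch] <- plane + noise
    }
    out
  })
  if (!is.null(spec@highlight)) {
    hl <- spec@highlight
    x <- matrix(rep(0:(W - 1L), each = H), H, W)
    y <- matrix(rep(0:(H - 1L), times = W), H, W)
    disk <- (x - hl$center[1])^2 + (y - hl$center[2])^2 <= hl$radius^2
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[disk] <- plane[disk] + hl$boost
      img[, , ch] <- plane
    }
  }
  scale <- NULL
  if (!is.null(spec@ruler)) {
    rl <- spec@ruler
    for (p in list(rl$p1, rl$p2)) {
      rr <- max(1L, round(p[2]) - 4L):min(H, round(p[2]) + 6L)
      cc <- max(1L, round(p[1])):min(W, round(p[1]) + 2L)
      img[rr, cc, ] <- 40
    }
    scale <- calibrateScale(rl$p1, rl$p2, rl$cm)
  }
  img <- round(pmin(pmax(img, 0), 255))
  list(image = img, boundary = .ellipseBoundary(spec),
       lesionMask = inside, skinMask = !inside, scale = scale)
}

#' Construct a synthetic-cohort specification
#'
#' When `groups` is `NULL` the defaults reproduce the packaged study
#' cohort's structure: the four diagnosis groups at their study sizes
#' (MCC 11, cherry 11, BCC/SCC 12, hemangioma 12), each with its observed
#' mean 7-vector and a diagonal covariance from the observed per-group
#' variances.
#'
#' @param groups Named list (`list(n, mean, cov)` per diagnosis) or
#'   `NULL` for the study defaults.
#' @param seed Integer RNG seed.
#' @return A [SyntheticCohortSpec][SyntheticCohortSpec-class].
#' @export
syntheticCohortSpec <- function(groups = NULL, seed = 1L) {
  if (is.null(groups)) {
    df <- loadStudyFixture()@records
    groups <- lapply(stats::setNames(nm = diagnosisLevels()), function(g) {
      sub <- as.matrix(df[df$diagnosis == g, colorParameters()])
      list(n = nrow(sub), mean = colMeans(sub),
           cov = diag(apply(sub, 2, stats::var), 7L, 7L))
    })
  }
  groups <- lapply(groups, function(el) {
    el$n <- as.integer(el$n)
    el$mean <- stats::setNames(as.numeric(el$mean), colorParameters())
    el$cov <- as.matrix(el$cov)
    dimnames(el$cov) <- list(colorParameters(), colorParameters())
    el
  })
  new("SyntheticCohortSpec", groups = groups, seed = as.integer(seed))
}

#' Generate a synthetic feature cohort
#'
#' Draws each group's records from a multivariate normal with the spec's
#' mean and covariance, clips RGB means to \[0, 255\] and L to
#' \[0, 100\], and recomputes the ITA column from the sampled L and b so
#' that every record satisfies the ITA identity (as the packaged cohort
#' does).
#'
#' @param spec A [SyntheticCohortSpec][SyntheticCohortSpec-class].
#' @return A [LesionCohort][LesionCohort-class].
#' @export
#' @examples
#' generateCohort(syntheticCohortSpec(seed = 3))
generateCohort <- function(spec) {
  stopifnot(is(spec, "SyntheticCohortSpec"))
  validObject(spec)
  df <- .withSeed(spec@seed, {
    do.call(rbind, lapply(names(spec@groups), function(g) {
      el <- spec@groups[[g]]
      m <- MASS::mvrnorm(el$n, mu = el$mean, Sigma = el$cov)
      m <- matrix(m, nrow = el$n, dimnames = list(NULL, colorParameters()))
      m[, 1:3] <- pmin(pmax(m[, 1:3], 0), 255)
      m[, "L"] <- pmin(pmax(m[, "L"], 0), 100)
      m[, "ITA"] <- itaFromLab(m[, "L"], m[, "b"])
      cbind(data.frame(patient_id = sprintf("SYN-%s-%02d", gsub("/", "", g),
                                            seq_len(el$n)),
                       diagnosis = g),
            as.data.frame(m))
    }))
  })
  lesionCohort(df)
}
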