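# Independent oracles, deliberately coded apart from the package paths.

# Scalar textbook sRGB -> CIELab: explicit per-component arithmetic,
# no shared code with the vectorized production implementation.
oracleRgbToLab <- function(rgb) {
  lin <- numeric(3)
  for (i in 1:3) {
    u <- rgb[i] / 255
    lin[i] <- if (u <= 0.04045) u / 12.92 else ((u + 0.055) / 1.055)^2.4
  }
  X <- 0.4124564 * lin[1] + 0.3575761 * lin[2] + 0.1804375 * lin[3]
  Y <- 0.2126729 * lin[1] + 0.7151522 * lin[2] + 0.0721750 * lin[3]
  Z <- 0.0193339 * lin[1] + 0.1191920 * lin[2] + 0.9503041 * lin[3]
  f <- function(t) if (t > (6 / 29)^3) t^(1 / 3) else
    t / (3 * (6 / 29)^2) + 4 / 29
  fx <- f(X / 0.95047); fy <- f(Y / 1.0); fz <- f(Z / 1.08883)
  c(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

# Direct double-loop histogram tally.
oracleHistogram <- function(image, mask, channel) {
  counts <- integer(256)
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask)))
    if (mask[r, c]) {
      v <- round(image[r, c, channel])
      counts[v + 1L] <- counts[v + 1L] + 1L
    }
  counts
}

# Uniform-color H x W x 3 image on the 0-255 scale.
uniformImage <- function(color, H = 10L, W = 10L) {
  array(rep(color, each = H * W), dim = c(H, W, 3L))
}

# Exact U null distribution by explicit enumeration of rank subsets.
oracleMWDistribution <- function(n1, n2) {
  N <- n1 + n2
  sets <- utils::combn(N, n1)
  u <- colSums(matrix(sets, nrow = n1)) - n1 * (n1 + 1) / 2
  tabulate(u + 1L, nbins = n1 * n2 + 1L)
}

# Direct confusion tally for a >=/<= threshold rule.
oracleConfusion <- function(values, labels, positive, threshold, above = TRUE) {
  called <- if (above) values >= threshold else values <= threshold
  isPos <- labels == positive
  c(tp = sum(called & isPos), fp = sum(called & !isPos),
    tn = sum(!called & !isPos), fn = sum(!called & isPos))
}

# Exhaustive threshold scan maximizing sensitivity + specificity.
oracleBestSeparation <- function(values, labels, positive) {
  vals <- sort(unique(values))
  gap <- if (length(vals) > 1) min(diff(vals)) else 1
  cand <- c(vals[1] - gap / 2, (vals[-length(vals)] + vals[-1]) / 2,
            vals[length(vals)] + gap / 2)
  best <- -Inf
  for (above in c(TRUE, FALSE)) for (th in cand) {
    cnt <- oracleConfusion(values, labels, positive, th, above)
    sens <- 100 * cnt["tp"] / (cnt["tp"] + cnt["fn"])
    spec <- 100 * cnt["tn"] / (cnt["tn"] + cnt["fp"])
    best <- max(best, sens + spec)
  }
  unname(best)
}

diceCoefficient <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
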