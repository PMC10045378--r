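# Scalar (per-pixel loop) oracles, deliberately naive and independent of
# the vectorised implementations they check.

oracleMaskStats <- function(ref, gen) {
  TP <- FP <- FN <- TN <- 0
  rs <- rc <- rn <- gs <- gc <- gn <- 0
  for (i in seq_len(nrow(ref))) {
    for (j in seq_len(ncol(ref))) {
      r <- ref[i, j] != 0
      g <- gen[i, j] != 0
      if (r && g) TP <- TP + 1
      if (!r && g) FP <- FP + 1
      if (r && !g) FN <- FN + 1
      if (!r && !g) TN <- TN + 1
      if (r) { rs <- rs + i; rc <- rc + j; rn <- rn + 1 }
      if (g) { gs <- gs + i; gc <- gc + j; gn <- gn + 1 }
    }
  }
  list(TP = TP, FP = FP, FN = FN, TN = TN,
       centroidRef = if (rn) c(rs / rn, rc / rn) else c(NA, NA),
       centroidGen = if (gn) c(gs / gn, gc / gn) else c(NA, NA),
       sRef = rn, sGen = gn)
}

oracleDice <- function(ref, gen) {
  s <- oracleMaskStats(ref, gen)
  denom <- (s$TP + s$FP) + (s$TP + s$FN)
  if (denom == 0) return(1)
  if (s$sRef == 0 || s$sGen == 0) return(0)
  2 * s$TP / denom
}

oracleCenterError <- function(ref, gen) {
  s <- oracleMaskStats(ref, gen)
  if (anyNA(c(s$centroidRef, s$centroidGen))) return(NA_real_)
  d <- sqrt((s$centroidRef[1] - s$centroidGen[1])^2 +
            (s$centroidRef[2] - s$centroidGen[2])^2)
  100 * d / sqrt(nrow(ref)^2 + ncol(ref)^2)
}

oracleAreaIndex <- function(ref, gen) {
  s <- oracleMaskStats(ref, gen)
  if (s$sRef == 0 || s$sGen == 0) return(NA_real_)
  100 * abs(s$sRef - s$sGen) / (nrow(ref) * ncol(ref))
}

# Scalar-loop mean absolute difference between two arrays.
oracleMeanAbs <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  tot <- 0
  for (k in seq_along(a)) tot <- tot + abs(a[k] - b[k])
  tot / length(a)
}

randomMask <- function(h, w, p = 0.3) {
  matrix(as.integer(runif(h * w) < p), h, w)
}

# A deterministic sharp disk test image: background 0.1, disk 0.9
# (contrast 0.8), pixel-center rasterisation.
diskImage <- function(n = 100, center = c(50, 50), radius = 20,
                      low = 0.1, contrast = 0.8) {
  rr <- matrix(seq_len(n) - 0.5, n, n)
  cc <- t(rr)
  mask <- (rr - center[1])^2 + (cc - center[2])^2 <= radius^2
  list(image = low + contrast * mask, mask = mask * 1L)
}

readMaskFixture <- function(name) {
  as.matrix(read.table(test_path("fixtures", name)))
}
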