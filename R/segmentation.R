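## Automatic lesion segmentation: inverse-Gaussian-gradient edge maps and
## morphological geodesic active contours (MorphGAC).  The contour
## evolution mirrors the reference morphological-snakes formulation:
## a balloon erosion/dilation gated by the edge map, gradient advection,
## and alternating sup-inf / inf-sup curvature smoothing with four line
## structuring elements.  All operators use zero out-of-bounds values.

## Shift a matrix by (dr, dc), filling vacated cells with `fill`.
.shiftMat <- function(m, dr, dc, fill = 0) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  if (length(rs) && length(cs)) {
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  }
  out
}

## Binary erosion / dilation over a set of (row, col) offsets.
.erodeSE <- function(u, offsets) {
  out <- NULL
  for (o in offsets) {
    s <- .shiftMat(u, o[1], o[2], fill = 0)
    out <- if (is.null(out)) s else pmin(out, s)
  }
  out
}

.dilateSE <- function(u, offsets) {
  out <- NULL
  for (o in offsets) {
    s <- .shiftMat(u, o[1], o[2], fill = 0)
    out <- if (is.null(out)) s else pmax(out, s)
  }
  out
}

.SE_FULL3 <- {
  g <- expand.grid(dr = -1:1, dc = -1:1)
  lapply(seq_len(nrow(g)), function(i) c(g$dr[i], g$dc[i]))
}

## The four length-3 line structuring elements through the center
## (diagonal, vertical, anti-diagonal, horizontal).
.SE_LINES <- list(
  list(c(-1, -1), c(0, 0), c(1, 1)),
  list(c(-1, 0), c(0, 0), c(1, 0)),
  list(c(1, -1), c(0, 0), c(-1, 1)),
  list(c(0, -1), c(0, 0), c(0, 1))
)

.supInf <- function(u) {
  out <- NULL
  for (se in .SE_LINES) {
    e <- .erodeSE(u, se)
    out <- if (is.null(out)) e else pmax(out, e)
  }
  out
}

.infSup <- function(u) {
  out <- NULL
  for (se in .SE_LINES) {
    d <- .dilateSE(u, se)
    out <- if (is.null(out)) d else pmin(out, d)
  }
  out
}

#' Inverse Gaussian gradient edge-stopping map
#'
#' `g = 1 / sqrt(1 + alpha * |grad(G_sigma * image)|)`: close to 1 in flat
#' regions and near 0 at strong edges.  RGB input is converted to
#' luminance first.  The gradient magnitude uses derivative-of-Gaussian
#' filtering with replicate boundary handling.
#'
#' @param image grayscale matrix or RGB array in \[0, 1\].
#' @param alpha steepness of the inversion (> 0, default 100).
#' @param sigma Gaussian standard deviation in pixels (> 0, default 1.5).
#' @return edge-stopping map in (0, 1\], same H x W as the input.
#' @export
inverseGaussianGradient <- function(image, alpha = 100, sigma = 1.5) {
  if (alpha <= 0 || sigma <= 0) stop("alpha and sigma must be positive")
  gray <- luminance(image)
  1 / sqrt(1 + alpha * .gaussianGradientMagnitude(gray, sigma))
}

#' Morphological geodesic active contour evolution
#'
#' Iterates the morphological GAC update on a precomputed edge-stopping
#' map `g`: (1) a balloon step (erosion for `balloon = -1`, dilation for
#' `+1`, 3x3 structuring element) applied where
#' `g > threshold / |balloon|`; (2) advection toward edges, switching
#' pixels by the sign of `grad(g) . grad(u)`; (3) `smoothing` curvature
#' passes alternating the sup-inf and inf-sup operators.  Deterministic;
#' `iterations = 0` returns the binarised initial level set.
#'
#' @param g edge-stopping map in (0, 1\] (e.g. from
#'   [inverseGaussianGradient()]).
#' @param config a [GACConfig-class] (alpha/sigma are not used here; they
#'   belong to the preprocessing).
#' @param initLevelSet binary matrix of the same shape as `g`.
#' @return final binary mask (integer matrix).
#' @export
morphGAC <- function(g, config = GACConfig(), initLevelSet) {
  stopifnot(is.matrix(g), is.matrix(initLevelSet))
  if (!identical(dim(g), dim(initLevelSet))) {
    stop("init level set shape differs from the edge map")
  }
  u <- matrix(as.numeric(initLevelSet > 0), nrow(g), ncol(g))
  if (!any(u > 0) && config@balloon <= 0) {
    message("empty initial level set with a non-expanding balloon; ",
            "returning an empty mask")
    return(matrix(0L, nrow(g), ncol(g)))
  }
  threshold <- if (identical(config@threshold, "auto")) {
    unname(quantile(g, 0.40, type = 7))
  } else config@threshold
  balloon <- config@balloon
  gateMask <- if (balloon != 0) g > threshold / abs(balloon) else NULL
  dg <- .gradient2d(g)
  curvopPhase <- 0L
  for (it in seq_len(config@iterations)) {
    if (balloon > 0) {
      aux <- .dilateSE(u, .SE_FULL3)
      u[gateMask] <- aux[gateMask]
    } else if (balloon < 0) {
      aux <- .erodeSE(u, .SE_FULL3)
      u[gateMask] <- aux[gateMask]
    }
    du <- .gradient2d(u)
    adv <- dg[[1]] * du[[1]] + dg[[2]] * du[[2]]
    u[adv > 0] <- 1
    u[adv < 0] <- 0
    for (s in seq_len(config@smoothing)) {
      u <- if (curvopPhase == 0L) .supInf(.infSup(u)) else .infSup(.supInf(u))
      curvopPhase <- 1L - curvopPhase
    }
  }
  matrix(as.integer(u > 0), nrow(g), ncol(g))
}

## Initial level set: a filled circle.
.circleLevelSet <- function(height, width, center, radius) {
  U <- matrix(seq_len(height) - center[1], height, width)
  V <- matrix(seq_len(width) - center[2], height, width, byrow = TRUE)
  matrix(as.integer(sqrt(U^2 + V^2) < radius), height, width)
}

## Scale-space blob detection: argmax of a difference-of-Gaussians ladder
## over the (polarity-normalised, despeckled) intensity, with an excluded
## border margin (replicate padding makes DoG responses spurious there).
## Returns the blob center and an approximate radius (sqrt(2) * sigma of
## the best-responding scale).
.detectLesionBlob <- function(work) {
  H <- nrow(work); W <- ncol(work)
  sigmas <- c(3, 4.5, 6.5, 9, 13, 18, 26)
  sigmas <- sigmas[sigmas <= min(H, W) / 3]
  if (!length(sigmas)) sigmas <- 3
  best <- NULL; bestVal <- -Inf
  for (s in sigmas) {
    resp <- gaussianBlur(work, s) - gaussianBlur(work, 1.6 * s)
    mg <- min(ceiling(1.6 * s), floor((min(H, W) - 1) / 2))
    resp[c(seq_len(mg), (H - mg + 1):H), ] <- -Inf
    resp[, c(seq_len(mg), (W - mg + 1):W)] <- -Inf
    v <- max(resp)
    if (v > bestVal) {
      bestVal <- v
      idx <- which(resp == v, arr.ind = TRUE)[1, ]
      best <- list(center = c(idx[1], idx[2]), radius = sqrt(2) * s)
    }
  }
  best
}

#' Segment a lesion in an ultrasound or pseudo-anatomical image
#'
#' One polarity convention serves both domains: grayscale input is treated
#' as ultrasound and inverted first (the dark mass becomes bright), RGB
#' input is treated as optical / pseudo-anatomical and reduced to
#' luminance (the mass is already bright).  The polarity-normalised image
#' is lightly despeckled (Gaussian, sigma 2 px), the lesion is located by
#' scale-space blob detection (which also estimates its radius), and the
#' contour is initialised as a circle 1.6x the estimated radius around the
#' blob.  The evolution then runs in two phases on the
#' [inverseGaussianGradient()] edge map: a short balloon phase that
#' shrinks the circle onto the mass, followed by a balloon-free phase
#' (advection + curvature only) that settles on the edge without eroding
#' through weak-gradient gaps.  The largest 4-connected component of the
#' result is returned; an empty result is a valid output meaning "no
#' lesion found".
#'
#' When `seedPoint` is given (GUI-parity mode) the blob search is skipped
#' and the initial circle has radius 25% of `min(H, W)` at that point.
#'
#' @param image grayscale matrix (ultrasound) or RGB array (optical /
#'   pseudo-anatomical) in \[0, 1\].
#' @param config a [GACConfig-class]; `iterations` is the total budget
#'   across both phases and `balloon` drives the first phase.
#' @param seedPoint optional (row, col) in pixels for the initial circle.
#' @return binary integer matrix, same H x W as the input.
#' @export
segmentLesion <- function(image, config = GACConfig(), seedPoint = NULL) {
  isUS <- is.matrix(image)
  gray <- luminance(image)
  if (any(gray < 0) || any(gray > 1)) stop("image must lie in [0, 1]")
  H <- nrow(gray); W <- ncol(gray)
  work <- gaussianBlur(if (isUS) 1 - gray else gray, 2)
  if (!isUS) {
    ## optical / pseudo-anatomical images carry a black lower band that is
    ## background by construction; its edge otherwise reads as the
    ## strongest "blob" and edge in the image.  Replace near-black pixels
    ## by the median tissue intensity so neither the blob search nor the
    ## contour can settle on the band boundary.
    band <- work < 0.10
    if (any(band) && !all(band)) {
      work[band] <- median(work[!band])
      work <- gaussianBlur(work, 2)
    }
  }
  if (is.null(seedPoint)) {
    blob <- .detectLesionBlob(work)
    center <- blob$center
    initR <- min(max(1.6 * blob$radius, 8), 0.45 * min(H, W))
    shrink <- as.integer(ceiling(initR - blob$radius)) + 3L
  } else {
    center <- seedPoint
    initR <- 0.25 * min(H, W)
    shrink <- as.integer(ceiling(0.4 * initR)) + 3L
  }
  init <- if (config@init == "bounding_box") {
    m <- matrix(0L, H, W)
    m[max(1, round(0.1 * H)):round(0.9 * H),
      max(1, round(0.1 * W)):round(0.9 * W)] <- 1L
    m
  } else {
    .circleLevelSet(H, W, center, initR)
  }
  g <- inverseGaussianGradient(work, config@alpha, config@sigma)
  it1 <- min(shrink, config@iterations)
  cfg1 <- config; cfg1@iterations <- as.integer(it1)
  u <- morphGAC(g, cfg1, init)
  it2 <- as.integer(config@iterations - it1)
  if (any(u > 0) && it2 > 0L) {
    cfg2 <- config; cfg2@iterations <- it2; cfg2@balloon <- 0
    u <- morphGAC(g, cfg2, u)
  }
  largestComponent(u)
}
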