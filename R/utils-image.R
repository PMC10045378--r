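## Low-level image helpers shared by the phantom, segmentation and
## translation modules.  All images are numeric arrays in [0, 1]:
## grayscale H x W matrices, RGB H x W x 3 arrays (row-major origin
## top-left, 0-based offsets at the API surface where documented).

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Convert an image to grayscale luminance
#'
#' RGB images are reduced with ITU-R BT.601 weights (0.299, 0.587, 0.114);
#' grayscale matrices are returned unchanged.
#'
#' @param image numeric matrix (H x W) or array (H x W x 3) in \[0, 1\].
#' @return numeric H x W matrix.
#' @export
luminance <- function(image) {
  if (is.matrix(image)) return(image)
  if (length(dim(image)) == 3L) {
    d <- dim(image)
    if (d[3] >= 3L) {
      return(0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3])
    }
    return(image[, , 1])
  }
  stop("image must be an H x W matrix or an H x W x C array")
}

#' Replicate a grayscale image over three channels
#'
#' @param image numeric H x W matrix.
#' @return H x W x 3 array.
#' @export
grayToRGB <- function(image) {
  stopifnot(is.matrix(image))
  array(rep(image, 3L), dim = c(dim(image), 3L))
}

## Separable correlation with replicate ("nearest") boundary handling,
## matching scipy.ndimage mode = "nearest".  `kernel` is applied along one
## axis via index-clamped shifts; cheap for the small kernels used here.
.correlate1d <- function(img, kernel, axis) {
  r <- (length(kernel) - 1L) %/% 2L
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (t in seq(-r, r)) {
    w <- kernel[t + r + 1L]
    if (w == 0) next
    if (axis == 1L) {
      idx <- pmin(pmax(seq_len(H) + t, 1L), H)
      out <- out + w * img[idx, , drop = FALSE]
    } else {
      idx <- pmin(pmax(seq_len(W) + t, 1L), W)
      out <- out + w * img[, idx, drop = FALSE]
    }
  }
  out
}

## Gaussian kernel (and its first derivative) discretised exactly as in
## scipy.ndimage: radius = round(truncate * sigma), normalised Gaussian,
## derivative = (x / sigma^2) * phi(x) in correlation orientation.
.gaussianKernel1d <- function(sigma, order = 0L, truncate = 4) {
  r <- as.integer(truncate * sigma + 0.5)
  x <- seq(-r, r)
  phi <- exp(-0.5 * x^2 / sigma^2)
  phi <- phi / sum(phi)
  if (order == 0L) return(phi)
  if (order == 1L) return(rev(-x / sigma^2 * phi))
  stop("order must be 0 or 1")
}

#' Gaussian blur with replicate boundary
#'
#' @param image numeric H x W matrix in any range.
#' @param sigma Gaussian standard deviation in pixels.
#' @param truncate kernel cut-off in standard deviations.
#' @return blurred matrix, same shape.
#' @export
gaussianBlur <- function(image, sigma, truncate = 4) {
  k <- .gaussianKernel1d(sigma, 0L, truncate)
  .correlate1d(.correlate1d(image, k, 1L), k, 2L)
}

## |grad(G_sigma * image)|: derivative-of-Gaussian along each axis,
## smoothing along the other, replicate boundary.
.gaussianGradientMagnitude <- function(image, sigma, truncate = 4) {
  ks <- .gaussianKernel1d(sigma, 0L, truncate)
  kd <- .gaussianKernel1d(sigma, 1L, truncate)
  gr <- .correlate1d(.correlate1d(image, kd, 1L), ks, 2L)
  gc <- .correlate1d(.correlate1d(image, ks, 1L), kd, 2L)
  sqrt(gr^2 + gc^2)
}

## np.gradient-style finite differences: central in the interior, one-sided
## at the boundary rows/cols.  Returns list(drow, dcol).
.gradient2d <- function(u) {
  H <- nrow(u); W <- ncol(u)
  dr <- matrix(0, H, W)
  dc <- matrix(0, H, W)
  if (H >= 2L) {
    dr[1L, ] <- u[2L, ] - u[1L, ]
    dr[H, ] <- u[H, ] - u[H - 1L, ]
    if (H >= 3L) dr[2:(H - 1L), ] <- (u[3:H, ] - u[1:(H - 2L), ]) / 2
  }
  if (W >= 2L) {
    dc[, 1L] <- u[, 2L] - u[, 1L]
    dc[, W] <- u[, W] - u[, W - 1L]
    if (W >= 3L) dc[, 2:(W - 1L)] <- (u[, 3:W] - u[, 1:(W - 2L)]) / 2
  }
  list(dr, dc)
}

#' Largest 4-connected component of a binary mask
#'
#' @param mask binary H x W matrix.
#' @return binary matrix keeping only the largest component (all zeros if
#'   the mask is empty).
#' @export
largestComponent <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  if (!any(m == 1L)) return(m * 0L)
  lab <- cpp_label4(m)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  matrix(as.integer(lab == keep), nrow(mask), ncol(mask))
}

## Number of 4-connected components (used by phantom validity checks).
.nComponents4 <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  if (!any(m == 1L)) return(0L)
  max(cpp_label4(m))
}

#' Read a PNG image as a numeric array in \[0, 1\]
#'
#' Alpha channels are dropped; gray+alpha collapses to the gray channel.
#'
#' @param path PNG file path.
#' @return H x W matrix or H x W x 3 array.
#' @export
readImagePNG <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 2L) img <- img[, , 1L]
    else if (dim(img)[3] == 4L) img <- img[, , 1:3]
  }
  img
}

#' Write a numeric image in \[0, 1\] as an 8-bit PNG
#'
#' @param image H x W matrix or H x W x 3 array in \[0, 1\].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeImagePNG <- function(image, path) {
  if (any(image < 0) || any(image > 1)) {
    stop("image intensities must lie in [0, 1]")
  }
  png::writePNG(image, target = path)
  invisible(path)
}

#' Largest-remainder apportionment
#'
#' Distribute `n` items over categories proportionally to `weights`,
#' assigning floors first and the remaining items to the largest fractional
#' parts.  Ties are broken toward the category with the larger weight,
#' then toward the earlier index.
#'
#' @param n total number of items.
#' @param weights nonnegative weights (need not sum to 1).
#' @return integer vector of counts summing to `n`.
#' @export
apportion <- function(n, weights) {
  stopifnot(n >= 0, all(weights >= 0), sum(weights) > 0)
  quota <- n * weights / sum(weights)
  base <- floor(quota)
  rem <- as.integer(round(n - sum(base)))
  if (rem > 0L) {
    frac <- quota - base
    ord <- order(-frac, -weights, seq_along(weights))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}
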