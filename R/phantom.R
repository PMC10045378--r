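## Synthetic paired-domain phantom generator.  Emulates the statistical
## structure of the two training domains: grayscale speckle ultrasound
## images with dark lesions and acoustic artifacts, and colour optical
## tissue images with light "etched" lesions over a black lower band.

.PHANTOM_DEFAULTS <- list(
  tissue_level = 0.45,     # mean background intensity, US domain
  lesion_level = 0.15,     # mean lesion intensity, US domain (darker)
  speckle_cov = 0.40,      # coefficient of variation of the speckle field
  speckle_grain = 1.2,     # speckle correlation scale, px
  edge_blur_benign = 1.0,  # lesion margin blur, px: benign margins sharp,
  edge_blur_malignant = 2.5,  # malignant margins blurred and indistinct
  depth_decay_rate = 0.6,  # exp(-rate * depth_fraction)
  shadow_gain = 0.6,       # multiplicative gain of the posterior shadow
  enhancement_gain = 1.3,  # multiplicative gain of posterior enhancement
  tissue_rgb = c(0.80, 0.52, 0.50),  # optical tissue base colour
  lesion_rgb = c(0.97, 0.95, 0.93),  # optical lesion (etched) colour
  lesion_blend = 0.65,     # lesion colour blend factor, optical domain
  texture_amp = 0.06,      # low-frequency optical texture amplitude
  black_band_range = c(0.1, 0.3)  # fractional height of the black band
)

#' Rasterise a lesion mask from its parametric spec
#'
#' The boundary is an ellipse with fractional radii `radii(spec)` whose
#' radius at polar angle theta is modulated by
#' `1 + irregularity * sum_j a_j cos(j*theta + phi_j)`, with harmonic
#' amplitudes (normalised to unit total magnitude) and phases drawn from
#' the spec's seeded generator.  The modulation factor is clamped at 0.25
#' so the region stays star-shaped around its center, which keeps the
#' rasterised mask a single 4-connected component.
#'
#' @param spec a [LesionSpec-class].
#' @param height,width output mask size in pixels.
#' @return binary height x width matrix; all-zero for class "normal".
#' @examples
#' m <- makeLesionMask(LesionSpec("benign", irregularity = 0), 100, 100)
#' sum(m)  # close to pi * 15^2
#' @export
makeLesionMask <- function(spec, height, width) {
  stopifnot(is(spec, "LesionSpec"), height >= 1, width >= 1)
  if (spec@classLabel == "normal") {
    return(matrix(0L, height, width))
  }
  nl <- spec@lobes
  harm <- withr::with_seed(spec@seed, {
    if (nl > 0L) {
      a <- rnorm(nl)
      a <- a / max(sum(abs(a)), 1e-12)
      list(a = a, phi = runif(nl, 0, 2 * pi))
    } else list(a = numeric(0), phi = numeric(0))
  })
  cr <- spec@center[1] * height
  cc <- spec@center[2] * width
  rr <- spec@radii[1] * height
  rc <- spec@radii[2] * width
  u <- ((seq_len(height) - 0.5) - cr) / rr   # normalised row offset
  v <- ((seq_len(width) - 0.5) - cc) / rc    # normalised col offset
  U <- matrix(u, height, width)
  V <- matrix(v, height, width, byrow = TRUE)
  rho <- sqrt(U^2 + V^2)
  boundary <- matrix(1, height, width)
  if (nl > 0L && spec@irregularity > 0) {
    theta <- atan2(U, V)
    pert <- 0
    for (j in seq_len(nl)) {
      pert <- pert + harm$a[j] * cos(j * theta + harm$phi[j])
    }
    boundary <- pmax(1 + spec@irregularity * pert, 0.25)
  }
  mask <- matrix(as.integer(rho <= boundary), height, width)
  if (!any(mask > 0)) stop("degenerate lesion: mass lies outside the image")
  largestComponent(mask)
}

## Multiplicative speckle field: Rayleigh envelope samples smoothed to the
## grain scale, then affinely renormalised to mean 1 and the target
## coefficient of variation (smoothing alone would wash the contrast out
## of the fully-developed-speckle regime).
.speckleField <- function(height, width, cov, grain) {
  raw <- matrix(sqrt(-2 * log(runif(height * width))), height, width)
  s <- gaussianBlur(raw, grain)
  s <- 1 + (s - mean(s)) / max(sd(s), 1e-12) * cov
  pmax(s, 0.02)
}

## Lesion margin blur by tumour class: malignant borders are blurred and
## indistinct, benign borders comparatively sharp.  Clamped at 0.35x the
## lesion's equivalent radius so the blur (a margin property) never
## washes out a small mass's dark core — the dark-in-ultrasound /
## light-in-optical polarity must hold for every rendered sample.
.edgeBlur <- function(spec, mask) {
  p <- .PHANTOM_DEFAULTS
  blur <- if (spec@classLabel == "malignant") p$edge_blur_malignant
          else p$edge_blur_benign
  area <- sum(mask)
  if (area > 0) blur <- min(blur, 0.35 * sqrt(area / pi))
  max(blur, 0.5)
}

#' Render the ultrasound-domain phantom image
#'
#' Background tissue is a multiplicative speckle field around the tissue
#' level; lesion pixels are rendered darker (masses appear as dark regions
#' in B-mode images).  Lesion margins are blurred by a class-dependent
#' amount (malignant masses have indistinct borders; benign margins stay
#' comparatively sharp).  Optional acoustic artifacts: `"depth_decay"`
#' multiplies intensity by a decaying exponential of depth; `"shadow"` /
#' `"enhancement"` darken / brighten the column band posterior (below) the
#' lesion.
#'
#' @param mask binary lesion mask (H x W).
#' @param spec the generating [LesionSpec-class].
#' @param artifacts character subset of c("shadow", "enhancement",
#'   "depth_decay").
#' @param seed integer RNG seed; defaults to the spec seed.
#' @return grayscale H x W matrix in \[0, 1\].
#' @export
renderUltrasound <- function(mask, spec, artifacts = character(),
                             seed = spec@seed) {
  stopifnot(is.matrix(mask))
  p <- .PHANTOM_DEFAULTS
  H <- nrow(mask); W <- ncol(mask)
  level <- p$tissue_level * (1 - mask) + p$lesion_level * mask
  level <- gaussianBlur(level, .edgeBlur(spec, mask))
  img <- withr::with_seed(seed, {
    level * .speckleField(H, W, p$speckle_cov, p$speckle_grain)
  })
  if ("depth_decay" %in% artifacts) {
    decay <- exp(-p$depth_decay_rate * (seq_len(H) - 1) / H)
    img <- img * decay
  }
  post <- intersect(artifacts, c("shadow", "enhancement"))
  if (length(post) && any(mask > 0)) {
    cols <- range(which(colSums(mask) > 0))
    bottom <- max(which(rowSums(mask) > 0))
    if (bottom < H) {
      gain <- if ("shadow" %in% post) p$shadow_gain else p$enhancement_gain
      img[(bottom + 1):H, cols[1]:cols[2]] <-
        img[(bottom + 1):H, cols[1]:cols[2]] * gain
    }
  }
  clamp01(img)
}

## Smooth low-frequency noise: coarse seeded grid, bilinearly interpolated
## up to H x W.
.lowFreqNoise <- function(height, width, grid = 8L) {
  g <- matrix(rnorm(grid * grid), grid, grid)
  rowPos <- seq(1, height, length.out = grid)
  colPos <- seq(1, width, length.out = grid)
  tmp <- apply(g, 2, function(col) {
    stats::approx(rowPos, col, xout = seq_len(height))$y
  })
  t(apply(tmp, 1, function(row) {
    stats::approx(colPos, row, xout = seq_len(width))$y
  }))
}

#' Render the optical-domain phantom image
#'
#' Pinkish textured tissue with the lesion region blended toward white
#' (mimicking thermally etched masses, which look lighter than the
#' surrounding tissue) and a black band over the lower part of the image.
#' The band height is drawn uniformly from 10--30% of the image height
#' unless given; when a lesion is present the band is clipped to start
#' below it.
#'
#' @param mask binary lesion mask (H x W).
#' @param spec the generating [LesionSpec-class].
#' @param seed integer RNG seed; defaults to the spec seed.
#' @param blackBand optional fixed fractional band height in \[0, 1\).
#' @return RGB H x W x 3 array in \[0, 1\].
#' @export
renderOptical <- function(mask, spec, seed = spec@seed, blackBand = NULL) {
  stopifnot(is.matrix(mask))
  p <- .PHANTOM_DEFAULTS
  H <- nrow(mask); W <- ncol(mask)
  img <- withr::with_seed(seed, {
    tint <- runif(3, -0.04, 0.04)
    band <- if (is.null(blackBand)) {
      runif(1, p$black_band_range[1], p$black_band_range[2])
    } else blackBand
    out <- array(0, dim = c(H, W, 3))
    blend <- p$lesion_blend * gaussianBlur(mask, .edgeBlur(spec, mask))
    for (ch in 1:3) {
      tissue <- p$tissue_rgb[ch] + tint[ch] +
        p$texture_amp * .lowFreqNoise(H, W)
      out[, , ch] <- tissue * (1 - blend) + p$lesion_rgb[ch] * blend
    }
    attr(out, "band") <- band
    out
  })
  band <- attr(img, "band")
  attr(img, "band") <- NULL
  bandTop <- floor(H * (1 - band)) + 1L
  if (any(mask > 0)) {
    bandTop <- max(bandTop, max(which(rowSums(mask) > 0)) + 3L)
  }
  if (bandTop <= H) img[bandTop:H, , ] <- 0
  clamp01(img)
}

#' Sample a lesion spec for a given tumour class
#'
#' Centers and radii are drawn from ranges that keep the mass inside the
#' upper tissue region (clear of the optical black band): center row in
#' \[0.25, 0.55\], center col in \[0.30, 0.70\], fractional radii in
#' \[0.08, 0.18\].  Irregularity and lobes take the class defaults of
#' [LesionSpec()].
#'
#' @param classLabel "normal", "benign" or "malignant".
#' @param seed integer seed.
#' @return a [LesionSpec-class].
#' @export
sampleLesionSpec <- function(classLabel, seed) {
  withr::with_seed(seed, {
    LesionSpec(classLabel,
               center = c(runif(1, 0.25, 0.55), runif(1, 0.30, 0.70)),
               radii = c(runif(1, 0.08, 0.18), runif(1, 0.08, 0.18)),
               seed = seed)
  })
}

#' Render a full dual-domain phantom pair
#'
#' @param spec a [LesionSpec-class].
#' @param height,width image size in pixels.
#' @param artifacts "auto" (seeded draw: depth decay with probability 0.7;
#'   shadow / enhancement / none with probability 0.35/0.35/0.30) or an
#'   explicit character vector.
#' @return a [PhantomPair-class].
#' @export
renderPhantomPair <- function(spec, height = 256L, width = 256L,
                              artifacts = "auto") {
  mask <- makeLesionMask(spec, height, width)
  if (identical(artifacts, "auto")) {
    artifacts <- withr::with_seed(spec@seed + 3L, {
      a <- character()
      if (runif(1) < 0.7) a <- c(a, "depth_decay")
      if (spec@classLabel != "normal") {
        u <- runif(1)
        if (u < 0.35) a <- c(a, "shadow")
        else if (u < 0.70) a <- c(a, "enhancement")
      }
      a
    })
  }
  us <- renderUltrasound(mask, spec, artifacts, seed = spec@seed + 1L)
  opt <- renderOptical(mask, spec, seed = spec@seed + 2L)
  new("PhantomPair", usImage = us, opticalImage = opt,
      mask = mask, spec = spec, artifacts = artifacts)
}

#' Generate a seeded phantom dataset on disk
#'
#' Writes `n` phantom pairs in BUSI layout under `outDir`: ultrasound
#' images and masks in `us/`, optical images and masks in `optical/`,
#' each as `"<class> (<index>).png"` + `"<class> (<index>)_mask.png"`
#' (8-bit PNG), plus `manifest.csv` with columns
#' `id,class,center_r,center_c,rad_r,rad_c,irregularity,seed`.  Class
#' counts follow largest-remainder apportionment of `classMix`; everything
#' is a deterministic function of `seed`.
#'
#' @param n number of samples (>= 1).
#' @param classMix weights for (normal, benign, malignant); default is the
#'   133:437:210 mix of the BUSI cohort.
#' @param outDir output directory (created if needed).
#' @param seed master seed.
#' @param height,width image size in pixels.
#' @return the manifest as a data.frame, invisibly.
#' @export
generateDataset <- function(n, classMix = c(133, 437, 210), outDir,
                            seed = 1L, height = 256L, width = 256L) {
  stopifnot(n >= 1, length(classMix) == 3L, all(classMix >= 0))
  counts <- apportion(n, classMix)
  classes <- rep(c("normal", "benign", "malignant"), counts)
  index <- unlist(lapply(counts, seq_len))
  seeds <- withr::with_seed(seed, sample.int(2147480000L, n))
  dirUS <- file.path(outDir, "us")
  dirOpt <- file.path(outDir, "optical")
  for (d in c(dirUS, dirOpt)) {
    if (!dir.exists(d) && !dir.create(d, recursive = TRUE)) {
      stop("cannot create output directory: ", d)
    }
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- sampleLesionSpec(classes[i], seeds[i])
    pair <- renderPhantomPair(spec, height, width)
    id <- sprintf("%s (%d)", classes[i], index[i])
    writeImagePNG(pair@usImage, file.path(dirUS, paste0(id, ".png")))
    writeImagePNG(pair@mask + 0, file.path(dirUS, paste0(id, "_mask.png")))
    writeImagePNG(pair@opticalImage, file.path(dirOpt, paste0(id, ".png")))
    writeImagePNG(pair@mask + 0, file.path(dirOpt, paste0(id, "_mask.png")))
    rows[[i]] <- data.frame(
      id = id, class = classes[i],
      center_r = spec@center[1], center_c = spec@center[2],
      rad_r = spec@radii[1], rad_c = spec@radii[2],
      irregularity = spec@irregularity, seed = spec@seed)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(outDir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
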