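## The modified CycleGAN objective: adversarial losses for the two GAN
## units, the L1 cycle-reconstruction loss, and the "opposite" loss that
## replaces the usual identity loss — each generator applied to the
## *negative* of an own-domain image must reproduce that image, rewarding
## contrast inversion across domains (dark ultrasound masses -> light
## optical masses).

.EPS_SCORE <- 1e-7

#' Pixelwise negative image
#'
#' @param image numeric array in \[0, 1\].
#' @return `1 - image` (channelwise).
#' @examples
#' negativeImage(matrix(0, 2, 2))  # all ones
#' @export
negativeImage <- function(image) {
  if (any(image < 0) || any(image > 1)) {
    stop("image intensities must lie in [0, 1]")
  }
  1 - image
}

## Apply a generator (a network built by buildModels(), or any plain R
## function in tests) to an image, adapting channel count at the network
## input: gray replicated to RGB, RGB reduced to luminance.  Single-channel
## outputs collapse to a matrix.
.applyGenerator <- function(g, x) {
  if (is.function(g)) return(g(x))
  want <- g$inCh
  have <- if (is.matrix(x)) 1L else dim(x)[3]
  if (want == 3L && have == 1L) x <- grayToRGB(if (is.matrix(x)) x else x[, , 1])
  if (want == 1L && have == 3L) x <- luminance(x)
  out <- .netForward(g, x, keepCache = FALSE)$out
  if (dim(out)[3] == 1L) out <- out[, , 1]
  out
}

.asBatch <- function(x) {
  if (is.list(x)) x else list(x)
}

## Batch mean of a per-image scalar; an empty batch contributes 0.
.batchMean <- function(batch, f) {
  if (!length(batch)) return(0)
  mean(vapply(batch, f, numeric(1)))
}

.meanAbs <- function(a, b) {
  if (!identical(dim(.as3d(a)), dim(.as3d(b)))) {
    stop("shape mismatch between image and its reconstruction")
  }
  mean(abs(a - b))
}

#' Adversarial (GAN) losses from discriminator scores
#'
#' Cross-entropy form: the discriminator loss is
#' `-mean(log D(real)) - mean(log(1 - D(fake)))`; the generator loss is
#' the non-saturating `-mean(log D(fake))`.  With `form = "lsq"` the
#' least-squares variants are returned instead.  Scores are clamped to
#' `[1e-7, 1 - 1e-7]` before taking logs.
#'
#' @param dRealScores,dFakeScores discriminator score arrays in (0, 1).
#' @param form "log" (default) or "lsq".
#' @return list with elements `discriminator` and `generator`.
#' @examples
#' adversarialLoss(0.5, 0.5)$discriminator  # 2 * log(2)
#' @export
adversarialLoss <- function(dRealScores, dFakeScores,
                            form = c("log", "lsq")) {
  form <- match.arg(form)
  if (form == "lsq") {
    return(list(discriminator = mean((dRealScores - 1)^2) +
                                mean(dFakeScores^2),
                generator = mean((dFakeScores - 1)^2)))
  }
  r <- pmin(pmax(dRealScores, .EPS_SCORE), 1 - .EPS_SCORE)
  f <- pmin(pmax(dFakeScores, .EPS_SCORE), 1 - .EPS_SCORE)
  list(discriminator = -mean(log(r)) - mean(log(1 - f)),
       generator = -mean(log(f)))
}

#' Cycle-consistency loss
#'
#' Mean L1 discrepancy of the round-trip reconstructions:
#' `mean|G_US(G_PA(x)) - x| + mean|G_PA(G_US(y)) - y|`, averaged over
#' channels, pixels and batch.
#'
#' @param xBatch ultrasound-domain image or list of images.
#' @param yBatch optical-domain image or list of images.
#' @param gPA,gUS generators (networks from [buildModels()] or plain
#'   functions).
#' @return nonnegative scalar.
#' @export
cycleLoss <- function(xBatch, yBatch, gPA, gUS) {
  xs <- .asBatch(xBatch); ys <- .asBatch(yBatch)
  t1 <- .batchMean(xs, function(x) {
    .meanAbs(.applyGenerator(gUS, .applyGenerator(gPA, x)), x)
  })
  t2 <- .batchMean(ys, function(y) {
    .meanAbs(.applyGenerator(gPA, .applyGenerator(gUS, y)), y)
  })
  t1 + t2
}

#' Opposite (contrast-inversion) loss
#'
#' Replaces the CycleGAN identity loss: each generator fed the *negative*
#' of an own-domain image must return that image,
#' `mean|G_US(neg(x)) - x| + mean|G_PA(neg(y)) - y|`.  A generator that
#' realises exact contrast inversion scores 0.
#'
#' @inheritParams cycleLoss
#' @return nonnegative scalar.
#' @export
oppositeLoss <- function(xBatch, yBatch, gPA, gUS) {
  xs <- .asBatch(xBatch); ys <- .asBatch(yBatch)
  t1 <- .batchMean(xs, function(x) {
    .meanAbs(.applyGenerator(gUS, negativeImage(x)), x)
  })
  t2 <- .batchMean(ys, function(y) {
    .meanAbs(.applyGenerator(gPA, negativeImage(y)), y)
  })
  t1 + t2
}

#' Weighted total generator objective
#'
#' `lambda_gan * (L_gan_PA + L_gan_US) / 2 + lambda_cycle * L_cycle +
#' lambda_opposite * L_opposite` (the two adversarial generator terms
#' enter as their mean).
#'
#' @param report list (or one-row data.frame) with components `LganPA`,
#'   `LganUS`, `Lcycle`, `Lopposite`.
#' @param weights a [LossWeights-class].
#' @return scalar total loss.
#' @export
totalLoss <- function(report, weights = LossWeights()) {
  validObject(weights)
  weights@lambdaGan * (report$LganPA + report$LganUS) / 2 +
    weights@lambdaCycle * report$Lcycle +
    weights@lambdaOpposite * report$Lopposite
}

## Resolve a model/training configuration against defaults.
.resolveModelConfig <- function(config = list()) {
  defaults <- list(
    image_size = 256L, base_filters = 64L, residual_blocks = NULL,
    lambda_gan = 1, lambda_cycle = 10, lambda_opposite = 0.3,
    epochs = 30L, lr = 2e-4, seed = 1L,
    adversarial_form = "log", buffer_size = 50L,
    checkpoint_dir = NULL, checkpoint_every = 10L, verbose = FALSE)
  cfg <- utils::modifyList(defaults, config[!vapply(config, is.null,
                                                    logical(1))])
  if (is.null(cfg$residual_blocks)) {
    cfg$residual_blocks <- if (cfg$image_size <= 128L) 6L else 9L
  }
  if (cfg$image_size %% 4L != 0L || cfg$image_size < 32L) {
    stop("image_size must be >= 32 and divisible by 4")
  }
  if (!cfg$adversarial_form %in% c("log", "lsq")) {
    stop("adversarial_form must be 'log' or 'lsq'")
  }
  cfg
}

.buildGenerator <- function(cin, cout, nf, nres) {
  layers <- list(
    .convLayer(cin, nf, 7L, 1L, 3L), .inormLayer(nf), .reluLayer(),
    .convLayer(nf, 2L * nf, 3L, 2L, 1L), .inormLayer(2L * nf), .reluLayer(),
    .convLayer(2L * nf, 4L * nf, 3L, 2L, 1L), .inormLayer(4L * nf),
    .reluLayer())
  for (i in seq_len(nres)) {
    layers[[length(layers) + 1L]] <- .resblockLayer(4L * nf)
  }
  layers <- c(layers, list(
    .upsampleLayer(), .convLayer(4L * nf, 2L * nf, 3L, 1L, 1L),
    .inormLayer(2L * nf), .reluLayer(),
    .upsampleLayer(), .convLayer(2L * nf, nf, 3L, 1L, 1L),
    .inormLayer(nf), .reluLayer(),
    .convLayer(nf, cout, 7L, 1L, 3L), .tanh01Layer()))
  list(layers = layers, inCh = cin, outCh = cout)
}

.buildDiscriminator <- function(cin, nf) {
  list(layers = list(
    .convLayer(cin, nf, 4L, 2L, 1L), .lreluLayer(),
    .convLayer(nf, 2L * nf, 4L, 2L, 1L), .inormLayer(2L * nf), .lreluLayer(),
    .convLayer(2L * nf, 4L * nf, 4L, 2L, 1L), .inormLayer(4L * nf),
    .lreluLayer(),
    .convLayer(4L * nf, 8L * nf, 4L, 2L, 1L), .inormLayer(8L * nf),
    .lreluLayer(),
    .convLayer(8L * nf, 1L, 4L, 1L, 1L), .sigmoidLayer()),
    inCh = cin, outCh = 1L)
}

#' Build the CycleGAN model bundle
#'
#' Generators follow the standard residual CycleGAN layout: a 7x7
#' stride-1 front end, two stride-2 down-convolutions, `residual_blocks`
#' residual blocks (6 at image sizes <= 128 px, 9 above), two
#' nearest-neighbour-upsample + convolution stages, and a 7x7 output
#' convolution whose tanh output is rescaled to \[0, 1\].  Discriminators
#' are PatchGAN stacks of four stride-2 convolutions followed by a
#' 1-channel sigmoid score map.  G_PA maps 1-channel ultrasound to
#' 3-channel colour; G_US the reverse.  All weights are seeded.
#'
#' @param config named list overriding the defaults: `image_size` (256),
#'   `base_filters` (64), `residual_blocks`, `lambda_gan` (1),
#'   `lambda_cycle` (10), `lambda_opposite` (0.3), `epochs` (30),
#'   `lr` (2e-4), `seed` (1), `adversarial_form` ("log" or "lsq"),
#'   `buffer_size` (50), `checkpoint_dir`, `checkpoint_every`.
#' @return a [CycleGANModel-class].
#' @export
buildModels <- function(config = list()) {
  cfg <- .resolveModelConfig(config)
  nf <- as.integer(cfg$base_filters)
  nets <- withr::with_seed(cfg$seed, {
    list(gPA = .buildGenerator(1L, 3L, nf, cfg$residual_blocks),
         gUS = .buildGenerator(3L, 1L, nf, cfg$residual_blocks),
         dPA = .buildDiscriminator(3L, nf),
         dUS = .buildDiscriminator(1L, nf))
  })
  new("CycleGANModel", gPA = nets$gPA, gUS = nets$gUS, dPA = nets$dPA,
      dUS = nets$dUS,
      weights = LossWeights(cfg$lambda_gan, cfg$lambda_cycle,
                            cfg$lambda_opposite),
      config = cfg)
}

#' Translate an ultrasound image to a pseudo-anatomical display
#'
#' Applies the trained G_PA generator.  Deterministic given the model
#' weights; inference only (no gradient bookkeeping).
#'
#' @param model a [CycleGANModel-class].
#' @param usImage grayscale H x W matrix in \[0, 1\].
#' @return H x W x 3 RGB array in \[0, 1\].
#' @export
translateImage <- function(model, usImage) {
  if (!is.matrix(usImage)) {
    stop("usImage must be a single-channel (grayscale) matrix")
  }
  if (any(usImage < 0) || any(usImage > 1)) {
    stop("usImage must lie in [0, 1]")
  }
  .netForward(model@gPA, usImage, keepCache = FALSE)$out
}
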