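setClassUnion("numericOrCharacter", c("numeric", "character"))

#' LesionSpec: parametric lesion geometry
#'
#' Describes one simulated breast mass shared by the ultrasound and optical
#' phantom renderers.  The boundary is an ellipse whose radius at polar
#' angle theta is modulated by seeded radial harmonics:
#' `r(theta) = 1 + irregularity * sum_j a_j cos(j theta + phi_j)`.
#' Benign masses default to small, low-order perturbations (regular
#' shapes); malignant masses to larger, higher-order ones (irregular,
#' spiculated shapes); `normal` means no mass at all.
#'
#' @slot center numeric(2), (row, col) as fractions of image height/width
#'   in \[0, 1\].
#' @slot radii numeric(2), (r_row, r_col) as fractions of image
#'   height/width, > 0.
#' @slot irregularity radial perturbation amplitude, unitless >= 0
#'   (0 = exact ellipse).
#' @slot lobes number of radial perturbation harmonics, integer >= 0.
#' @slot classLabel one of "normal", "benign", "malignant".
#' @slot seed integer seed for the harmonic amplitudes/phases.
#' @export
setClass("LesionSpec", representation(
  center = "numeric",
  radii = "numeric",
  irregularity = "numeric",
  lobes = "integer",
  classLabel = "character",
  seed = "integer"
))

setValidity("LesionSpec", function(object) {
  msg <- character()
  if (length(object@center) != 2L || any(object@center < 0) ||
      any(object@center > 1)) {
    msg <- c(msg, "center must be two fractions in [0, 1]")
  }
  if (length(object@radii) != 2L || any(object@radii <= 0)) {
    msg <- c(msg, "radii must be two positive fractions")
  }
  if (object@irregularity < 0) msg <- c(msg, "irregularity must be >= 0")
  if (object@lobes < 0L) msg <- c(msg, "lobes must be >= 0")
  if (!object@classLabel %in% c("normal", "benign", "malignant")) {
    msg <- c(msg, "classLabel must be normal, benign or malignant")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a LesionSpec
#'
#' Class-specific defaults encode the geometric regularity contrast between
#' tumour types: benign masses get irregularity 0.05 with 3 harmonics,
#' malignant 0.25 with 7, and `normal` carries no mass (the renderers
#' return an empty mask regardless of the other fields).
#'
#' @param classLabel "normal", "benign" or "malignant".
#' @param center (row, col) fractions in \[0, 1\].
#' @param radii (r_row, r_col) fractions of image height/width.
#' @param irregularity radial perturbation amplitude; default by class.
#' @param lobes number of radial harmonics; default by class.
#' @param seed integer seed for the boundary harmonics.
#' @return a [LesionSpec-class] object.
#' @examples
#' LesionSpec("benign", center = c(0.4, 0.5), radii = c(0.15, 0.12))
#' @export
LesionSpec <- function(classLabel = "benign", center = c(0.5, 0.5),
                       radii = c(0.15, 0.15), irregularity = NULL,
                       lobes = NULL, seed = 1L) {
  defaults <- switch(classLabel,
    normal = list(irr = 0, lobes = 0L),
    benign = list(irr = 0.05, lobes = 3L),
    malignant = list(irr = 0.25, lobes = 7L),
    stop("unknown classLabel: ", classLabel)
  )
  if (is.null(irregularity)) irregularity <- defaults$irr
  if (is.null(lobes)) lobes <- defaults$lobes
  new("LesionSpec", center = as.numeric(center), radii = as.numeric(radii),
      irregularity = as.numeric(irregularity), lobes = as.integer(lobes),
      classLabel = classLabel, seed = as.integer(seed))
}

#' PhantomPair: one synthetic sample in both imaging domains
#'
#' Holds the grayscale speckle ultrasound rendering and the colour optical
#' rendering of the same lesion geometry, with the shared ground-truth
#' mask.
#'
#' @slot usImage H x W grayscale matrix in \[0, 1\].
#' @slot opticalImage H x W x 3 RGB array in \[0, 1\].
#' @slot mask binary H x W matrix (1 = lesion).
#' @slot spec the generating [LesionSpec-class].
#' @slot artifacts character subset of c("shadow", "enhancement",
#'   "depth_decay") applied to the ultrasound rendering.
#' @export
setClass("PhantomPair", representation(
  usImage = "matrix",
  opticalImage = "array",
  mask = "matrix",
  spec = "LesionSpec",
  artifacts = "character"
))

setValidity("PhantomPair", function(object) {
  msg <- character()
  d <- dim(object@usImage)
  if (!identical(dim(object@mask), d)) {
    msg <- c(msg, "mask and usImage dimensions differ")
  }
  if (!identical(dim(object@opticalImage)[1:2], d)) {
    msg <- c(msg, "opticalImage spatial dimensions differ from usImage")
  }
  rng <- range(object@usImage, object@opticalImage)
  if (rng[1] < 0 || rng[2] > 1) msg <- c(msg, "intensities outside [0, 1]")
  if (!all(object@mask %in% c(0, 1))) msg <- c(msg, "mask must be binary")
  empty <- !any(object@mask > 0)
  if (object@spec@classLabel == "normal" && !empty) {
    msg <- c(msg, "normal sample must have an empty mask")
  }
  if (object@spec@classLabel != "normal" && empty) {
    msg <- c(msg, "non-normal sample must have a nonempty mask")
  }
  ok <- object@artifacts %in% c("shadow", "enhancement", "depth_decay")
  if (!all(ok)) msg <- c(msg, "unknown artifact name")
  if (length(msg)) msg else TRUE
})

#' ImageRecord: one source image with its reference masks
#'
#' @slot id record identifier (BUSI-style, e.g. "benign (12)").
#' @slot classLabel "normal", "benign" or "malignant".
#' @slot image grayscale matrix or RGB array in \[0, 1\].
#' @slot masks list of binary matrices (zero or more reference tracings;
#'   several manual tracings may exist for one lesion).
#' @slot sourcePath originating file path ("" for in-memory records).
#' @export
setClass("ImageRecord", representation(
  id = "character",
  classLabel = "character",
  image = "ANY",
  masks = "list",
  sourcePath = "character"
))

setValidity("ImageRecord", function(object) {
  msg <- character()
  d <- dim(object@image)[1:2]
  for (m in object@masks) {
    if (!identical(dim(m)[1:2], d)) {
      msg <- c(msg, "mask dimensions differ from image")
    }
  }
  if (!object@classLabel %in% c("normal", "benign", "malignant")) {
    msg <- c(msg, "bad classLabel")
  }
  if (object@classLabel == "normal" &&
      any(vapply(object@masks, function(m) any(m > 0), logical(1)))) {
    msg <- c(msg, "normal record must not have a nonempty mask")
  }
  if (length(msg)) msg else TRUE
})

#' DatasetSplit: stratified train/validation/test partition
#'
#' @slot train,val,test disjoint character vectors of record ids.
#' @slot fractions numeric(3) target fractions (default 0.80/0.05/0.15).
#' @export
setClass("DatasetSplit", representation(
  train = "character",
  val = "character",
  test = "character",
  fractions = "numeric"
))

setValidity("DatasetSplit", function(object) {
  ids <- c(object@train, object@val, object@test)
  msg <- character()
  if (anyDuplicated(ids)) msg <- c(msg, "partitions overlap")
  if (length(object@fractions) != 3L ||
      abs(sum(object@fractions) - 1) > 1e-8) {
    msg <- c(msg, "fractions must be three numbers summing to 1")
  }
  if (length(msg)) msg else TRUE
})

#' GACConfig: morphological geodesic active contour settings
#'
#' @slot alpha steepness of the inverse-Gaussian-gradient inversion
#'   (unitless, default 100).
#' @slot sigma Gaussian standard deviation of the edge filter in pixels
#'   (default 1.5).
#' @slot iterations number of contour-evolution steps (default 200).
#' @slot smoothing curvature-smoothing passes per iteration (default 1).
#' @slot balloon -1 (shrink), 0 (off) or +1 (grow); default -1.
#' @slot threshold level-set advection gate: "auto" (40th percentile of
#'   the edge map, as in the reference morphological-snakes
#'   implementation) or a fixed number in \[0, 1\].
#' @slot init initialisation rule, "circle_from_seed" or "bounding_box".
#' @export
setClass("GACConfig", representation(
  alpha = "numeric",
  sigma = "numeric",
  iterations = "integer",
  smoothing = "integer",
  balloon = "numeric",
  threshold = "numericOrCharacter",
  init = "character"
))

setValidity("GACConfig", function(object) {
  msg <- character()
  if (object@alpha <= 0) msg <- c(msg, "alpha must be > 0")
  if (object@sigma <= 0) msg <- c(msg, "sigma must be > 0")
  if (object@iterations < 0L) msg <- c(msg, "iterations must be >= 0")
  if (object@smoothing < 0L) msg <- c(msg, "smoothing must be >= 0")
  if (!object@balloon %in% c(-1, 0, 1)) msg <- c(msg, "balloon must be -1, 0 or +1")
  if (is.character(object@threshold) && !identical(object@threshold, "auto")) {
    msg <- c(msg, "threshold must be \"auto\" or a number")
  }
  if (!object@init %in% c("circle_from_seed", "bounding_box")) {
    msg <- c(msg, "init must be circle_from_seed or bounding_box")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GACConfig
#'
#' Defaults follow the segmentation protocol used throughout the package:
#' alpha = 100 and sigma = 1.5 for the edge-stopping map (the same settings
#' for ultrasound and pseudo-anatomical images), a shrinking balloon force,
#' 200 iterations with one curvature-smoothing pass each, and an adaptive
#' advection gate at the 40th percentile of the edge map.
#'
#' @param alpha,sigma,iterations,smoothing,balloon,threshold,init see
#'   [GACConfig-class].
#' @return a [GACConfig-class] object.
#' @export
GACConfig <- function(alpha = 100, sigma = 1.5, iterations = 200L,
                      smoothing = 1L, balloon = -1, threshold = "auto",
                      init = "circle_from_seed") {
  new("GACConfig", alpha = alpha, sigma = sigma,
      iterations = as.integer(iterations), smoothing = as.integer(smoothing),
      balloon = balloon, threshold = threshold, init = init)
}

#' LossWeights: weighting of the CycleGAN objective terms
#'
#' The cycle term is weighted 10x the adversarial term; the opposite
#' (contrast-inversion) term gets 0.03 x the cycle weight = 0.3.
#'
#' @slot lambdaGan adversarial weight (default 1).
#' @slot lambdaCycle cycle-consistency weight (default 10).
#' @slot lambdaOpposite opposite-loss weight (default 0.3).
#' @export
setClass("LossWeights", representation(
  lambdaGan = "numeric",
  lambdaCycle = "numeric",
  lambdaOpposite = "numeric"
))

setValidity("LossWeights", function(object) {
  if (object@lambdaGan < 0 || object@lambdaCycle < 0 ||
      object@lambdaOpposite < 0) {
    "loss weights must be >= 0"
  } else TRUE
})

#' Construct LossWeights
#' @param lambdaGan,lambdaCycle,lambdaOpposite nonnegative weights.
#' @return a [LossWeights-class] object.
#' @export
LossWeights <- function(lambdaGan = 1, lambdaCycle = 10,
                        lambdaOpposite = 0.3) {
  new("LossWeights", lambdaGan = lambdaGan, lambdaCycle = lambdaCycle,
      lambdaOpposite = lambdaOpposite)
}

#' CycleGANModel: the four networks plus loss weights
#'
#' `gPA` maps 1-channel ultrasound to 3-channel pseudo-anatomical images;
#' `gUS` maps 3-channel optical images to 1-channel ultrasound; `dPA` and
#' `dUS` are PatchGAN discriminators on the respective target domains with
#' per-patch sigmoid scores in (0, 1).
#'
#' @slot gPA,gUS,dPA,dUS network objects (see [buildModels()]).
#' @slot weights a [LossWeights-class].
#' @slot config resolved model configuration list.
#' @export
setClass("CycleGANModel", representation(
  gPA = "list",
  gUS = "list",
  dPA = "list",
  dUS = "list",
  weights = "LossWeights",
  config = "list"
))

#' MaskComparison: pixel-level comparison of two binary masks
#'
#' Confusion counts, centroids and areas between a reference and a
#' generated lesion mask, with the image-size normalisers used by the
#' centroid-error metric (the image diagonal) and the area-index metric
#' (the image area).
#'
#' @slot TP,FP,FN,TN pixel counts (TP+FP+FN+TN = H*W).
#' @slot centroidRef,centroidGen unweighted mask centroids (row, col) in
#'   pixels; NA when the mask is empty.
#' @slot sRef,sGen mask areas in pixels.
#' @slot H,W image dimensions in pixels.
#' @slot diagonal sqrt(H^2 + W^2), the centroid-error normaliser.
#' @slot areaNorm the area-index normaliser in pixels^2 (H*W by default).
#' @export
setClass("MaskComparison", representation(
  TP = "numeric", FP = "numeric", FN = "numeric", TN = "numeric",
  centroidRef = "numeric", centroidGen = "numeric",
  sRef = "numeric", sGen = "numeric",
  H = "numeric", W = "numeric",
  diagonal = "numeric", areaNorm = "numeric"
))

setValidity("MaskComparison", function(object) {
  msg <- character()
  if (abs(object@TP + object@FP + object@FN + object@TN -
          object@H * object@W) > 1e-6) {
    msg <- c(msg, "TP+FP+FN+TN must equal H*W")
  }
  if (abs(object@sRef - (object@TP + object@FN)) > 1e-6) {
    msg <- c(msg, "sRef must equal TP+FN")
  }
  if (abs(object@sGen - (object@TP + object@FP)) > 1e-6) {
    msg <- c(msg, "sGen must equal TP+FP")
  }
  if (length(msg)) msg else TRUE
})
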