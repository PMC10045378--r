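#' @rdname accessors
#' @export
setGeneric("classLabel", function(object) standardGeneric("classLabel"))

#' @rdname accessors
#' @export
setGeneric("usImage", function(object) standardGeneric("usImage"))

#' @rdname accessors
#' @export
setGeneric("opticalImage", function(object) standardGeneric("opticalImage"))

#' @rdname accessors
#' @export
setGeneric("lesionMask", function(object) standardGeneric("lesionMask"))

#' @rdname accessors
#' @export
setGeneric("lesionSpec", function(object) standardGeneric("lesionSpec"))

#' @rdname accessors
#' @export
setGeneric("lossWeights", function(object) standardGeneric("lossWeights"))

#' @rdname accessors
#' @export
setGeneric("recordMasks", function(object) standardGeneric("recordMasks"))

#' @rdname accessors
#' @export
setGeneric("recordImage", function(object) standardGeneric("recordImage"))

#' Accessors for cycleUS classes
#'
#' Slot accessors: `classLabel()` for [LesionSpec-class] /
#' [ImageRecord-class] / [PhantomPair-class]; `usImage()`,
#' `opticalImage()`, `lesionMask()` and `lesionSpec()` for
#' [PhantomPair-class]; `recordImage()` and `recordMasks()` for
#' [ImageRecord-class]; `lossWeights()` for [CycleGANModel-class].
#'
#' @param object the object to access.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
setMethod("classLabel", "LesionSpec", function(object) object@classLabel)
#' @rdname accessors
setMethod("classLabel", "PhantomPair", function(object) object@spec@classLabel)
#' @rdname accessors
setMethod("classLabel", "ImageRecord", function(object) object@classLabel)
#' @rdname accessors
setMethod("usImage", "PhantomPair", function(object) object@usImage)
#' @rdname accessors
setMethod("opticalImage", "PhantomPair", function(object) object@opticalImage)
#' @rdname accessors
setMethod("lesionMask", "PhantomPair", function(object) object@mask)
#' @rdname accessors
setMethod("lesionSpec", "PhantomPair", function(object) object@spec)
#' @rdname accessors
setMethod("lossWeights", "CycleGANModel", function(object) object@weights)
#' @rdname accessors
setMethod("recordMasks", "ImageRecord", function(object) object@masks)
#' @rdname accessors
setMethod("recordImage", "ImageRecord", function(object) object@image)

setMethod("show", "LesionSpec", function(object) {
  cat(sprintf(
    "LesionSpec [%s] center=(%.2f, %.2f) radii=(%.2f, %.2f) irregularity=%.2f lobes=%d seed=%d\n",
    object@classLabel, object@center[1], object@center[2],
    object@radii[1], object@radii[2], object@irregularity, object@lobes,
    object@seed))
})

setMethod("show", "PhantomPair", function(object) {
  d <- dim(object@usImage)
  cat(sprintf(
    "PhantomPair [%s] %dx%d, lesion area %d px, artifacts: %s\n",
    object@spec@classLabel, d[1], d[2], sum(object@mask),
    if (length(object@artifacts)) paste(object@artifacts, collapse = ", ")
    else "none"))
})

setMethod("show", "ImageRecord", function(object) {
  d <- dim(object@image)
  cat(sprintf("ImageRecord '%s' [%s] %dx%d, %d mask(s)\n", object@id,
              object@classLabel, d[1], d[2], length(object@masks)))
})

setMethod("show", "DatasetSplit", function(object) {
  cat(sprintf(
    "DatasetSplit train/val/test = %d/%d/%d (target %.2f/%.2f/%.2f)\n",
    length(object@train), length(object@val), length(object@test),
    object@fractions[1], object@fractions[2], object@fractions[3]))
})

setMethod("show", "GACConfig", function(object) {
  thr <- if (is.character(object@threshold)) object@threshold
         else sprintf("%.3f", object@threshold)
  cat(sprintf(
    "GACConfig alpha=%g sigma=%g iterations=%d smoothing=%d balloon=%+d threshold=%s init=%s\n",
    object@alpha, object@sigma, object@iterations, object@smoothing,
    as.integer(object@balloon), thr, object@init))
})

setMethod("show", "LossWeights", function(object) {
  cat(sprintf("LossWeights gan=%g cycle=%g opposite=%g\n",
              object@lambdaGan, object@lambdaCycle, object@lambdaOpposite))
})

setMethod("show", "CycleGANModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "CycleGANModel %dx%d, %d base filters, %d residual blocks\n",
    cfg$image_size, cfg$image_size, cfg$base_filters, cfg$residual_blocks))
  show(object@weights)
})

setMethod("show", "MaskComparison", function(object) {
  cat(sprintf(
    "MaskComparison %dx%d: TP=%d FP=%d FN=%d | areas ref=%d gen=%d\n",
    object@H, object@W, object@TP, object@FP, object@FN, object@sRef,
    object@sGen))
})
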