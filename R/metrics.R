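## Lesion-fidelity metrics between a generated mask and a reference mask:
## Dice overlap, centroid error normalised by the image diagonal, and
## absolute area difference normalised by the image area; plus the
## per-class summary tables.

#' Compare two binary masks pixel-wise
#'
#' Computes the confusion counts, unweighted centroids, areas and the two
#' size normalisers: the image diagonal `sqrt(H^2 + W^2)` (for the
#' centroid error) and the image area `H * W` (for the area index; set
#' `areaNorm = "diagonal"` to normalise by diagonal^2 / 4 instead).
#'
#' @param maskRef,maskGen binary matrices of identical shape ("positive"
#'   means inside the lesion mask).
#' @param areaNorm "image" (H*W) or "diagonal" ((H^2+W^2)/4).
#' @return a [MaskComparison-class].
#' @export
compareMasks <- function(maskRef, maskGen, areaNorm = c("image", "diagonal")) {
  areaNorm <- match.arg(areaNorm)
  stopifnot(is.matrix(maskRef), is.matrix(maskGen))
  if (!identical(dim(maskRef), dim(maskGen))) {
    stop("mask shapes differ")
  }
  r <- maskRef != 0
  g <- maskGen != 0
  H <- nrow(maskRef); W <- ncol(maskRef)
  TP <- as.numeric(sum(r & g))
  FP <- as.numeric(sum(!r & g))
  FN <- as.numeric(sum(r & !g))
  centroid <- function(m) {
    if (!any(m)) return(c(NA_real_, NA_real_))
    idx <- which(m, arr.ind = TRUE)
    c(mean(idx[, 1]), mean(idx[, 2]))
  }
  diag2 <- sqrt(H^2 + W^2)
  new("MaskComparison",
      TP = TP, FP = FP, FN = FN, TN = H * W - TP - FP - FN,
      centroidRef = centroid(r), centroidGen = centroid(g),
      sRef = as.numeric(sum(r)), sGen = as.numeric(sum(g)), H = H, W = W,
      diagonal = diag2,
      areaNorm = if (areaNorm == "image") H * W else diag2^2 / 4)
}

.asComparison <- function(x, y) {
  if (is(x, "MaskComparison")) x else compareMasks(x, y)
}

#' Dice overlap index
#'
#' `2 * TP / ((TP + FP) + (TP + FN))`, in \[0, 1\].  Two empty masks score
#' 1 (perfect agreement on "no lesion"); exactly one empty mask scores 0.
#'
#' @param maskRef a binary matrix or a [MaskComparison-class].
#' @param maskGen binary matrix (ignored if `maskRef` is a comparison).
#' @return Dice score in \[0, 1\].
#' @examples
#' a <- matrix(0, 8, 8); a[2:4, 2:4] <- 1
#' diceIndex(a, a)  # 1
#' @export
diceIndex <- function(maskRef, maskGen = NULL) {
  cmp <- .asComparison(maskRef, maskGen)
  denom <- (cmp@TP + cmp@FP) + (cmp@TP + cmp@FN)
  if (denom == 0) return(1)          # both masks empty
  if (cmp@sRef == 0 || cmp@sGen == 0) return(0)
  2 * cmp@TP / denom
}

#' Centroid error in percent of the image diagonal
#'
#' Euclidean distance between the unweighted mask centroids divided by the
#' image diagonal (the largest possible in-image distance), times 100.
#' Symmetric in its two masks; undefined (NA) when either mask is empty.
#'
#' @inheritParams diceIndex
#' @return percent in \[0, 100\], or NA for an empty mask.
#' @export
centerError <- function(maskRef, maskGen = NULL) {
  cmp <- .asComparison(maskRef, maskGen)
  if (anyNA(cmp@centroidRef) || anyNA(cmp@centroidGen)) {
    return(NA_real_)
  }
  100 * sqrt(sum((cmp@centroidRef - cmp@centroidGen)^2)) / cmp@diagonal
}

#' Area index in percent of the image area
#'
#' `100 * |S_ref - S_gen| / normaliser`, symmetric; undefined (NA) when
#' either mask is empty.  The default normaliser is the image area `H*W`;
#' see [compareMasks()] for the diagonal-based alternative.
#'
#' @inheritParams diceIndex
#' @return percent, or NA for an empty mask.
#' @export
areaIndex <- function(maskRef, maskGen = NULL) {
  cmp <- .asComparison(maskRef, maskGen)
  if (cmp@sRef == 0 || cmp@sGen == 0) return(NA_real_)
  100 * abs(cmp@sRef - cmp@sGen) / cmp@areaNorm
}

#' Build one per-lesion metric row
#'
#' @param id record identifier.
#' @param classLabel tumour class.
#' @param referenceSource "manual" (provided tracings) or "morphgac"
#'   (automatic re-segmentation of the source image).
#' @param maskRef,maskGen binary matrices.
#' @return one-row data.frame with columns
#'   `id,class,reference_source,dice,center_error_pct,area_index_pct`.
#' @export
metricRow <- function(id, classLabel, referenceSource, maskRef, maskGen) {
  cmp <- compareMasks(maskRef, maskGen)
  data.frame(id = id, class = classLabel,
             reference_source = referenceSource,
             dice = diceIndex(cmp),
             center_error_pct = centerError(cmp),
             area_index_pct = areaIndex(cmp))
}

#' Summarise per-lesion metric rows into a per-class table
#'
#' For every metric x class in (benign, malignant, all) x reference
#' source, reports the median, mean, population standard deviation and
#' quartiles.  "all" pools benign and malignant; normal records carry no
#' lesion and are excluded here (false positives on normals are counted
#' separately by the evaluation driver).
#'
#' @param rows data.frame as produced by [metricRow()] (row-bound).
#' @return data.frame with columns `metric,class,reference_source,
#'   median,mean,sd,q1,q3,n`.
#' @export
summarizeMetrics <- function(rows) {
  lesionRows <- rows[rows$class %in% c("benign", "malignant"), , drop = FALSE]
  if (nrow(lesionRows) == 0L) {
    warning("no lesion rows to summarise")
    return(data.frame(metric = character(), class = character(),
                      reference_source = character(), median = numeric(),
                      mean = numeric(), sd = numeric(), q1 = numeric(),
                      q3 = numeric(), n = integer()))
  }
  popSD <- function(x) sqrt(mean((x - mean(x))^2))
  metrics <- c(dice = "dice", center_error = "center_error_pct",
               area_index = "area_index_pct")
  out <- list()
  for (m in names(metrics)) {
    for (cls in c("benign", "malignant", "all")) {
      sel <- if (cls == "all") lesionRows
             else lesionRows[lesionRows$class == cls, , drop = FALSE]
      for (src in unique(lesionRows$reference_source)) {
        x <- sel[sel$reference_source == src, metrics[[m]]]
        x <- x[is.finite(x)]
        out[[length(out) + 1L]] <- data.frame(
          metric = m, class = cls, reference_source = src,
          median = if (length(x)) median(x) else NA_real_,
          mean = if (length(x)) mean(x) else NA_real_,
          sd = if (length(x)) popSD(x) else NA_real_,
          q1 = if (length(x)) unname(quantile(x, 0.25)) else NA_real_,
          q3 = if (length(x)) unname(quantile(x, 0.75)) else NA_real_,
          n = length(x))
      }
    }
  }
  do.call(rbind, out)
}
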