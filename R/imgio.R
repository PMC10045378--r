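## BUSI-format IO, patch cropping and stratified splitting.
## BUSI filename dialect: "<class> (<index>).png" plus zero or more
## companion masks "<class> (<index>)_mask.png", "_mask_1.png", ...

.parseBusiClass <- function(id) {
  cls <- sub("^\\s*([A-Za-z]+).*$", "\\1", id)
  tolower(cls)
}

#' Load a BUSI-format directory of image/mask pairs
#'
#' Pairs every image PNG with all companion `_mask*` PNGs, parses the
#' class from the filename, and scales intensities to \[0, 1\].  Unreadable
#' image files are skipped with a warning; a mask whose shape differs from
#' its image is an error.
#'
#' @param path directory containing the PNGs.
#' @return list of [ImageRecord-class] objects (possibly empty).
#' @export
loadBusiDir <- function(path) {
  stopifnot(dir.exists(path))
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  isMask <- grepl("_mask(_[0-9]+)?\\.png$", basename(files))
  imageFiles <- files[!isMask]
  records <- list()
  for (f in imageFiles) {
    id <- sub("\\.png$", "", basename(f))
    img <- tryCatch(readImagePNG(f), error = function(e) NULL)
    if (is.null(img)) {
      warning("skipping unreadable PNG: ", f)
      next
    }
    maskFiles <- files[isMask &
      grepl(paste0("^", gsub("([][(){}.*+?^$\\\\|])", "\\\\\\1", id),
                   "_mask(_[0-9]+)?\\.png$"), basename(files))]
    masks <- lapply(maskFiles, function(mf) {
      m <- luminance(readImagePNG(mf))
      if (!identical(dim(m), dim(img)[1:2])) {
        stop("mask shape mismatch for ", mf)
      }
      matrix(as.integer(m > 0.5), nrow(m), ncol(m))
    })
    records[[length(records) + 1L]] <- new("ImageRecord",
      id = id, classLabel = .parseBusiClass(id), image = img,
      masks = masks, sourcePath = f)
  }
  records
}

## Reflect a 1..n index range up to length m (mirror without repeating the
## edge pixel), used to pad undersized images to the patch size.
.reflectIndex <- function(n, m) {
  if (n == 1L) return(rep(1L, m))
  i <- seq_len(m) - 1L
  period <- 2L * (n - 1L)
  n - abs((i %% period) - (n - 1L))
}

.reflectPadTo <- function(image, height, width) {
  ri <- .reflectIndex(dim(image)[1], height)
  ci <- .reflectIndex(dim(image)[2], width)
  if (is.matrix(image)) return(image[ri, ci, drop = FALSE])
  image[ri, ci, , drop = FALSE]
}

#' Crop an image record into partially overlapping square patches
#'
#' Patch offsets per axis are `{0, dim - patch}` (deduplicated), giving up
#' to four partially overlapping patches that jointly cover every pixel.
#' If a dimension is smaller than `patch` the image (and its masks) is
#' reflect-padded to the patch size along that axis.  Offsets are 0-based
#' (row, col), half-open `[offset, offset + patch)`.
#'
#' @param record an [ImageRecord-class].
#' @param patch square patch side in pixels (default 450).
#' @return list of lists with elements `image`, `masks`, `offset`.
#' @export
cropPatches <- function(record, patch = 450L) {
  stopifnot(is(record, "ImageRecord"), patch >= 1)
  img <- record@image
  masks <- record@masks
  d <- dim(img)[1:2]
  if (any(d < patch)) {
    H2 <- max(d[1], patch); W2 <- max(d[2], patch)
    img <- .reflectPadTo(img, H2, W2)
    masks <- lapply(masks, .reflectPadTo, height = H2, width = W2)
    d <- c(H2, W2)
  }
  offs <- function(dim) unique(c(0L, as.integer(dim - patch)))
  out <- list()
  for (ro in offs(d[1])) {
    for (co in offs(d[2])) {
      rows <- (ro + 1L):(ro + patch)
      cols <- (co + 1L):(co + patch)
      pimg <- if (is.matrix(img)) img[rows, cols, drop = FALSE]
              else img[rows, cols, , drop = FALSE]
      pmasks <- lapply(masks, function(m) m[rows, cols, drop = FALSE])
      out[[length(out) + 1L]] <- list(image = pimg, masks = pmasks,
                                      offset = c(ro, co))
    }
  }
  out
}

#' Stratified train/validation/test split at source-image level
#'
#' Splits whole source images (so all patches of one image land in the
#' same partition, preventing train/test leakage).  Within each class the
#' partition counts follow largest-remainder rounding of `fractions`
#' (remainder ties broken toward the partition with the larger target
#' fraction), after a seeded shuffle.
#'
#' @param records list of [ImageRecord-class] objects, or a character
#'   vector of ids in BUSI dialect (class parsed from the id).
#' @param fractions numeric(3) train/val/test fractions summing to 1.
#' @param seed integer shuffle seed.
#' @return a [DatasetSplit-class].
#' @export
stratifiedSplit <- function(records, fractions = c(0.80, 0.05, 0.15),
                            seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, length(fractions) == 3L)
  if (is.character(records)) {
    ids <- records
    classes <- vapply(records, .parseBusiClass, character(1))
  } else {
    ids <- vapply(records, function(r) r@id, character(1))
    classes <- vapply(records, function(r) r@classLabel, character(1))
  }
  stopifnot(!anyDuplicated(ids))
  train <- val <- test <- character()
  classOrder <- intersect(c("normal", "benign", "malignant"),
                          unique(classes))
  classOrder <- c(classOrder, setdiff(sort(unique(classes)), classOrder))
  withr::with_seed(seed, {
    for (cls in classOrder) {
      clsIds <- ids[classes == cls]
      clsIds <- clsIds[sample.int(length(clsIds))]
      counts <- apportion(length(clsIds), fractions)
      if (length(clsIds) < 3L) {
        warning("class '", cls, "' has fewer than 3 records; ",
                "some partitions stay empty")
      }
      train <- c(train, clsIds[seq_len(counts[1])])
      val <- c(val, clsIds[counts[1] + seq_len(counts[2])])
      test <- c(test, clsIds[counts[1] + counts[2] + seq_len(counts[3])])
    }
  })
  new("DatasetSplit", train = train, val = val, test = test,
      fractions = fractions)
}

#' Write a DatasetSplit as CSV
#'
#' @param split a [DatasetSplit-class].
#' @param path output CSV path; columns `id,partition`.
#' @return `path`, invisibly.
#' @export
writeSplitCSV <- function(split, path) {
  df <- data.frame(
    id = c(split@train, split@val, split@test),
    partition = rep(c("train", "val", "test"),
                    c(length(split@train), length(split@val),
                      length(split@test))))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
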