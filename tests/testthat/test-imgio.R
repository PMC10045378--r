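makePhantomDir <- function(n = 6, seed = 21L, size = 32L) {
  d <- file.path(tempdir(), paste0("busi", seed))
  generateDataset(n, outDir = d, seed = seed, height = size, width = size)
}

test_that("loadBusiDir pairs images with their masks and parses classes", {
  d <- tempfile("busi")
  dir.create(d)
  img <- matrix(runif(20 * 20), 20, 20)
  mask <- matrix(0, 20, 20); mask[5:9, 5:9] <- 1
  writeImagePNG(img, file.path(d, "benign (1).png"))
  writeImagePNG(mask, file.path(d, "benign (1)_mask.png"))
  recs <- loadBusiDir(d)
  expect_length(recs, 1)
  expect_s4_class(recs[[1]], "ImageRecord")
  expect_identical(recs[[1]]@id, "benign (1)")
  expect_identical(classLabel(recs[[1]]), "benign")
  expect_length(recordMasks(recs[[1]]), 1)
  expect_equal(sum(recordMasks(recs[[1]])[[1]]), 25)

  # multiple tracings attach to the same record
  writeImagePNG(mask, file.path(d, "benign (1)_mask_1.png"))
  expect_length(recordMasks(loadBusiDir(d)[[1]]), 2)

  # empty directory -> empty list
  d2 <- tempfile("empty"); dir.create(d2)
  expect_length(loadBusiDir(d2), 0)

  # mask shape mismatch is an error
  writeImagePNG(matrix(0.2, 10, 10), file.path(d, "benign (1)_mask_2.png"))
  expect_error(loadBusiDir(d), "mask shape mismatch")
  unlink(c(d, d2), recursive = TRUE)
})

test_that("a phantom-generated directory round-trips through loadBusiDir", {
  man <- makePhantomDir(6, seed = 31L)
  d <- file.path(tempdir(), "busi31", "us")
  recs <- loadBusiDir(d)
  expect_length(recs, 6)
  ids <- vapply(recs, function(r) r@id, character(1))
  expect_setequal(ids, man$id)
  for (r in recs) {
    expect_identical(r@classLabel, man$class[match(r@id, man$id)])
    if (r@classLabel == "normal") {
      expect_true(length(r@masks) == 0 || sum(r@masks[[1]]) == 0)
    } else {
      expect_gt(sum(r@masks[[1]]), 0)
    }
  }
  unlink(file.path(tempdir(), "busi31"), recursive = TRUE)
})

test_that("cropPatches uses the minimal covering offsets and pads
           undersized images by reflection", {
  rec <- function(h, w) {
    new("ImageRecord", id = "benign (1)", classLabel = "benign",
        image = matrix(runif(h * w), h, w),
        masks = list(matrix(0L, h, w)), sourcePath = "")
  }
  # the BUSI-average 500 x 600 image: 4 patches at {0,50} x {0,150}
  set.seed(3)
  r <- rec(500, 600)
  ps <- cropPatches(r, 450L)
  expect_length(ps, 4)
  offs <- t(vapply(ps, `[[`, numeric(2), "offset"))
  expect_setequal(paste(offs[, 1], offs[, 2]),
                  c("0 0", "0 150", "50 0", "50 150"))
  # union covers every pixel
  cov <- matrix(0, 500, 600)
  for (p in ps) {
    cov[p$offset[1] + 1:450, p$offset[2] + 1:450] <- 1
  }
  expect_true(all(cov == 1))
  # patch content matches the source at its offset
  expect_identical(ps[[2]]$image, r@image[1:450, 151:600])

  # exact fit -> a single patch at (0, 0)
  expect_length(cropPatches(rec(450, 450), 450L), 1)
  # undersized -> reflect-padded to the patch size, original in the corner
  r2 <- rec(256, 256)
  p1 <- cropPatches(r2, 450L)
  expect_length(p1, 1)
  expect_identical(dim(p1[[1]]$image), c(450L, 450L))
  expect_identical(p1[[1]]$image[1:256, 1:256], r2@image)
  # reflection: row 257 mirrors row 255
  expect_identical(p1[[1]]$image[257, 1:256], r2@image[255, ])
})

test_that("patch unions cover every pixel across image sizes", {
  for (h in c(256, 449, 450, 451, 600, 700)) {
    w <- 1156 - h  # paired odd sizes
    r <- new("ImageRecord", id = "benign (2)", classLabel = "benign",
             image = matrix(0.5, h, w), masks = list(), sourcePath = "")
    ps <- cropPatches(r, 450L)
    H2 <- max(h, 450); W2 <- max(w, 450)
    cov <- matrix(0, H2, W2)
    for (p in ps) cov[p$offset[1] + 1:450, p$offset[2] + 1:450] <- 1
    expect_true(all(cov == 1))
  }
})

test_that("stratifiedSplit reproduces the cohort-scale partition sizes and
           is leak-free", {
  ids <- sprintf("%s (%d)",
                 rep(c("normal", "benign", "malignant"), c(133, 437, 210)),
                 c(1:133, 1:437, 1:210))
  s <- stratifiedSplit(ids, c(0.80, 0.05, 0.15), seed = 4L)
  expect_length(s@train, 624)
  expect_length(s@val, 39)
  expect_length(s@test, 117)
  # disjoint and exhaustive
  all3 <- c(s@train, s@val, s@test)
  expect_false(anyDuplicated(all3) > 0)
  expect_setequal(all3, ids)
  # per-class proportions within one item of the global fractions
  for (cls in c("normal", "benign", "malignant")) {
    n <- sum(startsWith(ids, cls))
    got <- c(sum(startsWith(s@train, cls)), sum(startsWith(s@val, cls)),
             sum(startsWith(s@test, cls)))
    expect_true(all(abs(got - n * c(0.80, 0.05, 0.15)) <= 1))
  }
  # determinism
  s2 <- stratifiedSplit(ids, seed = 4L)
  expect_identical(s@train, s2@train)
  expect_identical(s@test, s2@test)

  # single-class 20 records -> (16, 1, 3)
  one <- sprintf("benign (%d)", 1:20)
  s3 <- stratifiedSplit(one, seed = 1L)
  expect_identical(lengths(list(s3@train, s3@val, s3@test)), c(16L, 1L, 3L))

  # undersized class triggers a warning but still partitions
  expect_warning(stratifiedSplit(sprintf("benign (%d)", 1:2), seed = 1L),
                 "fewer than 3")
})

test_that("split partitions stay disjoint and exhaustive over random
           record sets", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(5:60, 1)
    cls <- sample(c("normal", "benign", "malignant"), n, replace = TRUE)
    ids <- sprintf("%s (%d)", cls, seq_len(n))
    s <- suppressWarnings(stratifiedSplit(ids, seed = rep))
    all3 <- c(s@train, s@val, s@test)
    expect_setequal(all3, ids)
    expect_false(anyDuplicated(all3) > 0)
  }
})
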