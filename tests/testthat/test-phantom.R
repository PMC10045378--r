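test_that("lesion masks follow the parametric geometry", {
  # normal class: no mass regardless of geometry fields
  expect_equal(sum(makeLesionMask(LesionSpec("normal"), 100, 100)), 0)

  # pure ellipse (irregularity 0): rasterised area within 5% of pi*r^2
  spec <- LesionSpec("benign", center = c(0.5, 0.5), radii = c(0.2, 0.2),
                     irregularity = 0, seed = 2L)
  m <- makeLesionMask(spec, 100, 100)
  expect_lt(abs(sum(m) - pi * 20^2) / (pi * 20^2), 0.05)
  # oracle: brute-force point-in-ellipse test per pixel
  brute <- 0L
  for (i in 1:100) for (j in 1:100) {
    if (((i - 0.5 - 50) / 20)^2 + ((j - 0.5 - 50) / 20)^2 <= 1) {
      brute <- brute + 1L
    }
  }
  expect_equal(sum(m), brute)

  # seeded determinism
  expect_identical(makeLesionMask(spec, 100, 100),
                   makeLesionMask(spec, 100, 100))

  # degenerate: mass entirely outside the image
  tiny <- LesionSpec("benign", center = c(0, 0), radii = c(0.001, 0.001),
                     seed = 1L)
  expect_error(makeLesionMask(tiny, 20, 20), "degenerate lesion")
})

test_that("masks are single 4-connected components with class-dependent
           irregularity", {
  for (s in 1:12) {
    cls <- c("benign", "malignant")[1 + s %% 2]
    m <- makeLesionMask(sampleLesionSpec(cls, s), 96, 96)
    expect_gt(sum(m), 0)
    expect_equal(cycleUS:::.nComponents4(m), 1L)
  }
  # malignant default irregularity exceeds benign default
  expect_gt(LesionSpec("malignant")@irregularity,
            LesionSpec("benign")@irregularity)
})

test_that("ultrasound rendering is dark-lesion speckle with the requested
           artifacts", {
  spec <- LesionSpec("benign", center = c(0.4, 0.5), radii = c(0.15, 0.15),
                     irregularity = 0, seed = 3L)
  mask <- makeLesionMask(spec, 128, 128)
  img <- renderUltrasound(mask, spec, character())
  expect_true(all(img >= 0 & img <= 1))
  # masses appear dark
  expect_lt(mean(img[mask == 1]), mean(img[mask == 0]))

  # homogeneous background without a lesion: no 16x16 block deviates from
  # the global mean by more than 3 pixel standard deviations
  nl <- renderUltrasound(matrix(0L, 128, 128), LesionSpec("normal"),
                         character(), seed = 9L)
  blocks <- sapply(seq(1, 113, by = 16), function(r) {
    sapply(seq(1, 113, by = 16), function(c) {
      mean(nl[r:(r + 15), c:(c + 15)])
    })
  })
  expect_true(all(abs(blocks - mean(nl)) < 3 * sd(nl)))

  # depth decay: bottom rows dimmer than top rows
  dd <- renderUltrasound(mask, spec, "depth_decay")
  expect_lt(mean(dd[116:128, ]), mean(dd[1:13, ]))

  # posterior artifacts change the band below the lesion in the right
  # direction
  sh <- renderUltrasound(mask, spec, "shadow")
  en <- renderUltrasound(mask, spec, "enhancement")
  below <- max(which(rowSums(mask) > 0)) + 1
  cols <- range(which(colSums(mask) > 0))
  band <- function(im) mean(im[below:128, cols[1]:cols[2]])
  expect_lt(band(sh), band(img))
  expect_gt(band(en), band(img))

  # speckle contrast in the fully-developed regime
  cov <- sd(nl) / mean(nl)
  expect_gt(cov, 0.3); expect_lt(cov, 0.8)
})

test_that("optical rendering is light-lesion tissue over a black band", {
  spec <- LesionSpec("benign", center = c(0.35, 0.5),
                     radii = c(0.15, 0.15), irregularity = 0, seed = 4L)
  mask <- makeLesionMask(spec, 100, 100)
  img <- renderOptical(mask, spec, blackBand = 0.2)
  expect_true(all(img >= 0 & img <= 1))
  lum <- luminance(img)
  bandRows <- 81:100
  tissue <- mask == 0 & !(row(mask) %in% bandRows)
  expect_gt(mean(lum[mask == 1]), mean(lum[tissue]))
  expect_true(all(lum[bandRows, ] < 0.05))
  # determinism
  expect_identical(renderOptical(mask, spec), renderOptical(mask, spec))
})

test_that("generateDataset apportions classes and reproduces byte-identical
           outputs under a fixed seed", {
  # largest-remainder apportionment of the 133:437:210 cohort mix
  expect_identical(apportion(78, c(133, 437, 210)), c(13L, 44L, 21L))
  expect_identical(apportion(75, c(133, 437, 210)), c(13L, 42L, 20L))

  d1 <- file.path(tempdir(), "ph1"); d2 <- file.path(tempdir(), "ph2")
  man1 <- generateDataset(8, outDir = d1, seed = 5L, height = 48,
                          width = 48)
  man2 <- generateDataset(8, outDir = d2, seed = 5L, height = 48,
                          width = 48)
  expect_identical(man1, man2)
  expect_identical(names(man1),
                   c("id", "class", "center_r", "center_c", "rad_r",
                     "rad_c", "irregularity", "seed"))
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  # normal-only mix: every mask empty
  d3 <- file.path(tempdir(), "ph3")
  man3 <- generateDataset(3, classMix = c(1, 0, 0), outDir = d3, seed = 1L,
                          height = 32, width = 32)
  expect_true(all(man3$class == "normal"))
  for (id in man3$id) {
    m <- readImagePNG(file.path(d3, "us", paste0(id, "_mask.png")))
    expect_equal(sum(m), 0)
  }
  unlink(c(d1, d2, d3), recursive = TRUE)
})

test_that("phantom pairs satisfy the cross-domain polarity and mask
           contracts", {
  for (s in 1:10) {
    cls <- c("normal", "benign", "malignant")[1 + s %% 3]
    p <- renderPhantomPair(sampleLesionSpec(cls, 600 + s), 64, 64)
    expect_true(validObject(p))
    m <- lesionMask(p)
    expect_identical(any(m > 0), cls != "normal")
    if (cls != "normal") {
      us <- usImage(p); lum <- luminance(opticalImage(p))
      expect_lt(mean(us[m == 1]) - mean(us[m == 0]), 0)
      tissue <- m == 0 & rowSums(lum)[row(m)] > 0
      expect_gt(mean(lum[m == 1]) - mean(lum[tissue]), 0)
    }
  }
})

test_that("PNG round-trips preserve intensities to within 1/255", {
  set.seed(11)
  img <- matrix(runif(40 * 30), 40, 30)
  f <- tempfile(fileext = ".png")
  writeImagePNG(img, f)
  back <- readImagePNG(f)
  expect_lte(max(abs(back - img)), 1 / 255)
  rgb <- array(runif(20 * 20 * 3), c(20, 20, 3))
  writeImagePNG(rgb, f)
  expect_lte(max(abs(readImagePNG(f) - rgb)), 1 / 255)
  expect_error(writeImagePNG(img * 2, f), "0, 1")
  unlink(f)
})
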