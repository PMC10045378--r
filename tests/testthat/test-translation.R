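test_that("negativeImage is the bounded pixelwise complement", {
  expect_equal(negativeImage(matrix(0, 3, 3)), matrix(1, 3, 3))
  x <- array(runif(4 * 4 * 3), c(4, 4, 3))
  expect_equal(negativeImage(negativeImage(x)), x)       # involution
  expect_equal(negativeImage(matrix(0.5, 2, 2)), matrix(0.5, 2, 2))
  expect_error(negativeImage(matrix(1.5, 2, 2)), "0, 1")
})

test_that("adversarial losses match their closed forms", {
  # uninformative discriminator: 2 ln 2 for D, ln 2 for G
  half <- matrix(0.5, 4, 4)
  l <- adversarialLoss(half, half)
  expect_equal(l$discriminator, 2 * log(2), tolerance = 1e-12)
  expect_equal(l$generator, log(2), tolerance = 1e-12)
  # perfect discriminator limit -> 0 (clamped at 1e-7)
  lp <- adversarialLoss(matrix(1, 4, 4), matrix(0, 4, 4))
  expect_lt(lp$discriminator, 1e-5)
  # a perfect discriminator never scores worse than the 0.5 constant
  set.seed(1)
  fake <- matrix(runif(16, 0, 0.3), 4, 4)
  real <- matrix(runif(16, 0.7, 1), 4, 4)
  expect_lte(adversarialLoss(real, fake)$discriminator,
             adversarialLoss(half, half)$discriminator)
  # least-squares variant
  ll <- adversarialLoss(half, half, form = "lsq")
  expect_equal(ll$discriminator, 0.5)
  expect_equal(ll$generator, 0.25)
})

test_that("cycle and opposite losses satisfy their stub identities", {
  set.seed(5)
  xs <- lapply(1:3, function(i) matrix(runif(64), 8, 8))
  ys <- lapply(1:3, function(i) array(runif(192), c(8, 8, 3)))
  ident <- function(v) v
  neg <- function(v) 1 - v
  # identity generators reconstruct perfectly
  expect_equal(cycleLoss(xs, ys, ident, ident), 0)
  # negation generators invert the negative back to the input
  expect_equal(oppositeLoss(xs, ys, neg, neg), 0)
  # identity generators: opposite loss has the closed form mean|1 - 2x|
  expect_equal(oppositeLoss(xs, ys, ident, ident),
               mean(sapply(xs, function(x) mean(abs(1 - 2 * x)))) +
               mean(sapply(ys, function(y) mean(abs(1 - 2 * y)))))
  # 0.5 is the fixed point of negation
  c05 <- list(matrix(0.5, 8, 8))
  c05y <- list(array(0.5, c(8, 8, 3)))
  expect_equal(oppositeLoss(c05, c05y, ident, ident), 0)
  # constant-offset generator pair: L1 equals the offset
  addc <- function(v) pmin(v + 0.1, 1)
  xs2 <- lapply(xs, function(x) x * 0.8)  # keep offset un-clipped
  expect_equal(cycleLoss(xs2, list(), addc, ident) , 0.1, tolerance = 1e-12)
})

test_that("vectorised losses agree with a scalar per-pixel loop", {
  set.seed(6)
  for (i in 1:5) {
    x <- matrix(runif(64), 8, 8)
    y <- array(runif(192), c(8, 8, 3))
    # random elementwise stub generators (shape preserving)
    a <- runif(1, 0.2, 0.8); b <- runif(1, 0, 0.2)
    g1 <- function(v) pmin(pmax(a * v + b, 0), 1)
    g2 <- function(v) pmin(pmax(1 - a * v, 0), 1)
    cl <- cycleLoss(x, y, g1, g2)
    clOracle <- oracleMeanAbs(g2(g1(x)), x) + oracleMeanAbs(g1(g2(y)), y)
    expect_lt(abs(cl - clOracle), 1e-6)
    ol <- oppositeLoss(x, y, g1, g2)
    olOracle <- oracleMeanAbs(g2(1 - x), x) + oracleMeanAbs(g1(1 - y), y)
    expect_lt(abs(ol - olOracle), 1e-6)
  }
})

test_that("totalLoss applies the default weighting", {
  rep1 <- list(LganPA = 1, LganUS = 1, Lcycle = 1, Lopposite = 1)
  expect_equal(totalLoss(rep1, LossWeights()), 11.3)
  expect_equal(totalLoss(rep1, LossWeights(0, 0, 0)), 0)
  expect_equal(totalLoss(list(LganPA = 0, LganUS = 0, Lcycle = 0.2,
                              Lopposite = 0),
                         LossWeights(0, 10, 0)), 2.0)
  expect_error(LossWeights(-1, 10, 0.3))
})

test_that("buildModels honours the architecture contract", {
  cfg <- list(image_size = 64L, base_filters = 4L, residual_blocks = 2L,
              seed = 3L)
  m <- buildModels(cfg)
  expect_s4_class(m, "CycleGANModel")
  x <- matrix(runif(64 * 64), 64, 64)
  out <- translateImage(m, x)
  expect_identical(dim(out), c(64L, 64L, 3L))
  expect_true(all(out >= 0 & out <= 1))
  # inference determinism
  expect_identical(out, translateImage(m, x))
  # discriminator emits a spatial score map in (0, 1)
  s <- cycleUS:::.netForward(m@dPA, array(runif(64 * 64 * 3),
                                          c(64, 64, 3)))$out
  expect_gt(length(s), 1)
  expect_true(all(s > 0 & s < 1))
  # seeded weight determinism
  m2 <- buildModels(cfg)
  expect_identical(m@gPA$layers[[1]]$params$W, m2@gPA$layers[[1]]$params$W)
  expect_error(buildModels(list(image_size = 30L)), "image_size")
})

test_that("backpropagated gradients match numerical differentiation", {
  set.seed(8)
  net <- cycleUS:::.buildGenerator(1L, 3L, 2L, 1L)
  x <- matrix(runif(16 * 16), 16, 16)
  tgt <- array(runif(16 * 16 * 3), c(16, 16, 3))
  fwd <- cycleUS:::.netForward
  lossFn <- function(n) 0.5 * sum((fwd(n, x, FALSE)$out - tgt)^2)
  f <- fwd(net, x)
  g <- cycleUS:::.netBackward(net, f$caches, f$out - tgt)
  eps <- 1e-5
  checkParam <- function(getP, setP, grad) {
    p <- getP(net)
    for (k in sample(length(p), min(2, length(p)))) {
      n2 <- setP(net, k, p[k] + eps)
      num <- (lossFn(n2) - lossFn(net)) / eps
      expect_lt(abs(num - grad[k]) / max(1e-3, abs(grad[k])), 0.02)
    }
  }
  # one conv, one instance norm, one resblock sub-conv
  checkParam(function(n) n$layers[[1]]$params$W,
             function(n, k, v) { n$layers[[1]]$params$W[k] <- v; n },
             g$grads[[1]]$W)
  checkParam(function(n) n$layers[[2]]$params$gamma,
             function(n, k, v) { n$layers[[2]]$params$gamma[k] <- v; n },
             g$grads[[2]]$gamma)
  ir <- which(vapply(net$layers, `[[`, character(1), "type") == "resblock")[1]
  checkParam(function(n) n$layers[[ir]]$layers[[1]]$params$W,
             function(n, k, v) {
               n$layers[[ir]]$layers[[1]]$params$W[k] <- v; n
             },
             g$grads[[ir]]$layers[[1]]$W)
  # input gradient
  for (j in 1:3) {
    x2 <- x; x2[j] <- x[j] + eps
    num <- (0.5 * sum((fwd(net, x2, FALSE)$out - tgt)^2) - lossFn(net)) / eps
    expect_lt(abs(num - g$dx[j]) / max(1e-3, abs(g$dx[j])), 0.02)
  }
})

test_that("zero-epoch training is a no-op and a frozen 0.5 discriminator
           yields the ln 2 generator loss", {
  set.seed(9)
  us <- lapply(1:2, function(i) matrix(runif(32 * 32), 32, 32))
  opt <- lapply(1:2, function(i) array(runif(32 * 32 * 3), c(32, 32, 3)))
  m <- buildModels(list(image_size = 32L, base_filters = 2L,
                        residual_blocks = 1L, epochs = 0L, seed = 2L))
  fit <- trainCycleGAN(m, list(us = us, optical = opt))
  expect_equal(nrow(fit$history), 0)
  expect_identical(fit$model@gPA$layers[[1]]$params$W,
                   m@gPA$layers[[1]]$params$W)
  # a constant-0.5 score under the log form gives exactly ln 2 per unit
  expect_equal(adversarialLoss(matrix(0.5, 2, 2),
                               matrix(0.5, 2, 2))$generator, log(2))
})
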