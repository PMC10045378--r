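## Alternating CycleGAN optimisation: generators minimise the weighted
## total objective; discriminators minimise their adversarial loss
## against a replay buffer of previously generated images.  Batch size 1,
## Adam (lr 2e-4, betas 0.5/0.999), linear learning-rate decay after half
## the epochs, all seeded.

## Replay buffer of generated images (image-pool): below capacity the new
## image is stored and returned; at capacity, with probability 1/2 a
## random stored image is returned and replaced by the new one.
.bufferQuery <- function(buffer, img, maxSize) {
  if (length(buffer$items) < maxSize) {
    buffer$items[[length(buffer$items) + 1L]] <- img
    return(list(buffer = buffer, img = img))
  }
  if (runif(1) < 0.5) {
    i <- sample.int(length(buffer$items), 1L)
    old <- buffer$items[[i]]
    buffer$items[[i]] <- img
    return(list(buffer = buffer, img = old))
  }
  list(buffer = buffer, img = img)
}

## Generator-side adversarial loss and d(loss)/d(score) for one score map.
.advGenGrad <- function(scores, form, lambda) {
  n <- length(scores)
  if (form == "lsq") {
    list(loss = mean((scores - 1)^2), grad = lambda * 2 * (scores - 1) / n)
  } else {
    s <- pmin(pmax(scores, .EPS_SCORE), 1 - .EPS_SCORE)
    list(loss = -mean(log(s)), grad = -lambda / (s * n))
  }
}

## Discriminator loss and gradients for (real, fake) score maps.
.advDiscGrad <- function(real, fake, form) {
  nr <- length(real); nf <- length(fake)
  if (form == "lsq") {
    list(loss = mean((real - 1)^2) + mean(fake^2),
         dReal = 2 * (real - 1) / nr, dFake = 2 * fake / nf)
  } else {
    r <- pmin(pmax(real, .EPS_SCORE), 1 - .EPS_SCORE)
    f <- pmin(pmax(fake, .EPS_SCORE), 1 - .EPS_SCORE)
    list(loss = -mean(log(r)) - mean(log(1 - f)),
         dReal = -1 / (r * nr), dFake = 1 / ((1 - f) * nf))
  }
}

#' Train the CycleGAN on unpaired domain pools
#'
#' Runs the alternating optimisation for `epochs` epochs over unpaired
#' ultrasound / optical image pools (batch size 1; one epoch =
#' `max(#us, #optical)` seeded independent draws from the two pools).
#' Each step updates the generators on the weighted sum of the
#' adversarial, cycle and opposite losses, then updates each
#' discriminator on real images and a replay buffer of generated ones.
#' Checkpoints (`{epoch}_{component}.ckpt`) are written every
#' `checkpoint_every` epochs when `checkpoint_dir` is set.  A NaN loss
#' aborts with a diagnostic.
#'
#' @param model a [CycleGANModel-class] from [buildModels()].
#' @param train list with elements `us` (list of grayscale matrices) and
#'   `optical` (list of RGB arrays); the two lists are unpaired.
#' @param val optional list of the same shape; when given, the validation
#'   cycle loss is recorded per epoch.
#' @param config optional overrides of the model's training config
#'   (epochs, lr, seed, adversarial_form, buffer_size, checkpoint_dir,
#'   checkpoint_every, verbose).
#' @return list with `model` (trained [CycleGANModel-class]) and
#'   `history` (data.frame: epoch, L_gan_PA, L_gan_US, L_cycle,
#'   L_opposite, total, and val_cycle when `val` is given).
#' @export
trainCycleGAN <- function(model, train, val = NULL, config = list()) {
  cfg <- utils::modifyList(model@config, config)
  stopifnot(length(train$us) > 0, length(train$optical) > 0)
  w <- model@weights
  form <- cfg$adversarial_form
  E <- as.integer(cfg$epochs)
  histCols <- c("epoch", "L_gan_PA", "L_gan_US", "L_cycle", "L_opposite",
                "total")
  if (!is.null(val)) histCols <- c(histCols, "val_cycle")
  if (E == 0L) {
    return(list(model = model,
                history = as.data.frame(setNames(
                  rep(list(numeric(0)), length(histCols)), histCols))))
  }
  gPA <- model@gPA; gUS <- model@gUS; dPA <- model@dPA; dUS <- model@dUS
  stPA <- .adamInitNet(gPA); stUS <- .adamInitNet(gUS)
  stDPA <- .adamInitNet(dPA); stDUS <- .adamInitNet(dUS)
  bufPA <- list(items = list()); bufUS <- list(items = list())
  nIter <- max(length(train$us), length(train$optical))
  half <- ceiling(E / 2)
  history <- vector("list", E)

  withr::with_seed(cfg$seed, for (epoch in seq_len(E)) {
    lr <- if (epoch <= half) cfg$lr else {
      cfg$lr * (E - epoch + 1) / (E - half + 1)
    }
    acc <- c(L_gan_PA = 0, L_gan_US = 0, L_cycle = 0, L_opposite = 0,
             total = 0)
    for (it in seq_len(nIter)) {
      x <- train$us[[sample.int(length(train$us), 1L)]]
      y <- train$optical[[sample.int(length(train$optical), 1L)]]
      x3 <- .as3d(x)

      ## ---- generator update -------------------------------------------
      fA <- .netForward(gPA, x)            # fake optical from x
      fB <- .netForward(gUS, y)            # fake US from y
      fC <- .netForward(gUS, fA$out)       # reconstruction of x
      fD <- .netForward(gPA, fB$out)       # reconstruction of y
      fE <- .netForward(gUS, grayToRGB(1 - x))   # opposite, US side
      fF <- .netForward(gPA, luminance(1 - y))   # opposite, optical side
      fG <- .netForward(dPA, fA$out)
      fH <- .netForward(dUS, fB$out)

      Lcyc <- mean(abs(fC$out - x3)) + mean(abs(fD$out - y))
      Lopp <- mean(abs(fE$out - x3)) + mean(abs(fF$out - y))
      advPA <- .advGenGrad(fG$out, form, w@lambdaGan / 2)
      advUS <- .advGenGrad(fH$out, form, w@lambdaGan / 2)
      total <- w@lambdaGan * (advPA$loss + advUS$loss) / 2 +
        w@lambdaCycle * Lcyc + w@lambdaOpposite * Lopp
      if (!is.finite(total)) {
        stop(sprintf("non-finite loss at epoch %d, iteration %d", epoch, it))
      }

      dRx <- w@lambdaCycle * sign(fC$out - x3) / length(fC$out)
      dRy <- w@lambdaCycle * sign(fD$out - y) / length(fD$out)
      dOx <- w@lambdaOpposite * sign(fE$out - x3) / length(fE$out)
      dOy <- w@lambdaOpposite * sign(fF$out - y) / length(fF$out)

      bC <- .netBackward(gUS, fC$caches, dRx)
      bD <- .netBackward(gPA, fD$caches, dRy)
      bE <- .netBackward(gUS, fE$caches, dOx)
      bF <- .netBackward(gPA, fF$caches, dOy)
      bG <- .netBackward(dPA, fG$caches, advPA$grad)  # dx only; D frozen
      bH <- .netBackward(dUS, fH$caches, advUS$grad)
      bA <- .netBackward(gPA, fA$caches, bC$dx + bG$dx)
      bB <- .netBackward(gUS, fB$caches, bD$dx + bH$dx)

      gradsGPA <- .addGrads(.addGrads(bD$grads, bF$grads), bA$grads)
      gradsGUS <- .addGrads(.addGrads(bC$grads, bE$grads), bB$grads)
      up <- .adamStepNet(gPA, gradsGPA, stPA, lr)
      gPA <- up$net; stPA <- up$state
      up <- .adamStepNet(gUS, gradsGUS, stUS, lr)
      gUS <- up$net; stUS <- up$state

      ## ---- discriminator updates --------------------------------------
      q <- .bufferQuery(bufPA, fA$out, cfg$buffer_size)
      bufPA <- q$buffer; fakePA <- q$img
      q <- .bufferQuery(bufUS, fB$out, cfg$buffer_size)
      bufUS <- q$buffer; fakeUS <- q$img

      fR <- .netForward(dPA, y)
      fK <- .netForward(dPA, fakePA)
      gd <- .advDiscGrad(fR$out, fK$out, form)
      gradsDPA <- .addGrads(.netBackward(dPA, fR$caches, gd$dReal)$grads,
                            .netBackward(dPA, fK$caches, gd$dFake)$grads)
      up <- .adamStepNet(dPA, gradsDPA, stDPA, lr)
      dPA <- up$net; stDPA <- up$state

      fR <- .netForward(dUS, x3)
      fK <- .netForward(dUS, fakeUS)
      gd2 <- .advDiscGrad(fR$out, fK$out, form)
      gradsDUS <- .addGrads(.netBackward(dUS, fR$caches, gd2$dReal)$grads,
                            .netBackward(dUS, fK$caches, gd2$dFake)$grads)
      up <- .adamStepNet(dUS, gradsDUS, stDUS, lr)
      dUS <- up$net; stDUS <- up$state

      acc <- acc + c(advPA$loss, advUS$loss, Lcyc, Lopp, total)
    }
    row <- as.data.frame(as.list(acc / nIter))
    names(row) <- c("L_gan_PA", "L_gan_US", "L_cycle", "L_opposite",
                    "total")
    row <- cbind(data.frame(epoch = epoch), row)
    if (!is.null(val)) {
      row$val_cycle <- cycleLoss(val$us, val$optical, gPA, gUS)
    }
    history[[epoch]] <- row
    if (isTRUE(cfg$verbose)) {
      message(sprintf("epoch %d/%d  cycle %.4f  opposite %.4f  total %.4f",
                      epoch, E, row$L_cycle, row$L_opposite, row$total))
    }
    if (!is.null(cfg$checkpoint_dir) &&
        epoch %% cfg$checkpoint_every == 0L) {
      dir.create(cfg$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      comps <- list(gPA = gPA, gUS = gUS, dPA = dPA, dUS = dUS)
      for (nm in names(comps)) {
        saveRDS(comps[[nm]], file.path(
          cfg$checkpoint_dir, sprintf("%04d_%s.ckpt", epoch, nm)))
      }
    }
  })
  model@gPA <- gPA; model@gUS <- gUS; model@dPA <- dPA; model@dUS <- dUS
  list(model = model, history = do.call(rbind, history))
}
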