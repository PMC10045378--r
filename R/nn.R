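## Minimal CNN engine used by the translation module: convolution via
## im2col + BLAS GEMM (the im2col/col2im shuffles live in src/ops.cpp),
## instance normalisation, (leaky) ReLU, nearest-neighbour upsampling,
## tanh rescaled to [0, 1], sigmoid, and residual blocks; manual backward
## passes and an Adam optimiser.  Images are H x W x C arrays; a network
## is a list of layers, each `list(type, params, ...)`.

.convLayer <- function(cin, cout, k, stride = 1L, pad = 0L, sd = 0.02) {
  list(type = "conv", k = k, stride = stride, pad = pad, cin = cin,
       cout = cout,
       params = list(W = matrix(rnorm(k * k * cin * cout, sd = sd),
                                k * k * cin, cout),
                     b = numeric(cout)))
}

.inormLayer <- function(c) {
  list(type = "inorm", c = c,
       params = list(gamma = rep(1, c), beta = numeric(c)))
}

.reluLayer <- function() list(type = "relu", params = NULL)
.lreluLayer <- function(slope = 0.2) list(type = "lrelu", slope = slope,
                                          params = NULL)
.upsampleLayer <- function() list(type = "upsample", params = NULL)
.tanh01Layer <- function() list(type = "tanh01", params = NULL)
.sigmoidLayer <- function() list(type = "sigmoid", params = NULL)

.resblockLayer <- function(c, sd = 0.02) {
  list(type = "resblock", params = NULL,
       layers = list(.convLayer(c, c, 3L, 1L, 1L, sd), .inormLayer(c),
                     .reluLayer(),
                     .convLayer(c, c, 3L, 1L, 1L, sd), .inormLayer(c)))
}

.as3d <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1L)) else x
}

.layerForward <- function(layer, x) {
  switch(layer$type,
    conv = {
      d <- dim(x)
      cols <- cpp_im2col(as.numeric(x), d[1], d[2], d[3], layer$k,
                         layer$stride, layer$pad)
      out <- cols %*% layer$params$W
      out <- out + rep(layer$params$b, each = nrow(out))
      Ho <- (d[1] + 2 * layer$pad - layer$k) %/% layer$stride + 1L
      Wo <- (d[2] + 2 * layer$pad - layer$k) %/% layer$stride + 1L
      dim(out) <- c(Ho, Wo, layer$cout)
      list(out = out, cache = list(cols = cols, dimIn = d))
    },
    inorm = {
      d <- dim(x)
      n <- d[1] * d[2]
      xm <- matrix(x, n, d[3])
      mu <- colMeans(xm)
      xc <- sweep(xm, 2, mu)
      v <- colMeans(xc^2)
      istd <- 1 / sqrt(v + 1e-5)
      xhat <- sweep(xc, 2, istd, `*`)
      out <- sweep(sweep(xhat, 2, layer$params$gamma, `*`), 2,
                   layer$params$beta, `+`)
      dim(out) <- d
      list(out = out, cache = list(xhat = xhat, istd = istd, d = d))
    },
    relu = {
      out <- pmax(x, 0)
      list(out = out, cache = x > 0)
    },
    lrelu = {
      pos <- x > 0
      out <- x
      out[!pos] <- layer$slope * out[!pos]
      list(out = out, cache = pos)
    },
    upsample = {
      d <- dim(x)
      out <- x[rep(seq_len(d[1]), each = 2L),
               rep(seq_len(d[2]), each = 2L), , drop = FALSE]
      list(out = out, cache = d)
    },
    tanh01 = {
      t <- tanh(x)
      list(out = (t + 1) / 2, cache = t)
    },
    sigmoid = {
      out <- 1 / (1 + exp(-x))
      list(out = out, cache = out)
    },
    resblock = {
      h <- x
      caches <- vector("list", length(layer$layers))
      for (i in seq_along(layer$layers)) {
        f <- .layerForward(layer$layers[[i]], h)
        h <- f$out
        caches[[i]] <- f$cache
      }
      list(out = x + h, cache = caches)
    },
    stop("unknown layer type: ", layer$type)
  )
}

.layerBackward <- function(layer, cache, dout) {
  switch(layer$type,
    conv = {
      d <- dim(dout)
      dY <- matrix(dout, d[1] * d[2], d[3])
      dW <- crossprod(cache$cols, dY)
      db <- colSums(dY)
      dcols <- tcrossprod(dY, layer$params$W)
      dx <- cpp_col2im(dcols, cache$dimIn[1], cache$dimIn[2],
                       cache$dimIn[3], layer$k, layer$stride, layer$pad)
      dim(dx) <- cache$dimIn
      list(dx = dx, grads = list(W = dW, b = db))
    },
    inorm = {
      d <- cache$d
      n <- d[1] * d[2]
      dY <- matrix(dout, n, d[3])
      dgamma <- colSums(dY * cache$xhat)
      dbeta <- colSums(dY)
      dxhat <- sweep(dY, 2, layer$params$gamma, `*`)
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * cache$xhat)
      dx <- sweep(dxhat, 2, s1 / n) - sweep(cache$xhat, 2, s2 / n, `*`)
      dx <- sweep(dx, 2, cache$istd, `*`)
      dim(dx) <- d
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    relu = list(dx = dout * cache, grads = NULL),
    lrelu = {
      dx <- dout
      dx[!cache] <- layer$slope * dx[!cache]
      list(dx = dx, grads = NULL)
    },
    upsample = {
      d <- cache
      dx <- dout[seq(1, 2 * d[1], by = 2), , , drop = FALSE] +
            dout[seq(2, 2 * d[1], by = 2), , , drop = FALSE]
      dx <- dx[, seq(1, 2 * d[2], by = 2), , drop = FALSE] +
            dx[, seq(2, 2 * d[2], by = 2), , drop = FALSE]
      list(dx = dx, grads = NULL)
    },
    tanh01 = list(dx = dout * (1 - cache^2) / 2, grads = NULL),
    sigmoid = list(dx = dout * cache * (1 - cache), grads = NULL),
    resblock = {
      dh <- dout
      grads <- vector("list", length(layer$layers))
      for (i in rev(seq_along(layer$layers))) {
        b <- .layerBackward(layer$layers[[i]], cache[[i]], dh)
        dh <- b$dx
        grads[i] <- list(b$grads)  # [i] <- list(): keep NULL placeholders
      }
      list(dx = dout + dh, grads = list(layers = grads))
    },
    stop("unknown layer type: ", layer$type)
  )
}

## Forward pass through a network; keepCache = FALSE for inference.
.netForward <- function(net, x, keepCache = TRUE) {
  h <- .as3d(x)
  caches <- if (keepCache) vector("list", length(net$layers)) else NULL
  for (i in seq_along(net$layers)) {
    f <- .layerForward(net$layers[[i]], h)
    h <- f$out
    if (keepCache) caches[[i]] <- f$cache
  }
  list(out = h, caches = caches)
}

## Backward pass; returns input gradient and the per-layer gradient tree.
.netBackward <- function(net, caches, dout) {
  dh <- dout
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    b <- .layerBackward(net$layers[[i]], caches[[i]], dh)
    dh <- b$dx
    grads[i] <- list(b$grads)  # [i] <- list(): keep NULL placeholders
  }
  list(dx = dh, grads = grads)
}

## Elementwise sum of two gradient trees (same structure; NULLs allowed).
.addGrads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    return(mapply(.addGrads, a, b, SIMPLIFY = FALSE))
  }
  a + b
}

## Adam optimiser over the layer/param tree.
.adamInitNet <- function(net) {
  zeroLike <- function(p) {
    if (is.null(p)) return(NULL)
    if (is.list(p)) return(lapply(p, zeroLike))
    p * 0
  }
  paramTree <- lapply(net$layers, function(l) {
    if (l$type == "resblock") list(layers = lapply(l$layers, `[[`, "params"))
    else l$params
  })
  list(m = zeroLike(paramTree), v = zeroLike(paramTree), t = 0L)
}

.adamUpdateParams <- function(p, g, m, v, lr, b1, b2, t, eps = 1e-8) {
  if (is.null(p)) return(list(p = p, m = m, v = v))
  if (is.list(p)) {
    out <- mapply(.adamUpdateParams, p, g, m, v,
                  MoreArgs = list(lr = lr, b1 = b1, b2 = b2, t = t,
                                  eps = eps),
                  SIMPLIFY = FALSE)
    return(list(p = lapply(out, `[[`, "p"),
                m = lapply(out, `[[`, "m"),
                v = lapply(out, `[[`, "v")))
  }
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g^2
  mhat <- m / (1 - b1^t)
  vhat <- v / (1 - b2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

## One Adam step on a network given its gradient tree; returns updated
## net and optimiser state.
.adamStepNet <- function(net, grads, state, lr, b1 = 0.5, b2 = 0.999) {
  state$t <- state$t + 1L
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    g <- grads[[i]]
    if (is.null(g)) next
    if (l$type == "resblock") {
      for (j in seq_along(l$layers)) {
        gj <- g$layers[[j]]
        if (is.null(gj)) next
        upd <- .adamUpdateParams(l$layers[[j]]$params, gj,
                                 state$m[[i]]$layers[[j]],
                                 state$v[[i]]$layers[[j]],
                                 lr, b1, b2, state$t)
        net$layers[[i]]$layers[[j]]$params <- upd$p
        state$m[[i]]$layers[[j]] <- upd$m
        state$v[[i]]$layers[[j]] <- upd$v
      }
    } else {
      upd <- .adamUpdateParams(l$params, g, state$m[[i]], state$v[[i]],
                               lr, b1, b2, state$t)
      net$layers[[i]]$params <- upd$p
      state$m[[i]] <- upd$m
      state$v[[i]] <- upd$v
    }
  }
  list(net = net, state = state)
}
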