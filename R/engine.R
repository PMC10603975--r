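# Self-contained CPU training engine for the encoder-decoder specs:
# forward/backward passes over the layer graph, Adam updates, binary (or
# two-class) cross-entropy with the head activation fused into the loss
# gradient for numerical stability.
#
# Tensors are stored as H x W x C x N arrays (N = mini-batch size).
# Convolutions run through the C++ im2col/col2im pair with 'same' padding;
# batch normalization uses joint batch+spatial statistics in training and
# running moments (momentum 0.9) at inference. All stochastic pieces
# (weight init, shuffling, dropout) draw from R's global RNG so a single
# seed reproduces a run.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

# 4-D aware center crop / zero pad (adjoint of itself with swapped sizes).
cropPad4 <- function(x, th, tw) {
  d <- dim(x)
  if (d[1] == th && d[2] == tw) return(x)
  if (d[1] > th) { off <- (d[1] - th) %/% 2
    x <- x[off + seq_len(th), , , , drop = FALSE] }
  if (d[2] > tw) { off <- (d[2] - tw) %/% 2
    x <- x[, off + seq_len(tw), , , drop = FALSE] }
  d <- dim(x)
  if (d[1] < th || d[2] < tw) {
    y <- array(0, c(th, tw, d[3], d[4]))
    ro <- (th - d[1]) %/% 2; co <- (tw - d[2]) %/% 2
    y[ro + seq_len(d[1]), co + seq_len(d[2]), , ] <- x
    x <- y
  }
  x
}

applyActivation <- function(z, act) {
  switch(act,
         relu = pmax(z, 0),
         sigmoid = 1 / (1 + exp(-z)),
         linear = z,
         softmax = {
           d <- dim(z)
           zs <- sweep(z, c(1, 2, 4), apply(z, c(1, 2, 4), max), "-")
           e <- exp(zs)
           sweep(e, c(1, 2, 4), apply(e, c(1, 2, 4), sum), "/")
         },
         stop("unknown activation: ", act))
}

initWeights <- function(spec) {
  W <- list()
  for (lay in spec@layers) {
    if (lay$kind == "conv") {
      fanIn <- lay$kernel^2 * lay$inChannels
      sdv <- if (identical(lay$activation, "relu")) sqrt(2 / fanIn)
             else sqrt(1 / fanIn)
      W[[lay$name]] <- list(
        W = array(rnorm(fanIn * lay$filters, 0, sdv),
                  c(lay$kernel, lay$kernel, lay$inChannels, lay$filters)),
        b = numeric(lay$filters))
    } else if (lay$kind == "batchnorm") {
      C <- lay$channels
      W[[lay$name]] <- list(gamma = rep(1, C), beta = numeric(C),
                            rmean = numeric(C), rvar = rep(1, C))
    }
  }
  W
}

convForward <- function(x, Wl, k, stride, Cout) {
  d <- dim(x)
  Wm <- matrix(Wl$W, nrow = k * k * d[3])
  Hout <- ceiling(d[1] / stride); Wout <- ceiling(d[2] / stride)
  z <- array(0, c(Hout, Wout, Cout, d[4]))
  for (n in seq_len(d[4])) {
    cols <- im2col_same(array(x[, , , n], d[1:3]), k, stride)
    y <- cols %*% Wm
    y <- sweep(y, 2, Wl$b, "+")
    z[, , , n] <- y
  }
  z
}

convBackward <- function(x, Wl, dz, k, stride) {
  d <- dim(x); dd <- dim(dz)
  Wm <- matrix(Wl$W, nrow = k * k * d[3])
  dW <- matrix(0, nrow(Wm), ncol(Wm))
  db <- numeric(dd[3])
  dx <- array(0, d)
  for (n in seq_len(d[4])) {
    cols <- im2col_same(array(x[, , , n], d[1:3]), k, stride)
    dzM <- matrix(dz[, , , n], dd[1] * dd[2], dd[3])
    dW <- dW + crossprod(cols, dzM)
    db <- db + colSums(dzM)
    dx[, , , n] <- col2im_same(dzM %*% t(Wm), d[1], d[2], d[3], k, stride)
  }
  list(dW = array(dW, dim(Wl$W)), db = db, dx = dx)
}

maxpoolForward <- function(x) {
  d <- dim(x)
  Hp <- 2L * ceiling(d[1] / 2); Wp <- 2L * ceiling(d[2] / 2)
  xp <- array(-Inf, c(Hp, Wp, d[3], d[4]))
  xp[seq_len(d[1]), seq_len(d[2]), , ] <- x
  planeIdx <- matrix(seq_len(Hp * Wp), Hp, Wp)
  or <- seq(1, Hp, 2); er <- seq(2, Hp, 2)
  oc <- seq(1, Wp, 2); ec <- seq(2, Wp, 2)
  pick <- function(r, c) xp[r, c, , , drop = FALSE]
  y <- pick(or, oc)
  best <- array(rep(planeIdx[or, oc], d[3] * d[4]), dim(y))
  for (rc in list(list(er, oc), list(or, ec), list(er, ec))) {
    cand <- pick(rc[[1]], rc[[2]])
    sel <- cand > y
    y[sel] <- cand[sel]
    ci <- array(rep(planeIdx[rc[[1]], rc[[2]]], d[3] * d[4]), dim(y))
    best[sel] <- ci[sel]
  }
  list(out = y, argmax = best, inDim = d, padDim = c(Hp, Wp))
}

maxpoolBackward <- function(dy, cache) {
  d <- dim(dy)
  Hp <- cache$padDim[1]; Wp <- cache$padDim[2]
  plane <- Hp * Wp
  off <- array(rep((seq_len(d[3] * d[4]) - 1) * plane, each = d[1] * d[2]),
               d)
  dxp <- numeric(plane * d[3] * d[4])
  dxp[cache$argmax + off] <- dy
  dxp <- array(dxp, c(Hp, Wp, d[3], d[4]))
  dxp[seq_len(cache$inDim[1]), seq_len(cache$inDim[2]), , , drop = FALSE]
}

upsampleForward <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
    drop = FALSE]
}

upsampleBackward <- function(dy) {
  d <- dim(dy)
  or <- seq(1, d[1], 2); er <- seq(2, d[1], 2)
  oc <- seq(1, d[2], 2); ec <- seq(2, d[2], 2)
  dy[or, oc, , , drop = FALSE] + dy[er, oc, , , drop = FALSE] +
    dy[or, ec, , , drop = FALSE] + dy[er, ec, , , drop = FALSE]
}

# Forward pass over the whole layer graph.
# xlist: list of H x W matrices. Returns per-layer caches.
forwardBatch <- function(spec, W, xlist, training = FALSE) {
  side <- spec@inputSide
  N <- length(xlist)
  x <- array(0, c(side, side, 1L, N))
  for (n in seq_len(N)) x[, , 1, n] <- xlist[[n]]
  acts <- new.env(parent = emptyenv())
  cache <- new.env(parent = emptyenv())
  assign("input", x, envir = acts)
  for (lay in spec@layers) {
    if (lay$kind == "input") next
    a <- get(lay$inputs[1], envir = acts)
    out <- switch(lay$kind,
      conv = {
        z <- convForward(a, W[[lay$name]], lay$kernel, lay$stride,
                         lay$filters)
        assign(lay$name, z, envir = cache)
        applyActivation(z, lay$activation)
      },
      maxpool = {
        mp <- maxpoolForward(a)
        assign(lay$name, mp, envir = cache)
        mp$out
      },
      upsample = upsampleForward(a),
      batchnorm = {
        p <- W[[lay$name]]
        if (training) {
          m <- apply(a, 3, mean)
          centered <- sweep(a, 3, m, "-")
          v <- apply(centered^2, 3, mean)
          xhat <- sweep(centered, 3, sqrt(v + BN_EPS), "/")
          W[[lay$name]]$rmean <- BN_MOMENTUM * p$rmean + (1 - BN_MOMENTUM) * m
          W[[lay$name]]$rvar <- BN_MOMENTUM * p$rvar + (1 - BN_MOMENTUM) * v
          assign(lay$name, list(xhat = xhat, v = v), envir = cache)
        } else {
          xhat <- sweep(sweep(a, 3, p$rmean, "-"), 3, sqrt(p$rvar + BN_EPS),
                        "/")
        }
        sweep(sweep(xhat, 3, p$gamma, "*"), 3, p$beta, "+")
      },
      dropout = {
        if (training) {
          mask <- array((runif(length(a)) >= lay$rate) / (1 - lay$rate),
                        dim(a))
          assign(lay$name, mask, envir = cache)
          a * mask
        } else a
      },
      concat = {
        b2 <- get(lay$inputs[2], envir = acts)
        d2 <- dim(b2)
        a <- cropPad4(a, d2[1], d2[2])
        assign(lay$name, dim(a)[3], envir = cache)  # decoder channel count
        y <- array(0, c(d2[1], d2[2], dim(a)[3] + d2[3], dim(a)[4]))
        y[, , seq_len(dim(a)[3]), ] <- a
        y[, , dim(a)[3] + seq_len(d2[3]), ] <- b2
        y
      },
      add = {
        b2 <- get(lay$inputs[2], envir = acts)
        d2 <- dim(b2)
        cropPad4(a, d2[1], d2[2]) + b2
      },
      stop("unknown layer kind: ", lay$kind))
    assign(lay$name, out, envir = acts)
  }
  # W is returned because training-mode batch norm updates running moments
  list(acts = acts, cache = cache, W = W)
}

# Backward pass. dzHead is the gradient w.r.t. the head's PRE-activation
# (loss and head activation fused). Returns per-layer parameter gradients.
backwardBatch <- function(spec, W, fw, dzHead) {
  acts <- fw$acts; cache <- fw$cache
  layerList <- spec@layers
  headName <- layerList[[length(layerList)]]$name
  grads <- new.env(parent = emptyenv())
  pgrads <- list()
  addGrad <- function(name, g) {
    if (exists(name, envir = grads))
      assign(name, get(name, envir = grads) + g, envir = grads)
    else assign(name, g, envir = grads)
  }
  assign(headName, dzHead, envir = grads)
  for (i in rev(seq_along(layerList))) {
    lay <- layerList[[i]]
    if (lay$kind == "input") next
    if (!exists(lay$name, envir = grads)) next
    g <- get(lay$name, envir = grads)
    if (lay$kind == "conv") {
      z <- get(lay$name, envir = cache)
      dz <- if (lay$name == headName) g
            else switch(lay$activation,
                        relu = g * (z > 0),
                        linear = g,
                        sigmoid = { p <- applyActivation(z, "sigmoid")
                                    g * p * (1 - p) },
                        stop("no gradient for activation ", lay$activation))
      x <- get(lay$inputs[1], envir = acts)
      cb <- convBackward(x, W[[lay$name]], dz, lay$kernel, lay$stride)
      pgrads[[lay$name]] <- list(W = cb$dW, b = cb$db)
      addGrad(lay$inputs[1], cb$dx)
    } else if (lay$kind == "maxpool") {
      addGrad(lay$inputs[1], maxpoolBackward(g, get(lay$name, envir = cache)))
    } else if (lay$kind == "upsample") {
      addGrad(lay$inputs[1], upsampleBackward(g))
    } else if (lay$kind == "batchnorm") {
      p <- W[[lay$name]]
      bc <- get(lay$name, envir = cache)
      xhat <- bc$xhat
      M <- prod(dim(g)[c(1, 2, 4)])
      dgamma <- apply(g * xhat, 3, sum)
      dbeta <- apply(g, 3, sum)
      dxhat <- sweep(g, 3, p$gamma, "*")
      sdx <- apply(dxhat, 3, sum)
      sdxx <- apply(dxhat * xhat, 3, sum)
      dx <- sweep(M * dxhat, 3, sdx, "-") - sweep(xhat, 3, sdxx, "*")
      dx <- sweep(dx, 3, M * sqrt(bc$v + BN_EPS), "/")
      pgrads[[lay$name]] <- list(gamma = dgamma, beta = dbeta)
      addGrad(lay$inputs[1], dx)
    } else if (lay$kind == "dropout") {
      addGrad(lay$inputs[1], g * get(lay$name, envir = cache))
    } else if (lay$kind == "concat") {
      c1 <- get(lay$name, envir = cache)
      g1 <- g[, , seq_len(c1), , drop = FALSE]
      g2 <- g[, , c1 + seq_len(dim(g)[3] - c1), , drop = FALSE]
      din <- dim(get(lay$inputs[1], envir = acts))
      addGrad(lay$inputs[1], cropPad4(g1, din[1], din[2]))
      addGrad(lay$inputs[2], g2)
    } else if (lay$kind == "add") {
      din <- dim(get(lay$inputs[1], envir = acts))
      addGrad(lay$inputs[1], cropPad4(g, din[1], din[2]))
      addGrad(lay$inputs[2], g)
    }
  }
  pgrads
}

# Loss (+ head pre-activation gradient) for sigmoid/BCE or softmax/CE.
lossAndGrad <- function(spec, fw, ylist) {
  headLay <- spec@layers[[length(spec@layers)]]
  p <- get(headLay$name, envir = fw$acts)
  d <- dim(p)
  N <- d[4]
  eps <- 1e-7
  if (headLay$activation == "softmax") {
    Y <- array(0, d)
    for (n in seq_len(N)) {
      Y[, , 2, n] <- ylist[[n]]
      Y[, , 1, n] <- 1 - ylist[[n]]
    }
    pc <- pmin(pmax(p, eps), 1 - eps)
    loss <- -sum(Y * log(pc)) / (d[1] * d[2] * N)
    dz <- (p - Y) / (d[1] * d[2] * N)
  } else {
    y <- array(0, d)
    for (n in seq_len(N)) y[, , 1, n] <- ylist[[n]]
    pc <- pmin(pmax(p, eps), 1 - eps)
    loss <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
    dz <- (p - y) / (d[1] * d[2] * N)
  }
  list(loss = loss, dz = dz)
}

# Scale all gradients so their global L2 norm is at most maxNorm.
clipGradients <- function(pgrads, maxNorm) {
  if (!is.finite(maxNorm)) return(pgrads)
  total <- 0
  for (l in pgrads) for (g in l) total <- total + sum(g^2)
  nrm <- sqrt(total)
  if (nrm <= maxNorm) return(pgrads)
  sc <- maxNorm / nrm
  for (ln in names(pgrads))
    for (pn in names(pgrads[[ln]]))
      pgrads[[ln]][[pn]] <- pgrads[[ln]][[pn]] * sc
  pgrads
}

# One Adam update over all parameter arrays; state carries (m, v, t).
adamStep <- function(W, pgrads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1
  for (lname in names(pgrads)) {
    for (pname in names(pgrads[[lname]])) {
      g <- pgrads[[lname]][[pname]]
      key <- paste0(lname, ".", pname)
      if (is.null(state$m[[key]])) {
        state$m[[key]] <- g * 0
        state$v[[key]] <- g * 0
      }
      state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
      state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g^2
      mhat <- state$m[[key]] / (1 - beta1^state$t)
      vhat <- state$v[[key]] / (1 - beta2^state$t)
      W[[lname]][[pname]] <- W[[lname]][[pname]] -
        lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(W = W, state = state)
}
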