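# Minimal neural-network layer library with manual backpropagation.
#
# No deep-learning framework is available in this R environment, so the
# layers needed by the model families (dense, ReLU, batch normalization,
# dropout, flatten, 1D/2D convolution with same-padding and L1/L2 kernel
# regularization, 2x2 max-pooling, LSTM) are implemented directly on base R
# arrays. Convolutions use a shift-and-matmul scheme: a k-tap convolution is
# the sum of k (spatially shifted input) %*% (tap weight matrix) products,
# so all heavy lifting happens in BLAS.
#
# Array conventions (batch first, channels last):
#   dense N x D; conv1d N x L x C; conv2d N x H x W x C; lstm N x T x C.
# Every forward returns list(out, cache, layer); every backward returns
# list(dx, grads). Layers are plain lists; `params` holds trainable arrays.

#' Neural-network layer constructors
#'
#' Building blocks for [nn_sequential()] networks: fully connected
#' (`layer_dense`), ReLU, batch normalization, (inverted) dropout, flatten,
#' same-padded 1D/2D convolution with optional L1/L2 kernel regularization,
#' 2x2 max-pooling, and an LSTM returning its final hidden state.
#'
#' @param units Layer width (dense: output units; lstm: hidden state size).
#' @param momentum,eps Batch-norm running-statistics momentum and variance
#'   floor.
#' @param rate Dropout rate in `[0, 1)`.
#' @param filters,kernel Convolution filter count and kernel size.
#' @param l1,l2 Kernel regularization coefficients (convolutions only).
#' @return A layer specification list consumed by [nn_sequential()].
#' @name nn_layers
NULL

#' @rdname nn_layers
#' @export
layer_dense <- function(units) {
  list(type = "dense", units = as.integer(units))
}
#' @rdname nn_layers
#' @export
layer_relu <- function() list(type = "relu")
#' @rdname nn_layers
#' @export
layer_batchnorm <- function(momentum = 0.9, eps = 1e-5) {
  list(type = "batchnorm", momentum = momentum, eps = eps)
}
#' @rdname nn_layers
#' @export
layer_dropout <- function(rate = 0.3) list(type = "dropout", rate = rate)
#' @rdname nn_layers
#' @export
layer_flatten <- function() list(type = "flatten")
#' @rdname nn_layers
#' @export
layer_conv1d <- function(filters, kernel = 3L, l1 = 0, l2 = 0) {
  list(type = "conv1d", filters = as.integer(filters),
       kernel = as.integer(kernel), l1 = l1, l2 = l2)
}
#' @rdname nn_layers
#' @export
layer_conv2d <- function(filters, kernel = 5L, l1 = 0, l2 = 0) {
  list(type = "conv2d", filters = as.integer(filters),
       kernel = as.integer(kernel), l1 = l1, l2 = l2)
}
#' @rdname nn_layers
#' @export
layer_maxpool2d <- function() list(type = "maxpool2d")
#' @rdname nn_layers
#' @export
layer_lstm <- function(units) list(type = "lstm", units = as.integer(units))

# ---- shape propagation & parameter init -----------------------------------

.init_layer <- function(layer, in_shape) {
  he <- function(fan_in, n) {
    array(stats::rnorm(n, sd = sqrt(2 / fan_in)), dim = NULL)
  }
  switch(layer$type,
    dense = {
      stopifnot(length(in_shape) == 1)
      D <- in_shape; U <- layer$units
      layer$params <- list(W = matrix(stats::rnorm(D * U, sd = sqrt(2 / D)), D, U),
                           b = rep(0, U))
      layer$out_shape <- U
    },
    relu = , dropout = {
      layer$out_shape <- in_shape
    },
    batchnorm = {
      C <- in_shape[length(in_shape)]
      layer$params <- list(gamma = rep(1, C), beta = rep(0, C))
      layer$run_mean <- rep(0, C)
      layer$run_var <- rep(1, C)
      layer$out_shape <- in_shape
    },
    flatten = {
      layer$out_shape <- prod(in_shape)
    },
    conv1d = {
      stopifnot(length(in_shape) == 2)
      k <- layer$kernel; C <- in_shape[2]; F <- layer$filters
      layer$params <- list(
        W = array(stats::rnorm(k * C * F, sd = sqrt(2 / (k * C))), c(k, C, F)),
        b = rep(0, F))
      layer$out_shape <- c(in_shape[1], F)
    },
    conv2d = {
      stopifnot(length(in_shape) == 3)
      k <- layer$kernel; C <- in_shape[3]; F <- layer$filters
      layer$params <- list(
        W = array(stats::rnorm(k * k * C * F, sd = sqrt(2 / (k * k * C))),
                  c(k, k, C, F)),
        b = rep(0, F))
      layer$out_shape <- c(in_shape[1:2], F)
    },
    maxpool2d = {
      stopifnot(length(in_shape) == 3)
      layer$out_shape <- c(ceiling(in_shape[1] / 2), ceiling(in_shape[2] / 2),
                           in_shape[3])
    },
    lstm = {
      stopifnot(length(in_shape) == 2)
      C <- in_shape[2]; H <- layer$units
      layer$params <- list(
        Wx = matrix(stats::rnorm(C * 4 * H, sd = sqrt(1 / C)), C, 4 * H),
        Wh = matrix(stats::rnorm(H * 4 * H, sd = sqrt(1 / H)), H, 4 * H),
        b = rep(0, 4 * H))
      layer$out_shape <- H
    },
    stop("unknown layer type: ", layer$type)
  )
  layer$in_shape <- in_shape
  layer
}

# ---- forward / backward ----------------------------------------------------

.as_channels <- function(x) {
  # reshape any channels-last array to (everything else) x channels
  d <- dim(x)
  if (is.null(d)) stop("expected array input")
  C <- d[length(d)]
  dim(x) <- c(prod(d[-length(d)]), C)
  x
}

.layer_forward <- function(layer, x, training, need_cache = TRUE) {
  switch(layer$type,
    dense = {
      out <- sweep(x %*% layer$params$W, 2, layer$params$b, "+")
      list(out = out, cache = list(x = x), layer = layer)
    },
    relu = {
      mask <- x > 0
      list(out = x * mask, cache = list(mask = mask), layer = layer)
    },
    dropout = {
      if (training && layer$rate > 0) {
        keep <- 1 - layer$rate
        mask <- array(stats::rbinom(length(x), 1, keep) / keep, dim = dim(x))
        list(out = x * mask, cache = list(mask = mask), layer = layer)
      } else {
        list(out = x, cache = list(mask = NULL), layer = layer)
      }
    },
    batchnorm = {
      d <- dim(x)
      x2 <- .as_channels(x)
      if (training) {
        mu <- colMeans(x2)
        v <- colMeans(x2^2) - mu^2
        layer$run_mean <- layer$momentum * layer$run_mean + (1 - layer$momentum) * mu
        layer$run_var <- layer$momentum * layer$run_var + (1 - layer$momentum) * v
      } else {
        mu <- layer$run_mean
        v <- layer$run_var
      }
      inv_sd <- 1 / sqrt(v + layer$eps)
      xhat <- sweep(sweep(x2, 2, mu, "-"), 2, inv_sd, "*")
      out <- sweep(sweep(xhat, 2, layer$params$gamma, "*"), 2,
                   layer$params$beta, "+")
      dim(out) <- d
      list(out = out,
           cache = list(xhat = xhat, inv_sd = inv_sd, d = d,
                        training = training),
           layer = layer)
    },
    flatten = {
      d <- dim(x)
      out <- x
      dim(out) <- c(d[1], prod(d[-1]))
      list(out = out, cache = list(d = d), layer = layer)
    },
    conv1d = {
      d <- dim(x); N <- d[1]; L <- d[2]; C <- d[3]
      k <- layer$kernel; F <- layer$filters
      pl <- (k - 1) %/% 2; pr <- k - 1 - pl
      xp <- array(0, c(N, L + k - 1, C))
      xp[, pl + seq_len(L), ] <- x
      out <- matrix(rep(layer$params$b, each = N * L), N * L, F)
      slices <- vector("list", k)
      for (dk in seq_len(k)) {
        xd <- xp[, dk:(dk + L - 1), , drop = FALSE]
        dim(xd) <- c(N * L, C)
        if (need_cache) slices[[dk]] <- xd
        Wm <- layer$params$W[dk, , , drop = TRUE]
        if (is.null(dim(Wm))) Wm <- matrix(Wm, nrow = C)
        out <- out + xd %*% Wm
      }
      dim(out) <- c(N, L, F)
      list(out = out, cache = list(slices = slices, N = N, L = L, C = C),
           layer = layer)
    },
    conv2d = {
      d <- dim(x); N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
      k <- layer$kernel; F <- layer$filters
      p <- (k - 1) %/% 2
      xp <- array(0, c(N, H + k - 1, W + k - 1, C))
      xp[, p + seq_len(H), p + seq_len(W), ] <- x
      out <- matrix(rep(layer$params$b, each = N * H * W), N * H * W, F)
      slices <- vector("list", k * k)
      for (di in seq_len(k)) for (dj in seq_len(k)) {
        xd <- xp[, di:(di + H - 1), dj:(dj + W - 1), , drop = FALSE]
        dim(xd) <- c(N * H * W, C)
        idx <- (di - 1) * k + dj
        if (need_cache) slices[[idx]] <- xd
        Wm <- layer$params$W[di, dj, , , drop = TRUE]
        if (is.null(dim(Wm))) Wm <- matrix(Wm, nrow = C)
        out <- out + xd %*% Wm
      }
      dim(out) <- c(N, H, W, F)
      list(out = out,
           cache = list(slices = slices, N = N, H = H, W = W, C = C),
           layer = layer)
    },
    maxpool2d = {
      d <- dim(x); N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
      He <- 2 * ceiling(H / 2); We <- 2 * ceiling(W / 2)
      xp <- array(-Inf, c(N, He, We, C))
      xp[, seq_len(H), seq_len(W), ] <- x
      H2 <- He / 2; W2 <- We / 2
      cand <- array(0, c(N, H2, W2, C, 4))
      q <- 0
      for (di in 1:2) for (dj in 1:2) {
        q <- q + 1
        cand[, , , , q] <- xp[, seq(di, He, 2), seq(dj, We, 2), , drop = FALSE]
      }
      # max and argmax (first winner) for backward routing
      arg <- array(1L, c(N, H2, W2, C))
      best <- cand[, , , , 1, drop = FALSE]
      dim(best) <- c(N, H2, W2, C)
      for (q in 2:4) {
        cq <- cand[, , , , q, drop = FALSE]
        dim(cq) <- c(N, H2, W2, C)
        better <- cq > best
        arg[better] <- q
        best[better] <- cq[better]
      }
      list(out = best, cache = list(arg = arg, d = d, He = He, We = We),
           layer = layer)
    },
    lstm = {
      d <- dim(x); N <- d[1]; T <- d[2]; C <- d[3]
      H <- layer$units
      Wx <- layer$params$Wx; Wh <- layer$params$Wh; b <- layer$params$b
      h <- matrix(0, N, H); cc <- matrix(0, N, H)
      steps <- vector("list", T)
      for (t in seq_len(T)) {
        xt <- x[, t, , drop = FALSE]; dim(xt) <- c(N, C)
        A <- sweep(xt %*% Wx + h %*% Wh, 2, b, "+")
        i <- 1 / (1 + exp(-A[, 1:H, drop = FALSE]))
        f <- 1 / (1 + exp(-A[, H + 1:H, drop = FALSE]))
        o <- 1 / (1 + exp(-A[, 2 * H + 1:H, drop = FALSE]))
        g <- tanh(A[, 3 * H + 1:H, drop = FALSE])
        c_new <- f * cc + i * g
        tc <- tanh(c_new)
        h_new <- o * tc
        steps[[t]] <- list(xt = xt, h_prev = h, c_prev = cc,
                           i = i, f = f, o = o, g = g, tc = tc)
        h <- h_new; cc <- c_new
      }
      list(out = h, cache = list(steps = steps, N = N, T = T, C = C, H = H),
           layer = layer)
    },
    stop("unknown layer type: ", layer$type)
  )
}

.layer_backward <- function(layer, dout, cache) {
  switch(layer$type,
    dense = {
      list(dx = dout %*% t(layer$params$W),
           grads = list(W = t(cache$x) %*% dout, b = colSums(dout)))
    },
    relu = {
      list(dx = dout * cache$mask, grads = NULL)
    },
    dropout = {
      if (is.null(cache$mask)) list(dx = dout, grads = NULL)
      else list(dx = dout * cache$mask, grads = NULL)
    },
    batchnorm = {
      d <- cache$d
      dout2 <- .as_channels(dout)
      xhat <- cache$xhat
      gamma <- layer$params$gamma
      dgamma <- colSums(dout2 * xhat)
      dbeta <- colSums(dout2)
      if (cache$training) {
        M <- nrow(dout2)
        dxhat <- sweep(dout2, 2, gamma, "*")
        t1 <- sweep(dxhat, 2, colSums(dxhat) / M, "-")
        t2 <- sweep(xhat, 2, colSums(dxhat * xhat) / M, "*")
        dx <- sweep(t1 - t2, 2, cache$inv_sd, "*")
      } else {
        dx <- sweep(sweep(dout2, 2, gamma, "*"), 2, cache$inv_sd, "*")
      }
      dim(dx) <- d
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    flatten = {
      dx <- dout
      dim(dx) <- cache$d
      list(dx = dx, grads = NULL)
    },
    conv1d = {
      N <- cache$N; L <- cache$L; C <- cache$C
      k <- layer$kernel; F <- layer$filters
      pl <- (k - 1) %/% 2
      dout2 <- dout; dim(dout2) <- c(N * L, F)
      dW <- array(0, c(k, C, F))
      dxp <- array(0, c(N, L + k - 1, C))
      for (dk in seq_len(k)) {
        dW[dk, , ] <- t(cache$slices[[dk]]) %*% dout2
        Wm <- layer$params$W[dk, , , drop = TRUE]
        if (is.null(dim(Wm))) Wm <- matrix(Wm, nrow = C)
        dslice <- dout2 %*% t(Wm)
        dim(dslice) <- c(N, L, C)
        dxp[, dk:(dk + L - 1), ] <- dxp[, dk:(dk + L - 1), , drop = FALSE] + dslice
      }
      dx <- dxp[, pl + seq_len(L), , drop = FALSE]
      dim(dx) <- c(N, L, C)
      W <- layer$params$W
      if (layer$l2 > 0) dW <- dW + 2 * layer$l2 * W
      if (layer$l1 > 0) dW <- dW + layer$l1 * sign(W)
      list(dx = dx, grads = list(W = dW, b = colSums(dout2)))
    },
    conv2d = {
      N <- cache$N; H <- cache$H; W_ <- cache$W; C <- cache$C
      k <- layer$kernel; F <- layer$filters
      p <- (k - 1) %/% 2
      dout2 <- dout; dim(dout2) <- c(N * H * W_, F)
      dW <- array(0, c(k, k, C, F))
      dxp <- array(0, c(N, H + k - 1, W_ + k - 1, C))
      for (di in seq_len(k)) for (dj in seq_len(k)) {
        idx <- (di - 1) * k + dj
        dW[di, dj, , ] <- t(cache$slices[[idx]]) %*% dout2
        Wm <- layer$params$W[di, dj, , , drop = TRUE]
        if (is.null(dim(Wm))) Wm <- matrix(Wm, nrow = C)
        dslice <- dout2 %*% t(Wm)
        dim(dslice) <- c(N, H, W_, C)
        dxp[, di:(di + H - 1), dj:(dj + W_ - 1), ] <-
          dxp[, di:(di + H - 1), dj:(dj + W_ - 1), , drop = FALSE] + dslice
      }
      dx <- dxp[, p + seq_len(H), p + seq_len(W_), , drop = FALSE]
      dim(dx) <- c(N, H, W_, C)
      Wk <- layer$params$W
      dWreg <- dW
      if (layer$l2 > 0) dWreg <- dWreg + 2 * layer$l2 * Wk
      if (layer$l1 > 0) dWreg <- dWreg + layer$l1 * sign(Wk)
      list(dx = dx, grads = list(W = dWreg, b = colSums(dout2)))
    },
    maxpool2d = {
      d <- cache$d; N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
      He <- cache$He; We <- cache$We
      dxp <- array(0, c(N, He, We, C))
      q <- 0
      for (di in 1:2) for (dj in 1:2) {
        q <- q + 1
        contrib <- dout * (cache$arg == q)
        dxp[, seq(di, He, 2), seq(dj, We, 2), ] <-
          dxp[, seq(di, He, 2), seq(dj, We, 2), , drop = FALSE] + contrib
      }
      dx <- dxp[, seq_len(H), seq_len(W), , drop = FALSE]
      dim(dx) <- c(N, H, W, C)
      list(dx = dx, grads = NULL)
    },
    lstm = {
      N <- cache$N; T <- cache$T; C <- cache$C; H <- cache$H
      Wx <- layer$params$Wx; Wh <- layer$params$Wh
      dWx <- matrix(0, C, 4 * H); dWh <- matrix(0, H, 4 * H); db <- rep(0, 4 * H)
      dx <- array(0, c(N, T, C))
      dh <- dout
      dc <- matrix(0, N, H)
      for (t in rev(seq_len(T))) {
        st <- cache$steps[[t]]
        do_ <- dh * st$tc
        dc <- dc + dh * st$o * (1 - st$tc^2)
        di_ <- dc * st$g
        dg <- dc * st$i
        df <- dc * st$c_prev
        dc <- dc * st$f
        dA <- cbind(di_ * st$i * (1 - st$i),
                    df * st$f * (1 - st$f),
                    do_ * st$o * (1 - st$o),
                    dg * (1 - st$g^2))
        dWx <- dWx + t(st$xt) %*% dA
        dWh <- dWh + t(st$h_prev) %*% dA
        db <- db + colSums(dA)
        dh <- dA %*% t(Wh)
        dx[, t, ] <- dA %*% t(Wx)
      }
      list(dx = dx, grads = list(Wx = dWx, Wh = dWh, b = db))
    },
    stop("unknown layer type: ", layer$type)
  )
}
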