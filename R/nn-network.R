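# Sequential network container: initialization, forward/backward passes,
# Adam optimizer, mini-batch training with early stopping, prediction, and
# input-gradient computation (used by VIS4Map saliency).

#' Create a sequential neural network
#'
#' @param layers A list of layer specs (`layer_dense()`, `layer_conv2d()`, ...).
#' @param input_shape Integer vector: shape of one sample (without the batch
#'   dimension), e.g. `c(145, 4)` for one-hot sequences.
#' @param loss `"mse"` (linear regression head) or `"softmax_ce"`
#'   (classification head; final dense layer gives the logits).
#' @param seed Optional integer seed for reproducible initialization.
#' @return An object of class `nn_net`.
#' @export
nn_sequential <- function(layers, input_shape, loss = c("mse", "softmax_ce"),
                          seed = NULL) {
  loss <- match.arg(loss)
  if (!is.null(seed)) set.seed(seed)
  shape <- input_shape
  layers <- lapply(layers, function(ly) {
    ly <- .init_layer(ly, shape)
    shape <<- ly$out_shape
    ly
  })
  structure(list(layers = layers, input_shape = input_shape,
                 output_shape = shape, loss = loss, trained = FALSE),
            class = "nn_net")
}

#' @export
print.nn_net <- function(x, ...) {
  cat("sequential network (", length(x$layers), " layers, loss ", x$loss,
      ", ", format(nn_count_params(x), big.mark = ","), " parameters)\n",
      sep = "")
  for (ly in x$layers) {
    cat("  ", format(ly$type, width = 10), " -> [",
        paste(ly$out_shape, collapse = " x "), "]\n", sep = "")
  }
  invisible(x)
}

#' Number of trainable parameters
#' @param net An `nn_net`.
#' @return Integer parameter count.
#' @export
nn_count_params <- function(net) {
  sum(vapply(net$layers, function(ly) {
    if (is.null(ly$params)) 0L else sum(vapply(ly$params, length, integer(1)))
  }, integer(1)))
}

.nn_forward <- function(net, x, training = FALSE, need_cache = TRUE) {
  caches <- vector("list", length(net$layers))
  for (li in seq_along(net$layers)) {
    fw <- .layer_forward(net$layers[[li]], x, training, need_cache)
    x <- fw$out
    if (need_cache) caches[li] <- list(fw$cache)
    net$layers[[li]] <- fw$layer
  }
  list(out = x, caches = caches, net = net)
}

# batched inference-mode loss (no caches kept: memory-safe for big inputs)
.nn_eval_loss <- function(net, x, y, batch_size = 64L) {
  N <- dim(x)[1]
  tot <- 0
  for (start in seq(1L, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, N)
    out <- .nn_forward(net, .slice_batch(x, idx), training = FALSE,
                       need_cache = FALSE)$out
    tot <- tot + .nn_loss(out, y[idx, , drop = FALSE], net$loss)$value *
      length(idx)
  }
  tot / N
}

.nn_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  for (li in rev(seq_along(net$layers))) {
    bw <- .layer_backward(net$layers[[li]], dout, caches[[li]])
    dout <- bw$dx
    grads[li] <- list(bw$grads)   # keep NULL slots (parameter-free layers)
  }
  list(grads = grads, dx = dout)
}

.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

.nn_loss <- function(out, y, loss) {
  N <- nrow(out)
  if (loss == "mse") {
    diff <- out - y
    list(value = mean(diff^2), dout = 2 * diff / length(diff))
  } else {
    p <- .softmax(out)
    eps <- 1e-12
    list(value = -mean(rowSums(y * log(p + eps))),
         dout = (p - y) / N)
  }
}

.slice_batch <- function(x, idx) {
  d <- dim(x)
  if (is.null(d) || length(d) == 2) return(x[idx, , drop = FALSE])
  if (length(d) == 3) return(x[idx, , , drop = FALSE])
  if (length(d) == 4) return(x[idx, , , , drop = FALSE])
  stop("unsupported array rank")
}

.adam_init <- function(net) {
  lapply(net$layers, function(ly) {
    if (is.null(ly$params)) return(NULL)
    lapply(ly$params, function(p) list(m = p * 0, v = p * 0))
  })
}

.adam_step <- function(net, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  for (li in seq_along(net$layers)) {
    g <- grads[[li]]
    if (is.null(g)) next
    for (pn in names(g)) {
      st <- state[[li]][[pn]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[pn]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[pn]]^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      net$layers[[li]]$params[[pn]] <-
        net$layers[[li]]$params[[pn]] - lr * mhat / (sqrt(vhat) + eps)
      state[[li]][[pn]] <- st
    }
  }
  list(net = net, state = state)
}

#' Train a network
#'
#' Mini-batch Adam with early stopping on validation loss. Defaults follow
#' the package's training protocol: up to 300 epochs, patience 20,
#' batch size 64, Adam at learning rate 1e-3 (the optimizer and rate are
#' package defaults, not study-specified values).
#'
#' @param net An [nn_sequential()] network.
#' @param x,y Training inputs/targets (batch-first arrays; `y` a matrix with
#'   one column per output, one-hot for classification).
#' @param x_val,y_val Optional validation split for early stopping; when
#'   omitted, `val_fraction` of the training data is held out.
#' @param epochs,patience,batch_size,lr Training hyperparameters.
#' @param val_fraction Fraction held out when no validation set is given.
#' @param seed Optional seed (shuffling, dropout).
#' @param verbose Print a line per epoch.
#' @return The trained `nn_net`, with a `history` tibble and the best
#'   (early-stopped) weights restored.
#' @export
nn_fit <- function(net, x, y, x_val = NULL, y_val = NULL, epochs = 300L,
                   patience = 20L, batch_size = 64L, lr = 1e-3,
                   val_fraction = 0.1, seed = NULL, verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  y <- as.matrix(y)
  N <- if (is.null(dim(x))) length(x) else dim(x)[1]
  stopifnot(nrow(y) == N)
  if (is.null(x_val)) {
    n_val <- max(1L, floor(val_fraction * N))
    vi <- sample.int(N, n_val)
    x_val <- .slice_batch(x, vi); y_val <- y[vi, , drop = FALSE]
    x <- .slice_batch(x, -vi); y <- y[-vi, , drop = FALSE]
    N <- N - n_val
  } else {
    y_val <- as.matrix(y_val)
  }
  state <- .adam_init(net)
  best_loss <- Inf; best_net <- net; wait <- 0L; t <- 0L
  history <- list()
  for (ep in seq_len(epochs)) {
    ord <- sample.int(N)
    tr_loss <- 0; nb <- 0L
    for (start in seq(1L, N, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, N)]
      xb <- .slice_batch(x, idx); yb <- y[idx, , drop = FALSE]
      fw <- .nn_forward(net, xb, training = TRUE)
      net <- fw$net
      ls <- .nn_loss(fw$out, yb, net$loss)
      bw <- .nn_backward(net, fw$caches, ls$dout)
      t <- t + 1L
      up <- .adam_step(net, bw$grads, state, lr, t)
      net <- up$net; state <- up$state
      tr_loss <- tr_loss + ls$value; nb <- nb + 1L
    }
    val_loss <- .nn_eval_loss(net, x_val, y_val, batch_size)
    history[[ep]] <- tibble::tibble(epoch = ep, train_loss = tr_loss / nb,
                                    val_loss = val_loss)
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  val %.5f", ep, tr_loss / nb,
                      val_loss))
    }
    if (val_loss < best_loss - 1e-7) {
      best_loss <- val_loss; best_net <- net; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  best_net$history <- dplyr::bind_rows(history)
  best_net$trained <- TRUE
  best_net
}

#' Predict with a trained network
#'
#' @param object An `nn_net`.
#' @param x Input batch array.
#' @param type `"response"`: regression outputs or class probabilities;
#'   `"raw"`: pre-softmax logits.
#' @param batch_size Evaluation batch size (memory control).
#' @param ... Unused.
#' @return A matrix of outputs (N x n_outputs).
#' @export
predict.nn_net <- function(object, x, type = c("response", "raw"),
                           batch_size = 64L, ...) {
  type <- match.arg(type)
  N <- dim(x)[1]
  outs <- list()
  for (start in seq(1L, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, N)
    outs[[length(outs) + 1L]] <-
      .nn_forward(object, .slice_batch(x, idx), training = FALSE,
                  need_cache = FALSE)$out
  }
  out <- do.call(rbind, outs)
  if (type == "response" && object$loss == "softmax_ce") out <- .softmax(out)
  out
}

#' Gradient of one output head with respect to the input
#'
#' Runs the network in inference mode (dropout off, batch-norm on running
#' statistics) and backpropagates a unit gradient from the selected output
#' head down to the input tensor.
#'
#' @param net A trained `nn_net`.
#' @param x A single-sample batch (leading dimension 1) or larger batch.
#' @param head Output column index (default 1).
#' @return An array with the same shape as `x`.
#' @export
nn_input_gradient <- function(net, x, head = 1L) {
  fw <- .nn_forward(net, x, training = FALSE)
  dout <- matrix(0, nrow(fw$out), ncol(fw$out))
  dout[, head] <- 1
  .nn_backward(fw$net, fw$caches, dout)$dx
}
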