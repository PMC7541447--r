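# Model families and training/evaluation protocol.
#
# Seven families: an MLP on the 30 rational features (dense 25/10/7), an MLP
# on the flattened one-hot sequence (dense 128/64/32), a hybrid MLP joining
# both branches through a 4-unit dense layer, a 1D CNN on the one-hot
# sequence (32/64/128 filters of size 3), a 2D CNN on the complementarity
# map (32/64/128 filters of 5x5, each block followed by 2x2 max-pooling), an
# LSTM (128 units + dense 100), and a linear/logistic baseline. All hidden
# blocks use ReLU, batch normalization and 30% dropout. Regression uses a
# 3-output linear head (ON, OFF, ON/OFF) and MSE; classification a 2-output
# softmax head (positive iff ON/OFF >= 0.7). Optimizer Adam at 1e-3
# (a package default; the study does not state optimizer or rate).

# sample() without the scalar-x trap
.resample <- function(x, n, replace = FALSE) {
  x[sample.int(length(x), n, replace = replace)]
}

.MODEL_FAMILIES <- c("mlp_rational", "mlp_onehot", "mlp_hybrid",
                     "cnn_onehot", "cnn_map", "lstm_onehot",
                     "logistic_baseline")

#' Model specification
#'
#' @param family One of `"mlp_rational"`, `"mlp_onehot"`, `"mlp_hybrid"`,
#'   `"cnn_onehot"`, `"cnn_map"`, `"lstm_onehot"`, `"logistic_baseline"`.
#' @param mode `"regression"` (linear head, 3 outputs by default) or
#'   `"classification"` (2-output softmax).
#' @param n_outputs Regression head width (default 3: ON, OFF, ON/OFF; set
#'   to 1 for single-target models such as an MFE predictor).
#' @param dropout Dropout rate (default 0.30).
#' @param l1,l2 Kernel regularization for convolutional layers
#'   (package defaults; coefficients are not study-specified).
#' @param conv_filters,conv_kernel Override the convolution stack (vector of
#'   filter counts and kernel size) for scaled-down CNNs.
#' @param dense_units Override the post-convolution dense stack.
#' @return A `model_spec` list.
#' @export
model_spec <- function(family, mode = c("regression", "classification"),
                       n_outputs = 3L, dropout = 0.30, l1 = 1e-5, l2 = 1e-4,
                       conv_filters = NULL, conv_kernel = NULL,
                       dense_units = NULL) {
  family <- match.arg(family, .MODEL_FAMILIES)
  mode <- match.arg(mode)
  structure(list(family = family, mode = mode,
                 n_outputs = if (mode == "classification") 2L else as.integer(n_outputs),
                 dropout = dropout, l1 = l1, l2 = l2,
                 conv_filters = conv_filters, conv_kernel = conv_kernel,
                 dense_units = dense_units),
            class = "model_spec")
}

.head_loss <- function(spec) if (spec$mode == "classification") "softmax_ce" else "mse"

.dense_block <- function(units, dropout) {
  list(layer_dense(units), layer_relu(), layer_batchnorm(),
       layer_dropout(dropout))
}

#' Build a trainable model from a specification
#'
#' @param spec A [model_spec()].
#' @param input_shape Shape of one sample, e.g. `30` (rational features),
#'   `c(145, 4)` (one-hot), `c(145, 145, 7)` (complementarity map). For
#'   `mlp_hybrid` supply `list(rational = 30, onehot = c(145, 4))`.
#' @param seed Seed for reproducible initialization.
#' @return An `nn_net` (or `nn_hybrid` for the hybrid family).
#' @export
build_model <- function(spec, input_shape, seed = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  dr <- spec$dropout
  head <- list(layer_dense(spec$n_outputs))
  loss <- .head_loss(spec)
  if (spec$family == "mlp_hybrid") {
    return(.build_hybrid(spec, input_shape, seed))
  }
  layers <- switch(spec$family,
    mlp_rational = c(.dense_block(25, dr), .dense_block(10, dr),
                     .dense_block(7, dr), head),
    mlp_onehot = c(list(layer_flatten()), .dense_block(128, dr),
                   .dense_block(64, dr), .dense_block(32, dr), head),
    logistic_baseline = c(if (length(input_shape) > 1) list(layer_flatten()),
                          head),
    cnn_onehot = {
      f <- spec$conv_filters %||% c(32, 64, 128)
      k <- spec$conv_kernel %||% 3L
      conv <- unlist(lapply(f, function(nf) {
        list(layer_conv1d(nf, k, l1 = spec$l1, l2 = spec$l2), layer_relu(),
             layer_batchnorm(), layer_dropout(dr))
      }), recursive = FALSE)
      du <- spec$dense_units %||% c(16, 16)
      dense <- unlist(lapply(du, .dense_block, dropout = dr),
                      recursive = FALSE)
      c(conv, list(layer_flatten()), dense, head)
    },
    cnn_map = {
      f <- spec$conv_filters %||% c(32, 64, 128)
      k <- spec$conv_kernel %||% 5L
      conv <- unlist(lapply(f, function(nf) {
        list(layer_conv2d(nf, k, l1 = spec$l1, l2 = spec$l2), layer_relu(),
             layer_batchnorm(), layer_maxpool2d(), layer_dropout(dr))
      }), recursive = FALSE)
      du <- spec$dense_units %||% c(16, 16)
      dense <- unlist(lapply(du, .dense_block, dropout = dr),
                      recursive = FALSE)
      c(conv, list(layer_flatten()), dense, head)
    },
    lstm_onehot = c(list(layer_lstm(128)), .dense_block(100, dr), head)
  )
  net <- nn_sequential(layers, input_shape, loss = loss, seed = seed)
  net$spec <- spec
  net
}

# hybrid: rational branch (25/10/7) and one-hot branch (128/64/32) joined by
# a 4-unit dense layer, then the output head. Implemented as a composite of
# three sequential nets with manual gradient routing through the concat.
.build_hybrid <- function(spec, input_shape, seed = NULL) {
  stopifnot(is.list(input_shape),
            all(c("rational", "onehot") %in% names(input_shape)))
  if (!is.null(seed)) set.seed(seed)
  dr <- spec$dropout
  branch_r <- nn_sequential(c(.dense_block(25, dr), .dense_block(10, dr),
                              .dense_block(7, dr)),
                            input_shape$rational, loss = "mse")
  branch_o <- nn_sequential(c(list(layer_flatten()), .dense_block(128, dr),
                              .dense_block(64, dr), .dense_block(32, dr)),
                            input_shape$onehot, loss = "mse")
  joiner <- nn_sequential(c(.dense_block(4, dr),
                            list(layer_dense(spec$n_outputs))),
                          branch_r$output_shape + branch_o$output_shape,
                          loss = .head_loss(spec))
  structure(list(branch_r = branch_r, branch_o = branch_o, joiner = joiner,
                 loss = .head_loss(spec), spec = spec, trained = FALSE),
            class = "nn_hybrid")
}

.hybrid_forward <- function(net, xr, xo, training = FALSE) {
  fr <- .nn_forward(net$branch_r, xr, training)
  fo <- .nn_forward(net$branch_o, xo, training)
  fj <- .nn_forward(net$joiner, cbind(fr$out, fo$out), training)
  net$branch_r <- fr$net; net$branch_o <- fo$net; net$joiner <- fj$net
  list(out = fj$out, net = net,
       caches = list(r = fr$caches, o = fo$caches, j = fj$caches),
       widths = c(ncol(fr$out), ncol(fo$out)))
}

#' Train the hybrid two-branch model
#'
#' @param net An `nn_hybrid` from [build_model()].
#' @param xr,xo Rational-feature matrix and one-hot array (same row order).
#' @param y Target matrix.
#' @inheritParams nn_fit
#' @return The trained `nn_hybrid`.
#' @export
nn_fit_hybrid <- function(net, xr, xo, y, epochs = 100L, patience = 20L,
                          batch_size = 64L, lr = 1e-3, val_fraction = 0.1,
                          seed = NULL, verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  y <- as.matrix(y)
  N <- nrow(xr)
  n_val <- max(1L, floor(val_fraction * N))
  vi <- sample.int(N, n_val)
  xr_v <- xr[vi, , drop = FALSE]; xo_v <- .slice_batch(xo, vi)
  y_v <- y[vi, , drop = FALSE]
  xr_t <- xr[-vi, , drop = FALSE]; xo_t <- .slice_batch(xo, -vi)
  y_t <- y[-vi, , drop = FALSE]; Nt <- N - n_val
  states <- list(r = .adam_init(net$branch_r), o = .adam_init(net$branch_o),
                 j = .adam_init(net$joiner))
  best <- Inf; best_net <- net; wait <- 0L; t <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(Nt)
    for (start in seq(1L, Nt, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, Nt)]
      fw <- .hybrid_forward(net, xr_t[idx, , drop = FALSE],
                            .slice_batch(xo_t, idx), training = TRUE)
      net <- fw$net
      ls <- .nn_loss(fw$out, y_t[idx, , drop = FALSE], net$loss)
      bj <- .nn_backward(net$joiner, fw$caches$j, ls$dout)
      wr <- fw$widths[1]
      br <- .nn_backward(net$branch_r, fw$caches$r,
                         bj$dx[, seq_len(wr), drop = FALSE])
      bo <- .nn_backward(net$branch_o, fw$caches$o,
                         bj$dx[, -seq_len(wr), drop = FALSE])
      t <- t + 1L
      uj <- .adam_step(net$joiner, bj$grads, states$j, lr, t)
      ur <- .adam_step(net$branch_r, br$grads, states$r, lr, t)
      uo <- .adam_step(net$branch_o, bo$grads, states$o, lr, t)
      net$joiner <- uj$net; states$j <- uj$state
      net$branch_r <- ur$net; states$r <- ur$state
      net$branch_o <- uo$net; states$o <- uo$state
    }
    val <- .hybrid_forward(net, xr_v, xo_v, training = FALSE)
    vl <- .nn_loss(val$out, y_v, net$loss)$value
    if (verbose) message(sprintf("epoch %3d  val %.5f", ep, vl))
    if (vl < best - 1e-7) { best <- vl; best_net <- net; wait <- 0L }
    else { wait <- wait + 1L; if (wait >= patience) break }
  }
  best_net$trained <- TRUE
  best_net
}

#' @export
predict.nn_hybrid <- function(object, xr, xo, ...) {
  out <- .hybrid_forward(object, xr, xo, training = FALSE)$out
  if (object$loss == "softmax_ce") out <- .softmax(out)
  out
}

#' Binarize ON/OFF values into classification labels
#'
#' Positive iff value >= `threshold` (inclusive boundary). The single
#' positive threshold at +0.7 reflects the top tail of the ON/OFF
#' distribution; values are expected in `[-1, 1]`.
#'
#' @param values Numeric vector of ON/OFF values.
#' @param threshold Positive-class threshold (default 0.7).
#' @return Integer vector of 0/1 labels.
#' @export
binarize_labels <- function(values, threshold = 0.7) {
  stopifnot(all(values >= -1 - 1e-9 & values <= 1 + 1e-9, na.rm = TRUE))
  as.integer(values >= threshold)
}

#' Data-balancing strategies
#'
#' Four strategies for skewed functional data:
#' `"quantile_transform"` maps values to a uniform distribution by rank
#' (returns an inverse transform; rank order preserved);
#' `"bin_resample_20"` splits the value range into 20 equal bins and
#' re-samples under-represented bins with replacement to the largest bin's
#' count; `"undersample"`/`"oversample"` equalize binary classes by removing
#' from the majority / duplicating from the minority. `"none"` returns the
#' input unchanged.
#'
#' @param data A data frame containing `label_col`.
#' @param strategy Balancing strategy.
#' @param label_col Column to balance on (numeric, or 0/1 for the class
#'   strategies).
#' @param seed Optional seed.
#' @return A list: `data` (transformed/resampled tibble), and for the
#'   quantile transform `transform`/`inverse` functions.
#' @export
balance_data <- function(data, strategy = c("none", "quantile_transform",
                                            "bin_resample_20", "undersample",
                                            "oversample"),
                         label_col = "onoff", seed = NULL) {
  strategy <- match.arg(strategy)
  if (!is.null(seed)) set.seed(seed)
  v <- data[[label_col]]
  if (strategy == "none") return(list(data = tibble::as_tibble(data)))
  if (strategy == "quantile_transform") {
    n <- length(v)
    sorted <- sort(v)
    transform <- function(x) {
      (findInterval(x, sorted, rightmost.closed = FALSE) +
         findInterval(x, sorted, left.open = TRUE)) / (2 * n)
    }
    inverse <- function(u) {
      # empirical quantile at the mid-rank grid: exact inverse of
      # `transform` on the training sample (up to ties)
      approx((seq_len(n) - 0.5) / n, sorted, xout = pmin(pmax(u, 0), 1),
             rule = 2)$y
    }
    out <- data
    out[[label_col]] <- transform(v)
    return(list(data = tibble::as_tibble(out), transform = transform,
                inverse = inverse))
  }
  if (strategy == "bin_resample_20") {
    brks <- seq(min(v), max(v), length.out = 21L)
    bin <- findInterval(v, brks, rightmost.closed = TRUE, all.inside = TRUE)
    target <- max(table(bin))
    idx <- unlist(lapply(split(seq_along(v), bin), function(ii) {
      if (length(ii) >= target) ii
      else c(ii, .resample(ii, target - length(ii), replace = TRUE))
    }), use.names = FALSE)
    return(list(data = tibble::as_tibble(data[idx, , drop = FALSE])))
  }
  # class strategies: label_col must be binary 0/1
  cls <- as.integer(v)
  stopifnot(all(cls %in% c(0L, 1L)))
  n1 <- sum(cls == 1L); n0 <- sum(cls == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("class balancing needs both classes present", call. = FALSE)
  }
  i1 <- which(cls == 1L); i0 <- which(cls == 0L)
  if (strategy == "undersample") {
    m <- min(n0, n1)
    idx <- c(.resample(i0, m), .resample(i1, m))
  } else {
    maj <- if (n0 >= n1) i0 else i1
    mnr <- if (n0 >= n1) i1 else i0
    idx <- c(maj, mnr, .resample(mnr, length(maj) - length(mnr),
                                 replace = TRUE))
  }
  list(data = tibble::as_tibble(data[.resample(idx, length(idx)), ,
                                     drop = FALSE]))
}

#' Cross-validated training and evaluation
#'
#' Trains a fresh model per fold and reports per-fold metrics: R-squared and
#' MAE per output in regression (10 folds by default), AUROC and AUPRC in
#' classification (3 folds by default). Balancing is applied to the training
#' portion only; test folds stay untouched.
#'
#' @param spec A [model_spec()].
#' @param x Input array (batch first) matching the family's encoding.
#' @param y Target matrix (regression: one column per output; classification:
#'   a single 0/1 vector or column).
#' @param folds Number of CV folds (default 10 regression / 3 classification).
#' @param balancing Strategy name for [balance_data()] applied to training
#'   folds (regression: `quantile_transform`/`bin_resample_20`;
#'   classification: `undersample`/`oversample`).
#' @param seed Seed controlling fold assignment, balancing and training.
#' @param output_names Names for regression outputs.
#' @param ... Passed to [nn_fit()] (`epochs`, `patience`, `batch_size`, `lr`).
#' @return An object of class `toehold_eval` with `metrics` (per-fold tibble)
#'   and the last fold's fitted model.
#' @export
train_and_evaluate <- function(spec, x, y, folds = NULL, balancing = "none",
                               seed = 1L, output_names = NULL, ...) {
  stopifnot(inherits(spec, "model_spec"))
  classify <- spec$mode == "classification"
  folds <- folds %||% if (classify) 3L else 10L
  y <- as.matrix(y)
  N <- dim(x)[1]
  if (any(table(rep_len(seq_len(folds), N)) < 10)) {
    stop("each fold needs >= 10 samples", call. = FALSE)
  }
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), N))
  output_names <- output_names %||%
    (colnames(y) %||% paste0("y", seq_len(ncol(y))))
  rows <- list(); fit <- NULL
  input_shape <- dim(x)[-1]
  if (is.null(input_shape)) input_shape <- ncol(x)
  for (fd in seq_len(folds)) {
    te <- which(fold_id == fd); tr <- which(fold_id != fd)
    xtr <- .slice_batch(x, tr); ytr <- y[tr, , drop = FALSE]
    if (balancing != "none") {
      df <- tibble::tibble(.row = seq_along(tr),
                           .lab = if (classify) as.integer(ytr[, 1] > 0.5)
                                  else ytr[, 1])
      bal <- balance_data(df, balancing, label_col = ".lab",
                          seed = seed + fd)
      keep <- bal$data$.row
      xtr <- .slice_batch(xtr, keep); ytr <- ytr[keep, , drop = FALSE]
      if (balancing == "quantile_transform") ytr[, 1] <- bal$data$.lab
    }
    ytr_fit <- if (classify) cbind(1 - ytr[, 1], ytr[, 1]) else ytr
    net <- build_model(spec, input_shape, seed = seed + 1000L * fd)
    net <- nn_fit(net, xtr, ytr_fit, seed = seed + fd, ...)
    pred <- predict(net, .slice_batch(x, te))
    yte <- y[te, , drop = FALSE]
    if (classify) {
      score <- pred[, 2]
      rows[[fd]] <- tibble::tibble(fold = fd, metric = c("auroc", "auprc"),
                                   output = "onoff_class",
                                   value = c(auroc(yte[, 1], score),
                                             auprc(yte[, 1], score)))
    } else {
      if (balancing == "quantile_transform") {
        pred[, 1] <- bal$inverse(pred[, 1])
      }
      rows[[fd]] <- dplyr::bind_rows(lapply(seq_len(ncol(yte)), function(j) {
        tibble::tibble(fold = fd, metric = c("r_squared", "mae"),
                       output = output_names[j],
                       value = c(r_squared(yte[, j], pred[, j]),
                                 mae(yte[, j], pred[, j])))
      }))
    }
    fit <- net
  }
  structure(list(metrics = dplyr::bind_rows(rows), spec = spec,
                 folds = folds, model = fit, seed = seed),
            class = "toehold_eval")
}

#' @export
tidy.toehold_eval <- function(x, ...) x$metrics

#' @export
glance.toehold_eval <- function(x, ...) {
  x$metrics |>
    dplyr::group_by(.data$metric, .data$output) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     .groups = "drop") |>
    dplyr::mutate(family = x$spec$family, mode = x$spec$mode,
                  folds = x$folds)
}

#' @export
print.toehold_eval <- function(x, ...) {
  cat("cross-validated evaluation:", x$spec$family, "(", x$spec$mode, "),",
      x$folds, "folds\n")
  print(glance(x))
  invisible(x)
}
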