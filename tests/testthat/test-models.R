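test_that("model families build with the documented layer shapes", {
  # rational-feature MLP: 30-wide input, dense 25/10/7, 3-output head
  net <- build_model(model_spec("mlp_rational", "regression"), 30, seed = 1)
  dense_units <- vapply(Filter(function(l) l$type == "dense", net$layers),
                        function(l) l$out_shape, numeric(1))
  expect_equal(dense_units, c(25, 10, 7, 3))
  expect_equal(net$layers[[1]]$in_shape, 30)
  # one-hot MLP: flatten then 128/64/32
  net2 <- build_model(model_spec("mlp_onehot", "regression"), c(145, 4))
  du2 <- vapply(Filter(function(l) l$type == "dense", net2$layers),
                function(l) l$out_shape, numeric(1))
  expect_equal(du2, c(128, 64, 32, 3))
  # 1D CNN: 32/64/128 filters of size 3
  net3 <- build_model(model_spec("cnn_onehot", "regression"), c(145, 4))
  convs <- Filter(function(l) l$type == "conv1d", net3$layers)
  expect_identical(vapply(convs, `[[`, integer(1), "filters"),
                   c(32L, 64L, 128L))
  expect_true(all(vapply(convs, `[[`, integer(1), "kernel") == 3L))
  # 2D map CNN: 32/64/128 filters of 5x5
  net4 <- build_model(model_spec("cnn_map", "regression"), c(60, 60, 7))
  convs2 <- Filter(function(l) l$type == "conv2d", net4$layers)
  expect_identical(vapply(convs2, `[[`, integer(1), "filters"),
                   c(32L, 64L, 128L))
  expect_true(all(vapply(convs2, `[[`, integer(1), "kernel") == 5L))
  # LSTM: 128 units then dense 100
  net5 <- build_model(model_spec("lstm_onehot", "regression"), c(145, 4))
  expect_identical(net5$layers[[1]]$units, 128L)
  expect_equal(net5$layers[[2]]$out_shape, 100)
  # heads: classification nets end in 2 outputs
  net6 <- build_model(model_spec("mlp_rational", "classification"), 30)
  expect_equal(net6$output_shape, 2L)
  expect_identical(net6$loss, "softmax_ce")
  expect_error(model_spec("unknown_family"))
})

test_that("classification labels binarize at the inclusive +0.7 threshold", {
  expect_identical(binarize_labels(c(0.71, -0.9, 0.7, 0.69)),
                   c(1L, 0L, 1L, 0L))
  # uniform values on [-1, 1]: about (1 - 0.7) / 2 = 15% positive
  set.seed(14)
  v <- runif(20000, -1, 1)
  expect_lt(abs(mean(binarize_labels(v)) - 0.15), 0.01)
  expect_error(binarize_labels(2))
})

test_that("balancing strategies transform as documented", {
  set.seed(15)
  df <- tibble::tibble(onoff = rbeta(500, 0.5, 3) * 2 - 1,
                       id = seq_len(500))
  # quantile transform: rank order preserved, output uniform
  qt <- balance_data(df, "quantile_transform")
  expect_identical(cor(df$onoff, qt$data$onoff, method = "spearman"), 1)
  expect_lt(suppressWarnings(stats::ks.test(qt$data$onoff, "punif"))$statistic,
            0.05)
  # inverse transform recovers the original values
  expect_lt(max(abs(qt$inverse(qt$transform(df$onoff)) - df$onoff)), 0.02)
  # 20-bin resampling: uniform histogram by construction
  br <- balance_data(df, "bin_resample_20", seed = 1)
  brks <- seq(min(df$onoff), max(df$onoff), length.out = 21)
  counts <- table(findInterval(br$data$onoff, brks,
                               rightmost.closed = TRUE, all.inside = TRUE))
  expect_lte(diff(range(counts)), 1)
  # class balancing equalizes class sizes
  dfc <- tibble::tibble(lab = rbinom(300, 1, 0.2))
  un <- balance_data(dfc, "undersample", label_col = "lab", seed = 2)
  expect_identical(sum(un$data$lab == 0), sum(un$data$lab == 1))
  expect_identical(sum(un$data$lab == 1), sum(dfc$lab == 1))
  ov <- balance_data(dfc, "oversample", label_col = "lab", seed = 3)
  expect_identical(sum(ov$data$lab == 0), sum(ov$data$lab == 1))
  expect_identical(sum(ov$data$lab == 0), sum(dfc$lab == 0))
  dfz <- tibble::tibble(lab = rep(0L, 10))
  expect_error(balance_data(dfz, "undersample", label_col = "lab"),
               "both classes")
})

test_that("cross-validated evaluation reports per-fold metrics", {
  set.seed(16)
  n <- 240
  x <- matrix(rnorm(n * 6), n, 6)
  y <- matrix(x[, 1] - 0.5 * x[, 2] + rnorm(n, sd = 0.2), ncol = 1)
  colnames(y) <- "on"
  ev <- train_and_evaluate(model_spec("logistic_baseline", "regression",
                                      n_outputs = 1),
                           x, y, folds = 3, seed = 2,
                           epochs = 80, patience = 20, lr = 1e-2)
  td <- tidy(ev)
  expect_identical(sort(unique(td$fold)), 1:3)
  expect_true(all(c("r_squared", "mae") %in% td$metric))
  g <- glance(ev)
  expect_gt(g$mean[g$metric == "r_squared"], 0.7)
  # fold splits are deterministic under the seed
  ev2 <- train_and_evaluate(model_spec("logistic_baseline", "regression",
                                       n_outputs = 1),
                            x, y, folds = 3, seed = 2,
                            epochs = 80, patience = 20, lr = 1e-2)
  expect_identical(tidy(ev), tidy(ev2))
  expect_error(train_and_evaluate(model_spec("mlp_rational", "regression"),
                                  x[1:12, ], y[1:12, , drop = FALSE],
                                  folds = 3),
               ">= 10 samples")
})

test_that("classification evaluation keeps test folds untouched by balancing", {
  set.seed(17)
  n <- 300
  x <- matrix(rnorm(n * 5), n, 5)
  lab <- as.integer(x[, 1] + rnorm(n, sd = 0.5) > 0.8)
  ev <- train_and_evaluate(model_spec("logistic_baseline", "classification"),
                           x, matrix(lab, ncol = 1), folds = 3,
                           balancing = "undersample", seed = 3,
                           epochs = 60, patience = 20, lr = 1e-2)
  td <- tidy(ev)
  expect_true(all(td$value >= 0 & td$value <= 1))
  expect_gt(mean(td$value[td$metric == "auroc"]), 0.7)
})

test_that("the hybrid model trains and its one-hot branch adds information", {
  set.seed(18)
  n <- 200
  xr <- matrix(rnorm(n * 30), n, 30)
  xo <- array(rnorm(n * 10 * 4), c(n, 10, 4))
  y <- matrix(xr[, 1] + rnorm(n, sd = 0.3), ncol = 1)
  spec <- model_spec("mlp_hybrid", "regression", n_outputs = 1)
  net <- build_model(spec, list(rational = 30, onehot = c(10, 4)), seed = 4)
  expect_s3_class(net, "nn_hybrid")
  net <- nn_fit_hybrid(net, xr, xo, y, epochs = 120, patience = 25,
                       lr = 3e-3, seed = 5)
  pred <- predict(net, xr, xo)
  expect_equal(dim(pred), c(n, 1L))
  expect_gt(r_squared(y[, 1], pred[, 1]), 0.3)
})
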