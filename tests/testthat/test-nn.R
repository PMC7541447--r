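test_that("analytic gradients match numerical gradients for every layer type", {
  set.seed(1)
  cases <- list(
    list(net = nn_sequential(list(layer_dense(5), layer_relu(),
                                  layer_batchnorm(), layer_dense(3)),
                             input_shape = 4, loss = "mse", seed = 1),
         x = matrix(rnorm(32), 8, 4), y = matrix(rnorm(24), 8, 3)),
    list(net = nn_sequential(list(layer_conv1d(3, 3), layer_relu(),
                                  layer_flatten(), layer_dense(2)),
                             input_shape = c(7, 2), loss = "mse", seed = 1),
         x = array(rnorm(70), c(5, 7, 2)), y = matrix(rnorm(10), 5, 2)),
    list(net = nn_sequential(list(layer_conv2d(3, 3), layer_relu(),
                                  layer_maxpool2d(), layer_flatten(),
                                  layer_dense(2)),
                             input_shape = c(6, 6, 2), loss = "mse", seed = 1),
         x = array(rnorm(288), c(4, 6, 6, 2)), y = matrix(rnorm(8), 4, 2)),
    list(net = nn_sequential(list(layer_lstm(4), layer_dense(2)),
                             input_shape = c(6, 3), loss = "softmax_ce",
                             seed = 1),
         x = array(rnorm(90), c(5, 6, 3)),
         y = {cl <- rbinom(5, 1, 0.5); cbind(1 - cl, cl)})
  )
  for (cs in cases) {
    expect_lt(nn_grad_check(cs$net, cs$x, cs$y), 1e-4)
  }
})

test_that("training-mode batch-norm gradients are exact", {
  set.seed(2)
  ns <- asNamespace("toeholdr")
  net <- nn_sequential(list(layer_dense(4), layer_batchnorm(), layer_relu(),
                            layer_dense(2)), input_shape = 3, loss = "mse",
                       seed = 2)
  x <- matrix(rnorm(36), 12, 3); y <- matrix(rnorm(24), 12, 2)
  fw <- ns$.nn_forward(net, x, training = TRUE)
  ls <- ns$.nn_loss(fw$out, y, "mse")
  bw <- ns$.nn_backward(fw$net, fw$caches, ls$dout)
  eps <- 1e-5; worst <- 0
  for (li in seq_along(net$layers)) {
    g <- bw$grads[[li]]
    if (is.null(g)) next
    for (pn in names(g)) {
      for (k in sample(length(g[[pn]]), min(4, length(g[[pn]])))) {
        net2 <- fw$net
        p <- net2$layers[[li]]$params[[pn]]
        net2$layers[[li]]$params[[pn]][k] <- p[k] + eps
        l1 <- ns$.nn_loss(ns$.nn_forward(net2, x, TRUE)$out, y, "mse")$value
        net2$layers[[li]]$params[[pn]][k] <- p[k] - eps
        l2 <- ns$.nn_loss(ns$.nn_forward(net2, x, TRUE)$out, y, "mse")$value
        num <- (l1 - l2) / (2 * eps)
        worst <- max(worst, abs(num - g[[pn]][k]) /
                       max(1e-6, abs(num) + abs(g[[pn]][k])))
      }
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("a small network fits a learnable function", {
  set.seed(3)
  x <- matrix(runif(600, -1, 1), 300, 2)
  y <- matrix(x[, 1] * x[, 2], ncol = 1)   # multiplicative interaction
  net <- nn_sequential(list(layer_dense(16), layer_relu(), layer_dense(8),
                            layer_relu(), layer_dense(1)),
                       input_shape = 2, loss = "mse", seed = 3)
  net <- nn_fit(net, x, y, epochs = 150, patience = 30, batch_size = 32,
                lr = 5e-3, seed = 4)
  pred <- predict(net, x)
  expect_gt(r_squared(y[, 1], pred[, 1]), 0.8)
})

test_that("training is reproducible under a fixed seed", {
  set.seed(9)
  x <- matrix(rnorm(200), 50, 4); y <- matrix(rnorm(50), ncol = 1)
  f <- function() {
    net <- nn_sequential(list(layer_dense(6), layer_relu(), layer_dense(1)),
                         input_shape = 4, loss = "mse", seed = 11)
    nn_fit(net, x, y, epochs = 5, seed = 12)
  }
  expect_identical(predict(f(), x), predict(f(), x))
})

test_that("metrics match closed forms and an independent implementation", {
  truth <- c(1, 2, 3, 4, 5)
  expect_identical(r_squared(truth, truth), 1)
  expect_equal(r_squared(truth, rep(mean(truth), 5)), 0)
  expect_equal(mae(truth, truth + 0.5), 0.5)
  # AUROC equals brute-force pair counting; AUPRC equals average precision
  set.seed(5)
  lab <- rbinom(60, 1, 0.4)
  sc <- runif(60) + lab * 0.4
  pairs <- expand.grid(i = which(lab == 1), j = which(lab == 0))
  brute_auc <- mean(ifelse(sc[pairs$i] > sc[pairs$j], 1,
                           ifelse(sc[pairs$i] == sc[pairs$j], 0.5, 0)))
  expect_equal(auroc(lab, sc), brute_auc)
  expect_gte(auprc(lab, sc), mean(lab))   # better than the prevalence floor
  expect_lte(auprc(lab, sc), 1)
})

test_that("the logistic baseline agrees with stats::glm on the same data", {
  set.seed(6)
  x <- matrix(rnorm(1200), 300, 4)
  z <- x %*% c(1.5, -1, 0.5, 0)
  yb <- rbinom(300, 1, plogis(z))
  # package route: single dense layer + softmax head, trained by Adam
  net <- build_model(model_spec("logistic_baseline", "classification"),
                     input_shape = 4, seed = 7)
  net <- nn_fit(net, x, cbind(1 - yb, yb), epochs = 200, patience = 50,
                lr = 5e-2, seed = 8)
  p_net <- predict(net, x)[, 2]
  # independent route: IRLS via glm
  p_glm <- stats::glm.fit(cbind(1, x), yb,
                          family = stats::binomial())$fitted.values
  expect_gt(cor(p_net, p_glm), 0.98)
  expect_lt(abs(auroc(yb, p_net) - auroc(yb, p_glm)), 0.02)
})
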