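test_that("pretraining is deterministic and epochs = 0 returns the init", {
  set.seed(99)
  x <- scale(matrix(stats::rnorm(60 * 6), 60, 6))
  spec <- net_spec(6, c(5, 4, 3), 2, "linear")
  cfg0 <- train_config(pretrain_epochs = 0, seed = 21)
  p1 <- pretrain_stack(x, spec, cfg0)
  p2 <- pretrain_stack(x, spec, cfg0)
  expect_identical(p1, p2)
  expect_length(p1$weights, 3)
  expect_identical(dim(p1$weights[[1]]), c(6L, 5L))
  expect_length(p1$recon_log[[1]], 0)
  # the init equals a seeded draw of the documented Glorot-type scale
  set.seed(21)
  w_expected <- matrix(stats::rnorm(6 * 5, sd = 4 * sqrt(2 / 11)), 6, 5)
  expect_equal(p1$weights[[1]], w_expected)
  cfg <- train_config(pretrain_epochs = 5, seed = 21)
  q1 <- pretrain_stack(x, spec, cfg)
  q2 <- pretrain_stack(x, spec, cfg)
  expect_identical(q1, q2)
})

test_that("pretraining reduces first-layer reconstruction error on mixture data", {
  set.seed(5)
  centers <- matrix(c(2, 2, -2, -2), 2, byrow = TRUE)
  x <- centers[sample(1:2, 200, TRUE), ] + matrix(stats::rnorm(400, sd = 0.5),
                                                  200, 2)
  x <- scale(x)
  spec <- net_spec(2, c(8, 8, 8), 2, "linear")
  cfg <- train_config(pretrain_epochs = 20, lr_gaussian = 0.005, seed = 2)
  pre <- pretrain_stack(x, spec, cfg)
  rl <- pre$recon_log[[1]]
  expect_length(rl, 20)
  expect_lt(rl[20], rl[1])
})

test_that("non-finite inputs and zero-variance dimensions are rejected", {
  x <- matrix(stats::rnorm(40), 10, 4)
  spec <- net_spec(4, c(3, 3, 3), 2, "linear")
  cfg <- train_config(pretrain_epochs = 1, seed = 1)
  xb <- x; xb[3, 2] <- NA
  expect_error(pretrain_stack(xb, spec, cfg), "non-finite")
  xz <- x; xz[, 3] <- 1
  expect_error(train_dnn(xz, x, spec, cfg), "zero-variance.*3")
})

test_that("analytic gradients match central finite differences", {
  set.seed(12)
  x <- matrix(stats::rnorm(4 * 5), 4, 5)
  spec <- list(hidden = c(3, 3, 3))
  w <- lapply(list(c(5, 3), c(3, 3), c(3, 3), c(3, 2)), function(d)
    matrix(stats::rnorm(prod(d), sd = 0.5), d[1], d[2]))
  b <- lapply(c(3, 3, 3, 2), function(n) stats::rnorm(n, sd = 0.2))
  eps <- 1e-6
  for (kind in c("linear", "softmax")) {
    y <- if (kind == "linear") matrix(stats::rnorm(8), 4, 2) else
      outer(sample(1:2, 4, TRUE), 1:2, "==") * 1
    g <- artimap:::nn_loss_grad(w, b, x, y, kind)
    for (l in c(1, 2, 4)) {
      for (ij in list(c(1, 1), c(2, 2))) {
        wp <- w; wp[[l]][ij[1], ij[2]] <- wp[[l]][ij[1], ij[2]] + eps
        wm <- w; wm[[l]][ij[1], ij[2]] <- wm[[l]][ij[1], ij[2]] - eps
        fd <- (artimap:::nn_loss_grad(wp, b, x, y, kind)$loss -
                 artimap:::nn_loss_grad(wm, b, x, y, kind)$loss) / (2 * eps)
        expect_equal(g$gw[[l]][ij[1], ij[2]], fd, tolerance = 1e-5)
      }
    }
    # bias gradient, output layer
    bp <- b; bp[[4]][1] <- bp[[4]][1] + eps
    bm <- b; bm[[4]][1] <- bm[[4]][1] - eps
    fd <- (artimap:::nn_loss_grad(w, bp, x, y, kind)$loss -
             artimap:::nn_loss_grad(w, bm, x, y, kind)$loss) / (2 * eps)
    expect_equal(g$gb[[4]][1], fd, tolerance = 1e-5)
  }
})

test_that("training is deterministic and the loss never ends above its start", {
  set.seed(7)
  x <- matrix(stats::rnorm(200 * 6), 200, 6)
  y <- x %*% matrix(stats::rnorm(12), 6, 2)
  spec <- net_spec(6, c(10, 10, 10), 2, "linear")
  cfg <- train_config(pretrain_epochs = 3, finetune_epochs = 15, seed = 4)
  n1 <- train_dnn(x, y, spec, cfg)
  n2 <- train_dnn(x, y, spec, cfg)
  expect_identical(n1$weights, n2$weights)
  expect_lte(utils::tail(n1$log$loss, 1), n1$log$loss[1])
})

test_that("identity regression reaches RMSE below 0.05 standardized units", {
  set.seed(1)
  x <- matrix(stats::rnorm(400 * 20), 400, 20)
  spec <- net_spec(20, c(40, 40, 40), 20, "linear")
  cfg <- train_config(pretrain_epochs = 10, finetune_epochs = 400,
                      lr_finetune = 0.2, lr_decay = 0.99, weight_decay = 0,
                      seed = 3)
  net <- train_dnn(x, x, spec, cfg)
  rmse <- sqrt(mean((predict(net, x) - x)^2))
  expect_lt(rmse, 0.05)
})

test_that("zero fine-tune epochs leave the unrolled pretrained net untouched", {
  set.seed(3)
  x <- matrix(stats::rnorm(50 * 4), 50, 4)
  y <- matrix(stats::rnorm(100), 50, 2)
  spec <- net_spec(4, c(5, 5, 5), 2, "linear")
  cfg <- train_config(pretrain_epochs = 4, finetune_epochs = 0, seed = 17)
  net <- train_dnn(x, y, spec, cfg)
  # rebuild by hand: same pretraining, untouched random output layer
  xs <- artimap:::apply_standardize(x, net$x_standardize)
  pre <- pretrain_stack(xs, spec, cfg)
  expect_identical(net$weights[1:3], pre$weights)
  manual <- artimap:::forward_pass(net$weights, net$biases, xs, "linear")[[4]]
  ys <- artimap:::apply_standardize(y, net$y_standardize)
  expect_equal(max(abs(manual - artimap:::apply_standardize(
    predict(net, x), net$y_standardize))), 0, tolerance = 1e-12)
})

test_that("softmax predictions are normalized, batch-invariant and tie-break low", {
  set.seed(6)
  x <- matrix(stats::rnorm(90 * 5), 90, 5)
  labels <- sample(c("a", "b", "c"), 90, TRUE)
  spec <- net_spec(5, c(6, 6, 6), 3, "softmax")
  cfg <- train_config(pretrain_epochs = 2, finetune_epochs = 10, seed = 2)
  net <- train_dnn(x, labels, spec, cfg)
  p <- predict(net, x)
  expect_equal(rowSums(p), rep(1, 90), tolerance = 1e-12)
  # single-row prediction equals the matching row of a batched prediction
  expect_equal(predict(net, x[7, ]), p[7, , drop = FALSE], tolerance = 1e-12)
  expect_error(predict(net, x[, 1:3]), "dimension mismatch")
  expect_error(train_dnn(x, c(labels[-1], "zz"), spec, cfg,
                         levels = c("a", "b", "c")), "zz")
  # constructed tie: equal probabilities pick the first level
  tie <- net
  tie$weights[[4]][] <- 0
  tie$biases[[4]][] <- 0
  expect_equal(unique(classify_dnn(tie, x)), "a")
})

test_that("all-zero weights with a linear output predict the de-standardized bias", {
  set.seed(11)
  x <- matrix(stats::rnorm(30 * 3), 30, 3)
  y <- matrix(stats::rnorm(60), 30, 2)
  spec <- net_spec(3, c(4, 4, 4), 2, "linear")
  cfg <- train_config(pretrain_epochs = 1, finetune_epochs = 1, seed = 8)
  net <- train_dnn(x, y, spec, cfg)
  for (l in 1:4) net$weights[[l]][] <- 0
  net$biases[[4]][] <- c(0.5, -1)
  want <- c(0.5, -1) * net$y_standardize$scale + net$y_standardize$center
  p <- predict(net, x)
  expect_equal(p[1, ], want, ignore_attr = TRUE)
  expect_equal(p[30, ], want, ignore_attr = TRUE)
})

test_that("model serialization round-trips bit-exactly", {
  set.seed(14)
  x <- matrix(stats::rnorm(40 * 3), 40, 3)
  y <- matrix(stats::rnorm(40), 40, 1)
  net <- train_dnn(x, y, net_spec(3, c(4, 4, 4), 1, "linear"),
                   train_config(pretrain_epochs = 2, finetune_epochs = 2,
                                seed = 5))
  f <- withr::local_tempfile(fileext = ".txt")
  save_trained_net(net, f)
  back <- load_trained_net(f)
  expect_identical(back$weights, net$weights)
  expect_identical(back$biases, net$biases)
  expect_identical(predict(back, x), predict(net, x))
})
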