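test_that("initialization is seed-deterministic with the stated shapes", {
  a <- init_ann(251, n_hidden = 4, n_out = 5, seed = 3)
  b <- init_ann(251, n_hidden = 4, n_out = 5, seed = 3)
  expect_identical(a$W1, b$W1)
  expect_identical(a$W2, b$W2)
  expect_equal(dim(a$W1), c(4L, 251L))
  expect_equal(dim(a$W2), c(5L, 4L))
  expect_equal(a$b1, numeric(4))
  expect_equal(a$b2, numeric(5))
  # forward pass on zero input returns the (zero) output biases
  z <- matrix(0, 1, 251)
  expect_equal(as.vector(specal:::ann_forward(a, z)),
               as.vector(a$W2 %*% a$b1 + a$b2))
})

test_that("the purelin network equals its composed affine map exactly", {
  fx <- linear_fixture(n = 8, p = 10, m = 2, seed = 9)
  m <- fit_ann(fx$X, fx$Y, preset = "accurate", n_hidden = 3, epochs = 200,
               lr = 0.02, seed = 2)
  aff <- ann_as_affine(m)
  Xs <- specal:::ann_scale_x(m$scaler, fx$X)
  layered <- specal:::ann_forward(m, Xs)
  direct <- Xs %*% t(aff$A) + matrix(aff$c, nrow(Xs), length(aff$c), byrow = TRUE)
  expect_equal(layered, direct, tolerance = 1e-14)
  # effective rank bounded by the hidden width
  expect_lte(qr(aff$A)$rank, 3)
})

test_that("the analytic gradient matches finite differences", {
  withr::with_seed(4, {
    Xs <- matrix(rnorm(6 * 7), 6, 7)
    Ys <- matrix(rnorm(6 * 2), 6, 2)
  })
  m <- init_ann(7, n_hidden = 3, n_out = 2, seed = 5)
  g <- specal:::ann_gradient(m, Xs, Ys)
  loss_at <- function(model) mean((specal:::ann_forward(model, Xs) - Ys)^2)
  h <- 1e-6
  for (field in c("W1", "W2", "b1", "b2")) {
    analytic <- g[[paste0("d", field)]]
    num <- array(0, dim = if (is.null(dim(analytic))) length(analytic)
                 else dim(analytic))
    for (k in seq_along(m[[field]])) {
      mp <- m; mp[[field]][k] <- mp[[field]][k] + h
      mm <- m; mm[[field]][k] <- mm[[field]][k] - h
      num[k] <- (loss_at(mp) - loss_at(mm)) / (2 * h)
    }
    expect_lt(max(abs(as.vector(analytic) - as.vector(num))) /
                max(abs(as.vector(analytic))), 1e-5)
  }
})

test_that("zero learning rate leaves weights unchanged with a flat trace", {
  fx <- linear_fixture(n = 8, p = 10, m = 2, seed = 10)
  m0 <- init_ann(10, n_hidden = 3, n_out = 2, seed = 1)
  m1 <- train_ann(m0, fx$X, fx$Y, epochs = 5, lr = 0)
  expect_identical(m1$W1, m0$W1)
  expect_identical(m1$W2, m0$W2)
  expect_length(m1$loss_trace, 5)
  expect_equal(diff(m1$loss_trace), rep(0, 4))
})

test_that("gradient descent solves a tiny linear system, matching a by-hand oracle", {
  # 4 samples, 3 inputs, 1 output; independent oracle updates the composed
  # parameters with the same full-batch rule, step for step
  withr::with_seed(6, {
    X <- matrix(rnorm(12), 4, 3)
    Y <- X %*% matrix(c(1, -2, 0.5), 3, 1)
  })
  m <- init_ann(3, n_hidden = 3, n_out = 1, seed = 7)
  trained <- train_ann(m, X, Y, epochs = 5000, lr = 0.05)
  expect_lt(utils::tail(trained$loss_trace, 1), 1e-6)

  # step-for-step comparison over the first 50 epochs
  scaler <- specal:::fit_ann_scaler(X, Y)
  Xs <- specal:::ann_scale_x(scaler, X)
  Ys <- specal:::ann_scale_y(scaler, Y)
  W1 <- m$W1; b1 <- m$b1; W2 <- m$W2; b2 <- m$b2
  lr <- 0.05
  for (e in 1:50) {
    H <- Xs %*% t(W1) + matrix(b1, 4, 3, byrow = TRUE)
    Yh <- H %*% t(W2) + matrix(b2, 4, 1, byrow = TRUE)
    E <- Yh - Ys
    sc <- 2 / length(E)
    dH <- E %*% W2
    W2 <- W2 - lr * sc * t(E) %*% H; b2 <- b2 - lr * sc * colSums(E)
    W1 <- W1 - lr * sc * t(dH) %*% Xs; b1 <- b1 - lr * sc * colSums(dH)
  }
  ref50 <- train_ann(m, X, Y, epochs = 50, lr = lr)
  expect_equal(ref50$W1, W1, tolerance = 1e-12)
  expect_equal(ref50$W2, W2, tolerance = 1e-12)
  expect_equal(ref50$b1, b1, tolerance = 1e-12)
  expect_equal(ref50$b2, b2, tolerance = 1e-12)
})

test_that("training loss is non-increasing at a conservative learning rate", {
  fx <- linear_fixture(n = 10, p = 12, m = 2, noise = 0.05, seed = 11)
  m <- fit_ann(fx$X, fx$Y, preset = "accurate", n_hidden = 3, epochs = 300,
               lr = 0.01, seed = 3)
  expect_true(all(diff(m$loss_trace) <= 1e-12))
})

test_that("accurate preset recovers the five analytes on noiseless design data", {
  dd <- design_data(noise = NULL)
  m <- fit_ann(dd$X[dd$cal, ], dd$Y[dd$cal, ], preset = "accurate", seed = 1)
  rec <- 100 * predict(m, dd$X[dd$val, ]) / dd$Y[dd$val, ]
  expect_true(all(abs(colMeans(rec) - 100) < 1))
})

test_that("training and prediction are deterministic and validate dimensions", {
  fx <- linear_fixture(n = 8, p = 10, m = 2, seed = 12)
  m1 <- fit_ann(fx$X, fx$Y, preset = "accurate", n_hidden = 2, epochs = 100,
                lr = 0.02, seed = 8)
  m2 <- fit_ann(fx$X, fx$Y, preset = "accurate", n_hidden = 2, epochs = 100,
                lr = 0.02, seed = 8)
  expect_identical(m1$W1, m2$W1)
  expect_identical(predict(m1, fx$X), predict(m2, fx$X))
  expect_error(predict(m1, fx$X[, 1:3]), "expects")
  expect_error(train_ann(m1, fx$X[, 1:3], fx$Y), "dimensions")
})
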