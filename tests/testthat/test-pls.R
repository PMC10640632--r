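test_that("NIPALS scores are orthogonal and X variance is explained monotonely", {
  fx <- linear_fixture(n = 14, p = 20, m = 3, noise = 0.05, seed = 2)
  fit <- fit_pls(fx$X, fx$Y, n_lv = 6)
  G <- crossprod(fit$T)
  off <- G - diag(diag(G))
  expect_lt(max(abs(off)) / max(diag(G)), 1e-8)
  # residual X variance non-increasing in A
  resid <- vapply(1:6, function(a) fit_pls(fx$X, fx$Y, n_lv = a)$ss_x_residual,
                  numeric(1))
  expect_true(all(diff(resid) <= 1e-10))
})

test_that("PLS at full rank equals the minimum-norm least-squares oracle", {
  # wide case: rank = n - 1 after centering
  fx <- linear_fixture(n = 10, p = 25, m = 2, noise = 0.1, seed = 3)
  fit <- fit_pls(fx$X, fx$Y, n_lv = 9)
  Xc <- scale(fx$X, scale = FALSE)
  Yc <- scale(fx$Y, scale = FALSE)
  B_ls <- pinv(Xc) %*% Yc
  expect_lt(max(abs(fit$B - B_ls)) / max(abs(B_ls)), 1e-6)
  # tall case: full column rank
  fx2 <- linear_fixture(n = 20, p = 8, m = 2, noise = 0.1, seed = 4)
  fit2 <- fit_pls(fx2$X, fx2$Y, n_lv = 8)
  B_ls2 <- pinv(scale(fx2$X, scale = FALSE)) %*% scale(fx2$Y, scale = FALSE)
  expect_lt(max(abs(fit2$B - B_ls2)) / max(abs(B_ls2)), 1e-6)
})

test_that("predictions agree with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  fx <- linear_fixture(n = 20, p = 30, m = 3, noise = 0.1, seed = 5)
  Xn <- matrix(rnorm(5 * 30), 5, 30)
  colnames(Xn) <- colnames(fx$X)
  for (A in c(2, 5)) {
    mine <- predict(fit_pls(fx$X, fx$Y, n_lv = A), Xn)
    ref <- mixOmics::pls(fx$X, fx$Y, ncomp = A, mode = "regression",
                         scale = FALSE)
    pref <- predict(ref, Xn)$predict[, , A]
    expect_lt(max(abs(mine - pref)) / max(abs(pref)), 1e-6)
  }
})

test_that("noiseless synthetic design data are fitted exactly at A = 5", {
  dd <- design_data(noise = NULL)
  fit <- fit_pls(dd$X[dd$cal, ], dd$Y[dd$cal, ], n_lv = 5)
  rec <- 100 * predict(fit, dd$X[dd$val, ]) / dd$Y[dd$val, ]
  expect_true(all(abs(rec - 100) < 0.1))
  # rank-1 single-component case is exact with one latent variable
  g <- wl_grid(250, 300, 0.2)
  lib <- default_library(0)[1]
  C <- matrix(seq(2, 12, length.out = 8), 8, 1)
  colnames(C) <- "NZ"
  s <- simulate_mixtures(C, lib, g, noise = NULL)
  f1 <- fit_pls(s$absorbance[1:6, ], C[1:6, , drop = FALSE], n_lv = 1)
  expect_equal(as.vector(predict(f1, s$absorbance[7:8, ])), C[7:8, 1],
               tolerance = 1e-8)
})

test_that("prediction handles centering fixed point and dimension errors", {
  fx <- linear_fixture(seed = 6)
  fit <- fit_pls(fx$X, fx$Y, n_lv = 3)
  # the calibration mean spectrum predicts the mean concentrations
  mu <- matrix(colMeans(fx$X), 1)
  expect_equal(as.vector(predict(fit, mu)), unname(colMeans(fx$Y)),
               tolerance = 1e-10)
  expect_error(predict(fit, fx$X[, 1:4]), "fitted on")
  expect_error(fit_pls(fx$X, fx$Y, n_lv = 50), "min\\(n - 1, p\\)")
})

test_that("rank-deficient X stops with the achievable maximum", {
  X <- cbind(1:6, (1:6) * 2, (1:6) * 3)  # rank 1 after centering
  Y <- matrix(rnorm(12), 6, 2)
  expect_error(fit_pls(X, Y, n_lv = 3), "at most 1 latent")
})

test_that("LOO curve equals a naive double-loop re-fit oracle", {
  fx <- linear_fixture(n = 10, p = 12, m = 2, noise = 0.3, seed = 7)
  a_max <- 4
  curve <- loo_curve(fx$X, fx$Y, a_max = a_max)
  n <- nrow(fx$X)
  for (a in seq_len(a_max)) {
    pred <- matrix(NA_real_, n, ncol(fx$Y))
    for (i in seq_len(n)) {
      f <- fit_pls(fx$X[-i, ], fx$Y[-i, ], n_lv = a)   # refit at exactly a
      pred[i, ] <- predict(f, fx$X[i, , drop = FALSE])
    }
    E <- pred - fx$Y
    expect_equal(curve$rmsecv[curve$n_lv == a & curve$component == "overall"],
                 sqrt(mean(E^2)), tolerance = 1e-10)
    for (j in seq_len(ncol(fx$Y))) {
      expect_equal(
        curve$rmsecv[curve$n_lv == a & curve$component == colnames(fx$Y)[j]],
        sqrt(mean(E[, j]^2)), tolerance = 1e-10)
    }
  }
})

test_that("LOO reaches machine-level error on perfect linear data", {
  dd <- design_data(noise = NULL)
  curve <- loo_curve(dd$X[dd$cal, ], dd$Y[dd$cal, ], a_max = 5)
  overall <- curve$rmsecv[curve$component == "overall"]
  expect_lt(overall[5], 1e-6)
})

test_that("latent-variable selection applies the parsimony rule", {
  expect_equal(select_n_lv(c(5, 1, 0.5, 0.49, 0.489), threshold_ratio = 0.05), 3)
  expect_equal(select_n_lv(c(3, 2, 1), threshold_ratio = 0), 3)
  expect_equal(select_n_lv(rep(1, 6), threshold_ratio = 0.02), 1)
  # also accepts a cv_curve tibble
  fx <- linear_fixture(n = 10, p = 12, m = 2, noise = 0.3, seed = 8)
  curve <- loo_curve(fx$X, fx$Y, a_max = 4)
  a <- select_n_lv(curve)
  expect_true(a %in% 1:4)
})

test_that("validation RMSEP grows monotonically with noise level", {
  sigmas <- c(0.001, 0.005, 0.01)
  n_rep <- 20
  pooled <- sapply(seq_along(sigmas), function(si) {
    mean(sapply(seq_len(n_rep), function(r) {
      dd <- design_data(noise = noise_model(sigma_base = sigmas[si],
                                            sigma_below_250 = sigmas[si],
                                            seed = 1000 * si + r))
      fit <- fit_pls(dd$X[dd$cal, ], dd$Y[dd$cal, ], n_lv = 5)
      sqrt(mean((predict(fit, dd$X[dd$val, ]) - dd$Y[dd$val, ])^2))
    }))
  })
  expect_true(all(diff(pooled) > 0))
})
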