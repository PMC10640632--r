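test_that("recovery arithmetic behaves and guards its domain", {
  expect_equal(recovery_percent(11.286, 11.0), 102.6, tolerance = 1e-3)
  expect_equal(recovery_percent(7, 7), 100)
  expect_equal(recovery_percent(0, 4), 0)
  expect_error(recovery_percent(1, 0), "must be > 0")
  expect_error(summarize_recoveries(100), "at least 2")
  expect_equal(summarize_recoveries(c(99, 101, 100))$sd, 1)
  expect_equal(summarize_recoveries(rep(100, 5))$sd, 0)
})

test_that("published per-mixture recoveries reproduce every summary cell", {
  rec <- reference_recoveries()
  printed <- tibble::tribble(
    ~component, ~model, ~mean, ~sd,
    "NZ",      "pls",  99.5, 1.8,
    "NZ",      "ann", 100.2, 2.1,
    "PN",      "pls",  99.8, 1.8,
    "PN",      "ann", 100.0, 1.8,
    "NZ_impB", "pls", 100.0, 1.9,
    "NZ_impB", "ann", 100.0, 1.4,
    "PN_impA", "pls", 101.0, 1.9,
    "PN_impA", "ann", 100.2, 1.9,
    "PN_impB", "pls",  99.3, 1.9,
    "PN_impB", "ann",  98.7, 1.9
  )
  for (k in seq_len(nrow(printed))) {
    v <- rec$recovery[rec$component == printed$component[k] &
                        rec$model == printed$model[k]]
    expect_length(v, 10)
    s <- summarize_recoveries(v)
    expect_equal(round(s$mean, 1), printed$mean[k])
    expect_equal(round(s$sd, 1), printed$sd[k])
  }
})

test_that("RMSEP and SEP share residuals with the fixed n/(n-2) ratio", {
  expect_equal(rmsep(c(1, 2), c(1.1, 1.9)), 0.1)
  expect_equal(rmsep(1:5, 1:5), 0)
  withr::with_seed(13, {
    pred <- rnorm(10, 50, 2)
    act <- rnorm(10, 50, 2)
  })
  expect_equal(sep(pred, act) / rmsep(pred, act), sqrt(10 / 8))
  expect_equal(sep(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(sep(1:2, 1:2), "n >= 3")
  expect_error(rmsep(1:3, 1:4), "equal length")
  # the published SEP values follow from the published RMSEP at n = 10
  reg <- reference_regression()
  expect_equal(reg$sep, reg$rmsep * sqrt(10 / 8), tolerance = 2e-5)
})

test_that("predicted-versus-actual regression matches a least-squares oracle", {
  r <- pred_actual_regression(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 0)
  expect_equal(r$r, 1)
  same <- pred_actual_regression(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$slope, 1)
  expect_equal(same$s_residual, 0)
  withr::with_seed(14, {
    act <- runif(12, 2, 14)
    pred <- act + rnorm(12, 0, 0.2)
  })
  r2 <- pred_actual_regression(pred, act)
  # independent normal-equations oracle
  Z <- cbind(1, act)
  beta <- solve(crossprod(Z), crossprod(Z, pred))
  expect_equal(r2$intercept, beta[1], tolerance = 1e-10)
  expect_equal(r2$slope, beta[2], tolerance = 1e-10)
  resid <- pred - Z %*% beta
  expect_equal(r2$s_residual, sqrt(sum(resid^2) / 10), tolerance = 1e-10)
  expect_error(pred_actual_regression(c(1, 2, 3), c(2, 2, 2)), "constant")
})

test_that("LOD and LOQ keep the 3.3/10 structure, matching published pairs", {
  lim <- lod_loq(s_residual = 1, slope = 2)
  expect_equal(lim$loq / lim$lod, 10 / 3.3)
  expect_equal(lod_loq(0, 1)$lod, 0)
  expect_error(lod_loq(1, 0), "slope")
  reg <- reference_regression()
  expect_equal(round(reg$lod * 10 / 3.3, 3), reg$loq, tolerance = 3e-3)
})

test_that("standard addition recovers the added amount only", {
  sa <- standard_addition(4, c(6.04, 8.004, 11.968), c(2, 4, 8))
  expect_equal(sa$recovery, c(102.0, 100.1, 99.6), tolerance = 1e-10)
  expect_equal(round(attr(sa, "mean"), 1), 100.6)
  expect_equal(round(attr(sa, "sd"), 1), 1.3)
  exact <- standard_addition(10, c(15, 20, 30), c(5, 10, 20))
  expect_equal(exact$recovery, rep(100, 3))
  expect_error(standard_addition(4, c(6, 8), c(2, -4)), "> 0")
  # all four published spike series summarize to the printed cells
  sa_ref <- reference_standard_addition()
  printed <- tibble::tribble(
    ~model, ~component, ~mean, ~sd,
    "pls", "NZ", 100.6, 1.3,
    "pls", "PN", 100.6, 0.4,
    "ann", "NZ",  99.7, 0.7,
    "ann", "PN",  99.8, 0.5
  )
  for (k in seq_len(nrow(printed))) {
    v <- sa_ref$recovery[sa_ref$model == printed$model[k] &
                           sa_ref$component == printed$component[k]]
    s <- summarize_recoveries(v)
    expect_equal(round(s$mean, 1), printed$mean[k])
    expect_equal(round(s$sd, 1), printed$sd[k])
  }
})

test_that("method comparison computes pooled t and upper-tail F", {
  cmp <- compare_methods(99.5, 1.82, 10, 99.6, 0.98, 5)
  expect_equal(round(cmp$t_statistic, 2), 0.11)
  expect_equal(round(cmp$t_critical, 2), 2.16)
  expect_equal(cmp$t_df, 13)
  expect_equal(cmp$f_statistic, 1.82^2 / 0.98^2)
  expect_equal(cmp$f_df1, 9)
  expect_equal(cmp$f_df2, 4)
  expect_equal(cmp$f_critical, stats::qf(0.95, 9, 4))
  # identical samples: t = 0, F = 1, numerator convention keeps F >= 1
  same <- compare_methods(100, 1, 6, 100, 1, 6)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$f_statistic, 1)
  swapped <- compare_methods(99.6, 0.98, 5, 99.5, 1.82, 10)
  expect_gte(swapped$f_statistic, 1)
  expect_equal(swapped$f_df1, 9)
  expect_error(compare_methods(1, 0, 5, 2, 1, 5), "sd")
})

test_that("merit report assembles all figures per component", {
  dd <- design_data()
  fit <- fit_pls(dd$X[dd$cal, ], dd$Y[dd$cal, ], n_lv = 5)
  pred <- predict(fit, dd$X[dd$val, ])
  mr <- merit_report(pred, dd$Y[dd$val, ])
  expect_equal(nrow(mr), 5)
  expect_setequal(mr$component, colnames(dd$Y))
  expect_equal(mr$loq / mr$lod, rep(10 / 3.3, 5))
  expect_equal(mr$sep / mr$rmsep, rep(sqrt(10 / 8), 5))
  expect_true(all(mr$mean_recovery > 90 & mr$mean_recovery < 110))
  long <- tidy(mr)
  expect_equal(nrow(long), 50)
  expect_equal(long$recovery, 100 * long$predicted / long$actual)
})
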