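test_that("NIPALS model satisfies its structural invariants", {
  set.seed(8)
  X <- matrix(rnorm(20 * 8), 20, 8)
  y <- rnorm(20)
  m <- fit_pls(X, y, A = 5)
  expect_equal(colSums(m$W^2), rep(1, 5), tolerance = 1e-10)
  G <- crossprod(m$T)
  expect_lt(max(abs(G[upper.tri(G)])) / max(diag(G)), 1e-8)
  # b-form and factor-expansion predictions agree on training data
  expect_equal(predict(m, X), as.numeric(m$T %*% m$q) + m$y_mean,
               tolerance = 1e-8)
  expect_error(fit_pls(X, y, A = 25), "parameter error")
})

test_that("full-factor PLS reproduces the least-squares oracle", {
  skip_if_not_installed("MASS")
  set.seed(9)
  for (rep in 1:20) {
    X <- matrix(rnorm(20 * 8), 20, 8)
    y <- rnorm(20, 10)
    m <- fit_pls(X, y, A = 8)
    Xc <- sweep(X, 2, colMeans(X))
    b_ols <- MASS::ginv(Xc) %*% (y - mean(y))
    pred_ols <- as.numeric(Xc %*% b_ols) + mean(y)
    expect_equal(predict(m, X), pred_ols, tolerance = 1e-6,
                 label = paste("instance", rep))
  }
})

test_that("exact interpolation when y lies in the span of centered X", {
  ds <- rank1_dataset()
  m <- fit_pls(ds$X, ds$y, A = 1)
  expect_lt(rmse(predict(m, ds$X), ds$y), 1e-8)
  # requesting more factors than the residual supports names the max
  expect_error(fit_pls(ds$X, ds$y, A = 3), "rank error.*1")
})

test_that("prediction identities hold", {
  set.seed(10)
  X <- matrix(rnorm(15 * 6), 15, 6)
  y <- rnorm(15)
  m <- fit_pls(X, y, A = 3)
  expect_equal(predict(m, matrix(m$x_mean, 1)), m$y_mean, tolerance = 1e-10)
  two <- predict(m, X[c(4, 4), ])
  expect_identical(two[1], two[2])
  expect_error(predict(m, X[, 1:4]), "shape error")
})

test_that("prediction is affine-equivariant in y", {
  set.seed(11)
  X <- matrix(rnorm(18 * 7), 18, 7)
  y <- rnorm(18, 5)
  m1 <- fit_pls(X, y, A = 4)
  m2 <- fit_pls(X, 3 * y - 2, A = 4)
  expect_equal(m2$b, 3 * m1$b, tolerance = 1e-8)
  expect_equal(predict(m2, X), 3 * predict(m1, X) - 2, tolerance = 1e-8)
})

test_that("cross-validation is deterministic and exact on noiseless data", {
  ds <- rank1_dataset(n = 30)
  cv <- cross_validate(ds$X, ds$y, A_max = 1, k = 10)
  expect_lt(cv[1], 1e-6)
  set.seed(12)
  X <- matrix(rnorm(30 * 10), 30, 10); y <- rnorm(30)
  cv1 <- cross_validate(X, y, A_max = 5)
  cv2 <- cross_validate(X, y, A_max = 5)
  expect_identical(cv1, cv2)
  expect_true(all(cv1 >= 0))
  expect_error(cross_validate(X, y, A_max = 50), "parameter error")
})

test_that("VIP scores satisfy the normalization identity and match the oracle", {
  set.seed(13)
  for (rep in 1:10) {
    A <- sample(1:5, 1)
    X <- matrix(rnorm(15 * 6), 15, 6)
    y <- rnorm(15)
    m <- fit_pls(X, y, A = A)
    v <- vip_scores(m)
    expect_equal(sum(v$scores^2), 6, tolerance = 1e-8)
    expect_equal(v$scores, vip_oracle(m), tolerance = 1e-10)
  }
})

test_that("single-factor VIP with symmetric weights gives equal scores", {
  # two channels carrying identical information -> |w| equal -> VIP = 1 each
  set.seed(14)
  t <- rnorm(20)
  X <- cbind(t, -t)
  m <- fit_pls(X, t, A = 1)
  v <- vip_scores(m)
  expect_equal(v$scores, c(1, 1), tolerance = 1e-10)
})

test_that("variable selection thresholds with the documented fallback", {
  expect_identical(select_variables(c(2.0, 0.5, 1.5, 0.1), 1.0, A = 1),
                   c(1L, 3L))
  # all below threshold: the A top scores are kept
  expect_identical(select_variables(c(0.9, 0.2, 0.8, 0.7), 1.0, A = 3),
                   c(1L, 3L, 4L))
  # monotone: a higher threshold never enlarges the selection
  set.seed(15)
  sc <- runif(30, 0, 2)
  lo <- select_variables(sc, 0.8, A = 2)
  hi <- select_variables(sc, 1.2, A = 2)
  if (length(hi) > 2) expect_true(all(hi %in% lo))
})

test_that("exported models re-predict without refitting", {
  ds <- tiny_dataset(n = 10, p = 20)
  Xp <- apply_pretreatment(ds$X, "SNV")
  m <- fit_pls(Xp[, 3:18], ds$y, A = 2, variable_subset = 3:18)
  path <- withr::local_tempfile(fileext = ".json")
  export_model(m, path, pretreatment_label = "SNV", spacing = axis_spacing(ds))
  back <- load_model(path)
  expect_equal(predict_exported(back, ds), predict(m, Xp[, 3:18]),
               tolerance = 1e-10)
})
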