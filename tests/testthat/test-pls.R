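test_that("single-channel PLS1 equals the univariate least-squares fit", {
  set.seed(20)
  x <- matrix(rnorm(15), ncol = 1)
  y <- 2.5 * x[, 1] + rnorm(15, sd = 0.3)
  m <- pls1_fit(x, y, 1)
  slope <- cov(x[, 1], y) / var(x[, 1])
  pred <- pls_predict(m, x)
  expect_equal(pred, mean(y) + slope * (x[, 1] - mean(x[, 1])),
               tolerance = 1e-10)
})

test_that("full-rank PLS1 matches the least-squares oracle", {
  set.seed(21)
  n <- 12; p <- 4
  x <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  m <- pls1_fit(x, y, p) # n_lv = rank of centered x
  # independent oracle: normal equations on the centered instance
  xc <- scale(x, scale = FALSE); yc <- y - mean(y)
  b_ls <- solve(crossprod(xc), crossprod(xc, yc))
  oracle <- mean(y) + as.numeric(xc %*% b_ls)
  expect_equal(pls_predict(m, x), oracle, tolerance = 1e-8)
  xnew <- matrix(rnorm(5 * p), 5, p)
  oracle_new <- mean(y) +
    as.numeric(sweep(xnew, 2, colMeans(x)) %*% b_ls)
  expect_equal(pls_predict(m, xnew), oracle_new, tolerance = 1e-8)
})

test_that("NIPALS training scores are mutually orthogonal", {
  set.seed(22)
  x <- matrix(rnorm(20 * 10), 20)
  y <- rnorm(20)
  m <- pls1_fit(x, y, 6)
  TT <- m$scores
  for (i in 1:5) for (j in (i + 1):6) {
    expect_lt(abs(sum(TT[, i] * TT[, j])),
              1e-8 * sqrt(sum(TT[, i]^2)) * sqrt(sum(TT[, j]^2)))
  }
  # weight columns are unit norm
  expect_equal(unname(colSums(m$W^2)), rep(1, 6))
})

test_that("training RMSE is non-increasing in the number of components", {
  for (s in 1:3) {
    set.seed(s)
    n <- 15; p <- 8
    x <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    m <- pls1_fit(x, y, p)
    rmse <- vapply(seq_len(m$n_lv), function(a) {
      sqrt(mean((pls_predict(m, x, a) - y)^2))
    }, numeric(1))
    expect_true(all(diff(rmse) <= 1e-10))
  }
})

test_that("predictions shift with constant shifts of y (centering)", {
  set.seed(23)
  x <- matrix(rnorm(18 * 6), 18)
  y <- rnorm(18)
  m1 <- pls1_fit(x, y, 3)
  m2 <- pls1_fit(x, y + 100, 3)
  expect_equal(pls_predict(m2, x), pls_predict(m1, x) + 100,
               tolerance = 1e-9)
})

test_that("coefficient form agrees with the score-recursion form", {
  set.seed(24)
  x <- matrix(rnorm(16 * 9), 16)
  y <- rnorm(16)
  m <- pls1_fit(x, y, 5)
  xnew <- matrix(rnorm(4 * 9), 4)
  # factor form: deflate new spectra through the model's weights/loadings
  Xc <- sweep(xnew, 2, m$x_mean)
  yhat <- rep(m$y_mean, 4)
  for (a in seq_len(m$n_lv)) {
    t_a <- Xc %*% m$W[, a]
    yhat <- yhat + t_a * m$q[a]
    Xc <- Xc - tcrossprod(t_a, m$P[, a])
  }
  expect_equal(pls_predict(m, xnew), as.numeric(yhat), tolerance = 1e-10)
})

test_that("prediction is invariant to sample order and the mean maps to y_mean", {
  set.seed(25)
  x <- matrix(rnorm(14 * 5), 14)
  y <- rnorm(14)
  m <- pls1_fit(x, y, 3)
  expect_equal(pls_predict(m, matrix(colMeans(x), 1)), mean(y),
               tolerance = 1e-10)
  idx <- sample(14)
  expect_equal(pls_predict(m, x[idx, ]), pls_predict(m, x)[idx])
  expect_error(pls_predict(m, x[, 1:3]), "channel mismatch")
})

test_that("degenerate fits are rejected or stopped early", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(pls1_fit(x, rep(1, 10), 1), "zero variance")
  expect_error(pls1_fit(x, rnorm(10), 5), "exceeds")
  # rank-1 x: the response is fully deflated after one component
  set.seed(26)
  t1 <- rnorm(12)
  x1 <- outer(t1, c(1, 2, 3))
  expect_warning(m <- pls1_fit(x1, 2 * t1, 3), "fully deflated")
  expect_true(m$early_stop)
  expect_equal(m$n_lv, 1L)
})

test_that("PLS-DA separates two well-separated clusters with one component", {
  set.seed(27)
  x <- matrix(c(rnorm(10, 0, 0.1), rnorm(10, 10, 0.1)), ncol = 1)
  labels <- rep(c(FALSE, TRUE), each = 10)
  m <- plsda_fit(x, labels, 1, positive_label = "hi")
  pred <- plsda_predict(m, x)
  expect_equal(pred$labels, labels) # training CCR 100%
  expect_equal(m$positive_label, "hi")
  # encoding: positive samples carry response 1, so mean response is 0.5
  expect_equal(m$core$y_mean, 0.5)
  expect_error(plsda_fit(x, rep(TRUE, 20), 1), "both classes")
})

test_that("the decision threshold is strict at 0.5", {
  m <- fake_da_model()
  x <- matrix(c(0.5, 0.9, 0.1), ncol = 1)
  pred <- plsda_predict(m, x)
  expect_equal(pred$labels, c(FALSE, TRUE, FALSE))
  expect_equal(pred$scores, c(0.5, 0.9, 0.1))
})

test_that("models round-trip through the text serialization", {
  set.seed(28)
  tr <- toy_spectra(n = 8, p = 30, seed = 28)
  y <- rnorm(8)
  pp <- apply_pretreatment(pretreatment_spec("snv_d1"), tr)
  m <- pls1_fit(pp$train$absorbance, y, 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path, fitted = pp$fitted)
  r <- read_model(path)
  expect_equal(r$model$coefficients, m$coefficients)
  expect_equal(pls_predict(r$model, pp$train$absorbance),
               pls_predict(m, pp$train$absorbance))
  expect_equal(r$fitted$spec$name, "snv_d1")
  expect_equal(r$fitted$grid, pp$fitted$grid)
  # DA flavour
  labels <- y > median(y)
  da <- plsda_fit(pp$train$absorbance, labels, 2, "V")
  write_model(da, path, fitted = pp$fitted)
  rd <- read_model(path)
  expect_s3_class(rd$model, "da_model")
  expect_equal(plsda_predict(rd$model, pp$train$absorbance)$labels,
               plsda_predict(da, pp$train$absorbance)$labels)
})
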