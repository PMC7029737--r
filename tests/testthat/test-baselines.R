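test_that("GBLUP equals ridge regression in the dual parameterization", {
  set.seed(14)
  n <- 50
  p <- 200
  Xs <- scale(matrix(rnorm(n * p), n, p))[, ]
  ys <- drop(Xs[, 1:4] %*% c(1, -1, 0.5, 2)) + rnorm(n)
  train <- 1:40
  test <- 41:50
  lam <- 0.7
  fit <- fit_gblup(Xs, ys, train, test, lambda = lam)
  # SNP-ridge with penalty p * lambda_r and the same intercept
  Xtr <- Xs[train, ]
  beta <- solve(crossprod(Xtr) + diag(p * lam, p),
                crossprod(Xtr, ys[train] - fit$mu))
  pred_ridge <- fit$mu + drop(Xs[test, ] %*% beta)
  expect_equal(fit$pred_test, pred_ridge, tolerance = 1e-8)
})

test_that("the two-individual mixed-model hand case solves exactly", {
  # x = (-1, 1), y = (-1, 1), lambda_r = 1: G = [[1,-1],[-1,1]],
  # GLS intercept 0, alpha = (G + I)^{-1} y = (-1/3, 1/3),
  # fitted value at x = 1: (-1, 1) . alpha = 2/3.
  Xs <- matrix(c(-1, 1), 2, 1)
  ys <- c(-1, 1)
  fit <- fit_gblup(Xs, ys, train_idx = 1:2, test_idx = 2, lambda = 1)
  expect_equal(fit$mu, 0, tolerance = 1e-12)
  expect_equal(fit$pred_test, 2 / 3, tolerance = 1e-12)
  expect_equal(fit$pred_train, c(-2 / 3, 2 / 3), tolerance = 1e-12)
})

test_that("infinite shrinkage collapses GBLUP to the training mean", {
  set.seed(15)
  Xs <- scale(matrix(rnorm(60 * 30), 60, 30))[, ]
  ys <- rnorm(60) + 3
  fit <- fit_gblup(Xs, ys, 1:45, 46:60, lambda = 1e10)
  expect_equal(fit$pred_test, rep(mean(ys[1:45]), 15), tolerance = 1e-4)
})

test_that("GBLUP predictions shift with a constant added to the phenotype", {
  set.seed(16)
  Xs <- scale(matrix(rnorm(80 * 60), 80, 60))[, ]
  ys <- drop(Xs[, 2]) + rnorm(80, 0, 0.5)
  f0 <- fit_gblup(Xs, ys, 1:60, 61:80)
  f7 <- fit_gblup(Xs, ys + 7, 1:60, 61:80)
  expect_equal(f7$pred_test, f0$pred_test + 7, tolerance = 1e-8)
  expect_gt(f0$lambda_r, 0)
})

test_that("GBLUP beats the train-mean predictor on heritable traits", {
  wins <- vapply(1:3, function(s) {
    sim <- simulate_qtlmas(n = 800, p = 500, h2 = 0.4, seed = 100 + s)
    ds <- standardize(maf_filter(sim$genotypes)$genotypes, sim$phenotype)
    tr <- 1:600
    te <- 601:800
    gb <- fit_gblup(ds$Xs, ds$ys, tr, te)
    gb$mse_test < mean((mean(ds$ys[tr]) - ds$ys[te])^2)
  }, logical(1))
  expect_true(all(wins))
})

test_that("the LASSO null model engages exactly at lambda_max", {
  set.seed(17)
  n <- 60
  Xs <- scale(matrix(rnorm(n * 40), n, 40))[, ]
  ys <- drop(Xs[, 3]) + rnorm(n, 0, 0.5)
  tr <- 1:45
  te <- 46:60
  lam_max <- max(abs(crossprod(Xs[tr, ], ys[tr] - mean(ys[tr])))) / 45
  fit <- fit_lasso(Xs, ys, tr, te, lambda = lam_max * 1.0001)
  expect_equal(fit$beta, numeric(40))
  expect_equal(fit$pred_test, rep(mean(ys[tr]), 15))
  fit2 <- fit_lasso(Xs, ys, tr, te, lambda = lam_max * 0.9)
  expect_gt(length(fit2$active), 0)
})

test_that("orthonormal designs give soft-thresholded OLS coefficients", {
  set.seed(18)
  n <- 64
  p <- 16
  Q <- qr.Q(qr(matrix(rnorm(n * p), n, p))) * sqrt(n)  # (1/n) X'X = I
  beta_true <- c(3, -2, 1.5, rep(0, p - 3))
  y <- drop(Q %*% beta_true) + rnorm(n, 0, 0.3)
  tr <- seq_len(n)
  for (lam in c(0.2, 0.8)) {
    fit <- fit_lasso(Q, y, tr, tr, lambda = lam)
    z <- drop(crossprod(Q, y - mean(y))) / n
    expect_equal(fit$beta, sign(z) * pmax(abs(z) - lam, 0), tolerance = 1e-8)
  }
  # sparsity is monotone along a decreasing penalty path
  nzero <- vapply(c(1.5, 0.8, 0.4, 0.1), function(lam) {
    length(fit_lasso(Q, y, tr, tr, lambda = lam)$active)
  }, integer(1))
  expect_true(all(diff(nzero) >= 0))
})

test_that("an unpenalized fit recovers least squares", {
  set.seed(19)
  n <- 60
  p <- 10
  Xs <- scale(matrix(rnorm(n * p), n, p))[, ]
  ys <- drop(Xs %*% rnorm(p)) + rnorm(n, 0, 0.2)
  fit <- fit_lasso(Xs, ys, 1:n, 1:n, lambda = 1e-12)
  ols <- solve(crossprod(Xs), crossprod(Xs, ys - mean(ys)))
  expect_equal(fit$beta, drop(ols), tolerance = 1e-6)
})

test_that("coordinate descent satisfies the stationarity conditions", {
  set.seed(20)
  n <- 80
  p <- 120
  Xs <- scale(matrix(rnorm(n * p), n, p))[, ]
  ys <- drop(Xs[, 1:3] %*% c(2, -2, 1)) + rnorm(n)
  fit <- fit_lasso(Xs, ys, 1:n, 1:n, lambda = 0.15)
  r <- ys - mean(ys) - drop(Xs %*% fit$beta)
  grad <- drop(crossprod(Xs, r)) / n
  active <- fit$beta != 0
  expect_lt(max(abs(grad[active] - 0.15 * sign(fit$beta[active]))), 1e-8)
  expect_lt(max(abs(grad[!active])), 0.15 + 1e-8)
})

test_that("cross-validated LASSO agrees with glmnet on a random design", {
  set.seed(21)
  n <- 90
  p <- 50
  Xs <- scale(matrix(rnorm(n * p), n, p))[, ]
  ys <- drop(Xs[, c(4, 9)] %*% c(2, -1.5)) + rnorm(n, 0, 0.5)
  lam <- 0.2
  fit <- fit_lasso(Xs, ys, 1:n, 1:n, lambda = lam)
  gn <- glmnet::glmnet(Xs, ys, lambda = lam, standardize = FALSE,
                       thresh = 1e-14)
  expect_equal(fit$beta, drop(as.matrix(gn$beta)), tolerance = 1e-5,
               ignore_attr = TRUE)

  # CV selection produces a finite penalty strictly inside the path
  cvfit <- fit_lasso(Xs, ys, 1:70, 71:90, cv_folds = 4, nlambda = 25,
                     seed = 2)
  expect_true(is.finite(cvfit$lambda) && cvfit$lambda > 0)
  expect_gt(length(cvfit$active), 0)
})

test_that("method comparison computes percent improvements", {
  tab <- compare_methods(mse = c(CNNGWP = 62.34, GBLUP = 88.42,
                                 BLASSO = 89.22))
  expect_equal(round(tab$improvement_pct[2], 1), 29.5)
  expect_equal(round(tab$improvement_pct[3], 1), 30.1)
  expect_true(is.na(tab$improvement_pct[1]))

  y <- rnorm(10)
  tab2 <- compare_methods(predictions = list(a = y, b = y), y = y)
  expect_equal(tab2$mse, c(0, 0))
  expect_error(compare_methods(predictions = list(a = rnorm(3)),
                               y = rnorm(4)), "mismatch")
})
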