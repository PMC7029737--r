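test_that("shape inference reproduces the reference layer tables", {
  # 9,723-SNP architecture: 64 filters, kernel 27, stride 2, pool 2
  tab <- infer_shapes(cnn_spec(p = 9723, filters = 64, kernel_width = 27))
  expect_equal(tab$out_length, c(4862L, 2431L, 155584L, 1L))
  expect_equal(tab$params, c(1792L, 0L, 0L, 155585L))
  expect_equal(attr(tab, "total_params"), 157377L)

  # 47,299-SNP architecture, 25 filters, kernel 34
  tab4 <- infer_shapes(cnn_spec(p = 47299, filters = 25, kernel_width = 34))
  expect_equal(tab4$out_length[1], 23650L)
  expect_equal(tab4$params[1], 875L)

  # 41 filters, kernel 40 (conv parameter count is input-length free)
  tab3 <- infer_shapes(cnn_spec(p = 47299, filters = 41, kernel_width = 40))
  expect_equal(tab3$params[1], 1681L)

  # unit model
  tabu <- infer_shapes(cnn_spec(p = 10, filters = 1, kernel_width = 1,
                                stride = 1, pool_size = 1))
  expect_equal(tabu$out_length, c(10L, 10L, 10L, 1L))
  expect_equal(tabu$params, c(2L, 0L, 0L, 11L))

  expect_error(cnn_spec(p = 3, filters = 1, kernel_width = 1, stride = 2,
                        pool_size = 4), "pooled length")
})

test_that("conv layer matches hand computations and the Toeplitz oracle", {
  # identity filter
  sp <- cnn_spec(5, 1, 3, stride = 1, pool_size = 1)
  x <- c(5, 1, 4, 2, 8)
  expect_equal(drop(conv1d_forward(x, sp, K = matrix(c(0, 1, 0), 3, 1),
                                   bias_c = 0)), x)
  # x=(1,2,3), kernel (1,1,1): one zero each side -> (3, 6, 5)
  sp3 <- cnn_spec(3, 1, 3, stride = 1, pool_size = 1)
  expect_equal(drop(conv1d_forward(c(1, 2, 3), sp3, K = matrix(1, 3, 1),
                                   bias_c = 0)), c(3, 6, 5))

  # Toeplitz oracle across lengths, strides and kernel widths
  set.seed(17)
  for (L in c(3, 7, 16, 33, 64)) {
    for (stride in c(1, 2, 3)) {
      for (kw in c(1, 3, 5, 8)) {
        x <- rnorm(L)
        k <- rnorm(kw)
        sp <- cnn_spec(L, 1, kw, stride = stride, pool_size = 1)
        got <- drop(conv1d_forward(x, sp, K = matrix(k, kw, 1), bias_c = 0))
        expect_equal(got, toeplitz_conv(x, k, stride), tolerance = 1e-12)
      }
    }
  }
  expect_error(conv1d_forward(1:4, sp3, K = matrix(1, 3, 1), bias_c = 0),
               "width")
})

test_that("max pooling keeps window maxima and drops the remainder", {
  sp <- cnn_spec(4, 1, 1, stride = 1, pool_size = 2)
  g <- conv1d_forward(c(1, 3, 2, 5), sp, K = matrix(1, 1, 1), bias_c = 0)
  mp <- maxpool_forward(g, 2)
  expect_equal(drop(mp$pooled), c(3, 5))
  expect_equal(drop(mp$argmax), c(2, 4))

  # remainder dropped: length 5, pool 2 -> 2
  g5 <- array(seq_len(5), c(1, 5, 1))
  expect_equal(dim(maxpool_forward(g5, 2)$pooled)[2], 2L)

  # the reference pooled lengths
  expect_equal(4862L %/% 2L, 2431L)
  g_long <- array(rnorm(23657), c(1, 23657, 1))
  expect_equal(dim(maxpool_forward(g_long, 2)$pooled)[2], 11828L)

  # ties route to the first position
  gt <- array(c(7, 7), c(1, 2, 1))
  expect_equal(drop(maxpool_forward(gt, 2)$argmax), 1)
})

test_that("forward chains conv, pooling and the dense layer", {
  m <- init_network(cnn_spec(4, 1, 1, stride = 1, pool_size = 2), seed = 1)
  m$K <- matrix(1, 1, 1)
  m$bias_c <- 0
  m$W <- c(1, 1)
  m$b <- 0
  expect_equal(forward(m, c(1, 2, 3, 4)), 6)

  # zero parameters -> zero predictions
  z <- init_network(cnn_spec(12, 3, 4), seed = 2)
  z$K[] <- 0; z$bias_c[] <- 0; z$W[] <- 0; z$b <- 0
  expect_equal(forward(z, matrix(rnorm(60), 5)), rep(0, 5))

  # batch forward equals per-row forward
  m2 <- init_network(cnn_spec(20, 3, 5), seed = 3)
  X <- matrix(rnorm(7 * 20), 7)
  expect_equal(forward(m2, X),
               vapply(1:7, function(i) forward(m2, X[i, ]), numeric(1)))
  # chunked evaluation is invisible
  expect_equal(forward(m2, X, chunk = 2L), forward(m2, X))
})

test_that("the network is linear when pooling is disabled", {
  m <- init_network(cnn_spec(16, 2, 5, stride = 2, pool_size = 1), seed = 4)
  m$bias_c[] <- 0
  m$b <- 0
  x1 <- rnorm(16); x2 <- rnorm(16)
  expect_equal(forward(m, 2 * x1 - 3 * x2),
               2 * forward(m, x1) - 3 * forward(m, x2), tolerance = 1e-12)
})

test_that("loss decomposes into MSE plus the output-layer L1 penalty", {
  m <- init_network(cnn_spec(4, 1, 1, stride = 1, pool_size = 2,
                             l1_lambda = 0.5), seed = 1)
  m$W <- c(2, -2)
  y <- c(1, -1)
  expect_equal(cnn_loss(y, y, m)$mse, 0)
  got <- cnn_loss(y + c(1, -1), y, m)
  expect_equal(got$mse, 1)
  expect_equal(got$l1_penalty, 2)
  expect_equal(got$total, 3)
  m$spec$l1_lambda <- 0
  expect_equal(cnn_loss(y + c(1, -1), y, m)$total, 1)
  expect_error(cnn_loss(numeric(0), numeric(0), m), "empty")
})

test_that("backward matches central finite differences", {
  set.seed(42)
  sp <- cnn_spec(20, 3, 5, stride = 2, pool_size = 2, l1_lambda = 0.3)
  m <- init_network(sp, seed = 7)
  X <- matrix(rnorm(8 * 20), 8)
  y <- rnorm(8)
  # keep away from pooling ties and from W near zero (subgradient kink)
  expect_gt(min(abs(m$W)), 1e-4)
  gr <- backward(m, X, y)
  lossfun <- function(mm) cnn_loss(forward(mm, X), y, mm)$total
  h <- 1e-6
  relerr <- function(a, b) max(abs(a - b) / pmax(abs(a) + abs(b), 1e-8))
  fd <- function(field) {
    num <- m[[field]] * 0
    for (i in seq_along(num)) {
      mp <- m; mp[[field]][i] <- mp[[field]][i] + h
      mm_ <- m; mm_[[field]][i] <- mm_[[field]][i] - h
      num[i] <- (lossfun(mp) - lossfun(mm_)) / (2 * h)
    }
    num
  }
  expect_lt(relerr(fd("K"), gr$dK), 1e-5)
  expect_lt(relerr(fd("bias_c"), drop(gr$dbias)), 1e-5)
  expect_lt(relerr(fd("W"), drop(gr$dW)), 1e-5)
  mp <- m; mp$b <- m$b + h
  mm_ <- m; mm_$b <- m$b - h
  expect_lt(relerr((lossfun(mp) - lossfun(mm_)) / (2 * h), gr$db), 1e-5)
})

test_that("gradients vanish at zero residual and scale linearly in lambda", {
  sp <- cnn_spec(8, 1, 1, stride = 1, pool_size = 1, l1_lambda = 0)
  m <- init_network(sp, seed = 5)
  m$K[] <- 0; m$bias_c[] <- 0; m$W[] <- 0; m$b <- 0
  gr <- backward(m, matrix(rnorm(3 * 8), 3), c(0, 0, 0))
  expect_equal(max(abs(gr$dK)), 0)
  expect_equal(max(abs(gr$dW)), 0)
  expect_equal(gr$db, 0)

  # doubling lambda doubles the penalty part of the dense gradient
  m2 <- init_network(cnn_spec(8, 2, 3, l1_lambda = 0.2), seed = 6)
  X <- matrix(rnorm(4 * 8), 4)
  y <- rnorm(4)
  g1 <- drop(backward(m2, X, y)$dW)
  m2$spec$l1_lambda <- 0.4
  g2 <- drop(backward(m2, X, y)$dW)
  m2$spec$l1_lambda <- 0
  g0 <- drop(backward(m2, X, y)$dW)
  expect_equal(g2 - g0, 2 * (g1 - g0), tolerance = 1e-12)
})
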