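test_that("the GP surrogate interpolates and matches closed-form formulas", {
  # two equal scores: posterior mean between them is that score
  X <- rbind(c(0.2, 0.2), c(0.8, 0.8))
  gp <- gp_fit(X, c(1.5, 1.5))
  expect_equal(predict(gp, matrix(c(0.5, 0.5), 1))$mean, 1.5,
               tolerance = 1e-6)

  # near-noise-free interpolation at observed points
  set.seed(10)
  X <- lhs::randomLHS(12, 2)
  y <- sin(3 * X[, 1]) + X[, 2]^2
  gp <- gp_fit(X, y)
  expect_equal(predict(gp, X)$mean, y, tolerance = 1e-3)

  # dense closed-form oracle with the fitted kernel values (a noisy fit, so
  # the covariance is well conditioned and both algebra routes agree tightly)
  y2 <- y + rnorm(12, 0, 0.1)
  gp2 <- gp_fit(X, y2)
  Xnew <- lhs::randomLHS(5, 2)
  got <- predict(gp2, Xnew)
  oracle <- gp_closed_form(X, y2, Xnew, gp2$ls, gp2$s2, gp2$noise + gp2$jitter)
  expect_equal(got$mean, oracle$mean, tolerance = 1e-6)
  expect_equal(got$sd, oracle$sd, tolerance = 1e-6)

  expect_error(gp_fit(X[1, , drop = FALSE], y[1]), "at least 2")
})

test_that("posterior uncertainty grows away from the data", {
  set.seed(2)
  X <- cbind(runif(10, 0, 0.3), runif(10, 0, 0.3))
  gp <- gp_fit(X, rowSums(X) + rnorm(10, 0, 0.01))
  sd_obs <- max(predict(gp, X)$sd)
  sd_far <- predict(gp, matrix(c(0.95, 0.95), 1))$sd
  expect_gte(sd_far, sd_obs)
})

test_that("UCB trades off mean and standard deviation", {
  X <- rbind(c(0.1, 0.1), c(0.9, 0.9), c(0.5, 0.2))
  gp <- gp_fit(X, c(0, 1, 0.5))
  q <- matrix(c(0.4, 0.6), 1)
  pr <- predict(gp, q)
  expect_equal(ucb(gp, q, beta = 0), pr$mean)
  expect_equal(ucb(gp, q, beta = 2), pr$mean + 2 * pr$sd)
  # mu = 1, sd = 2, beta = 2.576 -> 6.152
  expect_equal(1 + 2.576 * 2, 6.152)
  betas <- c(0, 0.5, 1, 2, 5)
  expect_true(all(diff(vapply(betas, function(b) ucb(gp, q, b),
                              numeric(1))) >= 0))
})

test_that("proposals maximize UCB over the pool and avoid duplicates", {
  b <- bo_bounds(c(0, 0), c(1, 1))
  hist <- data.frame(x1 = c(0.1, 0.9, 0.5), x2 = c(0.1, 0.9, 0.2),
                     iteration = 1:3, score = c(0, 1, 0.5))
  gp <- gp_fit(as.matrix(hist[, c("x1", "x2")]), hist$score)
  state <- list(history = hist, gp = gp,
                keys = apply(hist[, 1:2], 1, function(r)
                  cnngwp:::gamma_key(r, b)))
  # explicit 3-point pool: the proposal is the enumerated UCB argmax
  pool <- rbind(c(0.3, 0.3), c(0.7, 0.7), c(0.2, 0.8))
  acq <- ucb(gp, pool, beta = 2.576)
  got <- propose_next(state, b, candidates = pool)
  expect_equal(unname(got), pool[which.max(acq), ], tolerance = 1e-12)

  # generated pools stay within bounds and are seed-deterministic
  g1 <- propose_next(state, b, seed = 4)
  g2 <- propose_next(state, b, seed = 4)
  expect_identical(g1, g2)
  expect_true(all(g1 >= b$lower & g1 <= b$upper))

  # an already-evaluated argmax is skipped
  pool_dup <- rbind(c(0.9, 0.9), c(0.25, 0.25))
  got_dup <- propose_next(state, b, candidates = pool_dup)
  expect_equal(unname(got_dup), c(0.25, 0.25), tolerance = 1e-12)
})

test_that("run_bo respects the budget and records every evaluation", {
  obj <- function(g) -(g[["x1"]] - 0.3)^2 - (g[["x2"]] - 0.7)^2
  b <- bo_bounds(c(0, 0), c(1, 1))
  st <- run_bo(obj, b, T = 5, seed = 2, n_init = 4)
  expect_equal(nrow(st$history), 9L)
  expect_false(any(duplicated(st$keys)))
  expect_true(all(st$history$x1 >= 0 & st$history$x1 <= 1))

  # T = 0 returns the best of the initial design only
  st0 <- run_bo(obj, b, T = 0, seed = 2, n_init = 4)
  expect_equal(nrow(st0$history), 4L)
  expect_equal(st0$best_score, max(st0$history$score))

  # failing evaluations are recorded as NA and skipped
  obj_flaky <- function(g) if (g[["x1"]] > 0.5) NaN else obj(g)
  w <- capture_warnings(stf <- run_bo(obj_flaky, b, T = 4, seed = 3,
                                      n_init = 4))
  expect_true(any(grepl("non-finite", w)))
  expect_equal(nrow(stf$history), 8L)
  expect_true(all(stf$history$score[is.finite(stf$history$score)] <= 0))
})

test_that("integer dimensions are proposed on the lattice", {
  obj <- function(g) -(g[["filters"]] - 40)^2 / 100 - (g[["l1_lambda"]] - 0.5)^2
  b <- bo_bounds(c(20, 0.1), c(100, 1), integer = c(TRUE, FALSE),
                 names = c("filters", "l1_lambda"))
  st <- run_bo(obj, b, T = 6, seed = 5, n_init = 4)
  expect_true(all(st$history$filters == round(st$history$filters)))
  expect_true(all(st$history$filters >= 20 & st$history$filters <= 100))
})

test_that("larger beta explores farther from the evaluated set", {
  obj <- function(g) -(g[["x1"]] - 0.5)^2 - (g[["x2"]] - 0.5)^2
  b <- bo_bounds(c(0, 0), c(1, 1))
  mean_dist <- function(beta, seed) {
    st <- run_bo(obj, b, T = 4, beta = beta, seed = seed, n_init = 4)
    H <- as.matrix(st$history[, c("x1", "x2")])
    d <- vapply(5:8, function(i) {
      min(sqrt(rowSums(sweep(H[1:(i - 1), , drop = FALSE], 2, H[i, ])^2)))
    }, numeric(1))
    mean(d)
  }
  diffs <- vapply(1:20, function(s) mean_dist(20, s) - mean_dist(0, s),
                  numeric(1))
  expect_gt(mean(diffs), 0)
})
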