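#' Hyperparameter bounds for Bayesian optimization
#'
#' Per-dimension lower/upper limits with an integrality flag. The reference
#' search space for the simulated data is `filters` in \[20, 100\],
#' `kernel_width` in \[10, 50\] (both integer) and `l1_lambda` in
#' \[0.1, 1.0\].
#'
#' @param lower,upper Numeric vectors, `lower < upper` per dimension.
#' @param integer Logical vector: round this dimension to integers.
#' @param names Dimension names.
#' @return Object of class `bo_bounds`.
#' @export
bo_bounds <- function(lower, upper, integer = rep(FALSE, length(lower)),
                      names = NULL) {
  if (length(lower) != length(upper) || length(lower) != length(integer)) {
    stopf("lower, upper and integer must have equal length")
  }
  if (any(lower >= upper)) stopf("need lower < upper in every dimension")
  names <- names %||% paste0("x", seq_along(lower))
  structure(list(lower = lower, upper = upper, integer = integer,
                 names = names, d = length(lower)),
            class = "bo_bounds")
}

#' @rdname bo_bounds
#' @export
cnngwp_bounds <- function(lower = c(20, 10, 0.1), upper = c(100, 50, 1.0)) {
  bo_bounds(lower, upper, integer = c(TRUE, TRUE, FALSE),
            names = c("filters", "kernel_width", "l1_lambda"))
}

scale01 <- function(X, bounds) {
  sweep(sweep(X, 2, bounds$lower), 2, bounds$upper - bounds$lower, "/")
}

unscale01 <- function(X01, bounds) {
  sweep(sweep(X01, 2, bounds$upper - bounds$lower, "*"), 2, bounds$lower, "+")
}

# Round integer dimensions (half away from zero) and clip into bounds.
round_gamma <- function(x, bounds) {
  x <- pmin(pmax(x, bounds$lower), bounds$upper)
  x[bounds$integer] <- round_half_away(x[bounds$integer])
  stats::setNames(x, bounds$names)
}

gamma_key <- function(x, bounds) {
  paste(ifelse(bounds$integer, sprintf("%d", as.integer(x)),
               sprintf("%.6f", x)), collapse = "|")
}

sqexp_cov <- function(X1, X2, ls, s2) {
  D2 <- matrix(0, nrow(X1), nrow(X2))
  for (d in seq_len(ncol(X1))) {
    D2 <- D2 + outer(X1[, d], X2[, d], "-")^2 / ls[d]^2
  }
  s2 * exp(-0.5 * D2)
}

matern52_cov <- function(X1, X2, ls, s2) {
  D2 <- matrix(0, nrow(X1), nrow(X2))
  for (d in seq_len(ncol(X1))) {
    D2 <- D2 + outer(X1[, d], X2[, d], "-")^2 / ls[d]^2
  }
  r <- sqrt(pmax(D2, 0))
  s2 * (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)
}

chol_jitter <- function(K) {
  jit <- 1e-10
  repeat {
    L <- tryCatch(chol(K + diag(jit, nrow(K))), error = function(e) NULL)
    if (!is.null(L)) {
      attr(L, "jitter") <- jit
      return(L)
    }
    jit <- jit * 10
    if (jit > 1e-6) stopf("covariance matrix singular even after jitter escalation")
  }
}

#' Fit a Gaussian-process surrogate
#'
#' Zero-mean GP on centered scores with a squared-exponential (default) or
#' Matern 5/2 kernel with per-dimension length-scales. Kernel amplitude,
#' length-scales and observation-noise variance are fitted by maximizing the
#' log marginal likelihood from several starting points (L-BFGS-B on log
#' parameters). Inputs are expected on the unit hypercube (see [scale01]
#' usage inside [run_bo()]).
#'
#' @param X Numeric matrix of evaluated inputs (rows in `[0,1]^d`).
#' @param y Scores at the rows of `X` (here: minus validation MSE).
#' @param kernel `"sqexp"` or `"matern52"`.
#' @param n_starts Number of multi-start optimizations.
#' @return Object of class `gp_surrogate`.
#' @export
gp_fit <- function(X, y, kernel = c("sqexp", "matern52"), n_starts = 3L) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  if (nrow(X) < 2) stopf("gp_fit needs at least 2 points")
  if (nrow(unique(X)) < 2) stopf("gp_fit needs at least 2 distinct points")
  y_mean <- mean(y)
  yc <- y - y_mean
  sy2 <- max(var(yc), 1e-12)
  d <- ncol(X)
  covfun <- if (kernel == "sqexp") sqexp_cov else matern52_cov

  nll <- function(par) {
    ls <- exp(par[seq_len(d)])
    s2 <- exp(par[d + 1])
    noise <- exp(par[d + 2])
    K <- covfun(X, X, ls, s2) + diag(noise, nrow(X))
    L <- tryCatch(chol_jitter(K), error = function(e) NULL)
    if (is.null(L)) return(1e10)
    alpha <- backsolve(L, forwardsolve(t(L), yc))
    val <- 0.5 * sum(yc * alpha) + sum(log(diag(L))) + 0.5 * nrow(X) * log(2 * pi)
    if (!is.finite(val)) 1e10 else val
  }

  starts <- list(c(rep(log(0.3), d), log(sy2), log(sy2 * 0.05)),
                 c(rep(log(1.0), d), log(sy2), log(sy2 * 0.01)),
                 c(rep(log(0.1), d), log(sy2), log(max(sy2 * 0.2, 1e-8))))
  starts <- starts[seq_len(min(n_starts, length(starts)))]
  lowerb <- c(rep(log(0.01), d), log(sy2 * 1e-4), log(1e-10))
  upperb <- c(rep(log(10), d), log(sy2 * 1e3), log(max(sy2, 1e-8) * 10))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      optim(st, nll, method = "L-BFGS-B", lower = lowerb, upper = upperb,
            control = list(maxit = 100)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stopf("GP hyperparameter optimization failed")
  par <- best$par
  ls <- exp(par[seq_len(d)])
  s2 <- exp(par[d + 1])
  noise <- exp(par[d + 2])
  K <- covfun(X, X, ls, s2) + diag(noise, nrow(X))
  L <- chol_jitter(K)
  alpha <- backsolve(L, forwardsolve(t(L), yc))
  structure(
    list(X = X, y = y, y_mean = y_mean, ls = ls, s2 = s2, noise = noise,
         jitter = attr(L, "jitter"), kernel = kernel, L = L, alpha = alpha),
    class = "gp_surrogate")
}

#' GP posterior mean and standard deviation
#'
#' Standard conditional-Gaussian formulas: `mu = k' K^{-1} y` and
#' `sd^2 = k(x,x) - k' K^{-1} k` (noise-free latent variance, floored at 0).
#'
#' @param object A `gp_surrogate`.
#' @param Xnew Matrix of query points (rows).
#' @param ... Unused.
#' @return List with `mean` and `sd` vectors.
#' @export
predict.gp_surrogate <- function(object, Xnew, ...) {
  Xnew <- as.matrix(Xnew)
  covfun <- if (object$kernel == "sqexp") sqexp_cov else matern52_cov
  Ks <- covfun(object$X, Xnew, object$ls, object$s2)
  mu <- object$y_mean + drop(crossprod(Ks, object$alpha))
  v <- forwardsolve(t(object$L), Ks)
  var_post <- pmax(object$s2 - colSums(v^2), 0)
  list(mean = mu, sd = sqrt(var_post))
}

#' Upper-confidence-bound acquisition
#'
#' `alpha(x) = mu(x) + beta * sd(x)`: large `beta` favours exploration
#' (posterior uncertainty), small `beta` exploitation (posterior mean).
#'
#' @param post A `gp_surrogate`.
#' @param Xnew Query points (matrix rows, unit-cube scale).
#' @param beta Non-negative trade-off parameter (default 2.576).
#' @return Acquisition values.
#' @export
ucb <- function(post, Xnew, beta = 2.576) {
  pr <- predict(post, Xnew)
  pr$mean + beta * pr$sd
}

#' Propose the next hyperparameter point
#'
#' Maximizes the UCB acquisition over a seeded candidate set: a large
#' Latin-hypercube pool plus Gaussian local refinements around the incumbent
#' best. Integer dimensions are rounded after optimization; a proposal whose
#' rounded key was already evaluated is stepped to the nearest unevaluated
#' integer-lattice neighbour.
#'
#' @param state A `bo_state` (from [run_bo()]) with a fitted surrogate.
#' @param bounds A [bo_bounds].
#' @param beta UCB trade-off.
#' @param n_cand Candidate-pool size.
#' @param seed RNG seed for the candidate pool.
#' @param candidates Optional explicit candidate matrix (rows on the unit
#'   hypercube) replacing the generated pool.
#' @return Named numeric vector (a hyperparameter point within bounds).
#' @export
propose_next <- function(state, bounds, beta = 2.576, n_cand = 500L,
                         seed = 1L, candidates = NULL) {
  gp <- state$gp
  if (is.null(gp)) stopf("no fitted surrogate in state")
  if (is.null(candidates)) {
    set.seed(seed)
    cand <- lhs::randomLHS(n_cand, bounds$d)
    hist_ok <- state$history[is.finite(state$history$score), , drop = FALSE]
    if (nrow(hist_ok) > 0) {
      inc <- as.numeric(hist_ok[which.max(hist_ok$score), bounds$names])
      inc01 <- scale01(matrix(inc, 1), bounds)
      local <- matrix(rep(inc01, each = 100L), 100L) +
        matrix(rnorm(100L * bounds$d, 0, 0.05), 100L)
      local <- pmin(pmax(local, 0), 1)
      cand <- rbind(cand, local)
    }
  } else {
    cand <- as.matrix(candidates)
  }
  acq <- ucb(gp, cand, beta)
  ord <- order(acq, decreasing = TRUE)
  keys <- state$keys %||% character(0)
  for (i in ord) {
    g <- round_gamma(drop(unscale01(cand[i, , drop = FALSE], bounds)), bounds)
    if (!(gamma_key(g, bounds) %in% keys)) return(g)
  }
  # Everything in the pool collides with evaluated points: walk integer-
  # lattice neighbours of the acquisition argmax.
  g0 <- round_gamma(drop(unscale01(cand[ord[1], , drop = FALSE], bounds)), bounds)
  for (radius in 1:50) {
    for (d in which(bounds$integer)) {
      for (s in c(-1, 1)) {
        g <- g0
        g[d] <- g[d] + s * radius
        g <- round_gamma(g, bounds)
        if (!(gamma_key(g, bounds) %in% keys)) return(g)
      }
    }
  }
  stopf("candidate space exhausted: all lattice points near the optimum evaluated")
}

#' Run Gaussian-process Bayesian optimization with UCB
#'
#' Evaluates a seeded initial Latin-hypercube design, then performs `T`
#' sequential fit-surrogate / propose / evaluate iterations, maximizing the
#' objective (for CNNGWP: minus the validation MSE, so maximization
#' minimizes prediction error). Non-finite objective values are recorded as
#' `NA`, skipped by the surrogate, and optimization continues.
#'
#' @param objective Function taking a named hyperparameter vector and
#'   returning a scalar score to maximize.
#' @param bounds A [bo_bounds].
#' @param T Number of sequential BO iterations (reference setting: 40).
#' @param beta UCB trade-off (default 2.576).
#' @param seed Seed controlling the design and proposals.
#' @param n_init Initial design size (default 7).
#' @param kernel GP kernel (`"sqexp"` or `"matern52"`).
#' @param verbose Print per-iteration progress.
#' @return Object of class `bo_state`: `history` (data frame: `iteration`,
#'   one column per dimension, `score`), `best_gamma`, `best_score`, `gp`,
#'   `beta`, `T`, `seed`.
#' @export
run_bo <- function(objective, bounds, T = 40L, beta = 2.576, seed = 1L,
                   n_init = 7L, kernel = "sqexp", verbose = FALSE) {
  if (n_init < 2) stopf("n_init must be >= 2")
  state <- list(history = NULL, keys = character(0), gp = NULL,
                beta = beta, T = as.integer(T), seed = as.integer(seed))
  record <- function(g, score, iter) {
    row <- as.data.frame(as.list(g))
    names(row) <- bounds$names
    row$iteration <- iter
    row$score <- score
    state$history <<- rbind(state$history, row)
    state$keys <<- c(state$keys, gamma_key(g, bounds))
  }
  eval_obj <- function(g) {
    failed <- FALSE
    sc <- tryCatch(objective(g), error = function(e) {
      failed <<- TRUE
      warning(sprintf("objective failed at (%s): %s",
                      paste(signif(g, 4), collapse = ", "),
                      conditionMessage(e)), call. = FALSE)
      NA_real_
    })
    if (!failed && (length(sc) != 1 || !is.finite(sc))) {
      warning("objective returned a non-finite score; recorded as NA",
              call. = FALSE)
    }
    if (length(sc) != 1 || !is.finite(sc)) NA_real_ else as.numeric(sc)
  }

  # Initial design: seeded Latin hypercube, re-drawn on rounded-key collision.
  set.seed(derive_seed(seed, 0L))
  D <- lhs::randomLHS(n_init, bounds$d)
  for (i in seq_len(n_init)) {
    g <- round_gamma(drop(unscale01(D[i, , drop = FALSE], bounds)), bounds)
    tries <- 0L
    while (gamma_key(g, bounds) %in% state$keys && tries < 100L) {
      g <- round_gamma(drop(unscale01(matrix(runif(bounds$d), 1), bounds)),
                       bounds)
      tries <- tries + 1L
    }
    record(g, eval_obj(g), iter = i - n_init)  # init iterations <= 0
    msgf(verbose, "init %d/%d: score %.6g", i, n_init,
         state$history$score[nrow(state$history)])
  }

  for (t in seq_len(T)) {
    ok <- is.finite(state$history$score)
    if (sum(ok) >= 2) {
      Xs01 <- scale01(as.matrix(state$history[ok, bounds$names]), bounds)
      state$gp <- gp_fit(Xs01, state$history$score[ok], kernel = kernel)
      g <- propose_next(state, bounds, beta = beta,
                        seed = derive_seed(seed, t))
    } else {
      set.seed(derive_seed(seed, t))
      g <- round_gamma(drop(unscale01(matrix(runif(bounds$d), 1), bounds)),
                       bounds)
    }
    record(g, eval_obj(g), iter = t)
    msgf(verbose, "iter %d/%d: (%s) score %.6g", t, T,
         paste(signif(g, 4), collapse = ", "),
         state$history$score[nrow(state$history)])
  }
  ok <- is.finite(state$history$score)
  if (!any(ok)) stopf("no finite objective evaluations")
  best_row <- state$history[ok, ][which.max(state$history$score[ok]), ]
  state$best_gamma <- stats::setNames(as.numeric(best_row[bounds$names]),
                                      bounds$names)
  state$best_score <- best_row$score
  state$bounds <- bounds
  structure(state, class = "bo_state")
}

#' @export
print.bo_state <- function(x, ...) {
  cat(sprintf("bo_state: %d evaluations (T = %d), best score %.6g at (%s)\n",
              nrow(x$history), x$T, x$best_score,
              paste(signif(x$best_gamma, 5), collapse = ", ")))
  invisible(x)
}

#' Build the CNNGWP tuning objective
#'
#' Returns the closure handed to [run_bo()]: train the network at the given
#' hyperparameters and return minus the best-epoch validation MSE.
#'
#' @param Xs,ys Standardized genotypes and centered phenotype.
#' @param train_idx,val_idx Training and scoring rows.
#' @param stride,pool_size Fixed architecture settings.
#' @param epochs,lr,batch_size Training settings (see [fit_cnn()]).
#' @param seed Training seed used for every evaluation (so the objective is
#'   a deterministic function of the hyperparameters).
#' @return Function mapping a named vector `(filters, kernel_width,
#'   l1_lambda)` to minus the validation MSE.
#' @export
make_cnn_objective <- function(Xs, ys, train_idx, val_idx, stride = 2L,
                               pool_size = 2L, epochs = 250L, lr = 0.00025,
                               batch_size = NULL, seed = 1L) {
  function(gamma) {
    spec <- cnn_spec(p = ncol(Xs), filters = gamma[["filters"]],
                     kernel_width = gamma[["kernel_width"]],
                     stride = stride, pool_size = pool_size,
                     l1_lambda = gamma[["l1_lambda"]])
    fit <- fit_cnn(Xs = Xs, ys = ys, train_idx = train_idx,
                   val_idx = val_idx, spec = spec, epochs = epochs, lr = lr,
                   batch_size = batch_size, seed = seed)
    -fit$best_val_mse
  }
}
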