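#' Network specification
#'
#' Defines the CNNGWP architecture: a single 1-D convolution layer (linear
#' activation, equal zero padding, strided), max pooling over non-overlapping
#' windows, a flatten step, and a 1-unit dense output layer whose weights
#' carry an L1 penalty. The three entries of the hyperparameter vector tuned
#' by Bayesian optimization are `filters`, `kernel_width` and `l1_lambda`.
#'
#' @param p Input length (number of SNPs).
#' @param filters Number of convolution filters q.
#' @param kernel_width Convolution window size.
#' @param stride Convolution stride (reference setting: 2).
#' @param pool_size Max-pooling window (reference setting: 2).
#' @param l1_lambda Non-negative L1 penalty on the output-layer weights.
#' @return Object of class `cnn_spec`.
#' @export
cnn_spec <- function(p, filters, kernel_width, stride = 2L, pool_size = 2L,
                     l1_lambda = 0) {
  filters <- as.integer(filters)
  kernel_width <- as.integer(kernel_width)
  stride <- as.integer(stride)
  pool_size <- as.integer(pool_size)
  if (p < 1 || filters < 1 || kernel_width < 1 || stride < 1 || pool_size < 1) {
    stopf("p, filters, kernel_width, stride and pool_size must all be >= 1")
  }
  if (l1_lambda < 0) stopf("l1_lambda must be >= 0")
  spec <- structure(
    list(p = as.integer(p), filters = filters, kernel_width = kernel_width,
         stride = stride, pool_size = pool_size, l1_lambda = l1_lambda),
    class = "cnn_spec")
  if (pooled_length(spec) < 1) {
    stopf("pooled length is 0: input %d too short for stride %d, pool %d",
          p, stride, pool_size)
  }
  spec
}

conv_out_length <- function(spec) as.integer(ceiling(spec$p / spec$stride))
pooled_length <- function(spec) conv_out_length(spec) %/% spec$pool_size
flatten_size <- function(spec) pooled_length(spec) * spec$filters

#' Layer shape and parameter-count table
#'
#' Reproduces the layer summary of the architecture: conv output length
#' `ceil(p / stride)` under equal zero padding with `kernel_width x filters
#' + filters` trainable parameters (single input channel, per-filter bias),
#' pooled length `floor(conv / pool)`, flatten `pooled x filters`, and
#' `flatten + 1` dense parameters.
#'
#' @param spec A [cnn_spec] (or a fitted `cnn_model`, whose spec is used).
#' @return Data frame with columns `layer`, `out_length`, `channels`,
#'   `params`; total parameter count in attribute `"total_params"`.
#' @examples
#' infer_shapes(cnn_spec(p = 9723, filters = 64, kernel_width = 27))
#' @export
infer_shapes <- function(spec) {
  if (inherits(spec, "cnn_model")) spec <- spec$spec
  cl <- conv_out_length(spec)
  pl <- pooled_length(spec)
  fl <- flatten_size(spec)
  out <- data.frame(
    layer = c("conv1d", "maxpool", "flatten", "dense"),
    out_length = c(cl, pl, fl, 1L),
    channels = c(spec$filters, spec$filters, 1L, 1L),
    params = c(spec$kernel_width * spec$filters + spec$filters, 0L, 0L, fl + 1L),
    stringsAsFactors = FALSE)
  attr(out, "total_params") <- sum(out$params)
  out
}

#' Describe a network in a layer/shape/parameter summary
#'
#' @param spec A [cnn_spec].
#' @return The [infer_shapes()] table, invisibly; prints a formatted summary.
#' @export
describe_network <- function(spec) {
  tab <- infer_shapes(spec)
  cat("Layer (type)      Output shape          # Parameters\n")
  shapes <- c(sprintf("(None, %d, %d)", tab$out_length[1], tab$channels[1]),
              sprintf("(None, %d, %d)", tab$out_length[2], tab$channels[2]),
              sprintf("(None, %d)", tab$out_length[3]),
              "(None, 1)")
  for (i in 1:4) {
    cat(sprintf("%-17s %-21s %d\n", tab$layer[i], shapes[i], tab$params[i]))
  }
  cat(sprintf("Total%38d\n", attr(tab, "total_params")))
  invisible(tab)
}

#' Initialize network parameters
#'
#' Glorot-uniform weights, `U(-sqrt(6 / (fan_in + fan_out)),
#' +sqrt(6 / (fan_in + fan_out)))` per layer, zero biases; deterministic
#' under `seed`.
#'
#' @param spec A [cnn_spec].
#' @param seed RNG seed.
#' @return Object of class `cnn_model`: `spec`, conv kernels `K`
#'   (`kernel_width x filters`), conv biases `bias_c`, output weights `W`
#'   (length [flatten]), output bias `b`.
#' @export
init_network <- function(spec, seed = 1L) {
  set.seed(seed)
  kw <- spec$kernel_width
  q <- spec$filters
  fl <- flatten_size(spec)
  lim_conv <- sqrt(6 / (kw + kw * q))
  lim_dense <- sqrt(6 / (fl + 1))
  structure(
    list(spec = spec,
         K = matrix(runif(kw * q, -lim_conv, lim_conv), kw, q),
         bias_c = numeric(q),
         W = runif(fl, -lim_dense, lim_dense),
         b = 0,
         seed = as.integer(seed)),
    class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  s <- x$spec
  cat(sprintf("cnn_model: p=%d, filters=%d, kernel=%d, stride=%d, pool=%d, lambda=%g\n",
              s$p, s$filters, s$kernel_width, s$stride, s$pool_size, s$l1_lambda))
  invisible(x)
}

#' 1-D convolution layer forward pass
#'
#' Strided discrete cross-correlation (filters slid without flipping) with
#' equal zero padding: the total padding `max((ceil(L/s) - 1) s + k - L, 0)`
#' is split evenly with the extra zero on the right, so the output length is
#' `ceil(L / stride)`.
#'
#' @param X Numeric matrix, one row per individual (a single row is accepted
#'   as a vector).
#' @param spec A [cnn_spec] or `cnn_model`; a bare model supplies `K` and
#'   `bias_c`.
#' @param K,bias_c Kernel matrix (`kernel_width x filters`) and per-filter
#'   biases when `spec` is a plain [cnn_spec].
#' @return Array `n x out_length x filters`.
#' @export
conv1d_forward <- function(X, spec, K = NULL, bias_c = NULL) {
  if (inherits(spec, "cnn_model")) {
    K <- spec$K
    bias_c <- spec$bias_c
    spec <- spec$spec
  }
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != spec$p) stopf("input width %d != spec p = %d", ncol(X), spec$p)
  if (nrow(K) != spec$kernel_width || ncol(K) != spec$filters) {
    stopf("kernel shape (%d, %d) does not match spec (%d, %d)",
          nrow(K), ncol(K), spec$kernel_width, spec$filters)
  }
  conv1d_fwd_cpp(X, K, bias_c %||% numeric(spec$filters), spec$stride)
}

#' Max-pooling layer forward pass
#'
#' Non-overlapping windows of `pool_size` along the position axis; a trailing
#' remainder shorter than the window is dropped. The in-window argmax
#' positions are recorded for gradient routing (ties broken by the first
#' position).
#'
#' @param g Feature-map array `n x L x q` from [conv1d_forward()].
#' @param pool_size Window length (must not exceed `L`).
#' @return List with `pooled` (`n x floor(L/pool) x q`) and `argmax`
#'   (same shape, 1-based position along the input axis).
#' @export
maxpool_forward <- function(g, pool_size) {
  if (length(dim(g)) != 3) stopf("feature map must be an n x L x q array")
  if (pool_size > dim(g)[2]) {
    stopf("pool_size %d exceeds feature-map length %d", pool_size, dim(g)[2])
  }
  maxpool_fwd_cpp(g, as.integer(pool_size))
}

#' Network forward pass
#'
#' `conv -> max pool -> flatten -> dense`, linear throughout except the max
#' pooling. The flatten order is position-major (filters fastest), so output
#' weight index `(t - 1) q + l` corresponds to pooled position `t` — the
#' ordering on which the SNP/weight-index mapping of [snp_to_weight_index()]
#' relies.
#'
#' @param model A `cnn_model`.
#' @param X Input matrix (`n x p`, standardized genotypes) or vector.
#' @param chunk Rows per internal block (memory control).
#' @return Numeric vector of predictions.
#' @export
forward <- function(model, X, chunk = 256L) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  spec <- model$spec
  if (ncol(X) != spec$p) stopf("input width %d != model p = %d", ncol(X), spec$p)
  n <- nrow(X)
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    out[rows] <- cnn_predict_cpp(X[rows, , drop = FALSE], model$K,
                                 model$bias_c, model$W, model$b,
                                 spec$stride, spec$pool_size)
  }
  out
}

#' Training loss
#'
#' Mean squared error plus the L1 penalty on the output-layer weights only
#' (conv kernels and all biases are unpenalized):
#' `J = mean((y - yhat)^2) + lambda * sum(|W|)`.
#'
#' @param y_hat Predictions.
#' @param y Observed phenotypes.
#' @param model A `cnn_model` (supplies `W` and `l1_lambda`).
#' @return List with `mse`, `l1_penalty`, `total`.
#' @export
cnn_loss <- function(y_hat, y, model) {
  if (length(y_hat) != length(y)) stopf("prediction/response length mismatch")
  if (length(y) == 0) stopf("empty batch")
  mse <- mean((y_hat - y)^2)
  pen <- model$spec$l1_lambda * sum(abs(model$W))
  list(mse = mse, l1_penalty = pen, total = mse + pen)
}

#' Exact gradients of the training loss
#'
#' Single fused forward/backward pass over a batch. The dense gradient
#' includes the L1 subgradient `lambda * sign(W)` with `sign(0) = 0`; the
#' pooling stage routes gradient only to the recorded argmax positions; the
#' conv gradient is accumulated over all strided positions and batch rows.
#'
#' @param model A `cnn_model`.
#' @param X Batch input (`n x p`).
#' @param y Batch response.
#' @return List with the loss decomposition (`mse`, `penalty`, `total`),
#'   `pred`, and gradients `dK`, `dbias`, `dW`, `db`.
#' @export
backward <- function(model, X, y) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (nrow(X) != length(y)) stopf("X rows (%d) != length(y) (%d)", nrow(X), length(y))
  if (length(y) == 0) stopf("empty batch")
  spec <- model$spec
  if (ncol(X) != spec$p) stopf("input width %d != model p = %d", ncol(X), spec$p)
  cnn_batch_grad_cpp(X, y, model$K, model$bias_c, model$W, model$b,
                     spec$stride, spec$pool_size, spec$l1_lambda)
}
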