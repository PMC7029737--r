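#' Default mini-batch size
#'
#' The integer part of the square root of the number of training
#' observations (e.g. 2,326 training individuals give batches of 48).
#'
#' @param n_train Training-set size.
#' @return `floor(sqrt(n_train))`, at least 1.
#' @export
default_batch_size <- function(n_train) {
  if (n_train < 1) stopf("n_train must be >= 1")
  max(1L, as.integer(floor(sqrt(n_train))))
}

#' ADAM optimizer state
#'
#' First/second moment accumulators matching the shapes of the parameter
#' list, with bias-corrected updates. Defaults: `beta1 = 0.9`,
#' `beta2 = 0.999`, `epsilon = 1e-7`.
#'
#' @param params Named list of numeric arrays (the trainable parameters).
#' @param lr Learning rate (reference setting for the simulated data:
#'   0.00025).
#' @param beta1,beta2 Moment decay rates in `[0, 1)`.
#' @param epsilon Numerical floor in the denominator.
#' @return Object of class `adam_state`.
#' @export
adam_init <- function(params, lr = 0.00025, beta1 = 0.9, beta2 = 0.999,
                      epsilon = 1e-7) {
  if (beta1 < 0 || beta1 >= 1 || beta2 < 0 || beta2 >= 1) {
    stopf("beta1 and beta2 must be in [0, 1)")
  }
  structure(
    list(lr = lr, beta1 = beta1, beta2 = beta2, epsilon = epsilon,
         m = lapply(params, function(x) x * 0),
         v = lapply(params, function(x) x * 0),
         t = 0L),
    class = "adam_state")
}

#' One ADAM update
#'
#' Standard recurrences `m <- b1 m + (1 - b1) g`, `v <- b2 v + (1 - b2) g^2`
#' with bias correction, then `theta <- theta - lr * mhat / (sqrt(vhat) +
#' epsilon)`.
#'
#' @param state An `adam_state`.
#' @param params Named list of parameter arrays.
#' @param grads Named list of gradients, shape-matching `params`.
#' @return List with updated `params` and `state`.
#' @export
adam_step <- function(state, params, grads) {
  state$t <- state$t + 1L
  c1 <- 1 - state$beta1^state$t
  c2 <- 1 - state$beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (any(!is.finite(g))) stopf("non-finite gradient in component '%s'", nm)
    state$m[[nm]] <- state$beta1 * state$m[[nm]] + (1 - state$beta1) * g
    state$v[[nm]] <- state$beta2 * state$v[[nm]] + (1 - state$beta2) * g^2
    mhat <- state$m[[nm]] / c1
    vhat <- state$v[[nm]] / c2
    params[[nm]] <- params[[nm]] - state$lr * mhat / (sqrt(vhat) + state$epsilon)
  }
  list(params = params, state = state)
}

model_params <- function(model) {
  list(K = model$K, bias_c = model$bias_c, W = model$W, b = model$b)
}

set_model_params <- function(model, params) {
  model$K <- params$K
  model$bias_c <- params$bias_c
  model$W <- params$W
  model$b <- params$b
  model
}

#' Train a CNNGWP model with mini-batch ADAM
#'
#' One epoch is a full seeded-shuffled pass over the training rows in
#' batches of `batch_size` (the last, possibly smaller, batch is kept).
#' After every epoch the validation MSE (no penalty term) is computed and
#' the parameters of the epoch with the lowest validation MSE are
#' checkpointed; those best-epoch parameters are what [predict.cnn_fit()]
#' uses. The per-epoch shuffling seed is derived from `(seed, epoch)`, so
#' replicate runs differ only through their run seed. Note that this
#' function seeds the session RNG.
#'
#' @param model A `cnn_model` from [init_network()], or `NULL` to initialize
#'   from `spec` and `seed`.
#' @param Xs Standardized genotype matrix (`n x p`).
#' @param ys Centered phenotype vector.
#' @param train_idx,val_idx Row indices for training and validation;
#'   `val_idx` must be non-empty.
#' @param spec A [cnn_spec] (needed when `model` is `NULL`).
#' @param batch_size Mini-batch size; default [default_batch_size()].
#' @param epochs Maximum number of epochs (reference setting: 250).
#' @param lr ADAM learning rate.
#' @param seed Run seed (initialization and shuffling).
#' @param shuffle Reshuffle training rows every epoch.
#' @return Object of class `cnn_fit`: `trace` (data frame `epoch`,
#'   `train_loss`, `val_mse`), `best_epoch`, `best_params`, `model` (final
#'   epoch), `spec`, `seed`.
#' @export
fit_cnn <- function(model = NULL, Xs, ys, train_idx, val_idx, spec = NULL,
                    batch_size = NULL, epochs = 250L, lr = 0.00025,
                    seed = 1L, shuffle = TRUE) {
  if (is.null(model)) {
    if (is.null(spec)) stopf("either `model` or `spec` must be given")
    model <- init_network(spec, seed = seed)
  }
  if (length(val_idx) == 0) stopf("validation set is empty")
  n_train <- length(train_idx)
  batch_size <- batch_size %||% default_batch_size(n_train)
  if (batch_size < 1 || batch_size > n_train) {
    stopf("batch_size must be in [1, %d]", n_train)
  }
  Xtr <- Xs[train_idx, , drop = FALSE]
  ytr <- ys[train_idx]
  Xval <- Xs[val_idx, , drop = FALSE]
  yval <- ys[val_idx]
  spec_ <- model$spec

  # Seeded per-epoch visiting orders; the compiled loop consumes them as-is,
  # so the shuffling contract lives entirely here.
  perms <- matrix(0L, epochs, n_train)
  for (ep in seq_len(epochs)) {
    if (shuffle) {
      set.seed(derive_seed(seed, ep))
      perms[ep, ] <- sample.int(n_train)
    } else {
      perms[ep, ] <- seq_len(n_train)
    }
  }
  adam_defaults <- adam_init(list(), lr = lr)
  out <- cnn_train_cpp(Xtr, ytr, Xval, yval, model$K, model$bias_c,
                       model$W, model$b, spec_$stride, spec_$pool_size,
                       spec_$l1_lambda, lr, adam_defaults$beta1,
                       adam_defaults$beta2, adam_defaults$epsilon,
                       perms, as.integer(batch_size))
  trace <- data.frame(epoch = seq_len(epochs),
                      train_loss = out$trace[, 1], val_mse = out$trace[, 2])
  best_params <- list(K = out$K_best, bias_c = drop(out$bias_c_best),
                      W = drop(out$W_best), b = out$b_best)
  final_params <- list(K = out$K, bias_c = drop(out$bias_c),
                       W = drop(out$W), b = out$b)
  structure(
    list(trace = trace, best_epoch = out$best_epoch,
         best_val_mse = out$best_val, best_params = best_params,
         model = set_model_params(model, final_params),
         spec = spec_, seed = as.integer(seed)),
    class = "cnn_fit")
}

#' @export
print.cnn_fit <- function(x, ...) {
  cat(sprintf("cnn_fit: %d epochs, best epoch %d (validation MSE %.6g)\n",
              nrow(x$trace), x$best_epoch, x$best_val_mse))
  invisible(x)
}

#' Predict from a trained CNNGWP model
#'
#' Forward pass with the checkpointed best-epoch parameters (default) or the
#' final-epoch parameters.
#'
#' @param object A `cnn_fit`.
#' @param X Input matrix (`n x p`).
#' @param use `"best"` (best validation epoch) or `"final"`.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.cnn_fit <- function(object, X, use = c("best", "final"), ...) {
  use <- match.arg(use)
  if (use == "best") {
    if (is.na(object$best_epoch)) stopf("no checkpoint available")
    model <- set_model_params(object$model, object$best_params)
  } else {
    model <- object$model
  }
  forward(model, X)
}

#' Write a training trace as CSV
#'
#' @param fit A `cnn_fit`.
#' @param path Output path for the `epoch,train_loss,val_mse` table.
#' @export
write_trace_csv <- function(fit, path) {
  data.table::fwrite(fit$trace, path)
  invisible(path)
}
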