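#' Average replicate-best hyperparameters
#'
#' Componentwise mean of the per-replicate best hyperparameter vectors;
#' integer components (filters, kernel width) are rounded half away from
#' zero, the penalty stays continuous.
#'
#' @param gammas List of named numeric vectors (one per replicate).
#' @param integer Logical vector marking integer components (default:
#'   `filters` and `kernel_width` integer, `l1_lambda` continuous).
#' @return Named numeric vector `gamma_MA`.
#' @export
average_hyperparams <- function(gammas, integer = NULL) {
  if (length(gammas) == 0) stopf("empty hyperparameter list")
  M <- do.call(rbind, lapply(gammas, function(g) g[names(gammas[[1]])]))
  avg <- colMeans(M)
  if (is.null(integer)) {
    integer <- names(avg) %in% c("filters", "kernel_width")
  }
  avg[integer] <- round_half_away(avg[integer])
  avg
}

#' Model-averaged ensemble prediction
#'
#' Elementwise mean of the per-replicate prediction vectors.
#'
#' @param preds List of equal-length prediction vectors (or a matrix with
#'   one column per replicate).
#' @return Averaged prediction vector.
#' @export
ma_predict <- function(preds) {
  if (is.list(preds)) {
    len <- vapply(preds, length, 1L)
    if (length(unique(len)) != 1) stopf("prediction vectors differ in length")
    preds <- do.call(cbind, preds)
  }
  rowMeans(preds)
}

#' Run the full CNNGWP pipeline
#'
#' Four stages: (1) `S` independent Bayesian-optimization replicates with
#' distinct derived seeds, each returning its best hyperparameters; (2)
#' averaging into `gamma_MA` via [average_hyperparams()]; (3) `S` trainings
#' at the fixed `gamma_MA` with distinct seeds; (4) averaging the `S` test
#' predictions into the ensemble prediction and its test MSE. The weight
#' sets of the `S` models are kept separately (conv filters may pick up
#' different QTLs per run, so weights are never averaged into one model);
#' only the output-layer weights are additionally averaged for QTL
#' localization plots.
#'
#' By default the BO score is computed on the same rows the final test MSE
#' is reported on, reproducing the reference protocol (`validation =
#' "test"`; a form of selection leakage). `validation = "holdout"` instead
#' carves `val_frac` off the training block for scoring.
#'
#' @param Xs,ys Standardized genotypes and centered phenotype.
#' @param split A `split_plan` (holdout mode).
#' @param S Number of replicates (reference setting: 25).
#' @param T BO iterations per replicate (reference setting: 40).
#' @param bounds A [bo_bounds] (default [cnngwp_bounds()]).
#' @param base_seed Base seed; replicate seeds are derived deterministically.
#' @param epochs,lr,batch_size,stride,pool_size Training settings.
#' @param bo_epochs Epoch budget for the tuning-stage trainings (default:
#'   `epochs`); hyperparameter search only needs the relative ranking of
#'   candidate settings, so it can run on a shorter budget than the final
#'   ensemble trainings.
#' @param beta,n_init BO settings (see [run_bo()]).
#' @param validation `"test"` or `"holdout"`.
#' @param val_frac Fraction of the training block used for scoring when
#'   `validation = "holdout"`.
#' @param checkpoint_dir Optional directory: per-replicate results are
#'   saved there and reloaded on re-run (resumable stages).
#' @param verbose Log stage progress.
#' @return Object of class `ensemble_result`: `per_rep_gamma`, `gamma_ma`,
#'   `preds` (test rows x S), `y_ma`, `mse_ma`, `per_run_mse`, `weights`
#'   (output-layer weights, flatten x S), `weights_ma`, `models`, `bo`.
#' @export
run_cnngwp <- function(Xs, ys, split, S = 25L, T = 40L,
                       bounds = cnngwp_bounds(), base_seed = 1L,
                       epochs = 250L, bo_epochs = epochs, lr = 0.00025,
                       batch_size = NULL,
                       stride = 2L, pool_size = 2L, beta = 2.576,
                       n_init = 7L, validation = c("test", "holdout"),
                       val_frac = 0.2, checkpoint_dir = NULL,
                       verbose = FALSE) {
  validation <- match.arg(validation)
  if (S < 1) stopf("S must be >= 1")
  train_idx <- split$train_idx
  test_idx <- split$test_idx
  if (validation == "holdout") {
    if (length(split$val_idx) > 0) {
      val_idx <- split$val_idx
    } else {
      n_val <- max(1L, floor(val_frac * length(train_idx)))
      val_idx <- train_idx[(length(train_idx) - n_val + 1L):length(train_idx)]
      train_idx <- setdiff(train_idx, val_idx)
    }
  } else {
    val_idx <- test_idx
  }

  ckpt <- function(name) {
    if (is.null(checkpoint_dir)) return(NULL)
    file.path(checkpoint_dir, paste0(name, ".rds"))
  }
  load_or <- function(name, fn) {
    path <- ckpt(name)
    if (!is.null(path) && file.exists(path)) return(readRDS(path))
    out <- tryCatch(fn(), error = function(e) {
      stopf("replicate '%s' failed: %s", name, conditionMessage(e))
    })
    if (!is.null(path)) {
      dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
      saveRDS(out, path)
    }
    out
  }

  # Stage 1: S Bayesian-optimization replicates.
  bo_runs <- vector("list", S)
  for (s in seq_len(S)) {
    rep_seed <- derive_seed(base_seed, s)
    msgf(verbose, "stage 1: BO replicate %d/%d (seed %d)", s, S, rep_seed)
    obj <- make_cnn_objective(Xs, ys, train_idx, val_idx, stride = stride,
                              pool_size = pool_size, epochs = bo_epochs,
                              lr = lr, batch_size = batch_size,
                              seed = rep_seed)
    bo_runs[[s]] <- load_or(sprintf("bo_rep%03d", s), function() {
      run_bo(obj, bounds, T = T, beta = beta, seed = rep_seed,
             n_init = n_init)
    })
  }
  per_rep <- lapply(bo_runs, `[[`, "best_gamma")

  # Stage 2: averaged hyperparameters.
  gamma_ma <- average_hyperparams(per_rep, integer = bounds$integer)
  msgf(verbose, "stage 2: gamma_MA = (%s)",
       paste(signif(gamma_ma, 5), collapse = ", "))

  # Stage 3: S re-trainings at fixed gamma_MA.
  spec <- cnn_spec(p = ncol(Xs), filters = gamma_ma[["filters"]],
                   kernel_width = gamma_ma[["kernel_width"]],
                   stride = stride, pool_size = pool_size,
                   l1_lambda = gamma_ma[["l1_lambda"]])
  fits <- vector("list", S)
  for (s in seq_len(S)) {
    run_seed <- derive_seed(base_seed, 10000L + s)
    msgf(verbose, "stage 3: MA training %d/%d (seed %d)", s, S, run_seed)
    fits[[s]] <- load_or(sprintf("ma_fit%03d", s), function() {
      fit_cnn(Xs = Xs, ys = ys, train_idx = train_idx, val_idx = val_idx,
              spec = spec, epochs = epochs, lr = lr,
              batch_size = batch_size, seed = run_seed)
    })
  }

  # Stage 4: ensemble prediction on the test block.
  preds <- vapply(fits, function(f) predict(f, Xs[test_idx, , drop = FALSE]),
                  numeric(length(test_idx)))
  preds <- matrix(preds, ncol = S)
  y_ma <- ma_predict(preds)
  y_test <- ys[test_idx]
  per_run_mse <- colMeans((preds - y_test)^2)
  mse_ma <- mean((y_ma - y_test)^2)
  weights <- vapply(fits, function(f) f$best_params$W,
                    numeric(flatten_size(spec)))
  weights <- matrix(weights, ncol = S)
  msgf(verbose, "stage 4: MSE_MA = %.6g (mean per-run %.6g)",
       mse_ma, mean(per_run_mse))
  structure(
    list(per_rep_gamma = per_rep, gamma_ma = gamma_ma, spec = spec,
         preds = preds, y_ma = y_ma, mse_ma = mse_ma,
         per_run_mse = per_run_mse, weights = weights,
         weights_ma = rowMeans(weights), models = fits, bo = bo_runs,
         test_idx = test_idx, val_idx = val_idx, train_idx = train_idx,
         base_seed = as.integer(base_seed)),
    class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("ensemble_result: S = %d, gamma_MA = (%s)\n",
              ncol(x$preds), paste(signif(x$gamma_ma, 5), collapse = ", ")))
  cat(sprintf("  MSE_MA = %.6g; per-run MSE mean = %.6g\n",
              x$mse_ma, mean(x$per_run_mse)))
  invisible(x)
}

#' Cross-validated CNNGWP
#'
#' Runs [run_cnngwp()] on every fold of a k-fold `split_plan` and reports
#' per-fold and mean test MSE; baselines can be run on the identical folds
#' for comparability.
#'
#' @param Xs,ys Standardized genotypes and centered phenotype.
#' @param split A k-fold `split_plan` from [make_splits()].
#' @param ... Passed to [run_cnngwp()].
#' @return List with `folds` (per-fold `ensemble_result`), `per_fold_mse`,
#'   `mean_mse`.
#' @export
crossval_driver <- function(Xs, ys, split, ...) {
  if (is.null(split$folds) || length(split$folds) < 2) {
    stopf("crossval_driver needs a k-fold split_plan with k >= 2")
  }
  results <- lapply(seq_along(split$folds), function(f) {
    fold <- split$folds[[f]]
    if (length(fold$train_idx) < 2) stopf("fold %d has < 2 training individuals", f)
    plan <- structure(list(mode = "holdout", n = split$n,
                           train_idx = fold$train_idx, val_idx = integer(0),
                           test_idx = fold$test_idx, folds = NULL),
                      class = "split_plan")
    run_cnngwp(Xs, ys, plan, ...)
  })
  per_fold <- vapply(results, `[[`, numeric(1), "mse_ma")
  list(folds = results, per_fold_mse = per_fold, mean_mse = mean(per_fold))
}
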