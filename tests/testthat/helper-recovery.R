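# Reduced-scale parameter-recovery experiment used by the acceptance suite:
# simulate a QTLMAS2010-style dataset, run the full tuned ensemble pipeline,
# and compare against GBLUP, the train-mean predictor, and the planted loci.
run_qtl_recovery <- function(seed, n = 1200, p = 2000, h2 = 0.6,
                             S = 3, T = 8) {
  sim <- simulate_qtlmas(n = n, p = p, h2 = h2, seed = seed)
  mf <- maf_filter(sim$genotypes, 0.01)
  ds <- standardize(mf$genotypes, sim$phenotype)
  split <- make_splits(nrow(ds$Xs), "holdout", boundary = round(0.8 * n))
  bounds <- bo_bounds(c(4, 8, 0.5), c(16, 24, 4.0),
                      integer = c(TRUE, TRUE, FALSE),
                      names = c("filters", "kernel_width", "l1_lambda"))
  res <- run_cnngwp(ds$Xs, ds$ys, split, S = S, T = T, bounds = bounds,
                    base_seed = seed, epochs = 20, bo_epochs = 10,
                    lr = 0.003, n_init = 3)
  gb <- fit_gblup(ds$Xs, ds$ys, split$train_idx, split$test_idx)
  mse_mean <- mean((mean(ds$ys[split$train_idx]) - ds$ys[split$test_idx])^2)

  # planted major loci: the two +-3 additive genes and the dominance locus,
  # tracked through the MAF filter into the filtered coordinate system
  loci <- sim$architecture$loci
  major <- loci$snp_index[abs(loci$e1) == 3 | loci$kind == "dominance"]
  major_filt <- match(major, mf$kept)
  pk <- extract_peaks(weight_map(res$weights_ma, ncol(ds$Xs)), top_k = 5)
  hits <- sum(vapply(major_filt, function(t) {
    any(abs(pk$snp_index - t) <= 25)
  }, logical(1)))

  c(mse_cnn = res$mse_ma, mse_mean_run = mean(res$per_run_mse),
    mse_gblup = gb$mse_test, mse_trainmean = mse_mean, peak_hits = hits)
}
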