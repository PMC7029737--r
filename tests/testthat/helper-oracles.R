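# Independent oracles and small shared fixtures.

# Strided cross-correlation via an explicit Toeplitz matrix (same equal
# zero-padding convention: total pad split evenly, extra zero on the right).
toeplitz_conv <- function(x, k, stride) {
  L <- length(x)
  kw <- length(k)
  out_len <- ceiling(L / stride)
  tot <- max((out_len - 1) * stride + kw - L, 0)
  left <- tot %/% 2
  xp <- c(rep(0, left), x, rep(0, tot - left))
  Tm <- matrix(0, out_len, length(xp))
  for (t in seq_len(out_len)) Tm[t, (t - 1) * stride + seq_len(kw)] <- k
  drop(Tm %*% xp)
}

# Dense closed-form GP posterior with a squared-exponential ARD kernel.
gp_closed_form <- function(X, y, Xnew, ls, s2, noise) {
  se <- function(A, B) {
    D2 <- matrix(0, nrow(A), nrow(B))
    for (d in seq_len(ncol(A))) {
      D2 <- D2 + outer(A[, d], B[, d], "-")^2 / ls[d]^2
    }
    s2 * exp(-0.5 * D2)
  }
  ym <- mean(y)
  Kinv <- solve(se(X, X) + diag(noise, nrow(X)))
  Ks <- se(X, Xnew)
  mu <- ym + drop(crossprod(Ks, Kinv %*% (y - ym)))
  v <- pmax(s2 - colSums(Ks * (Kinv %*% Ks)), 0)
  list(mean = mu, sd = sqrt(v))
}

# Write a small PLINK RAW fixture from a genotype matrix (rows = lines).
write_raw_fixture <- function(path, G, pheno = NULL, snp_names = NULL) {
  n <- nrow(G)
  p <- ncol(G)
  snp_names <- snp_names %||% paste0("snp", seq_len(p), "_A")
  ph <- pheno %||% rep(-9, n)
  header <- paste(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE",
                    snp_names), collapse = " ")
  rows <- vapply(seq_len(n), function(i) {
    paste(c(i, i, 0, 0, 0, ph[i], ifelse(is.na(G[i, ]), "NA", G[i, ])),
          collapse = " ")
  }, "")
  writeLines(c(header, rows), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small standardized regression dataset with a sparse linear signal.
make_linear_dataset <- function(n, p, n_causal = 3, beta_scale = 2,
                                sd_e = 1, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  X <- scale(X)[, ]
  causal <- seq(1, p, length.out = n_causal)
  beta <- numeric(p)
  beta[causal] <- beta_scale * c(1, -1, 1)[seq_len(n_causal) %% 3 + 1]
  y <- drop(X %*% beta) + rnorm(n, 0, sd_e)
  list(X = X, y = y - mean(y), beta = beta, causal = causal)
}
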