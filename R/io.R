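#' Genotype matrix container
#'
#' Holds an n x p matrix of additive genotype codes (0 = one homozygote,
#' 1 = heterozygote, 2 = the other homozygote) together with SNP, chromosome
#' and individual labels. This is the input `X` of the prediction model.
#'
#' @param values Numeric n x p matrix with entries in \{0, 1, 2\} or `NA`.
#' @param snp_ids Character vector of p unique SNP names.
#' @param chromosome Integer vector of p chromosome labels.
#' @param individual_ids Character vector of n individual identifiers.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(values, snp_ids = colnames(values),
                            chromosome = rep(1L, ncol(values)),
                            individual_ids = rownames(values)) {
  values <- as.matrix(values)
  n <- nrow(values)
  p <- ncol(values)
  if (n < 1L || p < 1L) stopf("genotype matrix must have n >= 1 and p >= 1")
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(p))
  if (is.null(individual_ids)) individual_ids <- as.character(seq_len(n))
  snp_ids <- as.character(snp_ids)
  individual_ids <- as.character(individual_ids)
  if (length(snp_ids) != p) stopf("snp_ids length %d != p = %d", length(snp_ids), p)
  if (anyDuplicated(snp_ids)) stopf("snp_ids must be unique")
  if (length(chromosome) != p) stopf("chromosome length %d != p = %d", length(chromosome), p)
  if (length(individual_ids) != n) {
    stopf("individual_ids length %d != n = %d", length(individual_ids), n)
  }
  bad <- values[!is.na(values) & !(values %in% c(0, 1, 2))]
  if (length(bad) > 0) {
    stopf("genotype codes must be 0, 1, 2 or NA; found %s", bad[1])
  }
  dimnames(values) <- list(individual_ids, snp_ids)
  structure(
    list(values = values, snp_ids = snp_ids,
         chromosome = as.integer(chromosome), individual_ids = individual_ids),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs, %d chromosome(s)\n",
              nrow(x$values), ncol(x$values), length(unique(x$chromosome))))
  cat(sprintf("  missing entries: %d\n", sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

plink_fixed_cols <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")

#' Read a PLINK RAW (--recode A) file
#'
#' Parses the whitespace-delimited additive-coding dialect produced by
#' `plink --recode A`: six fixed columns (FID IID PAT MAT SEX PHENOTYPE)
#' followed by one column per SNP with cells 0/1/2/NA. SNP names may carry
#' the counted-allele suffix (`rs123_A`); the full token is kept as the label.
#' A PHENOTYPE column that is not entirely missing (`NA` or `-9`) is returned
#' as a phenotype table.
#'
#' @param path Path to the `.raw` file.
#' @param missing How to treat missing genotype cells: `"impute"` replaces
#'   each `NA` by the column mean of the observed codes rounded to the nearest
#'   code in \{0, 1, 2\}; `"error"` refuses files with missing genotypes;
#'   `"keep"` leaves `NA` in place.
#' @param verbose Log record counts.
#' @return List with elements `genotypes` ([genotype_matrix]) and `phenotype`
#'   (data frame with columns `individual_id`, `y`, or `NULL`).
#' @export
read_plink_raw <- function(path, missing = c("impute", "error", "keep"),
                           verbose = FALSE) {
  missing <- match.arg(missing)
  if (!file.exists(path)) stopf("file not found: %s", path)
  header <- strsplit(readLines(path, n = 1L), "[ \t]+")[[1]]
  if (length(header) < 7L || !identical(header[1:6], plink_fixed_cols)) {
    stopf("malformed PLINK RAW header: expected 'FID IID PAT MAT SEX PHENOTYPE <snps...>', got '%s ...'",
          paste(head(header, 6), collapse = " "))
  }
  nfields <- utils::count.fields(path)
  ragged <- which(nfields != length(header))
  if (length(ragged) > 0) {
    stopf("ragged row in %s: line %d has %d fields, expected %d",
          path, ragged[1], nfields[ragged[1]], length(header))
  }
  dt <- data.table::fread(path, header = TRUE, na.strings = c("NA", "na"),
                          data.table = FALSE, showProgress = FALSE)
  snp_cols <- header[-(1:6)]
  G <- as.matrix(dt[, snp_cols, drop = FALSE])
  storage.mode(G) <- "double"
  bad <- which(!is.na(G) & !(G %in% c(0, 1, 2)))
  if (length(bad) > 0) {
    stopf("invalid genotype value '%s' in SNP column '%s'",
          G[bad[1]], snp_cols[(bad[1] - 1) %/% nrow(G) + 1])
  }
  if (anyNA(G)) {
    if (missing == "error") {
      stopf("%d missing genotype cells and missing = \"error\"", sum(is.na(G)))
    }
    if (missing == "impute") G <- impute_column_mean(G)
  }
  ids <- as.character(dt$IID)
  gm <- genotype_matrix(G, snp_ids = snp_cols, individual_ids = ids)
  phe <- NULL
  ph <- suppressWarnings(as.numeric(dt$PHENOTYPE))
  ph[!is.na(ph) & ph == -9] <- NA
  if (any(!is.na(ph))) {
    if (anyNA(ph)) stopf("PHENOTYPE column is partially missing")
    phe <- data.frame(individual_id = ids, y = ph, stringsAsFactors = FALSE)
  }
  msgf(verbose, "read_plink_raw: %d individuals, %d SNPs from %s",
       nrow(G), ncol(G), path)
  list(genotypes = gm, phenotype = phe)
}

# Column-mean imputation of missing additive codes, rounded to the nearest
# code (half away from zero, so a column mean of exactly 0.5 becomes 1).
impute_column_mean <- function(G) {
  for (j in which(colSums(is.na(G)) > 0)) {
    obs <- G[!is.na(G[, j]), j]
    if (length(obs) == 0) stopf("column %d is entirely missing", j)
    fill <- round_half_away(mean(obs))
    fill <- min(max(fill, 0), 2)
    G[is.na(G[, j]), j] <- fill
  }
  G
}

#' Write a PLINK RAW (--recode A) file
#'
#' Inverse of [read_plink_raw()]; `NA` genotypes are written as `NA`, a
#' missing phenotype as `-9`.
#'
#' @param G A [genotype_matrix].
#' @param path Output path.
#' @param phenotype Optional phenotype data frame (`individual_id`, `y`).
#' @param verbose Log record counts.
#' @return `path`, invisibly.
#' @export
write_plink_raw <- function(G, path, phenotype = NULL, verbose = FALSE) {
  ph <- rep(-9, nrow(G$values))
  if (!is.null(phenotype)) {
    ph <- phenotype$y[match(G$individual_ids, phenotype$individual_id)]
    if (anyNA(ph)) stopf("phenotype does not cover all individuals")
  }
  df <- data.frame(FID = G$individual_ids, IID = G$individual_ids,
                   PAT = 0L, MAT = 0L, SEX = 0L, PHENOTYPE = ph,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(G$values))
  names(df) <- c(plink_fixed_cols, G$snp_ids)
  data.table::fwrite(df, path, sep = " ", na = "NA", quote = FALSE)
  msgf(verbose, "write_plink_raw: wrote %d individuals, %d SNPs to %s",
       nrow(G$values), ncol(G$values), path)
  invisible(path)
}

#' Read / write a phenotype CSV
#'
#' Two-column CSV with header `individual_id,value`.
#'
#' @param path File path.
#' @param verbose Log record counts.
#' @return Data frame with columns `individual_id`, `y`.
#' @export
read_phenotype_csv <- function(path, verbose = FALSE) {
  df <- data.table::fread(path, data.table = FALSE, showProgress = FALSE)
  if (ncol(df) < 2L) stopf("phenotype CSV needs columns individual_id,value")
  out <- data.frame(individual_id = as.character(df[[1]]),
                    y = as.numeric(df[[2]]), stringsAsFactors = FALSE)
  if (anyNA(out$y)) stopf("missing phenotype values in %s", path)
  msgf(verbose, "read_phenotype_csv: %d records from %s", nrow(out), path)
  out
}

#' @rdname read_phenotype_csv
#' @param phenotype Data frame with columns `individual_id`, `y`.
#' @export
write_phenotype_csv <- function(phenotype, path, verbose = FALSE) {
  data.table::fwrite(
    data.frame(individual_id = phenotype$individual_id, value = phenotype$y),
    path)
  msgf(verbose, "write_phenotype_csv: wrote %d records to %s",
       nrow(phenotype), path)
  invisible(path)
}

#' Minor-allele-frequency filter
#'
#' Removes SNPs whose minor allele frequency, computed from the additive
#' codes as `f = sum(codes) / (2n)` and `MAF = min(f, 1 - f)`, is strictly
#' below `threshold`. SNPs sitting exactly at the threshold are retained.
#'
#' @param G A [genotype_matrix] without missing entries.
#' @param threshold MAF cutoff in `[0, 0.5)`; the reference analysis uses 0.01.
#' @param verbose Log how many SNPs were removed.
#' @return List with `genotypes` (filtered [genotype_matrix]) and `kept`
#'   (integer vector of original column indices of the retained SNPs).
#' @export
maf_filter <- function(G, threshold = 0.01, verbose = FALSE) {
  if (threshold < 0 || threshold >= 0.5) stopf("threshold must be in [0, 0.5)")
  if (anyNA(G$values)) stopf("maf_filter requires complete genotypes; impute first")
  f <- colSums(G$values) / (2 * nrow(G$values))
  maf <- pmin(f, 1 - f)
  kept <- unname(which(maf >= threshold))
  if (length(kept) == 0) stopf("all %d SNPs fall below MAF threshold %g", ncol(G$values), threshold)
  msgf(verbose, "maf_filter: removed %d of %d SNPs at MAF < %g",
       ncol(G$values) - length(kept), ncol(G$values), threshold)
  out <- genotype_matrix(G$values[, kept, drop = FALSE],
                         snp_ids = G$snp_ids[kept],
                         chromosome = G$chromosome[kept],
                         individual_ids = G$individual_ids)
  list(genotypes = out, kept = kept)
}

#' Standardize genotypes and center the phenotype
#'
#' Scales every SNP column to mean zero and unit (population) variance and
#' mean-centers the phenotype. The statistics are computed over `stat_rows`
#' and applied to all rows; by default all individuals contribute, matching
#' the reference workflow that standardizes before splitting (a train-only
#' `stat_rows` gives the leakage-free variant).
#'
#' @param G A [genotype_matrix] without missing entries.
#' @param phenotype Data frame (`individual_id`, `y`) aligned to `G` by id.
#' @param stat_rows Integer indices of the rows the statistics come from
#'   (default: all rows).
#' @return Object of class `standardized_dataset`: `Xs`, `ys`, `col_means`,
#'   `col_sds`, `y_mean`, `stat_rows`, plus the label vectors.
#' @export
standardize <- function(G, phenotype, stat_rows = NULL) {
  X <- G$values
  if (anyNA(X)) stopf("standardize requires complete genotypes")
  n <- nrow(X)
  stat_rows <- stat_rows %||% seq_len(n)
  ord <- match(G$individual_ids, phenotype$individual_id)
  if (anyNA(ord)) stopf("phenotype ids do not cover all genotyped individuals")
  y <- phenotype$y[ord]
  Xr <- X[stat_rows, , drop = FALSE]
  m <- colMeans(Xr)
  s <- sqrt(colMeans(Xr^2) - m^2)  # population sd
  const <- which(s < 1e-12)
  if (length(const) > 0) {
    stopf("SNP '%s' is constant over the standardization rows", G$snp_ids[const[1]])
  }
  y_mean <- mean(y[stat_rows])
  structure(
    list(Xs = sweep(sweep(X, 2, m), 2, s, "/"),
         ys = y - y_mean,
         col_means = m, col_sds = s, y_mean = y_mean, stat_rows = stat_rows,
         snp_ids = G$snp_ids, chromosome = G$chromosome,
         individual_ids = G$individual_ids),
    class = "standardized_dataset"
  )
}

#' Invert a standardization
#'
#' Recovers the original genotype codes and phenotype from a
#' `standardized_dataset` using its stored statistics.
#'
#' @param ds A `standardized_dataset` from [standardize()].
#' @return List with `X` (original-scale matrix) and `y`.
#' @export
unstandardize <- function(ds) {
  list(X = sweep(sweep(ds$Xs, 2, ds$col_sds, "*"), 2, ds$col_means, "+"),
       y = ds$ys + ds$y_mean)
}

#' @export
print.standardized_dataset <- function(x, ...) {
  cat(sprintf("standardized_dataset: %d individuals x %d SNPs (statistics from %d rows)\n",
              nrow(x$Xs), ncol(x$Xs), length(x$stat_rows)))
  invisible(x)
}

#' Build train/validation/test splits or cross-validation folds
#'
#' Holdout mode supports the positional split of the reference analysis
#' (first block of individuals trains, last block tests; e.g. 1..2326 train,
#' 2327..3226 test for the QTLMAS2010-style data), optionally carving a
#' validation block off the end of the training block. K-fold mode produces
#' contiguous or seeded-shuffled folds whose test sets partition `1..n`.
#'
#' @param n Number of individuals.
#' @param mode `"holdout"` or `"kfold"`.
#' @param boundary Holdout: last training index (train = `1..boundary`).
#' @param val_n Holdout: validation block size taken from the end of the
#'   training block (0 = none; validation is then typically the test block,
#'   mirroring the reference workflow).
#' @param k K-fold: number of folds.
#' @param shuffle K-fold: permute individuals (seeded) before folding.
#' @param seed RNG seed for shuffling.
#' @return Object of class `split_plan` with 1-based `train_idx`, `val_idx`,
#'   `test_idx` and, in kfold mode, `folds` (list of `train_idx`/`test_idx`).
#' @export
make_splits <- function(n, mode = c("holdout", "kfold"), boundary = NULL,
                        val_n = 0L, k = NULL, shuffle = FALSE, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "holdout") {
    if (is.null(boundary)) stopf("holdout mode needs `boundary`")
    if (boundary < 1 || boundary >= n) stopf("boundary must be in [1, n-1]")
    if (val_n < 0 || val_n >= boundary) stopf("val_n must be in [0, boundary)")
    train <- seq_len(boundary - val_n)
    val <- if (val_n > 0) seq.int(boundary - val_n + 1L, boundary) else integer(0)
    test <- seq.int(boundary + 1L, n)
    plan <- list(mode = mode, n = n, train_idx = train, val_idx = val,
                 test_idx = test, folds = NULL)
  } else {
    if (is.null(k)) stopf("kfold mode needs `k`")
    if (k > n) stopf("k = %d exceeds n = %d", k, n)
    if (k < 2) stopf("k must be >= 2")
    idx <- seq_len(n)
    if (shuffle) {
      set.seed(seed)
      idx <- sample(idx)
    }
    grp <- rep(seq_len(k), length.out = 0)
    sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
    grp <- rep(seq_len(k), times = sizes)
    folds <- lapply(seq_len(k), function(f) {
      test <- sort(idx[grp == f])
      list(train_idx = sort(idx[grp != f]), test_idx = test)
    })
    plan <- list(mode = mode, n = n, train_idx = folds[[1]]$train_idx,
                 val_idx = integer(0), test_idx = folds[[1]]$test_idx,
                 folds = folds)
  }
  structure(plan, class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  if (is.null(x$folds)) {
    cat(sprintf("split_plan (holdout): %d train / %d val / %d test of n = %d\n",
                length(x$train_idx), length(x$val_idx), length(x$test_idx), x$n))
  } else {
    cat(sprintf("split_plan (%d-fold): fold test sizes %s over n = %d\n",
                length(x$folds),
                paste(vapply(x$folds, function(f) length(f$test_idx), 1L),
                      collapse = "/"), x$n))
  }
  invisible(x)
}

#' Serialize a split plan to a plain-text index-list file
#'
#' One line per set: `train: 1 2 ...`, `val: ...`, `test: ...`; in kfold
#' mode one `foldK_test:` line per fold.
#'
#' @param plan A `split_plan`.
#' @param path Output path.
#' @export
write_split_plan <- function(plan, path) {
  lines <- c(
    sprintf("n: %d", plan$n),
    sprintf("mode: %s", plan$mode),
    sprintf("train: %s", paste(plan$train_idx, collapse = " ")),
    sprintf("val: %s", paste(plan$val_idx, collapse = " ")),
    sprintf("test: %s", paste(plan$test_idx, collapse = " "))
  )
  if (!is.null(plan$folds)) {
    lines <- c(lines, vapply(seq_along(plan$folds), function(f) {
      sprintf("fold%d_test: %s", f,
              paste(plan$folds[[f]]$test_idx, collapse = " "))
    }, ""))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  lines <- readLines(path)
  get <- function(key) {
    ln <- grep(paste0("^", key, ":"), lines, value = TRUE)
    if (length(ln) == 0) return(NULL)
    val <- sub(paste0("^", key, ":\\s*"), "", ln[1])
    if (val == "") integer(0) else as.integer(strsplit(val, "\\s+")[[1]])
  }
  n <- get("n")
  mode <- sub("^mode:\\s*", "", grep("^mode:", lines, value = TRUE)[1])
  folds <- NULL
  fold_lines <- grep("^fold[0-9]+_test:", lines, value = TRUE)
  if (length(fold_lines) > 0) {
    all_idx <- seq_len(n)
    folds <- lapply(seq_along(fold_lines), function(f) {
      test <- get(sprintf("fold%d_test", f))
      list(train_idx = setdiff(all_idx, test), test_idx = test)
    })
  }
  structure(list(mode = mode, n = n, train_idx = get("train"),
                 val_idx = get("val"), test_idx = get("test"), folds = folds),
            class = "split_plan")
}
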