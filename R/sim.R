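#' Simulation configuration
#'
#' Describes the synthetic genotype/phenotype scenario: population size,
#' marker panel, linkage-disequilibrium strength, allele-frequency range and
#' the residual noise (directly, or via a target heritability).
#'
#' Haplotypes are generated chromosome by chromosome as first-order Markov
#' chains over \{0, 1\}: each locus copies its left neighbour's allele with
#' probability `ld_decay`, otherwise draws a fresh allele at that locus'
#' sampled frequency. The genotype is the sum of two independent haplotypes,
#' so every locus is in Hardy-Weinberg proportions while adjacent loci are
#' correlated — the locality a 1-D convolution exploits.
#'
#' @param n Number of individuals.
#' @param p Total number of SNPs.
#' @param chrom_sizes Integer vector of per-chromosome SNP counts
#'   (must sum to `p`); default splits `p` evenly over `n_chrom` chromosomes.
#' @param n_chrom Number of chromosomes when `chrom_sizes` is not given.
#' @param ld_decay Copy probability in `[0, 1)` for adjacent markers
#'   (default 0.95, giving realistic adjacent-marker correlation).
#' @param maf_range Allele-frequency sampling interval within `(0, 0.5]`.
#' @param h2 Target narrow+broad-sense heritability in `(0, 1]`; the residual
#'   standard deviation is set so `var(g) / (var(g) + sd^2) = h2`.
#' @param residual_sd Residual standard deviation (overrides `h2` when set).
#' @param monomorphic_frac Fraction of columns forced monomorphic (all zero),
#'   exercising the MAF-filter path the way real panels do.
#' @param monomorphic_exclude Column indices never forced monomorphic
#'   (typically the causal loci).
#' @param seed RNG seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n, p, chrom_sizes = NULL, n_chrom = 5L,
                       ld_decay = 0.95, maf_range = c(0.05, 0.5),
                       h2 = NULL, residual_sd = NULL,
                       monomorphic_frac = 0, monomorphic_exclude = integer(0),
                       seed = 1L) {
  if (is.null(chrom_sizes)) {
    chrom_sizes <- rep(p %/% n_chrom, n_chrom)
    chrom_sizes[seq_len(p %% n_chrom)] <- chrom_sizes[seq_len(p %% n_chrom)] + 1L
  }
  if (sum(chrom_sizes) != p) stopf("chrom_sizes must sum to p = %d", p)
  if (ld_decay < 0 || ld_decay >= 1) stopf("ld_decay must be in [0, 1)")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stopf("maf_range must lie within (0, 0.5]")
  }
  if (is.null(h2) && is.null(residual_sd)) h2 <- 0.5
  if (!is.null(h2) && (h2 <= 0 || h2 > 1)) stopf("h2 must be in (0, 1]")
  if (!is.null(residual_sd) && residual_sd < 0) stopf("residual_sd must be >= 0")
  structure(
    list(n = as.integer(n), p = as.integer(p),
         chrom_sizes = as.integer(chrom_sizes), ld_decay = ld_decay,
         maf_range = maf_range, h2 = h2, residual_sd = residual_sd,
         monomorphic_frac = monomorphic_frac,
         monomorphic_exclude = as.integer(monomorphic_exclude),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' QTL architecture
#'
#' A list of causal loci, each with a per-genotype effect triplet
#' `(e0, e1, e2)` — the contribution of genotype codes 0, 1, 2 — plus
#' optional epistatic pairs with a full 3 x 3 interaction table. An additive
#' locus with allele-substitution effect `a` has triplet `(0, a, 2a)`;
#' dominance-class loci deliberately break `e1 = (e0 + e2) / 2`.
#'
#' @param loci Data frame with columns `snp_index` (1-based), `kind`
#'   (`additive`, `dominance`, `overdominance`, `underdominance`), and
#'   `e0`, `e1`, `e2`.
#' @param epistatic_pairs List of entries `list(snp_i, snp_j, table)` where
#'   `table` is a 3 x 3 matrix indexed by genotype code + 1 at each locus.
#' @param p Marker panel size the indices refer to (for validation).
#' @return Object of class `qtl_architecture`.
#' @export
qtl_architecture <- function(loci, epistatic_pairs = list(), p = NULL) {
  stopifnot(is.data.frame(loci),
            all(c("snp_index", "kind", "e0", "e1", "e2") %in% names(loci)))
  if (anyDuplicated(loci$snp_index)) stopf("QTL snp_index values must be unique")
  if (!is.null(p) && any(loci$snp_index < 1 | loci$snp_index > p)) {
    stopf("QTL snp_index out of [1, p]")
  }
  add <- loci$kind == "additive"
  midpoint_gap <- abs(loci$e1 - (loci$e0 + loci$e2) / 2)
  if (any(midpoint_gap[add] > 1e-8)) {
    stopf("additive loci must satisfy e1 = (e0 + e2) / 2")
  }
  for (ep in epistatic_pairs) {
    stopifnot(length(ep) >= 3, is.matrix(ep[[3]]), all(dim(ep[[3]]) == c(3, 3)))
  }
  structure(list(loci = loci, epistatic_pairs = epistatic_pairs, p = p),
            class = "qtl_architecture")
}

#' @export
print.qtl_architecture <- function(x, ...) {
  cat(sprintf("qtl_architecture: %d loci (%s), %d epistatic pair(s)\n",
              nrow(x$loci),
              paste(sprintf("%d %s", table(x$loci$kind),
                            names(table(x$loci$kind))), collapse = ", "),
              length(x$epistatic_pairs)))
  invisible(x)
}

#' Simulate genotypes with chromosome-local LD
#'
#' Generates the Markov-haplotype genotypes described in [sim_config()];
#' deterministic under the config seed.
#'
#' @param cfg A `sim_config`.
#' @return A [genotype_matrix] with chromosome labels.
#' @export
simulate_genotypes <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n
  freqs <- runif(cfg$p, cfg$maf_range[1], cfg$maf_range[2])
  mono <- integer(0)
  if (cfg$monomorphic_frac > 0) {
    n_mono <- floor(cfg$monomorphic_frac * cfg$p)
    pool <- setdiff(seq_len(cfg$p), cfg$monomorphic_exclude)
    mono <- sort(sample(pool, min(n_mono, length(pool))))
    freqs[mono] <- 0
  }
  G <- matrix(0, n, cfg$p)
  chrom <- rep(seq_along(cfg$chrom_sizes), times = cfg$chrom_sizes)
  offset <- 0L
  for (pc in cfg$chrom_sizes) {
    for (hap in 1:2) {
      h <- matrix(0L, n, pc)
      h[, 1] <- rbinom(n, 1L, freqs[offset + 1L])
      if (pc > 1) {
        for (j in 2:pc) {
          keep <- runif(n) < cfg$ld_decay
          fresh <- rbinom(n, 1L, freqs[offset + j])
          h[, j] <- ifelse(keep, h[, j - 1L], fresh)
        }
      }
      G[, (offset + 1L):(offset + pc)] <-
        G[, (offset + 1L):(offset + pc)] + h
    }
    offset <- offset + pc
  }
  if (length(mono) > 0) G[, mono] <- 0  # forced monomorphic columns
  gm <- genotype_matrix(G, snp_ids = sprintf("snp%05d", seq_len(cfg$p)),
                        chromosome = chrom,
                        individual_ids = as.character(seq_len(n)))
  attr(gm, "allele_freqs") <- freqs
  gm
}

#' True genetic values under a QTL architecture
#'
#' Sums, per individual, the per-genotype effect triplets over all causal
#' loci and the 3 x 3 interaction tables over all epistatic pairs.
#'
#' @param G A [genotype_matrix].
#' @param arch A [qtl_architecture].
#' @return Numeric vector of length n (phenotype units).
#' @export
genetic_values <- function(G, arch) {
  X <- G$values
  p <- ncol(X)
  if (any(arch$loci$snp_index > p)) stopf("architecture index exceeds p = %d", p)
  g <- numeric(nrow(X))
  for (i in seq_len(nrow(arch$loci))) {
    idx <- arch$loci$snp_index[i]
    geno <- X[, idx]
    if (anyNA(geno)) stopf("missing genotype at causal SNP index %d", idx)
    eff <- c(arch$loci$e0[i], arch$loci$e1[i], arch$loci$e2[i])
    g <- g + eff[geno + 1]
  }
  for (ep in arch$epistatic_pairs) {
    gi <- X[, ep[[1]]]
    gj <- X[, ep[[2]]]
    if (anyNA(gi) || anyNA(gj)) {
      stopf("missing genotype at epistatic pair (%d, %d)", ep[[1]], ep[[2]])
    }
    g <- g + ep[[3]][cbind(gi + 1, gj + 1)]
  }
  g
}

#' Simulate phenotypes from genetic values
#'
#' Adds Gaussian residual noise and mean-centers the result. When the config
#' targets a heritability, the residual standard deviation is set from the
#' realized genetic variance so that `var(g) / (var(g) + sd^2) = h2`.
#'
#' @param gvals Genetic values from [genetic_values()].
#' @param cfg A `sim_config` (uses `h2` or `residual_sd`, and the seed
#'   offset by one so genotype and noise draws are independent).
#' @param individual_ids Optional ids for the returned table.
#' @return Phenotype data frame (`individual_id`, `y`), mean-centered, with
#'   attributes `residual_sd` and `h2_realized`.
#' @export
simulate_phenotypes <- function(gvals, cfg, individual_ids = NULL) {
  vg <- var(gvals)
  if (!is.null(cfg$residual_sd)) {
    sd_e <- cfg$residual_sd
  } else {
    if (vg <= 0) stopf("zero genetic variance: cannot target heritability")
    sd_e <- sqrt(vg * (1 - cfg$h2) / cfg$h2)
  }
  set.seed(derive_seed(cfg$seed, 1L))
  e <- rnorm(length(gvals), 0, sd_e)
  y <- gvals + e
  y <- y - mean(y)
  out <- data.frame(
    individual_id = individual_ids %||% as.character(seq_along(y)),
    y = y, stringsAsFactors = FALSE)
  attr(out, "residual_sd") <- sd_e
  attr(out, "h2_realized") <- vg / (vg + sd_e^2)
  out
}

# Reference locus positions on the 9,768-SNP QTLMAS2010-style panel.
qtlmas_ref <- list(
  p = 9768L, n = 3226L,
  additive = c(4354L, 5327L), additive_eff = c(-3, 3),
  epistatic = 931L,
  dominance = 9212L, overdominance = 9404L, underdominance = 9602L
)

#' QTLMAS2010-style scenario preset
#'
#' Returns the paper-shaped simulation scenario: 9,768 biallelic SNPs on
#' five chromosomes and 3,226 individuals by default, with two major
#' additive genes of effects -3 and +3 at SNP indices 4,354 and 5,327, an
#' epistatic locus at SNP 931 (a dominant additive part plus a pure
#' product-interaction pair with zero marginal means), dominance /
#' over-dominance / under-dominance loci at SNPs 9,212 / 9,404 / 9,602 with
#' per-genotype triplets (0, 5.00, 5.01), (-0.01, 5.00, 0.01) and
#' (-0.01, -5.00, 0.01), and 28 random small additive QTLs with effects
#' drawn from a standard normal truncated to `|effect| < 2`. About 2.5% of
#' columns are monomorphic so the MAF-filter path is exercised.
#'
#' When `n` or `p` differ from the reference panel the causal positions are
#' scaled proportionally, giving a reduced-scale scenario with the same
#' genetic architecture.
#'
#' @param n Number of individuals (default 3,226).
#' @param p Number of SNPs (default 9,768).
#' @param h2 Target heritability (default 0.5; the reference trait's
#'   residual variance is not published, so this is a scenario choice,
#'   not a reproduction).
#' @param ld_decay Adjacent-marker copy probability.
#' @param n_random Number of random small additive QTLs.
#' @param seed Seed for genotypes, random QTL placement and noise.
#' @return List with `config` ([sim_config]) and `architecture`
#'   ([qtl_architecture]).
#' @export
qtlmas_preset <- function(n = qtlmas_ref$n, p = qtlmas_ref$p, h2 = 0.5,
                          ld_decay = 0.95, n_random = 28L, seed = 1L) {
  scale_idx <- function(i) pmax(1L, pmin(p, as.integer(round(i / qtlmas_ref$p * p))))
  epi <- scale_idx(qtlmas_ref$epistatic)
  fixed <- data.frame(
    snp_index = c(scale_idx(qtlmas_ref$additive), epi,
                  scale_idx(qtlmas_ref$dominance),
                  scale_idx(qtlmas_ref$overdominance),
                  scale_idx(qtlmas_ref$underdominance)),
    kind = c("additive", "additive", "additive",
             "dominance", "overdominance", "underdominance"),
    e0 = c(0, 0, 0, 0, -0.01, -0.01),
    e1 = c(qtlmas_ref$additive_eff, 2, 5.00, 5.00, -5.00),
    e2 = c(2 * qtlmas_ref$additive_eff, 4, 5.01, 0.01, 0.01),
    stringsAsFactors = FALSE
  )
  # Random small additive QTLs, placed away from the fixed loci; effects
  # from a standard normal truncated to |effect| < 2.
  set.seed(derive_seed(seed, 2L))
  avoid <- fixed$snp_index
  pool <- setdiff(seq_len(p), outer(avoid, -10:10, "+"))
  pos <- sort(sample(pool, n_random))
  eff <- numeric(n_random)
  for (i in seq_len(n_random)) {
    repeat {
      a <- rnorm(1)
      if (abs(a) < 2) break
    }
    eff[i] <- a
  }
  random <- data.frame(snp_index = pos, kind = "additive",
                       e0 = 0, e1 = eff, e2 = 2 * eff,
                       stringsAsFactors = FALSE)
  loci <- rbind(fixed, random)
  loci <- loci[order(loci$snp_index), ]
  rownames(loci) <- NULL
  # Pure product interaction with zero marginal means at allele freq 1/2:
  # e_int * (g_i - 1) * (g_j - 1), partnered a short distance downstream.
  partner <- min(p, epi + max(2L, as.integer(round(40 / qtlmas_ref$p * p))))
  tab <- 2 * outer(c(-1, 0, 1), c(-1, 0, 1))
  arch <- qtl_architecture(loci, epistatic_pairs = list(list(epi, partner, tab)),
                           p = p)
  cfg <- sim_config(n = n, p = p, n_chrom = 5L, ld_decay = ld_decay,
                    h2 = h2, monomorphic_frac = 0.025,
                    monomorphic_exclude = c(loci$snp_index, partner),
                    seed = seed)
  list(config = cfg, architecture = arch)
}

#' Simulate a complete QTLMAS2010-style dataset
#'
#' Convenience wrapper: build the preset, simulate genotypes, compute the
#' genetic values and draw phenotypes.
#'
#' @inheritParams qtlmas_preset
#' @return List with `genotypes`, `phenotype`, `gvals`, `architecture`,
#'   `config`.
#' @export
simulate_qtlmas <- function(n = qtlmas_ref$n, p = qtlmas_ref$p, h2 = 0.5,
                            ld_decay = 0.95, seed = 1L) {
  preset <- qtlmas_preset(n = n, p = p, h2 = h2, ld_decay = ld_decay,
                          seed = seed)
  G <- simulate_genotypes(preset$config)
  gv <- genetic_values(G, preset$architecture)
  ph <- simulate_phenotypes(gv, preset$config, individual_ids = G$individual_ids)
  list(genotypes = G, phenotype = ph, gvals = gv,
       architecture = preset$architecture, config = preset$config)
}

#' Serialize / read a QTL architecture as a plain-text config
#'
#' One `locus` line per causal SNP (`index kind e0 e1 e2`) and one
#' `epistasis` line per pair (`i j` followed by the 9 table entries in
#' row-major order).
#'
#' @param arch A [qtl_architecture].
#' @param path File path.
#' @export
write_architecture <- function(arch, path) {
  lines <- c(sprintf("p: %d", arch$p %||% NA_integer_),
             sprintf("locus: %d %s %.10g %.10g %.10g",
                     arch$loci$snp_index, arch$loci$kind,
                     arch$loci$e0, arch$loci$e1, arch$loci$e2))
  for (ep in arch$epistatic_pairs) {
    lines <- c(lines, sprintf("epistasis: %d %d %s", ep[[1]], ep[[2]],
                              paste(format(t(ep[[3]]), digits = 10),
                                    collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_architecture
#' @export
read_architecture <- function(path) {
  lines <- readLines(path)
  p <- as.integer(sub("^p:\\s*", "", grep("^p:", lines, value = TRUE)[1]))
  loc <- grep("^locus:", lines, value = TRUE)
  parts <- strsplit(sub("^locus:\\s*", "", loc), "\\s+")
  loci <- data.frame(
    snp_index = as.integer(vapply(parts, `[`, "", 1)),
    kind = vapply(parts, `[`, "", 2),
    e0 = as.numeric(vapply(parts, `[`, "", 3)),
    e1 = as.numeric(vapply(parts, `[`, "", 4)),
    e2 = as.numeric(vapply(parts, `[`, "", 5)),
    stringsAsFactors = FALSE)
  eps <- lapply(grep("^epistasis:", lines, value = TRUE), function(ln) {
    v <- as.numeric(strsplit(sub("^epistasis:\\s*", "", ln), "\\s+")[[1]])
    list(as.integer(v[1]), as.integer(v[2]),
         matrix(v[3:11], 3, 3, byrow = TRUE))
  })
  qtl_architecture(loci, epistatic_pairs = eps,
                   p = if (is.na(p)) NULL else p)
}
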