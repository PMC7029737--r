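test_that("Markov haplotypes give the requested adjacent-marker LD", {
  n <- 2000
  cfg0 <- sim_config(n = n, p = 60, n_chrom = 1, ld_decay = 0,
                     maf_range = c(0.2, 0.5), seed = 11)
  G0 <- simulate_genotypes(cfg0)$values
  r0 <- vapply(seq_len(ncol(G0) - 1),
               function(j) cor(G0[, j], G0[, j + 1]), numeric(1))
  expect_lt(abs(mean(r0)), 0.05)

  cfg9 <- sim_config(n = n, p = 60, n_chrom = 1, ld_decay = 0.99,
                     maf_range = c(0.2, 0.5), seed = 11)
  G9 <- simulate_genotypes(cfg9)$values
  r9 <- vapply(seq_len(ncol(G9) - 1),
               function(j) cor(G9[, j], G9[, j + 1]), numeric(1))
  expect_gt(mean(r9), 0.8)

  expect_identical(simulate_genotypes(cfg9)$values, G9)
})

test_that("per-locus genotype frequencies follow Hardy-Weinberg", {
  cfg <- sim_config(n = 2000, p = 100, n_chrom = 2, ld_decay = 0.5,
                    maf_range = c(0.1, 0.5), seed = 5)
  G <- simulate_genotypes(cfg)$values
  pvals <- apply(G, 2, function(g) {
    f <- mean(g) / 2
    expd <- 2000 * c((1 - f)^2, 2 * f * (1 - f), f^2)
    obs <- tabulate(g + 1, 3)
    suppressWarnings(stats::chisq.test(obs, p = expd / sum(expd))$p.value)
  })
  expect_gte(mean(pvals > 0.001), 0.95)
})

test_that("genetic values sum per-genotype triplets and epistatic tables", {
  G <- genotype_matrix(cbind(c(0, 1, 2), c(2, 0, 1)))
  # dominance triplet from the simulated-data design
  arch <- qtl_architecture(data.frame(snp_index = 1, kind = "dominance",
                                      e0 = 0, e1 = 5.00, e2 = 5.01))
  expect_equal(genetic_values(G, arch), c(0, 5.00, 5.01))

  arch_u <- qtl_architecture(data.frame(snp_index = 1, kind = "underdominance",
                                        e0 = -0.01, e1 = -5.00, e2 = 0.01))
  expect_equal(genetic_values(G, arch_u)[2], -5.00)

  empty <- qtl_architecture(data.frame(snp_index = integer(0),
                                       kind = character(0), e0 = numeric(0),
                                       e1 = numeric(0), e2 = numeric(0)))
  expect_equal(genetic_values(G, empty), c(0, 0, 0))

  tab <- outer(c(-1, 0, 1), c(-1, 0, 1))
  arch_e <- qtl_architecture(data.frame(snp_index = integer(0),
                                        kind = character(0), e0 = numeric(0),
                                        e1 = numeric(0), e2 = numeric(0)),
                             epistatic_pairs = list(list(1L, 2L, tab)))
  # individuals: (g1,g2) = (0,2), (1,0), (2,1) -> (-1)(1), 0, 0
  expect_equal(genetic_values(G, arch_e), c(-1, 0, 0))

  Gna <- genotype_matrix(matrix(c(NA, 1), 2, 1))
  expect_error(genetic_values(Gna, arch), "missing genotype")

  # additive loci must sit on the homozygote midpoint
  expect_error(qtl_architecture(data.frame(snp_index = 1, kind = "additive",
                                           e0 = 0, e1 = 1, e2 = 5)),
               "midpoint|additive")
})

test_that("phenotype simulation hits the target heritability", {
  # residual_sd = 0: phenotype is exactly the centered genetic value
  gv <- c(1, 3, 5, 7)
  cfg <- sim_config(n = 4, p = 10, residual_sd = 0, seed = 1)
  ph <- simulate_phenotypes(gv, cfg)
  expect_equal(ph$y, gv - mean(gv))

  # closed form: h2 = Vg / (Vg + Ve)
  set.seed(2)
  gv <- rnorm(2000, sd = 2)
  cfg <- sim_config(n = 2000, p = 10, h2 = 0.5, seed = 1)
  ph <- simulate_phenotypes(gv, cfg)
  expect_equal(attr(ph, "residual_sd"), sqrt(var(gv)), tolerance = 1e-12)

  # empirical heritability over replicates
  h2_hat <- vapply(1:20, function(s) {
    cfgs <- sim_config(n = 2000, p = 10, h2 = 0.4, seed = s)
    y <- simulate_phenotypes(gv, cfgs)$y
    var(gv) / var(y)
  }, numeric(1))
  expect_lt(abs(mean(h2_hat) - 0.4), 0.05)

  cfg0 <- sim_config(n = 4, p = 10, h2 = 0.5, seed = 1)
  expect_error(simulate_phenotypes(rep(1, 4), cfg0), "zero genetic variance")
})

test_that("regression of phenotype on true genetic values has slope one", {
  sim <- simulate_qtlmas(n = 2000, p = 800, h2 = 0.5, seed = 21)
  slope <- coef(lm(sim$phenotype$y ~ sim$gvals))[2]
  expect_lt(abs(slope - 1), 0.05)
})

test_that("the QTLMAS2010-style preset encodes the reference architecture", {
  preset <- qtlmas_preset()
  loci <- preset$architecture$loci
  expect_equal(loci$kind[loci$snp_index == 9404], "overdominance")
  expect_equal(loci$kind[loci$snp_index == 9602], "underdominance")
  expect_equal(loci$kind[loci$snp_index == 9212], "dominance")
  expect_equal(loci$e1[loci$snp_index == 9212], 5.00)
  expect_equal(loci$e2[loci$snp_index == 9212], 5.01)
  maj <- loci[loci$snp_index %in% c(4354, 5327), ]
  expect_equal(sort(maj$e1), c(-3, 3))
  rand <- loci[!loci$snp_index %in% c(4354, 5327, 931, 9212, 9404, 9602), ]
  expect_equal(nrow(rand), 28L)
  expect_true(all(abs(rand$e1) < 2))
  expect_equal(length(preset$architecture$epistatic_pairs), 1L)
  # interaction table has zero marginal means
  tab <- preset$architecture$epistatic_pairs[[1]][[3]]
  expect_equal(rowSums(tab), c(0, 0, 0), ignore_attr = TRUE)

  # reduced-scale preset keeps causal loci polymorphic despite the injected
  # monomorphic columns
  sim <- simulate_qtlmas(n = 300, p = 600, h2 = 0.5, seed = 4)
  mono <- which(apply(sim$genotypes$values, 2, function(g) all(g == g[1])))
  expect_gt(length(mono), 0)
  causal <- sim$architecture$loci$snp_index
  expect_length(intersect(mono, causal), 0)
})

test_that("architecture files round-trip through the text format", {
  preset <- qtlmas_preset(n = 200, p = 400, seed = 6)
  path <- withr::local_tempfile(fileext = ".txt")
  write_architecture(preset$architecture, path)
  back <- read_architecture(path)
  expect_equal(back$loci$snp_index, preset$architecture$loci$snp_index)
  expect_equal(back$loci$e1, preset$architecture$loci$e1, tolerance = 1e-9)
  expect_equal(back$epistatic_pairs[[1]][[3]],
               preset$architecture$epistatic_pairs[[1]][[3]],
               tolerance = 1e-9)
})
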