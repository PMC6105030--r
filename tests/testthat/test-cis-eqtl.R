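# cis-eQTL mapping: LD pruning, covariate construction, per-SNP OLS,
# BH FDR and eSNP/eGene counting.

test_that("LD pruning keeps independent SNPs and drops duplicates", {
  set.seed(1)
  n <- 200
  dos <- matrix(rbinom(n * 6, 2, 0.4), n, 6)
  geno <- toy_genotypes(dos)
  expect_identical(ld_prune(geno, window = 50, r2_threshold = 0.3),
                   geno$snps$snp_id)

  dup <- cbind(dos, dos[, 2])
  geno_dup <- toy_genotypes(dup)
  kept <- ld_prune(geno_dup, window = 50, r2_threshold = 0.3)
  expect_identical(kept, paste0("s", 1:6))  # the later duplicate is removed

  expect_error(ld_prune(geno, window = 1), "window")
})

test_that("LD pruning matches a brute-force re-implementation", {
  set.seed(2)
  for (i in 1:15) {
    n <- 80
    base <- matrix(rbinom(n * 5, 2, 0.5), n, 5)
    # induce correlation by copying columns with noise
    base[, 3] <- pmin(pmax(base[, 1] + rbinom(n, 1, 0.2) - rbinom(n, 1, 0.2), 0), 2)
    geno <- toy_genotypes(base)
    kept <- ld_prune(geno, window = 3, r2_threshold = 0.2)
    oracle <- ld_prune_oracle(base, window = 3, r2_threshold = 0.2)
    expect_identical(kept, geno$snps$snp_id[oracle])
  }
})

test_that("monomorphic SNPs are always kept by pruning", {
  set.seed(3)
  dos <- cbind(matrix(rbinom(100 * 3, 2, 0.4), 100, 3), 0)
  kept <- ld_prune(toy_genotypes(dos), window = 10, r2_threshold = 0.3)
  expect_true("s4" %in% kept)
})

test_that("genotype PCs are orthonormal and separate diverged populations", {
  pops <- list(population_spec("P1", 80, 0.3), population_spec("P2", 80, 0.3))
  snps <- draw_population_frequencies(300, pops, seed = 4)
  g1 <- simulate_genotypes(snps, pops[[1]], seed = 5)
  g2 <- simulate_genotypes(snps, pops[[2]], seed = 6)
  pooled <- genotype_matrix(rbind(g1$dosages, g2$dosages), snps,
                            c(g1$samples, g2$samples))
  pcs <- genotype_pcs(pooled, 3)
  M <- as.matrix(pcs[-1])
  expect_equal(unname(crossprod(M)), diag(3), tolerance = 1e-8)
  # PC1 separates the two cohorts with zero overlap
  s1 <- M[seq_len(80), 1]
  s2 <- M[80 + seq_len(80), 1]
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))

  empty <- genotype_pcs(pooled, 0)
  expect_identical(ncol(empty), 1L)  # just sample ids
  expect_error(genotype_pcs(toy_genotypes(matrix(rbinom(40, 2, .5), 10, 4)), 10),
               "n_pcs")
})

test_that("hidden expression factors recover a planted batch and respect protection", {
  set.seed(7)
  n <- 100
  vals <- matrix(rnorm(n * 30), n, 30)
  batch <- rep(c(0, 1), each = n / 2)
  vals <- vals + outer(batch, rnorm(30, 0, 2))
  expr <- toy_expression(vals, samples = paste0("S", 1:n))
  fac <- hidden_expression_factors(expr, 2)
  expect_gt(abs(cor(fac$factor1, batch)), 0.9)

  protect <- covariate_set(expr$samples, batchvar = batch + rnorm(n, 0, 1e-8))
  fac_p <- hidden_expression_factors(expr, 2, protect = protect)
  expect_lt(abs(cor(fac_p$factor1, protect$batchvar)), 1e-6)

  expect_identical(ncol(hidden_expression_factors(expr, 0)), 1L)
  expect_error(hidden_expression_factors(expr, n), "n_factors")
})

test_that("BH adjustment matches the hand step-up calculation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  # order invariance
  p <- c(0.4, 0.001, 0.2, 0.02)
  expect_equal(bh_fdr(p)[order(p)], sort(bh_fdr(sort(p))))
})

test_that("cis window is the closed 1 Mb interval around the TSS", {
  snps <- tibble::tibble(
    snp_id = c("in_lo", "in_hi", "out_hi"),
    chromosome = "chr1",
    position = c(1e6, 2e6 + 1e6, 2e6 + 1e6 + 1),
    ref_allele = "A", alt_allele = "G"
  )
  ids <- cis_snp_ids(snps, "chr1", 2e6, 1e6)
  expect_setequal(ids, c("in_lo", "in_hi"))
})

test_that("a planted eQTL is the top association nearly always", {
  hits <- vapply(seq_len(100), function(i) {
    st <- single_gene_study(n = 300, m = 50, h2 = 0.3, seed = 5000 + 7 * i)
    assoc <- map_cis_eqtls(st$expression, st$genotypes)
    assoc$snp_id[which.min(assoc$p_value)] == st$truth$causal_snp_ids
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("null expression yields uniform p-values and almost no eGenes", {
  pop <- population_spec("P1", 300, 0.1)
  sim <- simulate_study(list(pop), n_genes = 40, n_cis_snps = 20,
                        n_causal = 1, h2 = 0, seed = 60)
  assoc <- map_cis_eqtls(sim$expression$P1, sim$genotypes$P1)
  expect_gt(stats::ks.test(assoc$p_value, "punif")$p.value, 0.01)
  counts <- summarize_eqtls(assoc, 0.05, "P1")
  expect_lte(counts$n_egenes, 1L)
  expect_true(all(assoc$fdr >= assoc$p_value - 1e-12))
})

test_that("genotype PCs deflate stratification-driven inflation", {
  pops <- list(population_spec("P1", 120, 0.3), population_spec("P2", 120, 0.3))
  snps <- draw_population_frequencies(400, pops, seed = 70)
  g1 <- simulate_genotypes(snps, pops[[1]], seed = 71)
  g2 <- simulate_genotypes(snps, pops[[2]], seed = 72)
  pooled <- genotype_matrix(rbind(g1$dosages, g2$dosages), snps,
                            c(g1$samples, g2$samples))
  # phenotype = population mean shift + noise, no genetic effect
  set.seed(73)
  y <- rep(c(0, 1), each = 120) + rnorm(240)
  expr <- expression_panel(
    matrix(y, ncol = 1),
    tibble::tibble(gene_id = "g1", chromosome = "chr1",
                   tss = as.integer(median(snps$position))),
    pooled$samples
  )
  a0 <- map_cis_eqtls(expr, pooled, covariates = NULL)
  pcs <- genotype_pcs(pooled, 3)
  a3 <- map_cis_eqtls(expr, pooled, covariates = pcs)
  med0 <- median(a0$t_stat^2)
  med3 <- median(a3$t_stat^2)
  expect_lt(med3, med0)
  expect_lt(abs(med3 - 0.455), abs(med0 - 0.455))
})

test_that("eSNP/eGene counting follows the distinct-unit rules", {
  assoc <- tibble::tibble(
    gene_id = c("g1", "g1", "g1", "g2"),
    snp_id = c("s1", "s2", "s1", "s9"),
    fdr = c(0.01, 0.02, 0.03, 0.9)
  )
  s <- summarize_eqtls(assoc, 0.05)
  expect_identical(s$n_esnps, 2L)
  expect_identical(s$n_egenes, 1L)
  s_none <- summarize_eqtls(assoc, 0.001)
  expect_identical(c(s_none$n_esnps, s_none$n_egenes), c(0L, 0L))
})
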