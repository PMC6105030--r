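# Generator contracts: frequency divergence, genotype sampling, causal
# architectures, heritability calibration and determinism.

test_that("population frequencies follow the divergence model and its limits", {
  pops <- two_pop_specs(n = 50, f = 1e-13)
  snps <- draw_population_frequencies(200, pops, seed = 1)
  # divergence-free limit: population frequencies collapse onto the ancestor
  expect_equal(snps$freq_P1, attr(snps, "ancestral_freq"), tolerance = 1e-6)
  expect_equal(snps$freq_P1, snps$freq_P2, tolerance = 1e-6)

  snps3 <- draw_population_frequencies(3, two_pop_specs(), seed = 2)
  expect_identical(nrow(snps3), 3L)
  expect_true(all(diff(snps3$position) > 0))
  expect_true(all(snps3$ref_allele != snps3$alt_allele))

  expect_error(draw_population_frequencies(5, list(), seed = 1),
               "at least one")
  expect_error(
    draw_population_frequencies(5, two_pop_specs(), c(0.4, 0.4), seed = 1),
    "ancestral_freq_range"
  )
  expect_error(population_spec("A", 300, 0), "ancestry_fst")
  expect_error(population_spec("A", 1, 0.1), "n_samples")
})

test_that("genotype dosages are binomial with the population frequency", {
  pop <- population_spec("P1", 10000, 0.1)
  snps <- tibble::tibble(
    snp_id = c("a", "b", "c"), chromosome = "chr1",
    position = c(1L, 2L, 3L), ref_allele = "A", alt_allele = "G",
    freq_P1 = c(0, 1, 0.5)
  )
  geno <- simulate_genotypes(snps, pop, seed = 3)
  expect_true(all(geno$dosages[, "a"] == 0))
  expect_true(all(geno$dosages[, "b"] == 2))
  expect_lt(abs(mean(geno$dosages[, "c"]) - 1), 0.02)
  expect_true(all(geno$dosages >= 0 & geno$dosages <= 2))
  expect_error(simulate_genotypes(snps, population_spec("Q", 5, 0.1), seed = 1),
               "Q")
})

test_that("causal architectures respect the effect-correlation target", {
  snps <- draw_population_frequencies(20, two_pop_specs(), seed = 4)
  tr1 <- simulate_gene_architecture("g", snps, 3, c(P1 = 0.3, P2 = 0.3),
                                    rho_effects = 1, seed = 5)
  expect_identical(tr1$beta_by_population$P1, tr1$beta_by_population$P2)

  tr_single <- simulate_gene_architecture("g", snps, 1, c(P1 = 0.3, P2 = 0.3),
                                          rho_effects = 0.5, seed = 6)
  expect_length(tr_single$causal_snp_ids, 1L)

  # independent-effects null: paired effects over many genes are uncorrelated
  b <- vapply(seq_len(2000), function(i) {
    tr <- simulate_gene_architecture("g", snps, 1, c(P1 = 0.3, P2 = 0.3),
                                     rho_effects = 0, seed = 100 + i)
    c(tr$beta_by_population$P1, tr$beta_by_population$P2)
  }, numeric(2))
  expect_lt(abs(cor(b[1, ], b[2, ])), 0.03)

  expect_error(
    simulate_gene_architecture("g", snps, 100, c(P1 = 0.3, P2 = 0.3), 0, seed = 1),
    "exceeds"
  )
  # matrix-valued pairwise correlation
  rho_m <- matrix(c(1, 0.9, 0.9, 1), 2, 2)
  tr_m <- simulate_gene_architecture("g", snps, 5, c(P1 = 0.3, P2 = 0.3),
                                     rho_m, seed = 7)
  expect_length(tr_m$beta_by_population$P1, 5L)
})

test_that("expression phenotypes hit the target heritability", {
  pop <- population_spec("P1", 500, 0.1)
  # limits: pure noise and noiseless
  snps <- draw_population_frequencies(10, list(pop), seed = 8)
  geno <- simulate_genotypes(snps, pop, seed = 9)
  tr0 <- simulate_gene_architecture("g", snps, 2, c(P1 = 0), 0, seed = 10)
  y0 <- simulate_expression(geno, tr0, "P1", seed = 11)
  g0 <- drop(geno$dosages[, tr0$causal_snp_ids] %*% tr0$beta_by_population$P1)
  expect_lt(summary(lm(y0 ~ g0))$r.squared, 0.02)

  tr1 <- simulate_gene_architecture("g", snps, 2, c(P1 = 1), 0, seed = 12)
  y1 <- simulate_expression(geno, tr1, "P1", seed = 13)
  g1 <- drop(geno$dosages[, tr1$causal_snp_ids] %*% tr1$beta_by_population$P1)
  expect_gt(abs(cor(y1, g1)), 1 - 1e-12)

  # calibration: mean realized genetic-variance fraction near the target
  frac <- vapply(seq_len(200), function(i) {
    tri <- simulate_gene_architecture("g", snps, 2, c(P1 = 0.4), 0,
                                      seed = 1000 + i)
    yi <- simulate_expression(geno, tri, "P1", seed = 2000 + i)
    gi <- drop(geno$dosages[, tri$causal_snp_ids] %*%
                 tri$beta_by_population$P1)
    a <- sqrt(0.4 / ((1 - 0.4) * var(gi)))
    var(a * gi) / var(yi)
  }, 0)
  expect_lt(abs(mean(frac) - 0.4), 0.02)

  # degenerate genetic variance
  snps_mono <- snps
  snps_mono$freq_P1 <- 0
  geno_mono <- simulate_genotypes(snps_mono, pop, seed = 14)
  expect_error(simulate_expression(geno_mono, tr1, "P1", seed = 15),
               "degenerate genetic variance")
})

test_that("the h2-matched null regenerates panels deterministically", {
  pops <- two_pop_specs(n = 40)
  sim <- simulate_study(pops, n_genes = 4, n_cis_snps = 10, n_causal = NULL,
                        h2 = 0.4, rho_effects = 0.9, seed = 20)
  nulls <- simulate_h2_matched_null(sim$truths, sim$genotypes, 10, seed = 21)
  expect_length(nulls, 10L)
  expect_named(nulls[[1]], c("P1", "P2"))
  expect_identical(dim(nulls[[1]]$P1$values), c(40L, 4L))

  again <- simulate_h2_matched_null(sim$truths, sim$genotypes, 10, seed = 21)
  expect_identical(nulls, again)
  expect_error(simulate_h2_matched_null(sim$truths, sim$genotypes, 0, seed = 1),
               "n_replicates")
})

test_that("whole-study simulation is deterministic under a fixed seed", {
  pops <- two_pop_specs(n = 30)
  s1 <- simulate_study(pops, n_genes = 3, n_cis_snps = 8, seed = 30)
  s2 <- simulate_study(pops, n_genes = 3, n_cis_snps = 8, seed = 30)
  expect_identical(s1$genotypes$P1$dosages, s2$genotypes$P1$dosages)
  expect_identical(s1$expression$P2$values, s2$expression$P2$values)
  s3 <- simulate_study(pops, n_genes = 3, n_cis_snps = 8, seed = 31)
  expect_false(identical(s1$expression$P1$values, s3$expression$P1$values))
})
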