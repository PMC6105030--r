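# GRM construction and REML variance components: hand-computed GRM
# entries, likelihood-ascent, grid-search oracle agreement, bivariate
# recovery and bending behaviour.

test_that("the cis GRM equals the standardized outer product, entry for entry", {
  dos <- matrix(c(0, 1, 2,
                  1, 1, 0,
                  2, 0, 1,
                  0, 2, 2), nrow = 3)
  geno <- toy_genotypes(dos)
  grm <- build_cis_grm(geno)
  W <- apply(dos, 2, function(x) (x - mean(x)) / sd(x))
  expect_equal(grm$matrix, W %*% t(W) / 4, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(grm$n_snps_used, 4L)
})

test_that("identical genomes give off-diagonal equal to the diagonals", {
  set.seed(21)
  dos <- matrix(rbinom(40 * 20, 2, 0.4), 40, 20)
  dos[2, ] <- dos[1, ]
  grm <- build_cis_grm(toy_genotypes(dos))
  expect_equal(grm$matrix[1, 2], grm$matrix[1, 1], tolerance = 1e-12)
  expect_equal(grm$matrix[1, 2], grm$matrix[2, 2], tolerance = 1e-12)
})

test_that("GRM diagonal is near one for an outbred HWE cohort", {
  pop <- population_spec("P1", 500, 0.1)
  snps <- draw_population_frequencies(1000, list(pop), seed = 22)
  geno <- simulate_genotypes(snps, pop, seed = 23)
  grm <- build_cis_grm(geno)
  expect_lt(abs(mean(diag(grm$matrix)) - 1), 0.05)
  expect_error(build_cis_grm(toy_genotypes(matrix(0, 5, 2))), "filtered")
})

test_that("univariate REML recovers the null and noiseless limits", {
  pop <- population_spec("P1", 150, 0.1)
  snps <- draw_population_frequencies(30, list(pop), seed = 24)
  geno <- simulate_genotypes(snps, pop, seed = 25)
  grm <- build_cis_grm(geno)

  set.seed(26)
  h2_null <- vapply(seq_len(60), function(i) {
    reml_univariate_h2(grm, rnorm(150))$h2
  }, 0)
  expect_lte(mean(h2_null), 0.05)

  tr <- simulate_gene_architecture("g", snps, 5, c(P1 = 1), 0, seed = 27)
  y_noiseless <- simulate_expression(geno, tr, "P1", seed = 28)
  expect_gte(reml_univariate_h2(grm, y_noiseless)$h2, 0.95)
})

test_that("univariate REML agrees with a brute-force likelihood grid search", {
  set.seed(29)
  for (i in 1:8) {
    n <- 80
    dos <- matrix(rbinom(n * 25, 2, runif(25, 0.1, 0.5)), n, 25, byrow = FALSE)
    geno <- toy_genotypes(dos)
    grm <- build_cis_grm(geno)
    K <- grm$matrix
    h2_true <- runif(1, 0.1, 0.8)
    g <- drop(K %*% rnorm(n)) # smooth genetic signal along the GRM
    g <- g / sd(g) * sqrt(h2_true)
    y <- g + rnorm(n, 0, sqrt(1 - h2_true))
    fit <- reml_univariate_h2(grm, y)
    oracle <- reml_grid_oracle(K, y)
    expect_lt(abs(fit$h2 - oracle), 0.02)
    expect_true(all(diff(fit$ll_trace) >= -1e-9))
  }
})

test_that("univariate h2 recovery is calibrated at moderate scale", {
  pop <- population_spec("P1", 300, 0.1)
  h2_hat <- vapply(seq_len(40), function(i) {
    st <- single_gene_study(n = 300, m = 40, h2 = 0.4, seed = 8000 + 11 * i,
                            n_causal = 5)
    grm <- build_cis_grm(st$genotypes, maf_min = 0.01)
    reml_univariate_h2(grm, st$expression$values[, 1])$h2
  }, 0)
  expect_lt(abs(mean(h2_hat) - 0.4), 0.06)
})

test_that("low-rank and dense bivariate REML agree to numerical precision", {
  pops <- two_pop_specs(n = 80)
  sim <- simulate_study(pops, n_genes = 4, n_cis_snps = 15, n_causal = NULL,
                        h2 = 0.4, rho_effects = 0.6, seed = 31)
  for (j in 1:4) {
    gid <- sim$genes$gene_id[j]
    ids <- sim$snps$snp_id[sim$snps$chromosome == sim$genes$chromosome[j]]
    g <- build_cross_grm(sim$genotypes$P1, sim$genotypes$P2, ids,
                         maf_min = 0.01)
    y1 <- sim$expression$P1$values[, gid]
    y2 <- sim$expression$P2$values[, gid]
    fd <- reml_bivariate_rg(g$grm1, g$grm2, g$cross, y1, y2)
    fl <- xpopexpr:::reml_bivariate_lowrank(g$factors$W1, g$factors$W2, y1, y2)
    expect_equal(fl$sigma_g1g2, fd$sigma_g1g2, tolerance = 1e-6)
    expect_equal(fl$rg, fd$rg, tolerance = 1e-6)
    expect_true(all(diff(fd$ll_trace) >= -1e-9))
    expect_true(all(diff(fl$ll_trace) >= -1e-9))
  }
})

test_that("perfect effect sharing is recovered as rG near one", {
  pops <- two_pop_specs(n = 300)
  sim <- simulate_study(pops, n_genes = 40, n_cis_snps = 30, n_causal = NULL,
                        h2 = 0.4, rho_effects = 1, seed = 32)
  est <- estimate_rg_panel(sim$expression$P1, sim$expression$P2,
                           sim$genotypes$P1, sim$genotypes$P2)
  expect_gte(mean(est$rg[est$converged]), 0.9)
  expect_true(all(abs(est$rg) <= 1, na.rm = TRUE))
})

test_that("bending is recorded and never leaves rG outside [-1, 1]", {
  pops <- two_pop_specs(n = 100)
  sim <- simulate_study(pops, n_genes = 30, n_cis_snps = 20, n_causal = NULL,
                        h2 = 0.15, rho_effects = 0, seed = 33)
  est <- estimate_rg_panel(sim$expression$P1, sim$expression$P2,
                           sim$genotypes$P1, sim$genotypes$P2)
  expect_true(all(abs(est$rg) <= 1, na.rm = TRUE))
  # low h2 and a null correlation drive many fits to the boundary
  expect_gt(sum(est$bent), 0)
  expect_true(all(abs(est$rg[est$bent & est$converged]) <= 1))
})

test_that("degenerate genetic variance is flagged as non-converged", {
  pops <- two_pop_specs(n = 80)
  sim <- simulate_study(pops, n_genes = 10, n_cis_snps = 15, n_causal = NULL,
                        h2 = 0, rho_effects = 0, seed = 34)
  est <- estimate_rg_panel(sim$expression$P1, sim$expression$P2,
                           sim$genotypes$P1, sim$genotypes$P2)
  degen <- !is.na(est$reason) & est$reason == "degenerate genetic variance"
  expect_gt(sum(degen), 0)
  expect_true(all(!est$converged[degen]))
  expect_true(all(is.na(est$rg[degen])))
})

test_that("rG aggregation filters by h2 threshold and reports SEs", {
  est <- tibble::tibble(
    gene_id = paste0("g", 1:4),
    h2_1 = c(0.5, 0.3, 0.1, 0.6),
    h2_2 = c(0.4, 0.2, 0.5, 0.7),
    rg = c(0.8, 0.4, 0.2, 0.6),
    converged = c(TRUE, TRUE, TRUE, FALSE)
  )
  agg <- aggregate_rg(est, h2_threshold_grid = c(0, 0.25))
  expect_identical(agg$n_genes, c(3L, 1L))         # converged only
  expect_equal(agg$mean_rg[1], mean(c(0.8, 0.4, 0.2)))
  expect_equal(agg$mean_rg[2], 0.8)                # single gene above 0.25
  expect_true(is.na(agg$se_mean_rg[2]))            # SE undefined for one gene
  empty <- aggregate_rg(est, h2_threshold_grid = 0.9)
  expect_identical(empty$n_genes, 0L)
  expect_true(is.na(empty$mean_rg))
})
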