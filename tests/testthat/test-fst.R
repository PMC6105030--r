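# Weir-Cockerham FST, per-model summaries, and the divergence sweep.

test_that("FST limits: no differentiation and complete fixation", {
  set.seed(61)
  ests <- vapply(1:20, function(i) {
    d1 <- matrix(rbinom(200, 2, 0.4), ncol = 1)
    d2 <- matrix(rbinom(200, 2, 0.4), ncol = 1)
    weir_cockerham_fst(toy_genotypes(d1), toy_genotypes(d2))$fst
  }, 0)
  expect_lt(abs(mean(ests)), 0.02)  # small negatives expected

  fixed1 <- toy_genotypes(matrix(2, 50, 1))
  fixed0 <- toy_genotypes(matrix(0, 50, 1))
  expect_equal(weir_cockerham_fst(fixed1, fixed0)$fst, 1)

  # pooled-monomorphic SNP is flagged, absent SNP errors
  mono <- weir_cockerham_fst(fixed0, toy_genotypes(matrix(0, 50, 1)))
  expect_true(mono$monomorphic)
  expect_true(is.na(mono$fst))
  expect_error(weir_cockerham_fst(fixed1, fixed0, snp_ids = "nope"), "absent")
})

test_that("the estimator matches the component formula on HWE counts", {
  # n = 100 per population, p1 = 0.3, p2 = 0.5, exact HWE genotype counts
  d1 <- matrix(c(rep(2, 9), rep(1, 42), rep(0, 49)), ncol = 1)
  d2 <- matrix(c(rep(2, 25), rep(1, 50), rep(0, 25)), ncol = 1)
  got <- weir_cockerham_fst(toy_genotypes(d1), toy_genotypes(d2))$fst
  expect_equal(got, wc_theta_oracle(d1[, 1], d2[, 1]), tolerance = 1e-10)

  # and on arbitrary random draws
  set.seed(62)
  for (i in 1:10) {
    d1 <- matrix(rbinom(80, 2, runif(1, 0.1, 0.9)), ncol = 1)
    d2 <- matrix(rbinom(120, 2, runif(1, 0.1, 0.9)), ncol = 1)
    skip_if(sd(c(d1, d2)) == 0)
    expect_equal(weir_cockerham_fst(toy_genotypes(d1), toy_genotypes(d2))$fst,
                 wc_theta_oracle(d1[, 1], d2[, 1]), tolerance = 1e-10)
  }
})

test_that("multi-locus FST is calibrated to the generative divergence", {
  for (f in c(0.05, 0.1)) {
    pops <- list(population_spec("P1", 300, f), population_spec("P2", 300, f))
    snps <- draw_population_frequencies(4000, pops, seed = round(1000 * f))
    g1 <- simulate_genotypes(snps, pops[[1]], seed = 63)
    g2 <- simulate_genotypes(snps, pops[[2]], seed = 64)
    fst <- weir_cockerham_fst(g1, g2)
    expect_lt(abs(fst_multilocus(fst) - f), 0.01)
  }
})

test_that("per-model summaries follow the signed-product definition", {
  fst <- tibble::tibble(snp_id = c("a", "b", "c"),
                        fst = c(0.2, 0.1, 0.4),
                        fst_num = c(0.2, 0.1, 0.4), fst_den = c(1, 1, 1))
  one <- model_fst_summary(tibble::tibble(snp_id = "a", beta = 0.5), fst)
  expect_equal(one$mean_fst, 0.2)
  expect_equal(one$weighted_fst, 0.1)

  m3 <- tibble::tibble(snp_id = c("a", "b", "c"), beta = c(0.5, -1, 2))
  s3 <- model_fst_summary(m3, fst)
  expect_equal(s3$mean_fst, mean(c(0.2, 0.1, 0.4)))
  expect_equal(s3$weighted_fst, mean(c(0.5 * 0.2, -1 * 0.1, 2 * 0.4)))
  s3_abs <- model_fst_summary(m3, fst, weight_type = "abs")
  expect_equal(s3_abs$weighted_fst,
               sum(abs(m3$beta) * fst$fst) / sum(abs(m3$beta)))

  # equal FST: the unweighted mean ignores beta entirely
  fst_c <- dplyr::mutate(fst, fst = 0.15)
  expect_equal(model_fst_summary(m3, fst_c)$mean_fst, 0.15)
  expect_error(model_fst_summary(m3[0, ], fst), "empty model")
})

test_that("the exact Wilcoxon branch reproduces exhaustive enumeration", {
  x <- c(0.31, 0.02, 0.77)
  y <- c(0.15, 0.48, 0.09, 0.55)
  perf <- tibble::tibble(gene_id = paste0("g", 1:7),
                         r2_pop1 = c(1, 1, 1, 0, 0, 0, 0),
                         r2_pop2 = 0)
  summ <- tibble::tibble(gene_id = paste0("g", 1:7),
                         mean_fst = c(x, y), weighted_fst = c(x, y))
  res <- divergence_wilcoxon(perf, summ, threshold_grid = 0.5)
  expect_identical(c(res$n_divergent, res$n_similar), c(3L, 4L))
  expect_equal(res$p_value, wilcox_exact_oracle(x, y), tolerance = 1e-12)
})

test_that("the divergence sweep is calibrated under the null", {
  set.seed(65)
  frac_sig <- mean(vapply(1:40, function(i) {
    g <- 120
    perf <- tibble::tibble(gene_id = paste0("g", 1:g),
                           r2_pop1 = runif(g), r2_pop2 = runif(g))
    summ <- tibble::tibble(gene_id = paste0("g", 1:g),
                           mean_fst = runif(g, 0, 0.3),
                           weighted_fst = runif(g, 0, 0.3))
    divergence_wilcoxon(perf, summ, threshold_grid = 0.3)$p_value < 0.05
  }, TRUE))
  expect_lte(frac_sig, 0.15)  # 5% rate up to binomial noise at 40 replicates

  # empty group handling
  perf1 <- tibble::tibble(gene_id = "g1", r2_pop1 = 0.1, r2_pop2 = 0.1)
  summ1 <- tibble::tibble(gene_id = "g1", mean_fst = 0.1, weighted_fst = 0.1)
  expect_warning(res <- divergence_wilcoxon(perf1, summ1, threshold_grid = 0.2),
                 "empty")
  expect_true(is.na(res$p_value))
})
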