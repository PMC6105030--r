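# Elastic-net fitting, nested cross-validation, allele harmonization,
# transfer evaluation and alpha comparison.

test_that("the penalty boundary and vanishing-penalty limits are exact", {
  set.seed(41)
  n <- 80
  X <- matrix(rbinom(n * 6, 2, 0.4), n, 6,
              dimnames = list(NULL, paste0("s", 1:6)))
  y <- X[, 2] * 0.7 + rnorm(n)
  # lambda_max (unstandardized): the smallest lambda that zeroes all weights
  yc <- y - mean(y)
  Xc <- sweep(X, 2, colMeans(X))
  lmax <- max(abs(crossprod(Xc, yc))) / n
  at_max <- fit_elastic_net(y, X, alpha = 1, lambda = lmax, standardize = FALSE)
  expect_true(all(at_max$weights == 0))
  expect_equal(at_max$intercept, mean(y))

  tiny <- fit_elastic_net(y, X, alpha = 1, lambda = 1e-8, standardize = FALSE)
  ols <- coef(lm(y ~ X))
  expect_equal(unname(tiny$weights), unname(ols[-1]), tolerance = 1e-4)
  expect_equal(tiny$intercept, unname(ols[1]), tolerance = 1e-4)

  expect_error(fit_elastic_net(y, X, alpha = 0, lambda = 1), "alpha")
  expect_error(fit_elastic_net(rep(1, n), X, alpha = 1, lambda = 1), "variance")
})

test_that("the returned solution minimizes the stated objective", {
  set.seed(42)
  X <- matrix(rnorm(20 * 10), 20, 10, dimnames = list(NULL, paste0("s", 1:10)))
  y <- X[, 1] - 0.5 * X[, 4] + rnorm(20, 0, 0.5)
  fit <- fit_elastic_net(y, X, alpha = 0.5, lambda = 0.1, standardize = FALSE)
  oracle <- enet_fista(y, X, lambda = 0.1, alpha = 0.5)
  obj_fit <- enet_objective(y, X, fit$intercept, fit$weights, 0.1, 0.5)
  obj_oracle <- enet_objective(y, X, oracle$intercept, oracle$weights, 0.1, 0.5)
  expect_lt(abs(obj_fit - obj_oracle), 1e-6)
})

test_that("KKT conditions hold at the solution across random instances", {
  set.seed(43)
  for (i in 1:20) {
    n <- 40; p <- 8
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("s", 1:p)))
    y <- drop(X %*% (rnorm(p) * rbinom(p, 1, 0.4))) + rnorm(n)
    alpha <- runif(1, 0.2, 1)
    lambda <- runif(1, 0.05, 0.3)
    fit <- fit_elastic_net(y, X, alpha, lambda, standardize = FALSE)
    w <- fit$weights
    Xc <- sweep(X, 2, colMeans(X))
    yc <- y - mean(y)
    g <- -crossprod(Xc, yc - Xc %*% w) / n + lambda * (1 - alpha) * w
    nz <- w != 0
    if (any(nz)) {
      expect_lt(max(abs(g[nz] + lambda * alpha * sign(w[nz]))), 1e-6)
    }
    if (any(!nz)) {
      expect_lt(max(abs(g[!nz])) - lambda * alpha, 1e-6)
    }
  }
})

test_that("nested CV scores noise near zero and deterministic signal near one", {
  set.seed(44)
  null_r2 <- vapply(seq_len(60), function(i) {
    X <- matrix(rbinom(60 * 8, 2, 0.4), 60, 8,
                dimnames = list(NULL, paste0("s", 1:8)))
    nested_cv_performance(rnorm(60), X, alpha = 1, seed = i)$r2
  }, 0)
  expect_lte(mean(null_r2), 0.02)

  X <- matrix(rbinom(300 * 10, 2, 0.4), 300, 10,
              dimnames = list(NULL, paste0("s", 1:10)))
  y <- 2 * X[, 7]
  perf <- nested_cv_performance(y, X, alpha = 1, seed = 45)
  expect_gte(perf$r2, 0.95)

  # determinism of the fold split
  expect_identical(nested_cv_performance(y, X, alpha = 1, seed = 9)$fold_r2,
                   nested_cv_performance(y, X, alpha = 1, seed = 9)$fold_r2)
})

test_that("nested-CV R2 tracks but undershoots the planted heritability", {
  r2s <- vapply(seq_len(20), function(i) {
    st <- single_gene_study(n = 500, m = 150, h2 = 0.5, seed = 40000 + 13 * i,
                            n_causal = 2)
    nested_cv_performance(st$expression$values[, 1], st$genotypes$dosages,
                          alpha = 0.5, seed = i)$r2
  }, 0)
  expect_gte(mean(r2s), 0.30)
  expect_lte(mean(r2s), 0.55)
})

test_that("trained models store portable weights with allele metadata", {
  pop <- population_spec("P1", 150, 0.1)
  sim <- simulate_study(list(pop), n_genes = 5, n_cis_snps = 25, n_causal = 2,
                        h2 = 0.5, rho_effects = 0, seed = 46)
  models <- train_gene_models(sim$expression$P1, sim$genotypes$P1,
                              alpha_grid = c(0.5, 1), seed = 47,
                              population = "P1")
  expect_s3_class(models$weights, "tbl_df")
  expect_true(all(models$weights$beta != 0))
  expect_true(all(models$weights$effect_allele != models$weights$other_allele))
  expect_setequal(unique(models$performance$alpha), c(0.5, 1))
  expect_true(all(c("r2", "n_snps_in_model", "lambda_selected", "intercept")
                  %in% names(models$performance)))
})

test_that("harmonization arithmetic, flips and missing policies are exact", {
  models <- structure(list(
    weights = tibble::tibble(
      gene_id = "g1", alpha = 0.5, snp_id = "snpA", chromosome = "chr1",
      position = 500L, effect_allele = "G", other_allele = "A",
      beta = 0.5, training_freq = 0.25
    ),
    performance = tibble::tibble(gene_id = "g1", alpha = 0.5, r2 = 0.4,
                                 n_snps_in_model = 1L, lambda_selected = 0.1,
                                 intercept = 0),
    genes = tibble::tibble(gene_id = "g1", chromosome = "chr1", tss = 500L),
    population = "train", alpha_grid = 0.5
  ), class = "prediction_models")

  test_geno <- genotype_matrix(
    matrix(c(0, 1, 2), ncol = 1),
    tibble::tibble(snp_id = "x1", chromosome = "chr1", position = 500L,
                   ref_allele = "A", alt_allele = "G")
  )
  pred <- harmonize_and_predict(models, test_geno)
  expect_equal(unname(pred$values[, "g1"]), c(0, 0.5, 1.0))

  # swapped ref/alt with flipped dosage must give identical predictions
  flipped <- genotype_matrix(
    matrix(2 - c(0, 1, 2), ncol = 1),
    tibble::tibble(snp_id = "x1", chromosome = "chr1", position = 500L,
                   ref_allele = "G", alt_allele = "A")
  )
  pred_fl <- harmonize_and_predict(models, flipped)
  expect_equal(pred_fl$values, pred$values, tolerance = 1e-12)

  # strand-ambiguous test SNP is excluded; freq_impute fills 2 x training freq
  ambig <- genotype_matrix(
    matrix(c(0, 1, 2), ncol = 1),
    tibble::tibble(snp_id = "x1", chromosome = "chr1", position = 500L,
                   ref_allele = "A", alt_allele = "T")
  )
  pred_amb <- harmonize_and_predict(models, ambig)
  expect_equal(unname(pred_amb$values[, "g1"]), rep(0.5 * 2 * 0.25, 3))

  # under "drop" the gene disappears entirely and is listed
  expect_message(
    pred_drop <- harmonize_and_predict(models, ambig, missing_policy = "drop"),
    "omitting"
  )
  expect_identical(attr(pred_drop, "dropped_genes"), "g1")
})

test_that("whole-cohort flip invariance holds on simulated data", {
  pop <- population_spec("P1", 120, 0.1)
  sim <- simulate_study(list(pop), n_genes = 4, n_cis_snps = 20, n_causal = 2,
                        h2 = 0.5, rho_effects = 0, seed = 48)
  models <- train_gene_models(sim$expression$P1, sim$genotypes$P1,
                              alpha_grid = 1, seed = 49)
  geno <- sim$genotypes$P1
  swapped <- genotype_matrix(
    2 - geno$dosages,
    dplyr::mutate(geno$snps, ref_allele0 = ref_allele,
                  ref_allele = alt_allele, alt_allele = ref_allele0,
                  ref_allele0 = NULL),
    geno$samples
  )
  p1 <- harmonize_and_predict(models, geno)
  p2 <- harmonize_and_predict(models, swapped)
  expect_equal(p1$values, p2$values, tolerance = 1e-12)
})

test_that("transfer evaluation separates real replication from permutation", {
  set.seed(50)
  n <- 100; g <- 200
  truth <- matrix(rnorm(n * g), n, g)
  pred <- toy_expression(truth, samples = paste0("S", 1:n))
  obs <- toy_expression(truth + matrix(rnorm(n * g, 0, 0.2), n, g),
                        samples = paste0("S", 1:n))
  perf <- tibble::tibble(gene_id = pred$genes$gene_id, r2 = 0.3)
  te <- evaluate_transfer(pred, obs, perf, r2_thresholds = c(0, 0.2))
  expect_true(all(te$pi1$pi1 >= 0.95))

  # breaking the sample pairing gene-by-gene leaves only null correlations
  obs_perm <- toy_expression(apply(obs$values, 2, sample),
                             samples = obs$samples)
  te_perm <- evaluate_transfer(pred, obs_perm, perf, r2_thresholds = 0)
  expect_lte(te_perm$pi1$pi1, 0.05)

  expect_warning(
    evaluate_transfer(pred, obs, dplyr::mutate(perf, r2 = -1),
                      r2_thresholds = 0.5),
    "pi1 not estimated"
  )
})

test_that("alpha comparison counts sparse wins and handles edge cases", {
  set.seed(51)
  g <- 400
  base <- runif(g, 0, 0.5)
  perf <- dplyr::bind_rows(
    tibble::tibble(gene_id = paste0("g", 1:g), alpha = 1,
                   r2 = base + rnorm(g, 0, 1e-6)),
    tibble::tibble(gene_id = paste0("g", 1:g), alpha = 0.5,
                   r2 = base + rnorm(g, 0, 1e-6))
  )
  cmp <- compare_alpha_performance(perf)
  expect_identical(cmp$n_genes, as.integer(g))
  # exchangeable inputs: wins split evenly up to binomial noise
  expect_gt(cmp$proportion, 0.5 - 2 * sqrt(0.25 / g))
  expect_lt(cmp$proportion, 0.5 + 2 * sqrt(0.25 / g))

  one <- dplyr::bind_rows(
    tibble::tibble(gene_id = "g1", alpha = 1, r2 = 0.4),
    tibble::tibble(gene_id = "g1", alpha = 0.05, r2 = 0.2)
  )
  cmp1 <- compare_alpha_performance(one)
  expect_true(cmp1$proportion %in% c(0, 1))
  expect_error(compare_alpha_performance(one[one$alpha == 1, ]), "two alphas")
})
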