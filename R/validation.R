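# Validation experiments at the package's study conditions: each function
# simulates cohorts with known truth, runs the corresponding analysis
# stage, and returns the summary quantities a user would check before
# trusting the estimators on real data. Problem sizes default to the
# conditions the estimators are validated at (two cohorts of 300, gene
# panels in the hundreds); all are arguments.

#' Null-calibration of the genetic-correlation estimator
#'
#' Simulates h2-matched expression panels with independent effects in the
#' two populations (the rG null), fits the bivariate REML to every gene in
#' every replicate, and summarises the estimates. An unbiased estimator
#' yields a mean rG near zero, with point masses at -1 and +1 from
#' low-information genes driven to the boundary.
#'
#' @param n_per_pop Samples per population.
#' @param n_genes Genes per replicate panel.
#' @param n_replicates Replicate panels.
#' @param n_cis_snps cis SNPs per gene (all causal, effects standard
#'   normal, redrawn independently per population).
#' @param h2_range Per-gene heritability is uniform on this interval in
#'   both populations.
#' @param ancestry_fst Divergence of each cohort from the shared ancestor.
#' @param seed Integer seed.
#' @return List with `mean_rg`, `n_converged`, `n_at_plus1`, `n_at_minus1`
#'   (|rG| >= 0.99 among converged), and the per-gene `estimates` tibble.
#' @export
validate_rg_null <- function(n_per_pop = 300, n_genes = 100,
                             n_replicates = 10, n_cis_snps = 50,
                             h2_range = c(0.05, 0.6), ancestry_fst = 0.1,
                             seed = 1L) {
  pops <- list(population_spec("P1", n_per_pop, ancestry_fst),
               population_spec("P2", n_per_pop, ancestry_fst))
  sim <- simulate_study(
    pops, n_genes = n_genes, n_cis_snps = n_cis_snps, n_causal = NULL,
    h2 = function(n) stats::runif(n, h2_range[1], h2_range[2]),
    rho_effects = 0, seed = seed
  )
  panels <- simulate_h2_matched_null(sim$truths, sim$genotypes,
                                     n_replicates, seed = seed + 1L)
  estimates <- purrr::map_dfr(seq_along(panels), function(r) {
    dplyr::mutate(
      estimate_rg_panel(panels[[r]]$P1, panels[[r]]$P2,
                        sim$genotypes$P1, sim$genotypes$P2),
      replicate = r
    )
  })
  ok <- estimates$converged & !is.na(estimates$rg)
  list(
    mean_rg = mean(estimates$rg[ok]),
    n_converged = sum(ok),
    n_total = nrow(estimates),
    n_at_plus1 = sum(estimates$rg[ok] >= 0.99),
    n_at_minus1 = sum(estimates$rg[ok] <= -0.99),
    estimates = estimates
  )
}

#' Recovery of planted between-population effect correlations
#'
#' For each planted correlation, simulates a two-population panel with
#' infinitesimal cis architecture (every eligible cis SNP causal, so the
#' realized per-gene effect correlation concentrates at the target) and
#' reports the mean estimated rG over converged genes.
#'
#' @param rho_grid Planted effect correlations.
#' @param n_genes Genes per correlation level.
#' @param n_per_pop Samples per population.
#' @param h2 Per-gene cis heritability (both populations).
#' @param n_cis_snps cis SNPs per gene.
#' @param ancestry_fst Cohort divergence.
#' @param seed Integer seed.
#' @return A tibble: `rho`, `mean_rg`, `se_mean_rg`, `n_converged`.
#' @export
validate_rg_recovery <- function(rho_grid = c(0.3, 0.6, 0.9), n_genes = 300,
                                 n_per_pop = 300, h2 = 0.3, n_cis_snps = 50,
                                 ancestry_fst = 0.1, seed = 1L) {
  pops <- list(population_spec("P1", n_per_pop, ancestry_fst),
               population_spec("P2", n_per_pop, ancestry_fst))
  purrr::map_dfr(seq_along(rho_grid), function(i) {
    sim <- simulate_study(pops, n_genes = n_genes, n_cis_snps = n_cis_snps,
                          n_causal = NULL, h2 = h2,
                          rho_effects = rho_grid[i],
                          seed = derive_seed(seed, paste0("rho", i)))
    est <- estimate_rg_panel(sim$expression$P1, sim$expression$P2,
                             sim$genotypes$P1, sim$genotypes$P2)
    ok <- est$converged & !is.na(est$rg)
    tibble::tibble(
      rho = rho_grid[i],
      mean_rg = mean(est$rg[ok]),
      se_mean_rg = stats::sd(est$rg[ok]) / sqrt(sum(ok)),
      n_converged = sum(ok)
    )
  })
}

#' Mean rG against the h2 inclusion threshold on a planted gradient
#'
#' Builds a panel in which the true effect correlation rises with the true
#' heritability, mimicking the empirical observation that highly heritable
#' genes share architecture across populations, then checks that the mean
#' rG among genes passing increasing h2 thresholds rises accordingly.
#'
#' @param n_genes Panel size.
#' @param n_per_pop Samples per population.
#' @param n_cis_snps cis SNPs per gene.
#' @param h2_range Heritability range (uniform).
#' @param threshold_grid h2 inclusion thresholds.
#' @param seed Integer seed.
#' @return The [aggregate_rg()] table over `threshold_grid`.
#' @export
validate_rg_h2_gradient <- function(n_genes = 300, n_per_pop = 300,
                                    n_cis_snps = 40,
                                    h2_range = c(0.05, 0.7),
                                    threshold_grid = seq(0, 0.4, by = 0.1),
                                    seed = 1L) {
  pops <- list(population_spec("P1", n_per_pop, 0.1),
               population_spec("P2", n_per_pop, 0.1))
  h2_vec <- with_seed(derive_seed(seed, "h2grad"),
                      stats::runif(n_genes, h2_range[1], h2_range[2]))
  rho_vec <- pmin(0.95, 0.15 + 1.1 * h2_vec)
  sim <- simulate_study(pops, n_genes = n_genes, n_cis_snps = n_cis_snps,
                        n_causal = NULL, h2 = h2_vec, rho_effects = rho_vec,
                        seed = seed)
  est <- estimate_rg_panel(sim$expression$P1, sim$expression$P2,
                           sim$genotypes$P1, sim$genotypes$P2)
  aggregate_rg(est, h2_threshold_grid = threshold_grid)
}

#' Univariate heritability recovery at a fixed target
#'
#' @param n_genes Replicate genes.
#' @param n_samples Cohort size.
#' @param h2 Target heritability.
#' @param n_cis_snps cis SNPs per gene.
#' @param n_causal Causal SNPs per gene.
#' @param seed Integer seed.
#' @return List with `mean_h2`, `sd_h2`, `n_genes`, per-gene `estimates`.
#' @export
validate_h2_recovery <- function(n_genes = 200, n_samples = 500, h2 = 0.4,
                                 n_cis_snps = 200, n_causal = 5, seed = 1L) {
  pop <- population_spec("P1", n_samples, 0.1)
  sim <- simulate_study(list(pop), n_genes = n_genes,
                        n_cis_snps = n_cis_snps, n_causal = n_causal,
                        h2 = h2, rho_effects = 0, seed = seed)
  estimates <- estimate_h2_panel(sim$expression$P1, sim$genotypes$P1)
  list(mean_h2 = mean(estimates$h2), sd_h2 = stats::sd(estimates$h2),
       n_genes = nrow(estimates), estimates = estimates)
}

#' Sparse-architecture contrast across elastic-net mixing parameters
#'
#' Simulates genes with few causal cis SNPs, trains models at the full
#' mixing grid, and reports for each alpha pair the proportion of genes
#' where the sparser model predicts better - the signature of a sparse
#' genetic architecture.
#'
#' @param n_genes Panel size.
#' @param n_samples Cohort size.
#' @param n_cis_snps cis SNPs per gene.
#' @param n_causal Causal SNPs per gene (recycled; default cycles 1-3).
#' @param h2 Per-gene heritability.
#' @param alpha_grid Mixing parameters.
#' @param seed Integer seed.
#' @return The [compare_alpha_performance()] table.
#' @export
validate_sparse_alpha_contrast <- function(n_genes = 300, n_samples = 300,
                                           n_cis_snps = 50,
                                           n_causal = c(1L, 2L, 3L),
                                           h2 = 0.3,
                                           alpha_grid = c(0.05, 0.5, 1),
                                           seed = 1L) {
  pop <- population_spec("P1", n_samples, 0.1)
  sim <- simulate_study(list(pop), n_genes = n_genes,
                        n_cis_snps = n_cis_snps, n_causal = n_causal,
                        h2 = h2, rho_effects = 0, seed = seed)
  models <- train_gene_models(sim$expression$P1, sim$genotypes$P1,
                              alpha_grid = alpha_grid,
                              seed = derive_seed(seed, "train"),
                              population = "P1")
  list(comparison = compare_alpha_performance(models$performance),
       performance = models$performance)
}

#' Transfer improves when training and test cohorts share architecture
#'
#' Three populations with pairwise effect correlations: the test cohort B
#' shares most of its causal effects with the training cohort A
#' (`rho = rho_matched`), cohort C shares little (`rho = rho_mismatched`).
#' Models trained in A are ported into B and C and scored by pi1 of the
#' predicted-observed correlations.
#'
#' The test cohorts are deliberately smaller than the training cohort and
#' the per-gene heritabilities are spread over a realistic range: pi1
#' counts the fraction of genes whose predicted-observed correlation is
#' distinguishable from zero, so the matched/mismatched contrast appears
#' through genes whose attenuated (`rho_mismatched`-scaled) correlation
#' falls below detectability in the test cohort. Causal architecture is
#' dense (all eligible cis SNPs) so each gene's realized cross-population
#' effect correlation concentrates at the planted value.
#'
#' @param n_genes Panel size.
#' @param n_train Training-cohort samples.
#' @param n_test Samples in each test cohort (equal by design).
#' @param n_cis_snps cis SNPs per gene.
#' @param h2_range Per-gene heritability range (uniform).
#' @param rho_matched,rho_mismatched Effect correlations of A with B and
#'   with C.
#' @param alpha Mixing parameter used for the ported models.
#' @param r2_threshold Training-R2 inclusion threshold for the pi1.
#' @param seed Integer seed.
#' @return List with `pi1_matched`, `pi1_mismatched` and the two
#'   [evaluate_transfer()] objects.
#' @export
validate_transfer_ancestry <- function(n_genes = 150, n_train = 300,
                                       n_test = 100, n_cis_snps = 40,
                                       h2_range = c(0.1, 0.5),
                                       rho_matched = 0.9,
                                       rho_mismatched = 0.3, alpha = 0.5,
                                       r2_threshold = 0.01, seed = 1L) {
  pops <- list(population_spec("A", n_train, 0.1),
               population_spec("B", n_test, 0.1),
               population_spec("C", n_test, 0.1))
  rho_m <- matrix(c(1, rho_matched, rho_mismatched,
                    rho_matched, 1, rho_mismatched,
                    rho_mismatched, rho_mismatched, 1), 3, 3)
  sim <- simulate_study(pops, n_genes = n_genes, n_cis_snps = n_cis_snps,
                        n_causal = NULL,
                        h2 = function(n) stats::runif(n, h2_range[1],
                                                      h2_range[2]),
                        rho_effects = rho_m, seed = seed)
  models <- train_gene_models(sim$expression$A, sim$genotypes$A,
                              alpha_grid = alpha,
                              seed = derive_seed(seed, "trainA"),
                              population = "A")
  score <- function(lab) {
    pred <- harmonize_and_predict(models, sim$genotypes[[lab]])
    suppressWarnings(evaluate_transfer(
      pred, sim$expression[[lab]], models$performance,
      r2_thresholds = r2_threshold,
      training_population = "A", test_cohort = lab
    ))
  }
  te_b <- score("B")
  te_c <- score("C")
  list(pi1_matched = te_b$pi1$pi1[1], pi1_mismatched = te_c$pi1$pi1[1],
       transfer_matched = te_b, transfer_mismatched = te_c)
}

#' FST calibration and the frequency-divergence transfer mechanism
#'
#' Two checks. Calibration: the multi-locus Weir-Cockerham estimate over
#' many SNPs recovers the generative divergence for each F in `fst_grid`.
#' Mechanism: a panel is planted in which half the genes have causal SNPs
#' common in population 1 but rare in population 2 (high FST) while the
#' rest are frequency-matched; models are trained in both populations and
#' the divergent-vs-similar Wilcoxon sweep over R2-difference thresholds
#' must attribute the transfer gap to model FST.
#'
#' @param fst_grid Generative F values for the calibration check.
#' @param n_calib_snps SNPs per calibration cohort.
#' @param n_calib_samples Samples per calibration cohort.
#' @param n_genes Genes in the mechanism panel (half planted divergent).
#' @param n_per_pop Samples per population in the mechanism panel.
#' @param n_cis_snps cis SNPs per gene.
#' @param threshold_grid R2-difference thresholds for the sweep.
#' @param seed Integer seed.
#' @return List with `calibration` (tibble: `f`, `fst_multilocus`) and
#'   `sweep` (the [divergence_wilcoxon()] table).
#' @export
validate_fst_mechanism <- function(fst_grid = c(0.05, 0.1, 0.2),
                                   n_calib_snps = 10000,
                                   n_calib_samples = 500,
                                   n_genes = 160, n_per_pop = 300,
                                   n_cis_snps = 40,
                                   threshold_grid = seq(0.05, 0.3, by = 0.05),
                                   seed = 1L) {
  calibration <- purrr::map_dfr(fst_grid, function(f) {
    pops <- list(population_spec("P1", n_calib_samples, f),
                 population_spec("P2", n_calib_samples, f))
    snps <- draw_population_frequencies(
      n_calib_snps, pops, seed = derive_seed(seed, paste0("calib", f))
    )
    g1 <- simulate_genotypes(snps, pops[[1]],
                             seed = derive_seed(seed, paste0("cal1", f)))
    g2 <- simulate_genotypes(snps, pops[[2]],
                             seed = derive_seed(seed, paste0("cal2", f)))
    tibble::tibble(f = f,
                   fst_multilocus = fst_multilocus(weir_cockerham_fst(g1, g2)))
  })

  # mechanism panel: planted frequency-divergent causal SNPs
  pops <- list(population_spec("P1", n_per_pop, 0.1),
               population_spec("P2", n_per_pop, 0.1))
  n_div <- n_genes %/% 2
  blocks <- vector("list", n_genes)
  truths <- vector("list", n_genes)
  for (j in seq_len(n_genes)) {
    chrom <- sprintf("chr%d", j)
    blk <- draw_population_frequencies(
      n_cis_snps, pops, seed = derive_seed(seed, paste0("blk", j)),
      chromosome = chrom
    )
    divergent <- j <= n_div
    csl <- with_seed(derive_seed(seed, paste0("cs", j)), {
      idx <- sample(n_cis_snps, 3)
      if (divergent) {
        blk$freq_P1[idx] <- stats::runif(3, 0.35, 0.5)
        blk$freq_P2[idx] <- stats::runif(3, 0.01, 0.03)
      } else {
        f0 <- stats::runif(3, 0.3, 0.5)
        blk$freq_P1[idx] <- f0
        blk$freq_P2[idx] <- f0
      }
      idx
    })
    h2s <- if (divergent) c(P1 = 0.5, P2 = 0.05) else c(P1 = 0.5, P2 = 0.5)
    truths[[j]] <- simulate_gene_architecture(
      sprintf("gene%04d", j), blk[csl, ], 3, h2s, rho_effects = 1,
      seed = derive_seed(seed, paste0("arch", j))
    )
    # annotate with the full block so the cis window covers all SNPs
    truths[[j]]$chromosome <- chrom
    truths[[j]]$tss <- as.integer(round(mean(range(blk$position))))
    blocks[[j]] <- blk
  }
  snps <- dplyr::bind_rows(blocks)
  genes_tbl <- tibble::tibble(
    gene_id = vapply(truths, `[[`, "", "gene_id"),
    chromosome = vapply(truths, `[[`, "", "chromosome"),
    tss = vapply(truths, `[[`, 1L, "tss")
  )
  genotypes <- stats::setNames(lapply(pops, function(pop) {
    simulate_genotypes(snps, pop, derive_seed(seed, paste0("geno", pop$label)))
  }), c("P1", "P2"))
  expression <- stats::setNames(lapply(c("P1", "P2"), function(lab) {
    vals <- vapply(truths, function(tr) {
      simulate_expression(genotypes[[lab]], tr, lab,
                          derive_seed(seed, paste0("expr", tr$gene_id, lab)))
    }, numeric(n_per_pop))
    expression_panel(vals, genes_tbl, genotypes[[lab]]$samples)
  }), c("P1", "P2"))

  m1 <- train_gene_models(expression$P1, genotypes$P1, alpha_grid = 0.5,
                          seed = derive_seed(seed, "m1"), population = "P1")
  m2 <- train_gene_models(expression$P2, genotypes$P2, alpha_grid = 0.5,
                          seed = derive_seed(seed, "m2"), population = "P2")
  fst <- weir_cockerham_fst(genotypes$P1, genotypes$P2)
  summaries <- purrr::map_dfr(unique(m1$weights$gene_id), function(gid) {
    s <- tryCatch(
      model_fst_summary(m1$weights[m1$weights$gene_id == gid, ], fst),
      error = function(e) NULL
    )
    if (is.null(s)) tibble::tibble() else dplyr::mutate(s, gene_id = gid)
  })
  perf <- dplyr::inner_join(m1$performance[c("gene_id", "r2")],
                            m2$performance[c("gene_id", "r2")],
                            by = "gene_id", suffix = c("_pop1", "_pop2"))
  names(perf) <- c("gene_id", "r2_pop1", "r2_pop2")
  sweep_tbl <- suppressWarnings(
    divergence_wilcoxon(perf, summaries, threshold_grid)
  )
  list(calibration = calibration, sweep = sweep_tbl,
       performance = perf, summaries = summaries)
}
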