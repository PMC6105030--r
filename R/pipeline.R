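# Configuration-driven orchestration: simulate -> eQTL -> pi1 -> rG ->
# train -> transfer -> FST, with deterministic per-stage seeds, resumable
# stage outputs and a summary report.

PIPELINE_STAGES <- c("simulate", "eqtl", "pi1", "rg", "train", "transfer", "fst")

#' Build and validate a pipeline configuration
#'
#' Every parameter is validated against its legal range before any stage
#' runs. Defaults follow the analysis grids this package implements:
#' genotype PCs in \{0, 3, 5, 10\}, hidden expression factors in
#' \{0, 10, 20, 30\}, the elastic-net mixing grid \{0.05, 0.5, 1\},
#' FDR 0.05, training-R2 inclusion thresholds \{0, 0.01, 0.05, 0.1, 0.2\}
#' and FST-sweep thresholds 0.05-0.3.
#'
#' @param populations List of [population_spec()] objects (>= 2 for the
#'   cross-population stages).
#' @param n_genes Number of simulated genes.
#' @param n_cis_snps cis SNPs per gene.
#' @param n_causal Causal SNPs per gene.
#' @param h2_range Interval from which per-gene heritability is drawn
#'   uniformly.
#' @param rho_grid Between-population effect correlations; genes are
#'   assigned to grid values in equal blocks.
#' @param n_pcs Genotype PCs used as covariates (one of 0, 3, 5, 10).
#' @param n_factors Hidden expression factors (one of 0, 10, 20, 30).
#' @param alpha_grid Elastic-net mixing parameters, each in (0, 1].
#' @param fdr_threshold eQTL significance threshold.
#' @param r2_thresholds Training-R2 inclusion grid for transfer pi1.
#' @param fst_thresholds R2-difference thresholds for the divergence sweep.
#' @param window_bp cis window half-width.
#' @param maf_min MAF threshold.
#' @param seed Master seed; per-stage seeds are derived from it and the
#'   stage name so inserting a stage never shifts another stage's draws.
#' @param output_dir Directory for stage outputs (created if needed).
#' @return A validated `pipeline_config` object.
#' @export
pipeline_config <- function(populations, n_genes = 200L, n_cis_snps = 100L,
                            n_causal = 2L, h2_range = c(0.05, 0.6),
                            rho_grid = c(0.3, 0.6, 0.9),
                            n_pcs = 3L, n_factors = 10L,
                            alpha_grid = c(0.05, 0.5, 1),
                            fdr_threshold = 0.05,
                            r2_thresholds = c(0, 0.01, 0.05, 0.1, 0.2),
                            fst_thresholds = seq(0.05, 0.3, by = 0.05),
                            window_bp = 1e6, maf_min = 0.01,
                            seed = 1L, output_dir = tempfile("xpop_run_")) {
  stopifnot(length(populations) >= 1L,
            all(vapply(populations, inherits, TRUE, "population_spec")))
  n_genes <- as.integer(n_genes)
  if (n_genes < 1L) stop("`n_genes` must be >= 1", call. = FALSE)
  if (!n_pcs %in% c(0L, 3L, 5L, 10L)) {
    stop("`n_pcs` must be one of 0, 3, 5, 10", call. = FALSE)
  }
  if (!n_factors %in% c(0L, 10L, 20L, 30L)) {
    stop("`n_factors` must be one of 0, 10, 20, 30", call. = FALSE)
  }
  vapply(alpha_grid, check_alpha, 0)
  assert_prob(fdr_threshold, "fdr_threshold", allow_zero = FALSE)
  if (length(h2_range) != 2L || any(h2_range < 0) || any(h2_range > 1) ||
      h2_range[1] > h2_range[2]) {
    stop("`h2_range` must be an ordered interval inside [0, 1]", call. = FALSE)
  }
  if (any(abs(rho_grid) > 1)) {
    stop("`rho_grid` values must lie in [-1, 1]", call. = FALSE)
  }
  structure(
    list(populations = populations, n_genes = n_genes,
         n_cis_snps = as.integer(n_cis_snps), n_causal = as.integer(n_causal),
         h2_range = h2_range, rho_grid = rho_grid,
         n_pcs = as.integer(n_pcs), n_factors = as.integer(n_factors),
         alpha_grid = alpha_grid, fdr_threshold = fdr_threshold,
         r2_thresholds = r2_thresholds, fst_thresholds = fst_thresholds,
         window_bp = window_bp, maf_min = maf_min,
         seed = as.integer(seed), output_dir = output_dir),
    class = "pipeline_config"
  )
}

config_hash <- function(config) {
  flat <- config
  flat$output_dir <- NULL
  flat$populations <- lapply(config$populations, unclass)
  derive_seed(0L, paste(deparse(flat), collapse = ""))
}

stage_path <- function(config, stage) {
  file.path(config$output_dir, paste0(stage, ".rds"))
}

#' Run the full analysis pipeline
#'
#' Executes the stages simulate, eqtl, pi1, rg, train, transfer and fst in
#' dependency order, with per-stage seeds derived deterministically from
#' the master seed. Each completed stage's output is saved under
#' `config$output_dir`; rerunning with the same configuration resumes at
#' the first incomplete stage. A stage failure halts downstream stages and
#' is recorded in the manifest.
#'
#' @param config A [pipeline_config()].
#' @return A `run_manifest` object: list with `config_hash`, `stages`
#'   (tibble: `stage`, `completed`, `path`, `seconds`, `error`), and
#'   `outputs` (named list of in-memory stage results).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  hash_file <- file.path(config$output_dir, "config_hash.txt")
  if (file.exists(hash_file)) {
    old <- as.integer(readLines(hash_file)[1])
    if (!identical(old, hash)) {
      # different configuration: never resume from stale outputs
      unlink(list.files(config$output_dir, full.names = TRUE))
    }
  }
  writeLines(as.character(hash), hash_file)

  outputs <- list()
  rows <- list()
  failed <- FALSE
  for (stage in PIPELINE_STAGES) {
    path <- stage_path(config, stage)
    if (failed) {
      rows[[stage]] <- tibble::tibble(stage = stage, completed = FALSE,
                                      path = NA_character_, seconds = NA_real_,
                                      error = "skipped: upstream failure")
      next
    }
    if (file.exists(path)) {
      outputs[[stage]] <- readRDS(path)
      rows[[stage]] <- tibble::tibble(stage = stage, completed = TRUE,
                                      path = path, seconds = 0,
                                      error = NA_character_)
      next
    }
    t0 <- Sys.time()
    res <- tryCatch(
      run_stage(stage, config, outputs),
      error = function(e) structure(list(message = conditionMessage(e)),
                                    class = "stage_error")
    )
    secs <- as.numeric(Sys.time() - t0, units = "secs")
    if (inherits(res, "stage_error")) {
      failed <- TRUE
      rows[[stage]] <- tibble::tibble(stage = stage, completed = FALSE,
                                      path = NA_character_, seconds = secs,
                                      error = sprintf("stage %s: %s", stage,
                                                      res$message))
    } else {
      outputs[[stage]] <- res
      saveRDS(res, path)
      rows[[stage]] <- tibble::tibble(stage = stage, completed = TRUE,
                                      path = path, seconds = secs,
                                      error = NA_character_)
    }
  }
  structure(
    list(config_hash = hash, config = config,
         stages = dplyr::bind_rows(rows), outputs = outputs),
    class = "run_manifest"
  )
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>\n")
  print(x$stages[c("stage", "completed", "seconds")])
  invisible(x)
}

run_stage <- function(stage, config, outputs) {
  seed <- derive_seed(config$seed, stage)
  labs <- vapply(config$populations, `[[`, "", "label")
  switch(
    stage,
    simulate = {
      n_per_rho <- ceiling(config$n_genes / length(config$rho_grid))
      rho_vec <- rep(config$rho_grid, each = n_per_rho)[seq_len(config$n_genes)]
      h2_fun <- function(n) with_seed(derive_seed(seed, "h2"),
                                      stats::runif(n, config$h2_range[1],
                                                   config$h2_range[2]))
      simulate_study(config$populations, config$n_genes, config$n_cis_snps,
                     config$n_causal, h2 = h2_fun, rho_effects = rho_vec,
                     seed = seed)
    },
    eqtl = {
      sim <- outputs$simulate
      res <- lapply(labs, function(lab) {
        geno <- sim$genotypes[[lab]]
        pcs <- if (config$n_pcs > 0) {
          pruned <- ld_prune(geno)
          genotype_pcs(subset_snps(geno, pruned), config$n_pcs)
        } else {
          covariate_set(geno$samples)
        }
        n_fac <- min(config$n_factors, length(geno$samples) - config$n_pcs - 2L)
        fac <- hidden_expression_factors(sim$expression[[lab]], max(n_fac, 0L),
                                         protect = pcs)
        covs <- dplyr::left_join(pcs, fac, by = "sample_id")
        class(covs) <- c("covariate_set", class(tibble::tibble()))
        assoc <- map_cis_eqtls(sim$expression[[lab]], geno, covs,
                               config$window_bp, config$maf_min)
        list(associations = assoc,
             summary = summarize_eqtls(assoc, config$fdr_threshold, lab),
             covariates = covs)
      })
      stats::setNames(res, labs)
    },
    pi1 = {
      eq <- outputs$eqtl
      pairs <- expand.grid(discovery = labs, replication = labs,
                           stringsAsFactors = FALSE)
      pairs <- pairs[pairs$discovery != pairs$replication, ]
      purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
        d <- eq[[pairs$discovery[i]]]$associations
        r <- eq[[pairs$replication[i]]]$associations
        disc <- tibble::tibble(unit = paste(d$snp_id, d$gene_id, sep = ":"),
                               fdr = d$fdr)
        repl <- tibble::tibble(unit = paste(r$snp_id, r$gene_id, sep = ":"),
                               p_value = r$p_value)
        est <- tryCatch(
          replication_pi1(disc, repl, config$fdr_threshold),
          error = function(e) NULL
        )
        tibble::tibble(
          discovery = pairs$discovery[i], replication = pairs$replication[i],
          pi1 = if (is.null(est)) NA_real_ else est$pi1,
          n_overlap = if (is.null(est)) 0L else est$n_overlap
        )
      })
    },
    rg = {
      sim <- outputs$simulate
      pair_idx <- utils::combn(labs, 2L)
      res <- lapply(seq_len(ncol(pair_idx)), function(k) {
        l1 <- pair_idx[1, k]; l2 <- pair_idx[2, k]
        est <- estimate_rg_panel(sim$expression[[l1]], sim$expression[[l2]],
                                 sim$genotypes[[l1]], sim$genotypes[[l2]],
                                 config$window_bp, config$maf_min)
        truth_rho <- vapply(sim$truths, `[[`, 0, "rho_effects")
        est$true_rho <- truth_rho[match(est$gene_id,
                                        vapply(sim$truths, `[[`, "", "gene_id"))]
        list(pair = c(l1, l2), estimates = est,
             aggregate = aggregate_rg(est))
      })
      stats::setNames(res, apply(pair_idx, 2L, paste, collapse = "-"))
    },
    train = {
      sim <- outputs$simulate
      eq <- outputs$eqtl
      res <- lapply(labs, function(lab) {
        models <- train_gene_models(
          sim$expression[[lab]], sim$genotypes[[lab]],
          covariates = eq[[lab]]$covariates,
          alpha_grid = config$alpha_grid, window_bp = config$window_bp,
          maf_min = config$maf_min,
          seed = derive_seed(seed, lab), population = lab
        )
        list(models = models,
             alpha_comparison = compare_alpha_performance(models$performance))
      })
      stats::setNames(res, labs)
    },
    transfer = {
      sim <- outputs$simulate
      tr <- outputs$train
      alpha_use <- if (0.5 %in% config$alpha_grid) 0.5 else config$alpha_grid[1]
      pairs <- expand.grid(train = labs, test = labs, stringsAsFactors = FALSE)
      res <- lapply(seq_len(nrow(pairs)), function(i) {
        m <- filter_models_alpha(tr[[pairs$train[i]]]$models, alpha_use)
        pred <- harmonize_and_predict(m, sim$genotypes[[pairs$test[i]]])
        suppressWarnings(evaluate_transfer(
          pred, sim$expression[[pairs$test[i]]], m$performance,
          config$r2_thresholds, pairs$train[i], pairs$test[i]
        ))
      })
      stats::setNames(res, paste(pairs$train, pairs$test, sep = "->"))
    },
    fst = {
      sim <- outputs$simulate
      tr <- outputs$train
      alpha_use <- if (0.5 %in% config$alpha_grid) 0.5 else config$alpha_grid[1]
      pair_idx <- utils::combn(labs, 2L)
      res <- lapply(seq_len(ncol(pair_idx)), function(k) {
        l1 <- pair_idx[1, k]; l2 <- pair_idx[2, k]
        fst <- weir_cockerham_fst(sim$genotypes[[l1]], sim$genotypes[[l2]])
        w1 <- filter_models_alpha(tr[[l1]]$models, alpha_use)$weights
        summaries <- purrr::map_dfr(unique(w1$gene_id), function(gid) {
          s <- tryCatch(
            model_fst_summary(w1[w1$gene_id == gid, ], fst),
            error = function(e) NULL
          )
          if (is.null(s)) tibble::tibble() else dplyr::mutate(s, gene_id = gid)
        })
        p1 <- tr[[l1]]$models$performance
        p2 <- tr[[l2]]$models$performance
        perf <- dplyr::inner_join(
          p1[p1$alpha == alpha_use, c("gene_id", "r2")],
          p2[p2$alpha == alpha_use, c("gene_id", "r2")],
          by = "gene_id", suffix = c("_pop1", "_pop2")
        )
        names(perf) <- c("gene_id", "r2_pop1", "r2_pop2")
        sweep_tbl <- if (nrow(summaries)) {
          suppressWarnings(
            divergence_wilcoxon(perf, summaries, config$fst_thresholds)
          )
        } else {
          tibble::tibble()
        }
        list(pair = c(l1, l2), fst = fst, summaries = summaries,
             sweep = sweep_tbl)
      })
      stats::setNames(res, apply(pair_idx, 2L, paste, collapse = "-"))
    },
    stop(sprintf("unknown stage `%s`", stage), call. = FALSE)
  )
}

#' Summarise a completed pipeline run
#'
#' Collects the per-stage outputs into the five machine-readable table
#' families (eQTL counts, mean rG per pair and h2 threshold, alpha
#' comparison proportions, transfer pi1, divergence-test rows) plus a
#' plain-text narrative.
#'
#' @param manifest A `run_manifest` from [run_pipeline()].
#' @return A list with `eqtl_counts`, `rg_means`, `alpha_comparison`,
#'   `transfer_pi1`, `divergence_tests` (tibbles) and `narrative`
#'   (character).
#' @export
report_summary <- function(manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  missing <- manifest$stages$stage[!manifest$stages$completed]
  if (length(missing)) {
    stop(sprintf("incomplete stages: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  out <- manifest$outputs
  eqtl_counts <- purrr::map_dfr(out$eqtl, "summary")
  rg_means <- purrr::map_dfr(names(out$rg), function(pair) {
    dplyr::mutate(out$rg[[pair]]$aggregate, pop_pair = pair, .before = 1)
  })
  alpha_comparison <- purrr::map_dfr(names(out$train), function(lab) {
    dplyr::mutate(out$train[[lab]]$alpha_comparison, population = lab,
                  .before = 1)
  })
  transfer_pi1 <- purrr::map_dfr(out$transfer, function(te) {
    dplyr::mutate(te$pi1, training = te$training_population,
                  test = te$test_cohort, .before = 1)
  })
  divergence_tests <- purrr::map_dfr(names(out$fst), function(pair) {
    dplyr::mutate(out$fst[[pair]]$sweep, pop_pair = pair, .before = 1)
  })
  narrative <- c(
    sprintf("Pipeline run with %d populations, %d genes.",
            length(manifest$config$populations), manifest$config$n_genes),
    sprintf("eGenes at FDR < %.2g: %s.", manifest$config$fdr_threshold,
            paste(sprintf("%s = %d", eqtl_counts$population,
                          eqtl_counts$n_egenes), collapse = ", ")),
    sprintf("Mean rG (all converged genes): %s.",
            paste(sprintf("%s = %.2f", rg_means$pop_pair[rg_means$threshold == 0],
                          rg_means$mean_rg[rg_means$threshold == 0]),
                  collapse = ", "))
  )
  list(eqtl_counts = eqtl_counts, rg_means = rg_means,
       alpha_comparison = alpha_comparison, transfer_pi1 = transfer_pi1,
       divergence_tests = divergence_tests,
       narrative = paste(narrative, collapse = "\n"))
}
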