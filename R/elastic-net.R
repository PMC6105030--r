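# Per-gene elastic-net expression prediction: penalized fits via glmnet,
# the nested cross-validation protocol used to score models honestly,
# portable weight tables, allele harmonization into a test cohort, and
# transfer evaluation by per-gene Pearson correlation and pi1.

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop(paste("`alpha` must lie in (0, 1]; ridge (alpha = 0) has an",
               "unbounded lambda_max - use a small positive alpha instead"),
         call. = FALSE)
  }
  alpha
}

#' Elastic-net fit at a fixed penalty
#'
#' Minimizes `(1/2n) sum((y - b0 - X w)^2) + lambda (alpha ||w||_1 +
#' (1 - alpha) ||w||_2^2 / 2)` by glmnet's cyclic coordinate descent, at a
#' single `lambda`. With `standardize = FALSE` the objective is exactly as
#' written; with `standardize = TRUE` (glmnet's convention) predictors are
#' standardized internally and weights are returned on the original scale.
#'
#' @param y Response vector.
#' @param X Predictor (dosage) matrix.
#' @param alpha Mixing parameter in (0, 1].
#' @param lambda Penalty strength (single value).
#' @param standardize Standardize columns internally (default `TRUE`).
#' @return List with `intercept`, `weights` (named, full length), `lambda`.
#' @export
fit_elastic_net <- function(y, X, alpha, lambda, standardize = TRUE) {
  check_alpha(alpha)
  if (stats::var(y) == 0) {
    stop("response has zero variance", call. = FALSE)
  }
  # glmnet internally standardizes y (1/n sd), which scales its effective
  # ridge - but not lasso - penalty by 1/sd(y) relative to the objective
  # stated above; reparametrize (lambda, alpha) so the stated objective is
  # minimized exactly.
  sy <- sqrt(mean((y - mean(y))^2))
  lg <- lambda * alpha + sy * lambda * (1 - alpha)
  ag <- if (lg > 0) lambda * alpha / lg else 1
  fit <- glmnet::glmnet(X, y, alpha = ag, lambda = lg,
                        standardize = standardize, thresh = 1e-14,
                        maxit = 1e7)
  co <- as.numeric(stats::coef(fit, s = lg))
  list(intercept = co[1],
       weights = stats::setNames(co[-1], colnames(X)),
       lambda = lambda)
}

#' Elastic net with inner cross-validated penalty selection
#'
#' Fits the elastic net along a geometric lambda path (100 values spanning
#' three orders of magnitude down from the smallest lambda that zeroes all
#' weights) and selects the lambda minimizing the mean `inner_folds`-fold
#' cross-validated squared error. Fold assignment is deterministic under
#' `seed`.
#'
#' @inheritParams fit_elastic_net
#' @param inner_folds Number of CV folds for lambda selection (default 10).
#' @param seed Integer seed for fold assignment.
#' @param lambda_path Optional fixed lambda sequence (shared across outer
#'   folds of a gene for stability).
#' @return List with `intercept`, `weights` (named, full length),
#'   `lambda_selected`, `lambda_path`.
#' @export
fit_elastic_net_cv <- function(y, X, alpha, inner_folds = 10L, seed,
                               standardize = TRUE, lambda_path = NULL) {
  check_alpha(alpha)
  if (stats::var(y) == 0) {
    stop("response has zero variance", call. = FALSE)
  }
  n <- length(y)
  if (n < inner_folds) {
    stop("need at least `inner_folds` observations", call. = FALSE)
  }
  if (is.null(lambda_path)) {
    lambda_path <- glmnet::glmnet(X, y, alpha = alpha, nlambda = 100,
                                  lambda.min.ratio = 1e-3,
                                  standardize = standardize)$lambda
  }
  foldid <- with_seed(seed, sample(rep_len(seq_len(inner_folds), n)))
  sse <- matrix(NA_real_, inner_folds, length(lambda_path))
  for (k in seq_len(inner_folds)) {
    hold <- foldid == k
    fit_k <- glmnet::glmnet(X[!hold, , drop = FALSE], y[!hold],
                            alpha = alpha, lambda = lambda_path,
                            standardize = standardize)
    pred <- stats::predict(fit_k, X[hold, , drop = FALSE])
    # a fold fit may stop early on the path; score the lambdas it reached
    got <- match(signif(fit_k$lambda, 10), signif(lambda_path, 10))
    sse[k, got] <- colSums((pred - y[hold])^2)
  }
  mse <- colSums(sse, na.rm = FALSE) / n
  usable <- which(!is.na(mse))
  if (!length(usable)) {
    usable <- which(!is.na(colMeans(sse, na.rm = TRUE)))
    mse <- colMeans(sse, na.rm = TRUE)
  }
  lambda_min <- lambda_path[usable[which.min(mse[usable])]]
  final <- glmnet::glmnet(X, y, alpha = alpha, lambda = lambda_path,
                          standardize = standardize)
  co <- as.numeric(stats::coef(final, s = lambda_min, exact = FALSE))
  list(intercept = co[1],
       weights = stats::setNames(co[-1], colnames(X)),
       lambda_selected = lambda_min,
       lambda_path = lambda_path)
}

#' Nested cross-validated predictive performance
#'
#' Splits the samples into `outer_folds` disjoint folds of roughly equal
#' size; for each fold, fits [fit_elastic_net_cv()] on the complement and
#' predicts the held-out fold. The per-fold score is
#' `R2 = 1 - sum((y_o - y_p)^2) / sum((y_o - mean(y_o))^2)` against the
#' held-out observations (it may be negative), and the reported performance
#' is the mean over folds. A fold whose held-out expression has zero
#' variance has undefined R2 and is excluded with a notice.
#'
#' @inheritParams fit_elastic_net_cv
#' @param outer_folds Number of outer folds (default 5).
#' @return List with `r2` (mean over folds), `fold_r2`, `alpha`,
#'   `outer_folds`.
#' @export
nested_cv_performance <- function(y, X, alpha, outer_folds = 5L,
                                  inner_folds = 10L, seed,
                                  standardize = TRUE) {
  check_alpha(alpha)
  n <- length(y)
  outer_folds <- as.integer(outer_folds)
  if (outer_folds < 2L || n < 2L * outer_folds) {
    stop("need `outer_folds` >= 2 and n >= 2 * outer_folds", call. = FALSE)
  }
  fold <- with_seed(seed, sample(rep_len(seq_len(outer_folds), n)))
  lambda_path <- glmnet::glmnet(X, y, alpha = alpha, nlambda = 100,
                                lambda.min.ratio = 1e-3,
                                standardize = standardize)$lambda
  fold_r2 <- vapply(seq_len(outer_folds), function(k) {
    test <- fold == k
    y_tr <- y[!test]
    if (stats::var(y[test]) == 0) {
      message(sprintf("outer fold %d: held-out expression has zero variance, excluded", k))
      return(NA_real_)
    }
    fit <- fit_elastic_net_cv(y_tr, X[!test, , drop = FALSE], alpha,
                              inner_folds = inner_folds,
                              seed = derive_seed(seed, sprintf("inner%d", k)),
                              standardize = standardize,
                              lambda_path = lambda_path)
    y_hat <- fit$intercept + drop(X[test, , drop = FALSE] %*% fit$weights)
    1 - sum((y[test] - y_hat)^2) / sum((y[test] - mean(y[test]))^2)
  }, 0)
  list(r2 = mean(fold_r2, na.rm = TRUE), fold_r2 = fold_r2,
       alpha = alpha, outer_folds = outer_folds)
}

#' Train per-gene elastic-net prediction models
#'
#' For each gene and mixing parameter: expression is residualized on the
#' covariates (hidden factors and genotype PCs are adjusted for, not
#' penalized), nested cross-validation scores the architecture, and a
#' final inner-CV fit on all samples provides the deployable weights (its
#' nonzero coefficients). Genes without testable cis SNPs are skipped with
#' a notice.
#'
#' @param expression An [expression_panel()].
#' @param genotypes A [genotype_matrix()], identical sample order.
#' @param covariates Optional [covariate_set()].
#' @param alpha_grid Mixing parameters (default `c(0.05, 0.5, 1)`).
#' @param window_bp cis window half-width (default 1e6).
#' @param maf_min MAF threshold, exclusive (default 0.01).
#' @param seed Integer seed.
#' @param population Label stored with the models.
#' @param outer_folds,inner_folds Nested-CV fold counts (defaults 5, 10).
#' @return A `prediction_models` object: list with `weights` (tibble:
#'   `gene_id`, `alpha`, `snp_id`, `chromosome`, `position`,
#'   `effect_allele`, `other_allele`, `beta`, `training_freq`),
#'   `performance` (tibble: `gene_id`, `alpha`, `r2`, `n_snps_in_model`,
#'   `lambda_selected`, `intercept`), `genes` annotation, `population`.
#' @export
train_gene_models <- function(expression, genotypes, covariates = NULL,
                              alpha_grid = c(0.05, 0.5, 1), window_bp = 1e6,
                              maf_min = 0.01, seed = 1L,
                              population = "train",
                              outer_folds = 5L, inner_folds = 10L) {
  stopifnot(inherits(expression, "expression_panel"),
            inherits(genotypes, "genotype_matrix"))
  if (!identical(expression$samples, genotypes$samples)) {
    stop("expression and genotype samples must be identical and identically ordered",
         call. = FALSE)
  }
  vapply(alpha_grid, check_alpha, 0)
  y_res <- residualize(expression$values,
                       covariate_matrix(covariates, expression$samples))
  p_alt <- colMeans(genotypes$dosages) / 2
  testable <- pmin(p_alt, 1 - p_alt) > maf_min &
    apply(genotypes$dosages, 2L, stats::sd) > 0

  weights_list <- list()
  perf_list <- list()
  for (gi in seq_len(nrow(expression$genes))) {
    ann <- expression$genes[gi, ]
    ids <- cis_snp_ids(genotypes$snps, ann$chromosome, ann$tss, window_bp)
    idx <- match(ids, genotypes$snps$snp_id)
    idx <- idx[testable[idx]]
    if (length(idx) < 2L) {
      message(sprintf("gene %s: fewer than 2 testable cis SNPs, skipped",
                      ann$gene_id))
      next
    }
    X <- genotypes$dosages[, idx, drop = FALSE]
    yv <- y_res[, gi]
    if (stats::var(yv) == 0) {
      message(sprintf("gene %s: zero expression variance, skipped", ann$gene_id))
      next
    }
    for (alpha in alpha_grid) {
      gseed <- derive_seed(seed, sprintf("%s_a%s", ann$gene_id, alpha))
      perf <- nested_cv_performance(yv, X, alpha, outer_folds = outer_folds,
                                    inner_folds = inner_folds, seed = gseed)
      final <- fit_elastic_net_cv(yv, X, alpha, inner_folds = inner_folds,
                                  seed = derive_seed(gseed, "final"))
      nz <- which(final$weights != 0)
      perf_list[[length(perf_list) + 1L]] <- tibble::tibble(
        gene_id = ann$gene_id, alpha = alpha, r2 = perf$r2,
        n_snps_in_model = length(nz),
        lambda_selected = final$lambda_selected,
        intercept = final$intercept
      )
      if (length(nz)) {
        widx <- idx[nz]
        weights_list[[length(weights_list) + 1L]] <- tibble::tibble(
          gene_id = ann$gene_id, alpha = alpha,
          snp_id = genotypes$snps$snp_id[widx],
          chromosome = genotypes$snps$chromosome[widx],
          position = genotypes$snps$position[widx],
          effect_allele = genotypes$snps$alt_allele[widx],
          other_allele = genotypes$snps$ref_allele[widx],
          beta = unname(final$weights[nz]),
          training_freq = unname(p_alt[widx])
        )
      }
    }
  }
  structure(
    list(
      weights = dplyr::bind_rows(weights_list),
      performance = dplyr::bind_rows(perf_list),
      genes = expression$genes,
      population = population,
      alpha_grid = alpha_grid
    ),
    class = "prediction_models"
  )
}

#' @export
print.prediction_models <- function(x, ...) {
  cat(sprintf("<prediction_models> %s: %d gene(s) x alpha {%s}, %d weight rows\n",
              x$population, dplyr::n_distinct(x$performance$gene_id),
              paste(x$alpha_grid, collapse = ", "), nrow(x$weights)))
  invisible(x)
}

is_strand_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize model alleles into a test cohort and predict expression
#'
#' Model SNPs are matched to test SNPs by chromosome and position. An
#' exact allele match uses the test dosage as-is; swapped ref/alt alleles
#' flip the dosage to `2 - d`; strand-ambiguous (A/T, C/G) test SNPs are
#' excluded from matching. Unmatched model SNPs are handled by
#' `missing_policy`: `"freq_impute"` (default) substitutes the constant
#' `2 x` training effect-allele frequency, `"drop"` removes the SNP (a
#' gene with every SNP unmatched under `"drop"` is omitted and listed in
#' the `dropped_genes` attribute). The prediction is
#' `intercept + sum(beta * harmonized dosage)`.
#'
#' @param models A `prediction_models` object (or one filtered with
#'   [filter_models_alpha()]).
#' @param test_genotypes A [genotype_matrix()] for the test cohort.
#' @param missing_policy `"freq_impute"` or `"drop"`.
#' @param alpha Which mixing parameter's models to use (default: the
#'   single alpha present, else required).
#' @return An [expression_panel()] of predicted expression (attribute
#'   `dropped_genes` lists genes omitted under `"drop"`).
#' @export
harmonize_and_predict <- function(models, test_genotypes,
                                  missing_policy = c("freq_impute", "drop"),
                                  alpha = NULL) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(models, "prediction_models"),
            inherits(test_genotypes, "genotype_matrix"))
  w <- models$weights
  if (is.null(alpha)) {
    alphas <- unique(w$alpha)
    if (length(alphas) > 1L) {
      stop("models contain several alphas; pass `alpha =`", call. = FALSE)
    }
    alpha <- alphas
  }
  w <- w[w$alpha == alpha, ]
  perf <- models$performance[models$performance$alpha == alpha, ]
  test_snps <- test_genotypes$snps
  ambiguous <- is_strand_ambiguous(test_snps$ref_allele, test_snps$alt_allele)
  key_test <- paste(test_snps$chromosome, test_snps$position, sep = ":")
  key_model <- paste(w$chromosome, w$position, sep = ":")
  pos <- match(key_model, key_test)
  # classify each weight row
  status <- rep("missing", nrow(w))
  dosage_col <- rep(NA_integer_, nrow(w))
  flip <- rep(FALSE, nrow(w))
  hit <- !is.na(pos)
  for (j in which(hit)) {
    tj <- pos[j]
    if (ambiguous[tj]) next
    if (w$effect_allele[j] == test_snps$alt_allele[tj] &&
        w$other_allele[j] == test_snps$ref_allele[tj]) {
      status[j] <- "match"; dosage_col[j] <- tj
    } else if (w$effect_allele[j] == test_snps$ref_allele[tj] &&
               w$other_allele[j] == test_snps$alt_allele[tj]) {
      status[j] <- "swap"; dosage_col[j] <- tj; flip[j] <- TRUE
    }
  }
  n <- length(test_genotypes$samples)
  gene_ids <- unique(perf$gene_id)
  dropped <- character(0)
  pred_cols <- list()
  for (gid in gene_ids) {
    rows <- which(w$gene_id == gid)
    b0 <- perf$intercept[perf$gene_id == gid][1]
    if (!length(rows)) {
      # zero-weight model: constant prediction at the intercept
      pred_cols[[gid]] <- rep(b0, n)
      next
    }
    contrib <- rep(b0, n)
    used <- 0L
    for (j in rows) {
      if (status[j] == "missing") {
        if (missing_policy == "drop") next
        d <- rep(2 * w$training_freq[j], n)
      } else {
        d <- test_genotypes$dosages[, dosage_col[j]]
        if (flip[j]) d <- 2 - d
      }
      contrib <- contrib + w$beta[j] * d
      used <- used + 1L
    }
    if (used == 0L && missing_policy == "drop") {
      dropped <- c(dropped, gid)
      next
    }
    pred_cols[[gid]] <- contrib
  }
  if (length(dropped)) {
    message(sprintf("omitting %d gene(s) with no mappable SNPs under 'drop': %s",
                    length(dropped),
                    paste(utils::head(dropped, 5), collapse = ", ")))
  }
  keep_genes <- setdiff(gene_ids, dropped)
  vals <- if (length(keep_genes)) {
    do.call(cbind, pred_cols[keep_genes])
  } else {
    matrix(numeric(0), nrow = n, ncol = 0)
  }
  genes_tbl <- models$genes[match(keep_genes, models$genes$gene_id), ]
  out <- expression_panel(vals, genes_tbl, test_genotypes$samples)
  attr(out, "dropped_genes") <- dropped
  out
}

#' Evaluate cross-cohort prediction transfer
#'
#' Computes the per-gene Pearson correlation (and two-sided p-value)
#' between predicted and observed expression over the shared samples, then
#' summarises replication as pi1 over the genes whose training nested-CV
#' R2 meets each inclusion threshold. Genes with constant predictions have
#' undefined correlation and are excluded with a notice; a threshold
#' retaining fewer than 10 genes reports `pi1 = NA` with a warning.
#'
#' @param predicted,observed [expression_panel()] objects sharing genes
#'   and samples.
#' @param training_performance Performance tibble from
#'   [train_gene_models()] (columns `gene_id`, `r2`), already filtered to
#'   one alpha.
#' @param r2_thresholds Inclusion thresholds (default
#'   `c(0, 0.01, 0.05, 0.1, 0.2)`).
#' @param training_population,test_cohort Labels stored in the result.
#' @return A `transfer_evaluation` object: list with `correlations`
#'   (tibble: `gene_id`, `r`, `p_value`, `training_r2`) and `pi1` (tibble:
#'   `r2_threshold`, `n_genes`, `pi1`, `pi0`).
#' @export
evaluate_transfer <- function(predicted, observed, training_performance,
                              r2_thresholds = c(0, 0.01, 0.05, 0.1, 0.2),
                              training_population = "train",
                              test_cohort = "test") {
  stopifnot(inherits(predicted, "expression_panel"),
            inherits(observed, "expression_panel"))
  shared_genes <- intersect(predicted$genes$gene_id, observed$genes$gene_id)
  shared_samples <- intersect(predicted$samples, observed$samples)
  if (!length(shared_genes) || !length(shared_samples)) {
    stop("predicted and observed panels share no genes or no samples",
         call. = FALSE)
  }
  ip <- match(shared_samples, predicted$samples)
  io <- match(shared_samples, observed$samples)
  cors <- purrr::map_dfr(shared_genes, function(gid) {
    yp <- predicted$values[ip, gid]
    yo <- observed$values[io, gid]
    if (stats::sd(yp) == 0 || stats::sd(yo) == 0) {
      return(tibble::tibble(gene_id = gid, r = NA_real_, p_value = NA_real_))
    }
    ct <- stats::cor.test(yp, yo)
    tibble::tibble(gene_id = gid, r = unname(ct$estimate),
                   p_value = ct$p.value)
  })
  n_const <- sum(is.na(cors$r))
  if (n_const) {
    message(sprintf("%d gene(s) with constant predictions excluded", n_const))
  }
  cors <- dplyr::left_join(
    cors, training_performance[c("gene_id", "r2")], by = "gene_id"
  )
  names(cors)[names(cors) == "r2"] <- "training_r2"
  pi1_tbl <- purrr::map_dfr(r2_thresholds, function(t) {
    keep <- !is.na(cors$p_value) & !is.na(cors$training_r2) &
      cors$training_r2 >= t
    n <- sum(keep)
    if (n < 10L) {
      warning(sprintf("r2 threshold %.3g: only %d gene(s), pi1 not estimated",
                      t, n))
      return(tibble::tibble(r2_threshold = t, n_genes = n,
                            pi1 = NA_real_, pi0 = NA_real_))
    }
    est <- estimate_pi0(cors$p_value[keep])
    tibble::tibble(r2_threshold = t, n_genes = n, pi1 = est$pi1,
                   pi0 = est$pi0)
  })
  structure(
    list(correlations = cors, pi1 = pi1_tbl,
         training_population = training_population,
         test_cohort = test_cohort),
    class = "transfer_evaluation"
  )
}

#' @export
print.transfer_evaluation <- function(x, ...) {
  cat(sprintf("<transfer_evaluation> %s -> %s: %d gene(s)\n",
              x$training_population, x$test_cohort, nrow(x$correlations)))
  print(x$pi1)
  invisible(x)
}

#' Compare predictive performance between mixing parameters
#'
#' For each ordered pair of mixing parameters (sparser alpha first), counts
#' the genes - among those scored under both - whose nested-CV R2 is
#' strictly greater under the sparser model, and summarises the per-gene R2
#' difference distribution.
#'
#' @param performance Performance tibble from [train_gene_models()]
#'   (columns `gene_id`, `alpha`, `r2`).
#' @return A tibble with one row per alpha pair: `alpha_sparse`,
#'   `alpha_other`, `n_genes`, `n_sparse_better`, `proportion`,
#'   `mean_r2_diff`, `median_r2_diff`.
#' @export
compare_alpha_performance <- function(performance) {
  alphas <- sort(unique(performance$alpha), decreasing = TRUE)
  if (length(alphas) < 2L) {
    stop("need at least two alphas to compare", call. = FALSE)
  }
  pairs <- utils::combn(alphas, 2L)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a_hi <- pairs[1, k]; a_lo <- pairs[2, k]
    hi <- performance[performance$alpha == a_hi, c("gene_id", "r2")]
    lo <- performance[performance$alpha == a_lo, c("gene_id", "r2")]
    both <- dplyr::inner_join(hi, lo, by = "gene_id",
                              suffix = c("_sparse", "_other"))
    both <- both[stats::complete.cases(both), ]
    if (!nrow(both)) {
      stop("empty gene intersection between alphas", call. = FALSE)
    }
    diff <- both$r2_sparse - both$r2_other
    tibble::tibble(
      alpha_sparse = a_hi, alpha_other = a_lo, n_genes = nrow(both),
      n_sparse_better = sum(diff > 0), proportion = mean(diff > 0),
      mean_r2_diff = mean(diff), median_r2_diff = stats::median(diff)
    )
  })
}

#' Keep one mixing parameter's models
#'
#' @param models A `prediction_models` object.
#' @param alpha The alpha to retain.
#' @return A `prediction_models` object restricted to `alpha`.
#' @export
filter_models_alpha <- function(models, alpha) {
  stopifnot(inherits(models, "prediction_models"))
  models$weights <- models$weights[models$weights$alpha == alpha, ]
  models$performance <- models$performance[models$performance$alpha == alpha, ]
  models$alpha_grid <- alpha
  models
}
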