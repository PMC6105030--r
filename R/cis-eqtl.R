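# cis-eQTL mapping: LD pruning, genotype PCs, hidden expression factors,
# per-SNP ordinary least squares within the cis window, and
# Benjamini-Hochberg FDR over all tests in a run.

#' SNP ids inside a gene's cis window
#'
#' The cis window is the closed interval `[tss - window_bp, tss + window_bp]`
#' on the gene's chromosome (1-based coordinates; strand ignored).
#'
#' @param snps SNP metadata tibble (`snp_id`, `chromosome`, `position`).
#' @param chromosome Gene chromosome.
#' @param tss 1-based transcription start site.
#' @param window_bp Half-width in base pairs (default 1e6).
#' @return Character vector of SNP ids.
#' @export
cis_snp_ids <- function(snps, chromosome, tss, window_bp = 1e6) {
  snps$snp_id[snps$chromosome == chromosome &
                abs(snps$position - tss) <= window_bp]
}

#' Greedy LD pruning in a sliding SNP window
#'
#' Walks each chromosome in position order keeping a window of the last
#' `window` retained SNPs; a new SNP whose squared Pearson correlation with
#' any retained SNP in the window exceeds `r2_threshold` is removed (the
#' later SNP of the offending pair). Monomorphic SNPs have undefined
#' correlation; they are skipped in the r2 computation and always kept.
#'
#' @param genotypes A [genotype_matrix()].
#' @param window Window size in SNP count (>= 2, default 50).
#' @param r2_threshold Squared-correlation threshold (default 0.3).
#' @return Character vector of retained SNP ids, in position order.
#' @export
ld_prune <- function(genotypes, window = 50L, r2_threshold = 0.3) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  window <- as.integer(window)
  if (is.na(window) || window < 2L) {
    stop("`window` must be >= 2 SNPs", call. = FALSE)
  }
  snps <- genotypes$snps
  dos <- genotypes$dosages
  sds <- apply(dos, 2L, stats::sd)
  kept <- character(0)
  for (chrom in unique(snps$chromosome)) {
    idx <- which(snps$chromosome == chrom)
    idx <- idx[order(snps$position[idx])]
    kept_chr <- integer(0)
    for (j in idx) {
      if (sds[j] == 0) {
        kept_chr <- c(kept_chr, j)  # monomorphic: always kept
        next
      }
      win <- kept_chr[sds[kept_chr] > 0]
      win <- utils::tail(win, window - 1L)
      drop_j <- FALSE
      if (length(win)) {
        r2 <- drop(stats::cor(dos[, j], dos[, win, drop = FALSE]))^2
        drop_j <- any(r2 > r2_threshold)
      }
      if (!drop_j) {
        kept_chr <- c(kept_chr, j)
      }
    }
    kept <- c(kept, snps$snp_id[kept_chr])
  }
  kept
}

#' Genotype principal components
#'
#' PCs are the unit-norm eigenvectors of the sample-sample covariance of
#' column-standardized dosages, ordered by decreasing eigenvalue (the
#' classic EIGENSTRAT-style decomposition). Genotypes should be LD-pruned
#' first. Monomorphic SNPs are dropped before standardization.
#'
#' @param genotypes A [genotype_matrix()].
#' @param n_pcs Number of components, `0 <= n_pcs < min(n_samples, n_snps)`.
#' @return A [covariate_set()] with columns `PC1 ... PCk` (empty when
#'   `n_pcs = 0`).
#' @export
genotype_pcs <- function(genotypes, n_pcs) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  n_pcs <- as.integer(n_pcs)
  if (n_pcs == 0L) {
    return(covariate_set(genotypes$samples))
  }
  poly <- apply(genotypes$dosages, 2L, stats::sd) > 0
  W <- standardize_columns(genotypes$dosages[, poly, drop = FALSE])
  if (n_pcs >= min(nrow(W), ncol(W))) {
    stop(sprintf("`n_pcs` must be < min(n_samples, n_snps) = %d",
                 min(nrow(W), ncol(W))), call. = FALSE)
  }
  sv <- svd(W, nu = n_pcs, nv = 0)
  cols <- stats::setNames(
    lapply(seq_len(n_pcs), function(k) sv$u[, k]),
    paste0("PC", seq_len(n_pcs))
  )
  do.call(covariate_set, c(list(samples = genotypes$samples), cols))
}

#' Hidden expression factors by residualized PCA
#'
#' A variance-capturing stand-in for latent-confounder estimators such as
#' PEER: the expression matrix is residualized on the protected covariates
#' (so factors cannot re-absorb them), then its top principal components
#' (unit-norm sample scores, ordered by variance explained) are returned as
#' factors.
#'
#' @param expression An [expression_panel()].
#' @param n_factors Number of factors, `0 <= n_factors < n_samples`.
#' @param protect Optional [covariate_set()] to residualize on first
#'   (e.g. genotype PCs).
#' @return A [covariate_set()] with columns `factor1 ... factork`.
#' @export
hidden_expression_factors <- function(expression, n_factors, protect = NULL) {
  stopifnot(inherits(expression, "expression_panel"))
  n_factors <- as.integer(n_factors)
  if (n_factors == 0L) {
    return(covariate_set(expression$samples))
  }
  if (n_factors >= length(expression$samples)) {
    stop("`n_factors` must be < n_samples", call. = FALSE)
  }
  resid <- residualize(expression$values,
                       covariate_matrix(protect, expression$samples))
  sv <- svd(resid, nu = n_factors, nv = 0)
  cols <- stats::setNames(
    lapply(seq_len(n_factors), function(k) sv$u[, k]),
    paste0("factor", seq_len(n_factors))
  )
  do.call(covariate_set, c(list(samples = expression$samples), cols))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment with monotonicity enforcement (ties share an
#' adjusted value); a thin validating wrapper over
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p_values Numeric vector in (0, 1]; may be empty.
#' @return Adjusted values, same length and order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (!length(p_values)) {
    return(numeric(0))
  }
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Map cis-eQTLs by per-SNP ordinary least squares
#'
#' For every gene, tests each SNP with within-population MAF strictly above
#' `maf_min` and position within `window_bp` of the TSS, regressing
#' expression on dosage plus covariates. Reports the per-alt-allele effect,
#' its standard error, the t statistic and two-sided p-value, and the BH
#' FDR computed over all SNP-gene tests in the run (`fdr_scope = "global"`,
#' the default) or within each gene (`"per_gene"`).
#'
#' Covariates are projected out of both expression and dosages once, which
#' is algebraically identical to including them in each per-SNP regression;
#' the residual degrees of freedom are `n - 2 - n_covariates`.
#'
#' @param expression An [expression_panel()].
#' @param genotypes A [genotype_matrix()] with identical sample order.
#' @param covariates Optional [covariate_set()].
#' @param window_bp cis window half-width (default 1e6).
#' @param maf_min Within-population MAF threshold, exclusive (default 0.01).
#' @param fdr_scope `"global"` or `"per_gene"`.
#' @return A tibble: `gene_id`, `snp_id`, `chromosome`, `position`,
#'   `ref_allele`, `alt_allele`, `beta`, `se`, `t_stat`, `p_value`, `fdr`.
#' @export
map_cis_eqtls <- function(expression, genotypes, covariates = NULL,
                          window_bp = 1e6, maf_min = 0.01,
                          fdr_scope = c("global", "per_gene")) {
  fdr_scope <- match.arg(fdr_scope)
  stopifnot(inherits(expression, "expression_panel"),
            inherits(genotypes, "genotype_matrix"))
  if (!identical(expression$samples, genotypes$samples)) {
    stop("expression and genotype samples must be identical and identically ordered",
         call. = FALSE)
  }
  n <- length(expression$samples)
  cov_mat <- covariate_matrix(covariates, expression$samples)
  k <- if (is.null(cov_mat)) 0L else ncol(cov_mat)
  df <- n - 2L - k
  if (df < 1L) {
    stop("not enough residual degrees of freedom", call. = FALSE)
  }
  p_alt <- colMeans(genotypes$dosages) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  testable <- maf > maf_min & apply(genotypes$dosages, 2L, stats::sd) > 0

  y_res <- residualize(expression$values, cov_mat)
  x_res <- residualize(genotypes$dosages, cov_mat)
  xtx <- colSums(x_res^2)

  res <- purrr::map_dfr(seq_len(nrow(expression$genes)), function(gi) {
    ann <- expression$genes[gi, ]
    ids <- cis_snp_ids(genotypes$snps, ann$chromosome, ann$tss, window_bp)
    idx <- match(ids, genotypes$snps$snp_id)
    idx <- idx[testable[idx]]
    if (!length(idx)) {
      message(sprintf("gene %s: no testable cis SNPs, skipped", ann$gene_id))
      return(tibble::tibble())
    }
    yv <- y_res[, gi]
    xty <- drop(crossprod(x_res[, idx, drop = FALSE], yv))
    beta <- xty / xtx[idx]
    sse <- sum(yv^2) - beta * xty
    sigma2 <- pmax(sse, 0) / df
    se <- sqrt(sigma2 / xtx[idx])
    t_stat <- beta / se
    p <- 2 * stats::pt(-abs(t_stat), df)
    tibble::tibble(
      gene_id = ann$gene_id,
      snp_id = genotypes$snps$snp_id[idx],
      chromosome = genotypes$snps$chromosome[idx],
      position = genotypes$snps$position[idx],
      ref_allele = genotypes$snps$ref_allele[idx],
      alt_allele = genotypes$snps$alt_allele[idx],
      beta = beta, se = se, t_stat = t_stat,
      p_value = pmax(p, .Machine$double.xmin)
    )
  })
  if (!nrow(res)) {
    return(dplyr::mutate(res, fdr = numeric(0)))
  }
  if (fdr_scope == "global") {
    res$fdr <- bh_fdr(res$p_value)
  } else {
    res <- dplyr::mutate(dplyr::group_by(res, .data$gene_id),
                         fdr = bh_fdr(.data$p_value))
    res <- dplyr::ungroup(res)
  }
  res
}

#' Count eSNPs and eGenes at an FDR threshold
#'
#' @param associations Tibble from [map_cis_eqtls()] (must carry `fdr`).
#' @param fdr_threshold Significance threshold (default 0.05).
#' @param population Optional label recorded in the output.
#' @return A one-row tibble: `population`, `n_esnps` (distinct SNPs in any
#'   passing pair), `n_egenes` (distinct genes with >= 1 passing pair),
#'   `fdr_threshold`.
#' @export
summarize_eqtls <- function(associations, fdr_threshold = 0.05,
                            population = NA_character_) {
  stopifnot("fdr" %in% names(associations))
  pass <- associations[associations$fdr < fdr_threshold, ]
  tibble::tibble(
    population = population,
    n_esnps = dplyr::n_distinct(pass$snp_id),
    n_egenes = dplyr::n_distinct(pass$gene_id),
    fdr_threshold = fdr_threshold
  )
}
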