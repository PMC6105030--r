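# Two-population differentiation: per-SNP Weir-Cockerham FST, per-model
# mean and beta-weighted summaries, and the divergent-vs-similar Wilcoxon
# threshold sweep that ties transfer failure to allele-frequency divergence.

# Weir & Cockerham (1984) variance components for one biallelic SNP across
# r = 2 populations, from allele frequencies, sample sizes and observed
# heterozygote frequencies.
wc_components <- function(n_i, p_i, h_i) {
  r <- length(n_i)
  n_bar <- mean(n_i)
  nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
  p_bar <- sum(n_i * p_i) / sum(n_i)
  s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- sum(n_i * h_i) / sum(n_i)
  a <- (n_bar / nc) *
    (s2 - (1 / (n_bar - 1)) *
       (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 -
       ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  c_ <- h_bar / 2
  list(a = a, b = b, c = c_)
}

#' Per-SNP Weir-Cockerham fixation index between two populations
#'
#' Computes the Weir & Cockerham (1984) two-population estimator
#' `theta = a / (a + b + c)` from dosage-derived allele and heterozygote
#' counts. Slightly negative estimates are expected under no
#' differentiation. SNPs monomorphic in the pooled sample have an
#' undefined estimator and are returned with `fst = NA` and flagged.
#'
#' @param genotypes_pop1,genotypes_pop2 [genotype_matrix()] objects for the
#'   two populations (hard-call dosages; heterozygotes counted as
#'   dosage == 1).
#' @param snp_ids SNPs to evaluate; default all SNPs shared by both.
#' @param hudson Logical; if `TRUE` use the Hudson estimator
#'   (`1 - Hw/Hb` form via frequency differences) instead of
#'   Weir-Cockerham, for sensitivity analysis.
#' @return A tibble: `snp_id`, `fst`, `n1`, `n2`, `p1`, `p2`,
#'   `monomorphic`.
#' @export
weir_cockerham_fst <- function(genotypes_pop1, genotypes_pop2, snp_ids = NULL,
                               hudson = FALSE) {
  stopifnot(inherits(genotypes_pop1, "genotype_matrix"),
            inherits(genotypes_pop2, "genotype_matrix"))
  if (is.null(snp_ids)) {
    snp_ids <- intersect(genotypes_pop1$snps$snp_id, genotypes_pop2$snps$snp_id)
  }
  i1 <- match(snp_ids, genotypes_pop1$snps$snp_id)
  i2 <- match(snp_ids, genotypes_pop2$snps$snp_id)
  if (anyNA(i1) || anyNA(i2)) {
    bad <- snp_ids[is.na(i1) | is.na(i2)]
    stop(sprintf("SNP absent from a population: %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  d1 <- genotypes_pop1$dosages[, i1, drop = FALSE]
  d2 <- genotypes_pop2$dosages[, i2, drop = FALSE]
  n1 <- nrow(d1); n2 <- nrow(d2)
  p1 <- colMeans(d1) / 2
  p2 <- colMeans(d2) / 2
  h1 <- colMeans(abs(d1 - 1) < 1e-9)
  h2 <- colMeans(abs(d2 - 1) < 1e-9)
  p_pool <- (n1 * p1 + n2 * p2) / (n1 + n2)
  mono <- p_pool <= 0 | p_pool >= 1
  num <- rep(NA_real_, length(snp_ids))
  den <- rep(NA_real_, length(snp_ids))
  if (hudson) {
    hn <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    hd <- p1 * (1 - p2) + p2 * (1 - p1)
    num[!mono] <- hn[!mono]
    den[!mono] <- hd[!mono]
  } else {
    for (j in which(!mono)) {
      comp <- wc_components(c(n1, n2), c(p1[j], p2[j]), c(h1[j], h2[j]))
      num[j] <- comp$a
      den[j] <- comp$a + comp$b + comp$c
    }
  }
  tibble::tibble(
    snp_id = snp_ids, fst = unname(num / den),
    fst_num = unname(num), fst_den = unname(den),
    n1 = n1, n2 = n2, p1 = unname(p1), p2 = unname(p2),
    monomorphic = unname(mono)
  )
}

#' Multi-locus FST as the ratio of summed variance components
#'
#' The Weir-Cockerham multi-locus estimator `sum(a) / sum(a + b + c)`
#' over a SNP set. Unlike the mean of per-SNP ratios - which is biased
#' downward by Jensen's inequality - this estimator is unbiased for the
#' generative divergence, and is the standard genome-wide summary.
#'
#' @param fst_records Tibble from [weir_cockerham_fst()].
#' @return A single number.
#' @export
fst_multilocus <- function(fst_records) {
  ok <- !is.na(fst_records$fst_num)
  sum(fst_records$fst_num[ok]) / sum(fst_records$fst_den[ok])
}

#' Per-model mean and beta-weighted FST
#'
#' For a prediction model's SNP set, returns the unweighted mean FST and
#' the beta-weighted summary in which each SNP's FST is multiplied by its
#' model effect size before averaging, so large-effect SNPs dominate.
#' Because signed products can cancel, an absolute-beta normalised variant
#' (`sum(|beta| fst) / sum(|beta|)`) is available via `weight_type`.
#'
#' @param model Tibble of model weights with columns `snp_id`, `beta`
#'   (one gene's rows of a [train_gene_models()] weight table).
#' @param fst_records Tibble from [weir_cockerham_fst()].
#' @param weight_type `"signed"` (multiply by beta, then average; default)
#'   or `"abs"` (absolute-beta weighted mean).
#' @return A one-row tibble: `n_snps`, `mean_fst`, `weighted_fst`.
#' @export
model_fst_summary <- function(model, fst_records, weight_type = c("signed", "abs")) {
  weight_type <- match.arg(weight_type)
  if (!nrow(model)) {
    stop("empty model: no SNPs to summarise", call. = FALSE)
  }
  idx <- match(model$snp_id, fst_records$snp_id)
  if (anyNA(idx)) {
    stop(sprintf("no FST record for SNPs: %s",
                 paste(utils::head(model$snp_id[is.na(idx)], 5), collapse = ", ")),
         call. = FALSE)
  }
  fst <- fst_records$fst[idx]
  keep <- !is.na(fst)
  if (!all(keep)) {
    message(sprintf("excluding %d SNP(s) with undefined FST", sum(!keep)))
  }
  fst <- fst[keep]
  beta <- model$beta[keep]
  if (!length(fst)) {
    stop("no SNPs with defined FST in model", call. = FALSE)
  }
  weighted <- if (weight_type == "signed") {
    mean(beta * fst)
  } else {
    sum(abs(beta) * fst) / sum(abs(beta))
  }
  tibble::tibble(n_snps = length(fst), mean_fst = mean(fst),
                 weighted_fst = weighted)
}

#' Divergent-vs-similar Wilcoxon sweep over R-squared difference thresholds
#'
#' At each threshold `t`, genes are split into a divergent group
#' (`|R2_pop1 - R2_pop2| > t`) and a similar group (the rest), and the
#' chosen per-gene FST summary is compared between groups with a two-sided
#' Wilcoxon rank-sum test. Exact enumeration is used when both groups have
#' at most 20 genes; otherwise the normal approximation with continuity
#' correction.
#'
#' @param performance Tibble with columns `gene_id`, `r2_pop1`, `r2_pop2`.
#' @param summaries Tibble with columns `gene_id` and the FST summary
#'   columns `mean_fst`, `weighted_fst`.
#' @param threshold_grid Numeric thresholds, default `seq(0.05, 0.3, 0.05)`.
#' @param weighted Logical; use `weighted_fst` instead of `mean_fst`.
#' @return A tibble with one row per threshold: `threshold`, `n_divergent`,
#'   `n_similar`, `mean_fst_divergent`, `mean_fst_similar`,
#'   `wilcoxon_statistic`, `p_value`, `weighted`.
#' @export
divergence_wilcoxon <- function(performance, summaries,
                                threshold_grid = seq(0.05, 0.3, by = 0.05),
                                weighted = FALSE) {
  if (!length(threshold_grid)) {
    stop("`threshold_grid` must be nonempty", call. = FALSE)
  }
  dat <- dplyr::inner_join(performance, summaries, by = "gene_id")
  if (!nrow(dat)) {
    stop("no shared genes between performance and FST summaries", call. = FALSE)
  }
  stat_col <- if (weighted) "weighted_fst" else "mean_fst"
  gap <- abs(dat$r2_pop1 - dat$r2_pop2)
  vals <- dat[[stat_col]]
  purrr::map_dfr(threshold_grid, function(t) {
    div <- gap > t
    x <- vals[div]; y <- vals[!div]
    if (!length(x) || !length(y)) {
      warning(sprintf("threshold %.3g: a group is empty", t))
      return(tibble::tibble(
        threshold = t, n_divergent = length(x), n_similar = length(y),
        mean_fst_divergent = if (length(x)) mean(x) else NA_real_,
        mean_fst_similar = if (length(y)) mean(y) else NA_real_,
        wilcoxon_statistic = NA_real_, p_value = NA_real_,
        weighted = weighted
      ))
    }
    exact <- length(x) <= 20 && length(y) <= 20
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = TRUE)
    )
    tibble::tibble(
      threshold = t, n_divergent = length(x), n_similar = length(y),
      mean_fst_divergent = mean(x), mean_fst_similar = mean(y),
      wilcoxon_statistic = unname(wt$statistic), p_value = wt$p.value,
      weighted = weighted
    )
  })
}
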