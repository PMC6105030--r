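#' Describe a study population
#'
#' A population is characterised by a label, a sample size and a
#' divergence parameter giving how far its allele frequencies have drifted
#' from the shared ancestral frequency pool (the F parameter of the
#' Balding-Nichols model).
#'
#' @param label Short character label, e.g. `"AFA"`.
#' @param n_samples Number of individuals (>= 2).
#' @param ancestry_fst Divergence from the ancestral pool, in (0, 1).
#' @return A `population_spec` object (a named list).
#' @examples
#' population_spec("POP1", 300, 0.1)
#' @export
population_spec <- function(label, n_samples, ancestry_fst) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 2L) {
    stop("`n_samples` must be an integer >= 2", call. = FALSE)
  }
  if (!is.numeric(ancestry_fst) || length(ancestry_fst) != 1L ||
      ancestry_fst <= 0 || ancestry_fst >= 1) {
    stop("`ancestry_fst` must lie strictly inside (0, 1)", call. = FALSE)
  }
  structure(
    list(label = label, n_samples = n_samples, ancestry_fst = ancestry_fst),
    class = "population_spec"
  )
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("<population_spec> %s: n = %d, ancestry F = %.3g\n",
              x$label, x$n_samples, x$ancestry_fst))
  invisible(x)
}

#' Construct a genotype matrix container
#'
#' Holds a samples-by-SNPs dosage matrix (alt-allele counts in \[0, 2\],
#' real-valued to admit imputed dosages) together with SNP metadata.
#'
#' @param dosages Numeric matrix, rows = samples, columns = SNPs.
#' @param snps Tibble of SNP metadata with columns `snp_id`, `chromosome`,
#'   `position`, `ref_allele`, `alt_allele` and one `freq_<label>` column per
#'   population carrying the population alt-allele frequency.
#' @param samples Character vector of sample ids (defaults to rownames).
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(dosages, snps, samples = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  snps <- tibble::as_tibble(snps)
  if (is.null(samples)) {
    samples <- paste0("S", seq_len(nrow(dosages)))
  }
  if (nrow(snps) != ncol(dosages)) {
    stop("`snps` must have one row per dosage column", call. = FALSE)
  }
  if (length(samples) != nrow(dosages)) {
    stop("`samples` must have one id per dosage row", call. = FALSE)
  }
  rng <- range(dosages)
  if (rng[1] < -1e-9 || rng[2] > 2 + 1e-9) {
    stop("dosages must lie in [0, 2]", call. = FALSE)
  }
  ord_ok <- all(unlist(tapply(snps$position, snps$chromosome,
                              function(p) all(diff(p) > 0))))
  if (!ord_ok) {
    stop("SNP positions must be strictly increasing within a chromosome",
         call. = FALSE)
  }
  dimnames(dosages) <- list(samples, snps$snp_id)
  structure(
    list(samples = samples, snps = snps, dosages = dosages),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d SNPs (%s)\n",
              length(x$samples), nrow(x$snps),
              paste(unique(x$snps$chromosome)[seq_len(min(3, length(unique(x$snps$chromosome))))],
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by SNP id
#'
#' @param genotypes A [genotype_matrix()].
#' @param snp_ids Character vector of SNP ids to retain (order preserved).
#' @return A `genotype_matrix` restricted to the requested SNPs.
#' @export
subset_snps <- function(genotypes, snp_ids) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  idx <- match(snp_ids, genotypes$snps$snp_id)
  if (anyNA(idx)) {
    stop(sprintf("SNPs not present: %s",
                 paste(utils::head(snp_ids[is.na(idx)], 5), collapse = ", ")),
         call. = FALSE)
  }
  genotype_matrix(genotypes$dosages[, idx, drop = FALSE],
                  genotypes$snps[idx, ], genotypes$samples)
}

#' Construct an expression panel
#'
#' Holds a samples-by-genes expression matrix plus gene annotation
#' (chromosome and transcription start site) used to define cis windows.
#'
#' @param values Numeric matrix, rows = samples, columns = genes.
#' @param genes Tibble with columns `gene_id`, `chromosome`, `tss`
#'   (1-based TSS coordinate).
#' @param samples Character vector of sample ids (defaults to rownames).
#' @return An `expression_panel` object.
#' @export
expression_panel <- function(values, genes, samples = rownames(values)) {
  values <- as.matrix(values)
  genes <- tibble::as_tibble(genes)
  stopifnot(all(c("gene_id", "chromosome", "tss") %in% names(genes)))
  if (is.null(samples)) {
    samples <- paste0("S", seq_len(nrow(values)))
  }
  if (nrow(genes) != ncol(values)) {
    stop("`genes` must have one row per expression column", call. = FALSE)
  }
  if (length(samples) != nrow(values)) {
    stop("`samples` must have one id per expression row", call. = FALSE)
  }
  dimnames(values) <- list(samples, genes$gene_id)
  structure(
    list(samples = samples, genes = genes, values = values),
    class = "expression_panel"
  )
}

#' @export
print.expression_panel <- function(x, ...) {
  cat(sprintf("<expression_panel> %d samples x %d genes\n",
              length(x$samples), nrow(x$genes)))
  invisible(x)
}

#' @export
dim.expression_panel <- function(x) dim(x$values)

#' Construct a covariate set
#'
#' A tibble of per-sample covariates (genotype principal components, hidden
#' expression factors) whose row order matches the genotype and expression
#' panels it will be used with.
#'
#' @param samples Character vector of sample ids.
#' @param ... Named numeric vectors, one per covariate.
#' @return A `covariate_set` tibble with first column `sample_id`.
#' @export
covariate_set <- function(samples, ...) {
  cols <- list(...)
  if (length(cols)) {
    lens <- vapply(cols, length, 1L)
    stopifnot(all(lens == length(samples)))
    for (nm in names(cols)) {
      v <- cols[[nm]]
      if (stats::sd(v) == 0) {
        stop(sprintf("covariate `%s` is constant", nm), call. = FALSE)
      }
    }
  }
  out <- tibble::tibble(sample_id = samples, !!!cols)
  class(out) <- c("covariate_set", class(out))
  out
}

# Numeric covariate matrix (samples x k), NULL-safe; k may be 0.
covariate_matrix <- function(covariates, samples = NULL) {
  if (is.null(covariates)) {
    return(NULL)
  }
  stopifnot(inherits(covariates, "data.frame"))
  if (!is.null(samples) && !identical(covariates$sample_id, samples)) {
    stop("covariate sample order does not match the panel", call. = FALSE)
  }
  m <- as.matrix(covariates[setdiff(names(covariates), "sample_id")])
  if (ncol(m) == 0L) NULL else m
}
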