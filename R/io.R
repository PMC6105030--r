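# Plain-text interchange: minimal VCF, dosage/expression/truth TSVs and a
# binary-free GRM lower-triangle format.

#' Write genotypes as a tab-separated dosage matrix
#'
#' Rows are SNPs: `snp_id`, `chromosome`, `position`, `ref_allele`,
#' `alt_allele`, then one dosage column per sample.
#'
#' @param genotypes A [genotype_matrix()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  tbl <- dplyr::bind_cols(
    genotypes$snps[c("snp_id", "chromosome", "position",
                     "ref_allele", "alt_allele")],
    tibble::as_tibble(t(genotypes$dosages))
  )
  readr::write_tsv(tbl, path)
  invisible(path)
}

read_dosage_tsv <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  meta_cols <- c("snp_id", "chromosome", "position", "ref_allele", "alt_allele")
  samples <- setdiff(names(tbl), meta_cols)
  dos <- t(as.matrix(tbl[samples]))
  genotype_matrix(dos, tbl[meta_cols], samples)
}

#' Write genotypes as a minimal VCF (v4.2)
#'
#' Emits one biallelic record per SNP with a `GT:DS` FORMAT: hard
#' genotypes where the dosage is integral (`0/0`, `0/1`, `1/1`), `./.`
#' otherwise, and the dosage always in `DS`.
#'
#' @param genotypes A [genotype_matrix()].
#' @param path Output file (plain text, not compressed).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alt allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes$samples), collapse = "\t")
  ), con)
  gt_code <- function(d) {
    ifelse(abs(d - round(d)) < 1e-9,
           c("0/0", "0/1", "1/1")[round(d) + 1L], "./.")
  }
  snps <- genotypes$snps
  for (j in seq_len(nrow(snps))) {
    d <- genotypes$dosages[, j]
    writeLines(paste(c(
      snps$chromosome[j], snps$position[j], snps$snp_id[j],
      snps$ref_allele[j], snps$alt_allele[j], ".", "PASS", ".", "GT:DS",
      paste0(gt_code(d), ":", format(d, trim = TRUE, digits = 10))
    ), collapse = "\t"), con)
  }
  invisible(path)
}

#' Load genotype dosages from VCF or dosage TSV
#'
#' VCF records are converted to alt-allele counts; the `DS` field is
#' preferred when present, otherwise `GT` alleles are counted.
#' Multi-allelic records are skipped with a logged count. Sample order is
#' preserved.
#'
#' @param path Input file.
#' @param format `"vcf"` or `"dosage_tsv"`.
#' @return A [genotype_matrix()].
#' @export
load_genotypes <- function(path, format = c("vcf", "dosage_tsv")) {
  format <- match.arg(format)
  if (format == "dosage_tsv") {
    return(read_dosage_tsv(path))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    message(sprintf("skipping %d multi-allelic record(s)", sum(multi)))
  }
  keep <- which(!multi)
  if (!length(keep)) {
    stop("no biallelic records in VCF", call. = FALSE)
  }
  fmt <- v@gt[, 1]
  has_ds <- all(grepl("DS", fmt))
  if (has_ds) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    count_alt <- function(g) {
      ifelse(is.na(g) | grepl("\\.", g), NA_real_,
             vapply(strsplit(g, "[/|]"), function(a) sum(a == "1"), 0))
    }
    ds <- apply(gt, 2L, count_alt)
    if (is.null(dim(ds))) ds <- matrix(ds, nrow = nrow(gt), dimnames = dimnames(gt))
  }
  ds <- ds[keep, , drop = FALSE]
  if (anyNA(ds)) {
    bad <- which(rowSums(is.na(ds)) > 0)[1]
    stop(sprintf("malformed or missing genotype at record %d", keep[bad]),
         call. = FALSE)
  }
  snps <- tibble::tibble(
    snp_id = ifelse(fix[keep, "ID"] == ".", paste0("snp", keep), fix[keep, "ID"]),
    chromosome = fix[keep, "CHROM"],
    position = as.integer(fix[keep, "POS"]),
    ref_allele = fix[keep, "REF"],
    alt_allele = fix[keep, "ALT"]
  )
  genotype_matrix(t(ds), snps, colnames(v@gt)[-1])
}

#' Write an expression panel as genes-by-samples TSV
#'
#' Columns `gene_id`, `chromosome`, `tss`, then one column per sample.
#'
#' @param expression An [expression_panel()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expression, path) {
  stopifnot(inherits(expression, "expression_panel"))
  tbl <- dplyr::bind_cols(
    expression$genes[c("gene_id", "chromosome", "tss")],
    tibble::as_tibble(t(expression$values))
  )
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Read an expression panel written by [write_expression_tsv()]
#' @param path Input file.
#' @return An [expression_panel()].
#' @export
read_expression_tsv <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  meta <- c("gene_id", "chromosome", "tss")
  samples <- setdiff(names(tbl), meta)
  expression_panel(t(as.matrix(tbl[samples])), tbl[meta], samples)
}

#' Write simulation ground truth as TSV
#'
#' One row per (gene, causal SNP, population): `gene_id`, `snp_id`, `pop`,
#' `beta`, `h2`, `rho`.
#'
#' @param truths List of `gene_architecture` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truths, path) {
  tbl <- purrr::map_dfr(truths, function(tr) {
    purrr::map_dfr(names(tr$beta_by_population), function(lab) {
      tibble::tibble(
        gene_id = tr$gene_id,
        snp_id = names(tr$beta_by_population[[lab]]),
        pop = lab,
        beta = unname(tr$beta_by_population[[lab]]),
        h2 = unname(tr$h2_by_population[[lab]]),
        rho = tr$rho_effects
      )
    })
  })
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Write a GRM in lower-triangle tab-separated form
#'
#' One row per sample pair (including the diagonal): `id1`, `id2`,
#' `n_snps`, `value` - a binary-free layout interconvertible with the
#' common GRM-gz convention.
#'
#' @param grm A `grm` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_grm_tsv <- function(grm, path) {
  stopifnot(inherits(grm, "grm"))
  idx <- which(lower.tri(grm$matrix, diag = TRUE), arr.ind = TRUE)
  tbl <- tibble::tibble(
    id1 = grm$samples[idx[, 1]],
    id2 = grm$samples[idx[, 2]],
    n_snps = grm$n_snps_used,
    value = grm$matrix[idx]
  )
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Read a GRM written by [write_grm_tsv()]
#' @param path Input file.
#' @return A `grm` object.
#' @export
read_grm_tsv <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  samples <- unique(c(tbl$id1, tbl$id2))
  n <- length(samples)
  K <- matrix(0, n, n, dimnames = list(samples, samples))
  i <- match(tbl$id1, samples)
  j <- match(tbl$id2, samples)
  K[cbind(i, j)] <- tbl$value
  K[cbind(j, i)] <- tbl$value
  structure(list(samples = samples, matrix = K,
                 n_snps_used = tbl$n_snps[1]),
            class = "grm")
}

#' Write a prediction-model store as paired TSV tables
#'
#' Emits `<prefix>_weights.tsv` (gene, snp_id, chromosome, position,
#' effect_allele, other_allele, beta, training_freq per row) and
#' `<prefix>_extra.tsv` (gene, alpha, cv_r2, n_snps, lambda, intercept) -
#' field-compatible in spirit with PredictDB weight databases; converting
#' these two tables into that database layout is a straightforward
#' extension point.
#'
#' @param models A `prediction_models` object from [train_gene_models()].
#' @param prefix Output path prefix.
#' @return The two paths, invisibly.
#' @export
write_model_store <- function(models, prefix) {
  stopifnot(inherits(models, "prediction_models"))
  wpath <- paste0(prefix, "_weights.tsv")
  epath <- paste0(prefix, "_extra.tsv")
  readr::write_tsv(models$weights, wpath)
  extra <- dplyr::rename(models$performance, cv_r2 = "r2",
                         n_snps = "n_snps_in_model",
                         lambda = "lambda_selected")
  readr::write_tsv(extra, epath)
  invisible(c(wpath, epath))
}

#' Read a prediction-model store written by [write_model_store()]
#'
#' @param prefix Path prefix used when writing.
#' @param genes Gene annotation tibble (`gene_id`, `chromosome`, `tss`);
#'   reconstructed from the weight table positions when omitted.
#' @param population Label for the reconstructed object.
#' @return A `prediction_models` object.
#' @export
read_model_store <- function(prefix, genes = NULL, population = "train") {
  weights <- readr::read_tsv(paste0(prefix, "_weights.tsv"),
                             show_col_types = FALSE)
  extra <- readr::read_tsv(paste0(prefix, "_extra.tsv"),
                           show_col_types = FALSE)
  performance <- dplyr::rename(extra, r2 = "cv_r2",
                               n_snps_in_model = "n_snps",
                               lambda_selected = "lambda")
  if (is.null(genes)) {
    genes <- dplyr::summarise(
      dplyr::group_by(weights, .data$gene_id),
      chromosome = dplyr::first(.data$chromosome),
      tss = as.integer(round(mean(range(.data$position)))),
      .groups = "drop"
    )
  }
  structure(
    list(weights = weights, performance = performance, genes = genes,
         population = population,
         alpha_grid = sort(unique(performance$alpha))),
    class = "prediction_models"
  )
}
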