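# Synthetic multi-population cohorts with known cis architecture.
#
# The generator follows the Balding-Nichols model: each SNP has an ancestral
# alt-allele frequency p, and population k's frequency is drawn from
# Beta(p (1 - F_k) / F_k, (1 - p)(1 - F_k) / F_k), which has mean p and
# variance F_k p (1 - p). Genotypes are binomial(2, freq) within population,
# expression is genetic value plus Gaussian noise scaled to a target
# cis heritability.

#' Draw differentiated per-population allele frequencies
#'
#' Ancestral frequencies are uniform on `ancestral_freq_range`; each
#' population's frequency is drawn from the Balding-Nichols Beta
#' distribution with mean p and variance `F p (1 - p)`, where `F` is the
#' population's `ancestry_fst`. SNPs are laid out at strictly increasing
#' positions on one chromosome.
#'
#' @param n_snps Number of SNPs to draw (>= 1).
#' @param pops List of [population_spec()] objects (at least one).
#' @param ancestral_freq_range Length-2 interval inside (0, 1) for the
#'   ancestral frequency; default `c(0.05, 0.95)`.
#' @param seed Integer seed; required, every draw is reproducible.
#' @param chromosome Chromosome label for the SNP block.
#' @param start_pos 1-based position of the first SNP.
#' @param spacing_bp Distance between consecutive SNPs in base pairs.
#' @return A tibble of SNP records: `snp_id`, `chromosome`, `position`,
#'   `ref_allele`, `alt_allele`, and one `freq_<label>` column per population.
#' @examples
#' pops <- list(population_spec("A", 100, 0.1), population_spec("B", 100, 0.1))
#' snps <- draw_population_frequencies(5, pops, seed = 1)
#' @export
draw_population_frequencies <- function(n_snps, pops,
                                        ancestral_freq_range = c(0.05, 0.95),
                                        seed,
                                        chromosome = "chr1",
                                        start_pos = 1L,
                                        spacing_bp = 5000L) {
  n_snps <- as.integer(n_snps)
  if (is.na(n_snps) || n_snps < 1L) {
    stop("`n_snps` must be a positive integer", call. = FALSE)
  }
  if (!length(pops)) {
    stop("`pops` must contain at least one population_spec", call. = FALSE)
  }
  stopifnot(all(vapply(pops, inherits, TRUE, "population_spec")))
  labs <- vapply(pops, `[[`, "", "label")
  if (anyDuplicated(labs)) {
    stop("population labels must be unique", call. = FALSE)
  }
  rng <- sort(ancestral_freq_range)
  if (length(rng) != 2L || rng[1] <= 0 || rng[2] >= 1 || rng[1] >= rng[2]) {
    stop("`ancestral_freq_range` must be a non-degenerate interval inside (0, 1)",
         call. = FALSE)
  }
  with_seed(seed, {
    p_anc <- stats::runif(n_snps, rng[1], rng[2])
    # alleles drawn per SNP so ref != alt
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_snps, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
    out <- tibble::tibble(
      snp_id = sprintf("%s_snp%05d", chromosome, seq_len(n_snps)),
      chromosome = chromosome,
      position = as.integer(start_pos + (seq_len(n_snps) - 1L) * spacing_bp),
      ref_allele = ref,
      alt_allele = unname(alt)
    )
    for (pop in pops) {
      f <- pop$ancestry_fst
      if (f < 1e-12) {
        freq <- p_anc
      } else {
        shape_scale <- (1 - f) / f
        freq <- stats::rbeta(n_snps, p_anc * shape_scale,
                             (1 - p_anc) * shape_scale)
      }
      out[[paste0("freq_", pop$label)]] <- freq
    }
    attr(out, "ancestral_freq") <- p_anc
    out
  })
}

#' Simulate genotype dosages for one population
#'
#' Hard-call dosages are drawn as binomial(2, freq) per sample and SNP,
#' i.e. Hardy-Weinberg genotypes at the population's allele frequency.
#'
#' @param snps SNP tibble from [draw_population_frequencies()] (must carry a
#'   `freq_<label>` column for `pop`).
#' @param pop A [population_spec()].
#' @param seed Integer seed.
#' @return A [genotype_matrix()] for the population's samples.
#' @export
simulate_genotypes <- function(snps, pop, seed) {
  stopifnot(inherits(pop, "population_spec"))
  fcol <- paste0("freq_", pop$label)
  if (!fcol %in% names(snps)) {
    stop(sprintf("no frequency column for population label `%s`", pop$label),
         call. = FALSE)
  }
  freq <- snps[[fcol]]
  assert_prob(freq, fcol)
  n <- pop$n_samples
  m <- nrow(snps)
  with_seed(seed, {
    dos <- matrix(stats::rbinom(n * m, 2L, rep(freq, each = n)), nrow = n)
    rownames(dos) <- sprintf("%s_%04d", pop$label, seq_len(n))
    genotype_matrix(dos, snps)
  })
}

#' Simulate a gene's causal cis architecture
#'
#' Causal SNPs are sampled uniformly without replacement from the cis SNP
#' set; per-population causal effects are drawn from a multivariate normal
#' with unit marginal variances and pairwise correlation `rho_effects`
#' between populations (`rho_effects = 0` gives independent effects, the
#' null used to check estimator bias; `rho_effects = 1` gives identical
#' effect vectors).
#'
#' @param gene_id Gene identifier.
#' @param cis_snps SNP tibble for the gene's cis window.
#' @param n_causal Number of causal SNPs, `1 <= n_causal <= nrow(cis_snps)`;
#'   `NULL` makes every MAF-eligible cis SNP causal (the infinitesimal
#'   architecture used for genetic-correlation validation).
#' @param h2_by_population Named numeric vector of target cis heritabilities
#'   in \[0, 1\], one per population label.
#' @param rho_effects Between-population effect correlation in \[-1, 1\],
#'   or a full symmetric correlation matrix over the populations for
#'   pairwise-specific sharing.
#' @param seed Integer seed.
#' @param maf_min Causal SNPs are restricted to frequency in
#'   `[maf_min, 1 - maf_min]` in every population (default 0.01) so the
#'   architecture is testable in each cohort.
#' @return A `gene_architecture` object: gene id, causal SNP ids,
#'   per-population effect vectors, targets `h2_by_population` and
#'   `rho_effects`, plus the gene's chromosome and TSS (window midpoint).
#' @export
simulate_gene_architecture <- function(gene_id, cis_snps, n_causal,
                                       h2_by_population, rho_effects, seed,
                                       maf_min = 0.01) {
  cis_snps <- tibble::as_tibble(cis_snps)
  all_causal <- is.null(n_causal)
  if (!all_causal) {
    n_causal <- as.integer(n_causal)
    if (is.na(n_causal) || n_causal < 1L) {
      stop("`n_causal` must be >= 1 (or NULL for all eligible cis SNPs)",
           call. = FALSE)
    }
  }
  labs <- names(h2_by_population)
  if (is.null(labs) || !all(nzchar(labs))) {
    stop("`h2_by_population` must be a named vector of population labels",
         call. = FALSE)
  }
  assert_prob(h2_by_population, "h2_by_population")
  if (is.matrix(rho_effects)) {
    k0 <- length(labs)
    if (!identical(dim(rho_effects), c(k0, k0)) ||
        any(abs(rho_effects) > 1) || any(diag(rho_effects) != 1) ||
        !isSymmetric(rho_effects)) {
      stop("`rho_effects` matrix must be a symmetric correlation matrix over the populations",
           call. = FALSE)
    }
  } else if (abs(rho_effects) > 1) {
    stop("`rho_effects` must lie in [-1, 1]", call. = FALSE)
  }
  fcols <- paste0("freq_", labs)
  missing_cols <- setdiff(fcols, names(cis_snps))
  if (length(missing_cols)) {
    stop(sprintf("cis SNP table lacks columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  fmat <- as.matrix(cis_snps[fcols])
  eligible <- which(apply(fmat, 1L, function(f) {
    all(pmin(f, 1 - f) >= maf_min)
  }))
  if (all_causal) {
    if (!length(eligible)) {
      stop("no cis SNPs pass the MAF filter in every population", call. = FALSE)
    }
    n_causal <- length(eligible)
  }
  if (n_causal > length(eligible)) {
    stop(sprintf(
      "n_causal = %d exceeds the %d cis SNPs with MAF >= %.3g in every population",
      n_causal, length(eligible), maf_min), call. = FALSE)
  }
  k <- length(labs)
  with_seed(seed, {
    causal_idx <- sort(eligible[sample.int(length(eligible), n_causal)])
    causal_ids <- cis_snps$snp_id[causal_idx]
    # multivariate normal across populations: equicorrelated scalar rho, or
    # an explicit pairwise correlation matrix
    if (is.matrix(rho_effects)) {
      sigma <- rho_effects
    } else {
      sigma <- matrix(rho_effects, k, k)
      diag(sigma) <- 1
    }
    # symmetric square root: also valid for singular correlation matrices
    # (rho = 1 makes the effect vectors exactly identical)
    es <- eigen(sigma, symmetric = TRUE)
    sq <- es$vectors %*% (sqrt(pmax(es$values, 0)) * t(es$vectors))
    z <- matrix(stats::rnorm(n_causal * k), n_causal, k)
    betas <- z %*% sq
    beta_by_population <- stats::setNames(
      lapply(seq_len(k), function(j) stats::setNames(betas[, j], causal_ids)),
      labs
    )
    structure(
      list(
        gene_id = gene_id,
        causal_snp_ids = causal_ids,
        beta_by_population = beta_by_population,
        h2_by_population = h2_by_population,
        rho_effects = rho_effects,
        chromosome = cis_snps$chromosome[1],
        tss = as.integer(round(mean(range(cis_snps$position)))),
        cis_snp_ids = cis_snps$snp_id
      ),
      class = "gene_architecture"
    )
  })
}

#' @export
print.gene_architecture <- function(x, ...) {
  cat(sprintf("<gene_architecture> %s: %d causal SNP(s), rho = %.2g, h2 = {%s}\n",
              x$gene_id, length(x$causal_snp_ids), x$rho_effects,
              paste(sprintf("%s: %.2g", names(x$h2_by_population),
                            x$h2_by_population), collapse = ", ")))
  invisible(x)
}

#' Simulate one gene's expression phenotype
#'
#' The genetic value is `g = dosages[, causal] %*% beta`; the phenotype is
#' `y = a g + e` with `e ~ N(0, 1)` and the scale `a` chosen from the
#' realized sample variance of `g` so that `var(a g) / var(y)` equals the
#' target heritability in expectation: `a = sqrt(h2 / ((1 - h2) var(g)))`.
#' `h2 = 0` yields pure noise; `h2 = 1` yields the standardized genetic
#' value with no residual.
#'
#' @param genotypes A [genotype_matrix()] containing the causal SNPs.
#' @param truth A `gene_architecture` from [simulate_gene_architecture()].
#' @param pop_label Population label selecting effect vector and target h2.
#' @param seed Integer seed.
#' @return Named numeric vector of expression values (names = sample ids).
#' @export
simulate_expression <- function(genotypes, truth, pop_label, seed) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(truth, "gene_architecture"))
  if (!pop_label %in% names(truth$beta_by_population)) {
    stop(sprintf("no effects for population `%s`", pop_label), call. = FALSE)
  }
  beta <- truth$beta_by_population[[pop_label]]
  h2 <- unname(truth$h2_by_population[[pop_label]])
  idx <- match(names(beta), genotypes$snps$snp_id)
  if (anyNA(idx)) {
    stop("causal SNPs missing from the genotype matrix", call. = FALSE)
  }
  g <- drop(genotypes$dosages[, idx, drop = FALSE] %*% beta)
  n <- length(g)
  var_g <- stats::var(g)
  with_seed(seed, {
    if (h2 == 0) {
      y <- stats::rnorm(n)
    } else {
      if (var_g <= 0) {
        stop("degenerate genetic variance: realized var(g) = 0 with h2 > 0",
             call. = FALSE)
      }
      if (h2 == 1) {
        y <- g / sqrt(var_g)
      } else {
        a <- sqrt(h2 / ((1 - h2) * var_g))
        y <- a * g + stats::rnorm(n)
      }
    }
    stats::setNames(y, genotypes$samples)
  })
}

#' Regenerate expression panels under the independent-effects null
#'
#' For each replicate and gene, effects are redrawn with the
#' between-population correlation forced to zero while preserving each
#' population's target heritability. This is the h2-matched null used to
#' verify that the bivariate REML genetic-correlation estimator is unbiased
#' at small sample sizes: across many genes the mean estimated rG should be
#' near zero.
#'
#' @param panel_truths List of `gene_architecture` objects.
#' @param genotypes_by_pop Named list of [genotype_matrix()], one per
#'   population label appearing in the truths.
#' @param n_replicates Number of independent replicate panels (>= 1).
#' @param seed Integer seed.
#' @return A list of length `n_replicates`; each element is a named list of
#'   [expression_panel()] objects, one per population.
#' @export
simulate_h2_matched_null <- function(panel_truths, genotypes_by_pop,
                                     n_replicates, seed) {
  n_replicates <- as.integer(n_replicates)
  if (is.na(n_replicates) || n_replicates < 1L) {
    stop("`n_replicates` must be >= 1", call. = FALSE)
  }
  stopifnot(length(panel_truths) >= 1L)
  labs <- names(genotypes_by_pop)
  for (tr in panel_truths) {
    if (!all(labs %in% names(tr$h2_by_population))) {
      stop("every truth must carry h2 for every population", call. = FALSE)
    }
  }
  genes_tbl <- tibble::tibble(
    gene_id = vapply(panel_truths, `[[`, "", "gene_id"),
    chromosome = vapply(panel_truths, `[[`, "", "chromosome"),
    tss = vapply(panel_truths, `[[`, 1L, "tss")
  )
  lapply(seq_len(n_replicates), function(r) {
    rep_seed <- derive_seed(seed, sprintf("h2_null_rep%03d", r))
    panels <- lapply(labs, function(lab) {
      geno <- genotypes_by_pop[[lab]]
      vals <- vapply(seq_along(panel_truths), function(j) {
        tr <- panel_truths[[j]]
        gseed <- derive_seed(rep_seed, sprintf("%s_%s", tr$gene_id, lab))
        null_truth <- with_seed(
          derive_seed(rep_seed, paste0("arch_", tr$gene_id)),
          {
            ids <- tr$causal_snp_ids
            k <- length(labs)
            betas <- matrix(stats::rnorm(length(ids) * k), ncol = k)
            bb <- stats::setNames(
              lapply(seq_len(k), function(i) stats::setNames(betas[, i], ids)),
              labs
            )
            tr2 <- tr
            tr2$beta_by_population <- bb
            tr2$rho_effects <- 0
            tr2
          }
        )
        simulate_expression(geno, null_truth, lab, gseed)
      }, numeric(length(geno$samples)))
      expression_panel(vals, genes_tbl, geno$samples)
    })
    stats::setNames(panels, labs)
  })
}

#' Simulate a complete multi-population expression study
#'
#' Convenience wrapper tying the generator together: draws differentiated
#' allele frequencies, simulates genotypes per population, assigns each gene
#' its own cis SNP block (one block per chromosome so cis windows are
#' disjoint), draws sparse causal architectures and simulates expression.
#'
#' @param pops List of [population_spec()] objects.
#' @param n_genes Number of genes.
#' @param n_cis_snps SNPs per gene cis block.
#' @param n_causal Causal SNPs per gene (recycled over genes); `NULL` for
#'   the infinitesimal architecture (every eligible cis SNP causal).
#' @param h2 Target cis heritability: a single value, a vector over genes,
#'   or a function(n) returning n values (applied to all populations).
#' @param rho_effects Between-population effect correlation (single value,
#'   vector over genes, or a pairwise correlation matrix applied to all
#'   genes).
#' @param seed Integer seed.
#' @param spacing_bp Spacing between cis SNPs in bp.
#' @param ancestral_freq_range Interval for ancestral frequencies.
#' @return A list with elements `pops`, `snps` (all SNP records),
#'   `genotypes` (named list of [genotype_matrix()] per population),
#'   `expression` (named list of [expression_panel()] per population),
#'   `truths` (list of `gene_architecture`), and `genes` (annotation tibble).
#' @export
simulate_study <- function(pops, n_genes, n_cis_snps = 100L, n_causal = 2L,
                           h2 = 0.3, rho_effects = 0.8, seed = 1L,
                           spacing_bp = 5000L,
                           ancestral_freq_range = c(0.05, 0.95)) {
  stopifnot(n_genes >= 1L)
  labs <- vapply(pops, `[[`, "", "label")
  h2_vec <- if (is.function(h2)) h2(n_genes) else rep_len(h2, n_genes)
  rho_vec <- if (is.matrix(rho_effects)) {
    rep(list(rho_effects), n_genes)
  } else {
    as.list(rep_len(rho_effects, n_genes))
  }
  nc_vec <- if (is.null(n_causal)) {
    rep(list(NULL), n_genes)
  } else {
    as.list(rep_len(as.integer(n_causal), n_genes))
  }

  snp_blocks <- vector("list", n_genes)
  truths <- vector("list", n_genes)
  for (j in seq_len(n_genes)) {
    chrom <- sprintf("chr%d", j)
    snp_blocks[[j]] <- draw_population_frequencies(
      n_cis_snps, pops, ancestral_freq_range,
      seed = derive_seed(seed, paste0("freq_", chrom)),
      chromosome = chrom, spacing_bp = spacing_bp
    )
    truths[[j]] <- simulate_gene_architecture(
      sprintf("gene%04d", j), snp_blocks[[j]], nc_vec[[j]],
      stats::setNames(rep(h2_vec[j], length(labs)), labs),
      rho_vec[[j]],
      seed = derive_seed(seed, paste0("arch_", chrom))
    )
  }
  snps <- dplyr::bind_rows(snp_blocks)
  genes_tbl <- tibble::tibble(
    gene_id = vapply(truths, `[[`, "", "gene_id"),
    chromosome = vapply(truths, `[[`, "", "chromosome"),
    tss = vapply(truths, `[[`, 1L, "tss")
  )
  genotypes <- stats::setNames(lapply(pops, function(pop) {
    simulate_genotypes(snps, pop, derive_seed(seed, paste0("geno_", pop$label)))
  }), labs)
  expression <- stats::setNames(lapply(labs, function(lab) {
    geno <- genotypes[[lab]]
    vals <- vapply(truths, function(tr) {
      simulate_expression(geno, tr, lab,
                          derive_seed(seed, sprintf("expr_%s_%s", tr$gene_id, lab)))
    }, numeric(length(geno$samples)))
    expression_panel(vals, genes_tbl, geno$samples)
  }), labs)
  list(pops = pops, snps = snps, genotypes = genotypes,
       expression = expression, truths = truths, genes = genes_tbl)
}
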