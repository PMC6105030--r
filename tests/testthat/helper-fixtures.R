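# Small fixture builders shared across test files.

two_pop_specs <- function(n = 100, f = 0.1) {
  list(population_spec("P1", n, f), population_spec("P2", n, f))
}

# Genotype matrix with explicit dosages and minimal metadata.
toy_genotypes <- function(dosages, chromosome = "chr1",
                          ref = NULL, alt = NULL, positions = NULL,
                          freq_label = NULL) {
  m <- ncol(dosages)
  snps <- tibble::tibble(
    snp_id = paste0("s", seq_len(m)),
    chromosome = chromosome,
    position = if (is.null(positions)) seq_len(m) * 1000L else positions,
    ref_allele = if (is.null(ref)) rep("A", m) else ref,
    alt_allele = if (is.null(alt)) rep("G", m) else alt
  )
  if (!is.null(freq_label)) {
    snps[[paste0("freq_", freq_label)]] <- colMeans(dosages) / 2
  }
  genotype_matrix(dosages, snps)
}

toy_expression <- function(values, chromosome = "chr1", tss = 1L,
                           samples = rownames(values)) {
  g <- ncol(values)
  genes <- tibble::tibble(
    gene_id = paste0("g", seq_len(g)),
    chromosome = rep_len(chromosome, g),
    tss = rep_len(as.integer(tss), g)
  )
  expression_panel(values, genes, samples)
}

# One-gene study for planted-eQTL power checks: n samples, m cis SNPs,
# one causal SNP at a given h2. Returns genotypes, expression, causal id.
single_gene_study <- function(n, m, h2, seed, n_causal = 1) {
  pop <- population_spec("P1", n, 0.1)
  snps <- draw_population_frequencies(m, list(pop), seed = seed)
  geno <- simulate_genotypes(snps, pop, seed = seed + 1L)
  truth <- simulate_gene_architecture(
    "g1", snps, n_causal, c(P1 = h2), 0, seed = seed + 2L
  )
  y <- simulate_expression(geno, truth, "P1", seed = seed + 3L)
  expr <- expression_panel(
    matrix(y, ncol = 1),
    tibble::tibble(gene_id = "g1", chromosome = snps$chromosome[1],
                   tss = as.integer(round(mean(range(snps$position))))),
    geno$samples
  )
  list(genotypes = geno, expression = expr, truth = truth)
}
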