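---
title: "Methods: cross-population genetic architecture of gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-population genetic architecture of gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Genetic predictors of gene expression (per-gene SNP weight sets of the
PredictDB/TWAS kind) are mostly trained in European-ancestry cohorts and
lose accuracy when applied to other populations. `xpopexpr` implements the
full chain of analyses needed to quantify and explain that loss on cohorts
with known ground truth: per-population cis-eQTL mapping, replication
true-positive rates (Storey's $\pi_1$), cis heritability and bivariate
genetic correlation by REML, elastic-net expression prediction with nested
cross-validation, cross-population model transfer with allele
harmonization, and a Weir–Cockerham $F_{ST}$ analysis that attributes
transfer failure to allele-frequency divergence.

# Models and estimators

## Synthetic cohorts

Allele-frequency divergence follows the Balding–Nichols model: for a SNP
with ancestral frequency $p$, population $k$'s frequency is drawn from
$\mathrm{Beta}\!\left(p\frac{1-F_k}{F_k},\,(1-p)\frac{1-F_k}{F_k}\right)$,
with mean $p$ and variance $F_k\,p(1-p)$. `ancestry_fst` is that $F$;
two cohorts simulated at the same $F$ have pairwise multi-locus
Weir–Cockerham $F_{ST}$ equal to $F$ in expectation. Genotypes are
binomial$(2,\text{freq})$ within population (Hardy–Weinberg; no LD beyond
the frequency sharing — coalescent LD is an explicit non-goal). Cohort
admixture is approximated by intermediate $F$ values, not local-ancestry
tracts.

Each gene has a causal SNP set in its cis window; per-population effects
are multivariate normal across populations with unit marginals and
correlation $\rho$ (`rho_effects`; a full pairwise correlation matrix is
accepted for three-population designs). The phenotype is
$y = a\,g + e$, $e \sim N(0,1)$, with $g$ the genetic value and
$a = \sqrt{h^2 / ((1-h^2)\,\widehat{\mathrm{var}}(g))}$ chosen from the
*realized* sample variance of $g$. Using the realized variance rather than
the theoretical $2p(1-p)\sum\beta^2$ makes the expected realized
heritability equal to the target at finite $n$, so REML recovery targets
are exact in expectation; over 200 replicate genes the mean realized
genetic-variance fraction sits within $\pm 0.02$ of the target.

**Sparse versus infinitesimal architectures.** Two regimes are used
deliberately. The eQTL, prediction and $F_{ST}$ experiments use sparse
truth (1–3 causal SNPs), matching what elastic-net modelling of expression
exploits. The genetic-correlation experiments give *every* eligible cis
SNP an effect (`n_causal = NULL`). The reason is statistical, not
cosmetic: with $c$ causal SNPs the realized per-gene correlation of the
two populations' effect vectors is a ratio statistic over $c$ draws whose
mean is well below $\rho$ for small $c$ (for $c=2$, a planted
$\rho = 0.6$ yields realized per-gene correlations averaging near 0.45).
With a dense causal set the realized correlation concentrates at $\rho$,
so recovery of the planted value is a meaningful test of the estimator
rather than of sparse-sampling noise. The h2-matched null regenerates
effects independently ($\rho = 0$) per population while preserving each
gene's heritability — the bias check for the rG estimator.

Causal SNPs are restricted to MAF $\ge$ 0.01 in every population so no
architecture is untestable in any cohort. All random draws flow through a
single seeded generator per call; seeds are required arguments.

## cis-eQTL mapping

For each gene, every SNP with within-population MAF > 0.01 and position in
the closed window $[\mathrm{TSS}-10^6, \mathrm{TSS}+10^6]$ (1-based,
strand ignored) is tested by OLS of expression on dosage plus covariates.
Covariates (genotype PCs from LD-pruned, standardized dosages; hidden
expression factors) are projected out of both expression and dosages once
per run — algebraically identical to including them per regression, with
residual df $n - 2 - k$. FDR is Benjamini–Hochberg over all SNP–gene tests
in the run by default (the Matrix-eQTL convention); a per-gene option
exists behind `fdr_scope`. Hidden factors are the top principal components
of covariate-residualized expression — a variance-capturing stand-in for
variational-Bayes factor estimators such as PEER; since downstream results
are insensitive to the factor count beyond ~10, a variance-capturing
estimator suffices, and the grid {0, 10, 20, 30} stays configurable.

## Heritability and genetic correlation by REML

The cis GRM is $K = WW'/m$ over standardized dosages. Univariate fits use
a one-time eigendecomposition of $K$, after which each
average-information (AI) update costs $O(n)$; non-improving AI steps fall
back to step-halving and an EM step, so the restricted likelihood never
decreases. Convergence is $|\Delta \ell_R| < 10^{-8}$ (configurable),
`max_iter` 100, starting values $\sigma_g^2 = \sigma_e^2 =
\mathrm{var}(y)/2$. Variances are floored at $10^{-8}\mathrm{var}(y)$;
$h^2 = \sigma_g^2/(\sigma_g^2+\sigma_e^2) \in [0,1]$ by construction. SEs
come from the inverse AI matrix by the delta method.

The bivariate model stacks two disjoint cohorts:
$$V = \begin{pmatrix} A\sigma_{g1}^2 + I\sigma_{e1}^2 & C\,\sigma_{g12} \\
C'\sigma_{g12} & B\sigma_{g2}^2 + I\sigma_{e2}^2\end{pmatrix},\qquad
r_G = \frac{\sigma_{g12}}{\sqrt{\sigma_{g1}^2\sigma_{g2}^2}},$$
with no residual covariance (no individual belongs to both cohorts) and
per-cohort intercepts as fixed effects (genotype PCs can be supplied). A
key numerical point: $A$, $B$ and $C$ must be blocks of **one** GRM
standardized on the combined sample. If $A$ and $B$ are standardized
within-population while $C$ uses the combined sample, the joint genetic
covariance is indefinite for any $\sigma_{g12} \neq 0$ and the likelihood
is $-\infty$ off the axis; a common standardization makes it PSD for all
$|r_G| \le 1$. `build_cross_grm()` therefore returns the three blocks of
the combined-sample GRM.

When the implied $|r_G|$ exceeds 1 or the 2×2 genetic component matrix
loses positive definiteness, the matrix is *bent*: eigenvalues floored at
$10^{-6}$ of the trace, variances restored, the implied correlation kept
— and the event recorded in the `bent` flag. A fit with either genetic
variance at the zero floor is reported non-converged with reason
"degenerate genetic variance", mirroring the practice of summarising only
genes that converged.

Because the cis GRM has rank $m \ll n$, the bivariate fit uses an exact
reduced representation: each cohort's data are rotated onto an orthonormal
basis of $[\mathbf{1}, W]$; the orthogonal complement contributes only
i.i.d. residual variance through its RSS and degrees of freedom. The
restricted likelihood, gradient and AI matrix decompose exactly, cutting
the per-iteration cost from $O(n^3)$ to $O((2m)^3)$. A test asserts
agreement with the dense implementation to $10^{-6}$; the dense path
remains available (and is used automatically when fixed-effect covariates
beyond the intercept are supplied).

Aggregation (`aggregate_rg()`) reports the mean rG and its SE among
converged genes whose minimum (or single-population) estimated $h^2$
exceeds each threshold in a grid.

## Elastic-net prediction and transfer

Per gene and mixing parameter $\alpha \in \{0.05, 0.5, 1\}$ the model
minimizes
$\frac{1}{2n}\lVert y - b_0 - Xw\rVert^2 + \lambda(\alpha\lVert w\rVert_1
+ (1-\alpha)\lVert w\rVert_2^2/2)$
by glmnet's coordinate descent along a geometric path of 100 $\lambda$
values spanning three decades from $\lambda_{max}$; $\lambda$ is chosen at
the minimum 10-fold inner-CV squared error, with the path shared across
outer folds of a gene for stability. $\alpha = 0$ is rejected
($\lambda_{max}$ undefined for pure ridge). One subtlety: glmnet
internally standardizes $y$, which silently rescales its effective ridge
(but not lasso) penalty; `fit_elastic_net()` reparametrizes
$(\lambda, \alpha)$ so the objective above is solved exactly — verified
against an independent proximal-gradient solver to $10^{-6}$ and by KKT
residuals.

Performance is nested cross-validation: 5 outer folds, inner-CV refit on
each complement, $R^2 = 1 - \sum(y_o - y_p)^2 / \sum(y_o - \bar y_o)^2$
on the held-out fold (negative values possible), mean over folds.
Deployed weights come from a full-data inner-CV refit (PredictDB
practice); nested-CV $R^2$ is never computed from that final fit.
Expression is residualized on covariates before fitting; covariates are
never penalized regressors.

Transfer: model SNPs match test SNPs by chromosome and position; swapped
ref/alt flips the dosage to $2-d$; strand-ambiguous (A/T, C/G) test SNPs
are excluded; unmatched SNPs are imputed at twice the training
effect-allele frequency by default (`"drop"` available). Per-gene Pearson
correlations between predicted and observed expression feed $\pi_1$ at
training-$R^2$ inclusion thresholds $\{0, 0.01, 0.05, 0.1, 0.2\}$.

## Replication $\pi_1$

$\pi_0(\lambda) = \#\{p > \lambda\}/(m(1-\lambda))$ on
$\lambda \in \{0.05, \dots, 0.95\}$, smoothed with a cubic smoothing
spline (df 3) and read off at the largest $\lambda$ — the standard qvalue
recipe; a fixed $\lambda = 0.5$ fallback applies for $m < 100$ or smoother
failure, and estimates are clamped to $[0,1]$ with the event recorded in
`method`. $\pi_1 = 1 - \pi_0$ is the expected true-positive rate of a
discovery set evaluated in a replication cohort; `replication_pi1()`
restricts to discovery units passing FDR < 0.05 that are present in the
replication collection. Note what $\pi_1$ is: the fraction of
*distinguishable-from-null* units, not a measure of effect strength — the
transfer experiment's design (smaller test cohorts, heritabilities spread
over a realistic range) exists precisely so that attenuated correlations
drop below detectability rather than merely shrinking.

## $F_{ST}$ and the divergence mechanism

Per-SNP differentiation uses the Weir–Cockerham (1984) two-population
estimator $\hat\theta = a/(a+b+c)$ from dosage-derived allele and
heterozygote counts (a Hudson-style alternative is behind a flag). For
multi-locus summaries the package exposes the ratio-of-sums estimator
$\sum a / \sum(a+b+c)$: the mean of per-SNP ratios is biased downward by
Jensen's inequality (about 0.084 at a generative $F = 0.1$), while the
ratio of sums is unbiased and is the standard genome-wide estimate.
Per-model summaries are the unweighted mean of per-SNP $F_{ST}$ over the
model's SNPs and the signed-product weighted mean
$\frac{1}{m}\sum\beta_j F_{ST,j}$ (the literal reading of weighting by
the model beta); because signed products can cancel, an absolute-beta
normalised variant is provided. The divergence test splits genes at
$|R^2_1 - R^2_2| > t$ for $t \in \{0.05,\dots,0.3\}$ and compares model
$F_{ST}$ between groups by a two-sided Wilcoxon rank-sum test — exact
enumeration when both groups have $\le 20$ genes, normal approximation
with continuity correction otherwise.

# Validation experiments and problem sizes

The `validate_*()` family runs each claim end to end at the package's
study conditions (all sizes are arguments):

- `validate_rg_null()`: 2 × 300 samples, 10 replicate panels × 100 genes
  (1,000 fits), $h^2 \sim U(0.05, 0.6)$ — mean rG within ±0.05 of zero
  with boundary masses at ±1 on both sides.
- `validate_rg_recovery()`: $\rho \in \{0.3, 0.6, 0.9\}$, 300 genes each
  at $n = 300$/population, $h^2 = 0.3$ — means within ±0.07, strictly
  ordered.
- `validate_rg_h2_gradient()`: 300 genes whose planted $\rho$ rises with
  $h^2$ — mean rG nondecreasing across the $h^2$ threshold grid.
- `validate_h2_recovery()`: 200 genes at $n = 500$, target 0.4 — mean
  within ±0.03 (plus grid-search likelihood agreement within 0.02 in the
  test suite).
- `validate_sparse_alpha_contrast()`: 300 genes, 1–3 causal SNPs — the
  lasso beats $\alpha = 0.05$ on a majority of genes and by more than it
  beats $\alpha = 0.5$.
- `validate_transfer_ancestry()`: train at $n = 300$, two equal test
  cohorts of 100 with pairwise $\rho$ 0.9 vs 0.3 — $\pi_1$ higher in the
  architecture-sharing cohort.
- `validate_fst_mechanism()`: multi-locus $F_{ST}$ within ±0.01 of the
  generative $F \in \{0.05, 0.1, 0.2\}$ over 10,000 SNPs; a panel with
  planted frequency-divergent causal SNPs yields higher divergent-group
  model $F_{ST}$ and Wilcoxon $p < 0.01$ at every threshold.

These sizes keep each experiment in the minutes range on a single core
while leaving the Monte-Carlo error comfortably inside the stated bands.
`scripts/acceptance.R` reruns all of them from scratch under a caller
seed.

# What passing these checks does and does not show

The generator emulates differentiated allele frequencies, sparse or dense
cis architectures, tunable heritability and cross-population effect
correlation. It does **not** emulate linkage disequilibrium from a shared
genealogy, local-ancestry tracts in admixed individuals, genotype error or
imputation uncertainty, sex chromosomes, indels, or expression count
noise — so the validations establish the estimators' correctness and
calibration under the stated model, not robustness to every artefact of
real cohort data. Real-data mode accepts VCF or dosage-TSV genotypes and
tabular expression through the same interfaces.

# Degenerate inputs and tie-breaks

Monomorphic SNPs: always kept by LD pruning (undefined $r^2$), excluded
from eQTL testing and GRMs, flagged NA in $F_{ST}$. Genes without
testable cis SNPs are skipped with a notice. Zero-variance phenotypes are
errors in REML and elastic-net fitting; a zero-variance held-out fold is
excluded from the nested-CV mean with a notice. Ties in BH-adjusted
p-values share a value; the Wilcoxon switches to the exact branch only
when both groups are small and untied. Pipeline stage seeds are derived by
hashing (master seed, stage name), so inserting a stage never shifts
another stage's draws; rerunning `run_pipeline()` with an unchanged
configuration resumes at the first incomplete stage, and a changed
configuration clears stale outputs.
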