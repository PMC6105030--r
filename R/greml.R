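# cis-window GRM construction and restricted maximum likelihood variance
# components: univariate h2 per gene and bivariate genetic correlation (rG)
# between two disjoint cohorts, by average-information (AI) REML with
# likelihood-ascent safeguards and positive-definite bending of the genetic
# (co)variance matrix.

#' Build a cis-window genetic relationship matrix
#'
#' `K = W W' / m` where `W` is the column-standardized dosage matrix over
#' the `m` retained SNPs. Monomorphic SNPs and SNPs below the MAF floor are
#' dropped before standardization.
#'
#' @param genotypes A [genotype_matrix()].
#' @param snp_subset SNP ids to use (default: all SNPs in `genotypes`).
#' @param maf_min Minimum minor-allele frequency computed in this sample
#'   (default 0, i.e. only monomorphic SNPs are dropped).
#' @return A `grm` object: list with `samples`, `matrix`, `n_snps_used`.
#' @export
build_cis_grm <- function(genotypes, snp_subset = NULL, maf_min = 0) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (is.null(snp_subset)) {
    snp_subset <- genotypes$snps$snp_id
  }
  geno <- subset_snps(genotypes, snp_subset)
  p <- colMeans(geno$dosages) / 2
  maf <- pmin(p, 1 - p)
  keep <- maf > max(maf_min, 0) & apply(geno$dosages, 2L, stats::sd) > 0
  if (!any(keep)) {
    stop("all SNPs filtered out (monomorphic or below MAF floor)", call. = FALSE)
  }
  W <- standardize_columns(geno$dosages[, keep, drop = FALSE])
  m <- ncol(W)
  structure(
    list(samples = geno$samples, matrix = tcrossprod(W) / m, n_snps_used = m),
    class = "grm"
  )
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm> %d samples, %d SNPs used, mean diag = %.3f\n",
              length(x$samples), x$n_snps_used, mean(diag(x$matrix))))
  invisible(x)
}

#' Build within- and cross-population GRM blocks on a shared SNP set
#'
#' For a bivariate fit over two disjoint cohorts three relationship
#' matrices are needed: `A` and `B` within each population and the cross
#' matrix `C`. All three are blocks of one GRM computed on the stacked
#' combined sample (dosages standardized with combined-sample means and
#' variances). A common standardization is essential: it makes the joint
#' genetic covariance `[[s1 A, s12 C], [s12 C', s2 B]]` positive
#' semidefinite for every admissible correlation `|rho| <= 1`, whereas
#' mixing per-population and combined scalings leaves it indefinite the
#' moment `s12 != 0`.
#'
#' @param genotypes_pop1,genotypes_pop2 [genotype_matrix()] objects with
#'   disjoint samples.
#' @param snp_subset SNP ids shared by both (default: intersection).
#' @param maf_min MAF floor applied in the combined sample; SNPs
#'   monomorphic in either cohort are also dropped.
#' @return A list with `grm1`, `grm2` (`grm` objects holding the diagonal
#'   blocks) and `cross` (the n1 x n2 off-diagonal block).
#' @export
build_cross_grm <- function(genotypes_pop1, genotypes_pop2, snp_subset = NULL,
                            maf_min = 0) {
  if (is.null(snp_subset)) {
    snp_subset <- intersect(genotypes_pop1$snps$snp_id,
                            genotypes_pop2$snps$snp_id)
  }
  g1 <- subset_snps(genotypes_pop1, snp_subset)
  g2 <- subset_snps(genotypes_pop2, snp_subset)
  stacked <- rbind(g1$dosages, g2$dosages)
  p <- colMeans(stacked) / 2
  sdv <- apply(stacked, 2L, stats::sd)
  keep <- pmin(p, 1 - p) > max(maf_min, 0) & sdv > 0 &
    apply(g1$dosages, 2L, stats::sd) > 0 & apply(g2$dosages, 2L, stats::sd) > 0
  if (!any(keep)) {
    stop("all SNPs filtered out (monomorphic or below MAF floor)", call. = FALSE)
  }
  Wc <- standardize_columns(stacked[, keep, drop = FALSE])
  m <- ncol(Wc)
  n1 <- nrow(g1$dosages)
  K <- tcrossprod(Wc) / m
  i1 <- seq_len(n1)
  grm1 <- structure(list(samples = g1$samples,
                         matrix = K[i1, i1, drop = FALSE],
                         n_snps_used = m), class = "grm")
  grm2 <- structure(list(samples = g2$samples,
                         matrix = K[-i1, -i1, drop = FALSE],
                         n_snps_used = m), class = "grm")
  list(grm1 = grm1, grm2 = grm2, cross = K[i1, -i1, drop = FALSE],
       n_snps_used = m,
       factors = list(W1 = Wc[i1, , drop = FALSE] / sqrt(m),
                      W2 = Wc[-i1, , drop = FALSE] / sqrt(m)))
}

# Restricted log-likelihood pieces in the eigenbasis of K (univariate).
reml_uni_ll <- function(theta, lambda, ystar, Xstar) {
  d <- theta[1] * lambda + theta[2]
  if (any(d <= 0)) return(-Inf)
  XtVinvX <- crossprod(Xstar / d, Xstar)
  chX <- tryCatch(chol(XtVinvX), error = function(e) NULL)
  if (is.null(chX)) return(-Inf)
  XtVinvy <- crossprod(Xstar, ystar / d)
  beta_part <- backsolve(chX, forwardsolve(t(chX), XtVinvy))
  yPy <- sum(ystar^2 / d) - sum(XtVinvy * beta_part)
  -0.5 * (sum(log(d)) + 2 * sum(log(diag(chX))) + yPy)
}

#' Univariate cis heritability by AI-REML
#'
#' Fits `y = X b + g + e` with `var(y) = K sigma_g^2 + I sigma_e^2` by
#' restricted maximum likelihood. The GRM is eigendecomposed once, after
#' which each average-information update is linear-time; non-improving AI
#' steps fall back to step-halving and an EM update so the restricted
#' log-likelihood never decreases across accepted iterations. Variance
#' components are kept nonnegative by projection onto a small positive
#' floor.
#'
#' @param grm A `grm` from [build_cis_grm()].
#' @param phenotype Numeric phenotype vector aligned with `grm$samples`.
#' @param covariates Optional [covariate_set()] (fixed effects; an
#'   intercept is always included).
#' @param tol Convergence tolerance on the restricted log-likelihood
#'   change (default 1e-8).
#' @param max_iter Maximum iterations (default 100).
#' @return An `h2_estimate` object: list with `sigma_g2`, `sigma_e2`, `h2`,
#'   `se`, `converged`, `n_iter`, `loglik`.
#' @export
reml_univariate_h2 <- function(grm, phenotype, covariates = NULL,
                               tol = 1e-8, max_iter = 100L) {
  stopifnot(inherits(grm, "grm"))
  y <- as.numeric(phenotype)
  n <- length(y)
  stopifnot(n == length(grm$samples))
  vy <- stats::var(y)
  if (vy <= 0) {
    stop("phenotype variance is zero", call. = FALSE)
  }
  X <- cbind(intercept = rep(1, n), covariate_matrix(covariates, grm$samples))
  if (qr(X)$rank < ncol(X)) {
    stop("fixed-effect design is singular", call. = FALSE)
  }
  eig <- eigen(grm$matrix, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  U <- eig$vectors
  ystar <- drop(crossprod(U, y))
  Xstar <- crossprod(U, X)

  floor_v <- 1e-8 * vy
  theta <- c(g = vy / 2, e = vy / 2)
  ll <- reml_uni_ll(theta, lambda, ystar, Xstar)
  ll_trace <- ll
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    d <- theta[1] * lambda + theta[2]
    XtVinvX <- crossprod(Xstar / d, Xstar)
    XtVinvX_inv <- solve(XtVinvX)
    XtVinvy <- crossprod(Xstar, ystar / d)
    bhat <- XtVinvX_inv %*% XtVinvy
    # P y in the eigenbasis
    r <- ystar / d - (Xstar %*% bhat) / d
    # traces of P V_k for V_g = diag(lambda), V_e = I (eigenbasis)
    Xd <- Xstar / d
    trPVg <- sum(lambda / d) - sum((Xd %*% XtVinvX_inv) * (Xd * lambda))
    trPVe <- sum(1 / d) - sum((Xd %*% XtVinvX_inv) * Xd)
    s_g <- lambda * r
    s_e <- r
    Pmv <- function(v) {
      v / d - (Xstar %*% (XtVinvX_inv %*% crossprod(Xstar, v / d))) / d
    }
    t_g <- Pmv(s_g)
    t_e <- Pmv(s_e)
    grad <- 0.5 * c(sum(r * s_g) - trPVg,
                    sum(r * s_e) - trPVe)
    AI <- 0.5 * matrix(c(sum(s_g * t_g), sum(s_g * t_e),
                         sum(s_g * t_e), sum(s_e * t_e)), 2, 2)
    step <- tryCatch(solve(AI, grad), error = function(e) grad / n)
    accepted <- FALSE
    for (h in 0:10) {
      cand <- pmax(theta + step / 2^h, floor_v)
      ll_new <- reml_uni_ll(cand, lambda, ystar, Xstar)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) {
        accepted <- TRUE
        break
      }
    }
    if (!accepted) {
      # EM update: guaranteed ascent
      cand <- pmax(c(
        theta[1] + theta[1]^2 * (sum(r * s_g) - trPVg) / n,
        theta[2] + theta[2]^2 * (sum(r * s_e) - trPVe) / n
      ), floor_v)
      ll_new <- reml_uni_ll(cand, lambda, ystar, Xstar)
      if (!is.finite(ll_new)) {
        break
      }
    }
    delta <- ll_new - ll
    theta <- cand
    ll <- ll_new
    ll_trace <- c(ll_trace, ll)
    if (abs(delta) < tol) {
      converged <- TRUE
      break
    }
  }
  # SE of h2 by delta method from the inverse AI matrix at the optimum
  d <- theta[1] * lambda + theta[2]
  XtVinvX_inv <- solve(crossprod(Xstar / d, Xstar))
  bhat <- XtVinvX_inv %*% crossprod(Xstar, ystar / d)
  r <- ystar / d - (Xstar %*% bhat) / d
  Pmv <- function(v) {
    v / d - (Xstar %*% (XtVinvX_inv %*% crossprod(Xstar, v / d))) / d
  }
  s_g <- lambda * r; s_e <- r
  t_g <- Pmv(s_g); t_e <- Pmv(s_e)
  AI <- 0.5 * matrix(c(sum(s_g * t_g), sum(s_g * t_e),
                       sum(s_g * t_e), sum(s_e * t_e)), 2, 2)
  se <- NA_real_
  tot <- theta[1] + theta[2]
  h2 <- unname(theta[1] / tot)
  AIinv <- tryCatch(solve(AI), error = function(e) NULL)
  if (!is.null(AIinv)) {
    gvec <- c(theta[2], -theta[1]) / tot^2
    v <- drop(t(gvec) %*% AIinv %*% gvec)
    if (is.finite(v) && v >= 0) se <- sqrt(v)
  }
  structure(
    list(sigma_g2 = unname(theta[1]), sigma_e2 = unname(theta[2]),
         h2 = h2, se = se, converged = converged, n_iter = iter,
         loglik = ll, ll_trace = ll_trace),
    class = "h2_estimate"
  )
}

#' @export
print.h2_estimate <- function(x, ...) {
  cat(sprintf("<h2_estimate> h2 = %.3f (se %.3f), sigma_g2 = %.3g, sigma_e2 = %.3g, %s in %d iter\n",
              x$h2, x$se, x$sigma_g2, x$sigma_e2,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

# --- bivariate machinery -----------------------------------------------------

# V and restricted log-likelihood for the stacked two-cohort model.
bivar_V <- function(theta, A, B, C12) {
  n1 <- nrow(A); n2 <- nrow(B)
  V <- matrix(0, n1 + n2, n1 + n2)
  i1 <- seq_len(n1); i2 <- n1 + seq_len(n2)
  V[i1, i1] <- theta[1] * A + diag(theta[4], n1)
  V[i2, i2] <- theta[2] * B + diag(theta[5], n2)
  V[i1, i2] <- theta[3] * C12
  V[i2, i1] <- t(V[i1, i2])
  V
}

bivar_ll <- function(theta, A, B, C12, y, X, ll_only = FALSE) {
  V <- bivar_V(theta, A, B, C12)
  ch <- tryCatch(suppressWarnings(chol(V)), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf))
  # with the Cholesky factor, V^{-1} M costs two triangular solves
  Vsolve <- function(M) backsolve(ch, forwardsolve(t(ch), M))
  VinvX <- Vsolve(X)
  XtVinvX <- crossprod(X, VinvX)
  chX <- tryCatch(chol(XtVinvX), error = function(e) NULL)
  if (is.null(chX)) return(list(ll = -Inf))
  XtVinvX_inv <- chol2inv(chX)
  Vinvy <- drop(Vsolve(y))
  XtVinvy <- crossprod(X, Vinvy)
  yPy <- sum(y * Vinvy) - drop(crossprod(XtVinvy, XtVinvX_inv %*% XtVinvy))
  ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chX))) + yPy)
  if (ll_only) return(list(ll = ll))
  list(ll = ll, Vinv = chol2inv(ch), VinvX = VinvX,
       XtVinvX_inv = XtVinvX_inv, Vinvy = Vinvy, XtVinvy = XtVinvy)
}

# Floor the eigenvalues of the 2x2 genetic (co)variance matrix at
# `eps_frac * trace`, then rescale to restore the original variances, so the
# implied correlation is strictly inside (-1, 1).
bend_genetic_matrix <- function(sg1, sg2, sg12, eps_frac = 1e-6) {
  sg1 <- unname(sg1); sg2 <- unname(sg2); sg12 <- unname(sg12)
  G <- matrix(c(sg1, sg12, sg12, sg2), 2, 2)
  e <- eigen(G, symmetric = TRUE)
  floor_val <- eps_frac * max(sum(abs(diag(G))), .Machine$double.eps)
  vals <- pmax(e$values, floor_val)
  Gb <- e$vectors %*% diag(vals) %*% t(e$vectors)
  # restore variances, keep the bent correlation
  rho <- Gb[1, 2] / sqrt(Gb[1, 1] * Gb[2, 2])
  sg12_b <- rho * sqrt(sg1 * sg2)
  c(sg1 = sg1, sg2 = sg2, sg12 = sg12_b)
}

#' Bivariate genetic correlation between two populations by AI-REML
#'
#' Estimates the five variance components
#' `(sigma_g1^2, sigma_g2^2, sigma_g12, sigma_e1^2, sigma_e2^2)` of the
#' stacked model for two disjoint cohorts, where the phenotypic covariance
#' is `A sigma_g1^2 + I sigma_e1^2` within population 1,
#' `B sigma_g2^2 + I sigma_e2^2` within population 2 and `C sigma_g12`
#' across (the residual covariance is identically zero because no
#' individual belongs to both cohorts). Average-information updates with
#' step-halving keep the restricted likelihood ascending. If the genetic
#' (co)variance matrix loses positive definiteness, or the implied
#' `rG = sigma_g12 / sqrt(sigma_g1^2 sigma_g2^2)` leaves \[-1, 1\], the
#' component matrix is bent by eigenvalue flooring and the event recorded.
#' A fit with either genetic variance at the zero boundary is reported as
#' non-converged with reason "degenerate genetic variance" (rG undefined).
#'
#' @param grm1,grm2 Within-population `grm` objects from
#'   [build_cross_grm()] (same SNP set).
#' @param grm_cross The n1 x n2 cross block from [build_cross_grm()].
#' @param y1,y2 Phenotype vectors for the two cohorts.
#' @param covariates1,covariates2 Optional [covariate_set()]s (fixed
#'   effects per cohort; intercepts always included).
#' @param tol Convergence tolerance on the restricted log-likelihood
#'   change (default 1e-8).
#' @param max_iter Maximum iterations (default 100).
#' @return An `rg_estimate`: list with components `sigma_g1_2`,
#'   `sigma_g2_2`, `sigma_g1g2`, `sigma_e1_2`, `sigma_e2_2`, `rg`, `se_rg`,
#'   `converged`, `bent`, `n_iter`, `loglik`, `reason`.
#' @export
reml_bivariate_rg <- function(grm1, grm2, grm_cross, y1, y2,
                              covariates1 = NULL, covariates2 = NULL,
                              tol = 1e-8, max_iter = 100L) {
  stopifnot(inherits(grm1, "grm"), inherits(grm2, "grm"))
  A <- grm1$matrix; B <- grm2$matrix; C12 <- grm_cross
  n1 <- nrow(A); n2 <- nrow(B)
  stopifnot(length(y1) == n1, length(y2) == n2,
            nrow(C12) == n1, ncol(C12) == n2)
  if (length(intersect(grm1$samples, grm2$samples))) {
    stop("cohorts must have disjoint samples", call. = FALSE)
  }
  y <- c(as.numeric(y1), as.numeric(y2))
  X1 <- cbind(rep(1, n1), covariate_matrix(covariates1, grm1$samples))
  X2 <- cbind(rep(1, n2), covariate_matrix(covariates2, grm2$samples))
  X <- matrix(0, n1 + n2, ncol(X1) + ncol(X2))
  X[seq_len(n1), seq_len(ncol(X1))] <- X1
  X[n1 + seq_len(n2), ncol(X1) + seq_len(ncol(X2))] <- X2

  v1 <- stats::var(y1); v2 <- stats::var(y2)
  floor1 <- 1e-8 * v1; floor2 <- 1e-8 * v2
  theta <- c(g1 = v1 / 2, g2 = v2 / 2, g12 = 0, e1 = v1 / 2, e2 = v2 / 2)
  bent <- FALSE
  project <- function(th) {
    th[1] <- max(th[1], floor1); th[2] <- max(th[2], floor2)
    th[4] <- max(th[4], floor1); th[5] <- max(th[5], floor2)
    # keep the genetic matrix PD (bend if needed)
    was_bent <- FALSE
    lim <- sqrt(th[1] * th[2])
    if (abs(th[3]) >= lim) {
      b <- bend_genetic_matrix(th[1], th[2], th[3])
      th[3] <- b[["sg12"]]
      was_bent <- TRUE
    }
    attr(th, "bent") <- was_bent
    th
  }
  theta <- project(theta)
  state <- bivar_ll(theta, A, B, C12, y, X)
  ll <- state$ll
  ll_trace <- ll
  i1 <- seq_len(n1); i2 <- n1 + seq_len(n2)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    Vinv <- state$Vinv
    P <- Vinv - state$VinvX %*% state$XtVinvX_inv %*% t(state$VinvX)
    r <- drop(P %*% y)
    r1 <- r[i1]; r2 <- r[i2]
    # traces tr(P V_k) via elementwise products with the symmetric blocks
    P11 <- P[i1, i1]; P22 <- P[i2, i2]; P12 <- P[i1, i2]
    trP <- c(sum(P11 * A), sum(P22 * B), 2 * sum(P12 * C12),
             sum(diag(P11)), sum(diag(P22)))
    # s_k = V_k r
    S <- matrix(0, n1 + n2, 5)
    S[i1, 1] <- A %*% r1
    S[i2, 2] <- B %*% r2
    S[i1, 3] <- C12 %*% r2
    S[i2, 3] <- crossprod(C12, r1)
    S[i1, 4] <- r1
    S[i2, 5] <- r2
    yPVPy <- colSums(S * r)
    grad <- 0.5 * (yPVPy - trP)
    T <- P %*% S
    AI <- 0.5 * crossprod(S, T)
    step <- tryCatch(solve(AI, grad), error = function(e) grad / (n1 + n2))
    accepted <- FALSE
    for (h in 0:10) {
      cand <- project(theta + step / 2^h)
      ll_new <- bivar_ll(cand, A, B, C12, y, X, ll_only = TRUE)$ll
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) {
        accepted <- TRUE
        break
      }
    }
    if (!accepted) {
      # gradient backtracking fallback (ascent direction)
      gstep <- grad / max(sum(abs(grad)), 1)
      for (h in 0:20) {
        cand <- project(theta + gstep / 2^h)
        ll_new <- bivar_ll(cand, A, B, C12, y, X, ll_only = TRUE)$ll
        if (is.finite(ll_new) && ll_new >= ll - 1e-12) {
          accepted <- TRUE
          break
        }
      }
    }
    if (!accepted) break
    delta <- ll_new - ll
    theta <- cand
    bent <- bent || isTRUE(attr(cand, "bent"))
    state <- bivar_ll(theta, A, B, C12, y, X)
    ll <- state$ll
    ll_trace <- c(ll_trace, ll)
    if (abs(delta) < tol) {
      converged <- TRUE
      break
    }
  }
  degenerate <- theta[1] <= floor1 * 1.01 || theta[2] <= floor2 * 1.01
  rg <- NA_real_
  se_rg <- NA_real_
  reason <- NA_character_
  if (degenerate) {
    converged <- FALSE
    reason <- "degenerate genetic variance"
  } else {
    rg <- unname(theta[3] / sqrt(theta[1] * theta[2]))
    if (abs(rg) > 1) {
      b <- bend_genetic_matrix(theta[1], theta[2], theta[3])
      theta[3] <- b["sg12"]
      rg <- unname(theta[3] / sqrt(theta[1] * theta[2]))
      bent <- TRUE
    }
    rg <- max(min(rg, 1), -1)
    # delta-method SE from the genetic block of the inverse AI matrix
    Vinv <- state$Vinv
    P <- Vinv - state$VinvX %*% state$XtVinvX_inv %*% t(state$VinvX)
    r <- drop(P %*% y)
    r1 <- r[i1]; r2 <- r[i2]
    S <- matrix(0, n1 + n2, 5)
    S[i1, 1] <- A %*% r1
    S[i2, 2] <- B %*% r2
    S[i1, 3] <- C12 %*% r2
    S[i2, 3] <- crossprod(C12, r1)
    S[i1, 4] <- r1
    S[i2, 5] <- r2
    AI <- 0.5 * crossprod(S, P %*% S)
    AIinv <- tryCatch(solve(AI), error = function(e) NULL)
    if (!is.null(AIinv)) {
      gvec <- c(-0.5 * rg / theta[1], -0.5 * rg / theta[2],
                1 / sqrt(theta[1] * theta[2]), 0, 0)
      v <- drop(t(gvec) %*% AIinv %*% gvec)
      if (is.finite(v) && v >= 0) se_rg <- sqrt(v)
    }
  }
  structure(
    list(sigma_g1_2 = unname(theta[1]), sigma_g2_2 = unname(theta[2]),
         sigma_g1g2 = unname(theta[3]), sigma_e1_2 = unname(theta[4]),
         sigma_e2_2 = unname(theta[5]), rg = rg, se_rg = se_rg,
         converged = converged, bent = bent, n_iter = iter,
         loglik = ll, ll_trace = ll_trace, reason = reason),
    class = "rg_estimate"
  )
}

#' @export
print.rg_estimate <- function(x, ...) {
  cat(sprintf("<rg_estimate> rG = %s (se %s), %s%s\n",
              format(x$rg, digits = 3), format(x$se_rg, digits = 3),
              if (x$converged) "converged" else
                paste0("NOT converged",
                       if (!is.na(x$reason)) paste0(" (", x$reason, ")") else ""),
              if (x$bent) ", bent" else ""))
  invisible(x)
}

# Exact reduced-rank bivariate AI-REML for intercept-only fixed effects.
#
# With m cis SNPs and factor blocks W1 (n1 x m), W2 (n2 x m) such that the
# genetic covariance blocks are W1 W1', W2 W2', W1 W2', each cohort's data
# can be rotated onto an orthonormal basis of [1, Wk]; the orthogonal
# complement contributes only iid residual variance through RSS_k and
# df_k = n_k - rank. The restricted likelihood, its gradient and the AI
# matrix decompose exactly, so each iteration costs O((2m)^3) instead of
# O((n1+n2)^3). Identical model and estimates to reml_bivariate_rg().
reml_bivariate_lowrank <- function(W1, W2, y1, y2, tol = 1e-8,
                                   max_iter = 100L) {
  n1 <- nrow(W1); n2 <- nrow(W2)
  qr1 <- qr(cbind(1, W1)); r1 <- qr1$rank
  qr2 <- qr(cbind(1, W2)); r2 <- qr2$rank
  Q1 <- qr.Q(qr1)[, seq_len(r1), drop = FALSE]
  Q2 <- qr.Q(qr2)[, seq_len(r2), drop = FALSE]
  yt1 <- drop(crossprod(Q1, y1)); yt2 <- drop(crossprod(Q2, y2))
  Wt1 <- crossprod(Q1, W1); Wt2 <- crossprod(Q2, W2)
  Xt <- matrix(0, r1 + r2, 2)
  Xt[seq_len(r1), 1] <- drop(crossprod(Q1, rep(1, n1)))
  Xt[r1 + seq_len(r2), 2] <- drop(crossprod(Q2, rep(1, n2)))
  rss1 <- sum(y1^2) - sum(yt1^2); df1 <- n1 - r1
  rss2 <- sum(y2^2) - sum(yt2^2); df2 <- n2 - r2
  G11 <- tcrossprod(Wt1); G22 <- tcrossprod(Wt2); G12 <- tcrossprod(Wt1, Wt2)
  yt <- c(yt1, yt2)
  i1 <- seq_len(r1); i2 <- r1 + seq_len(r2)
  q <- r1 + r2

  build_V <- function(th) {
    V <- matrix(0, q, q)
    V[i1, i1] <- th[1] * G11 + diag(th[4], r1)
    V[i2, i2] <- th[2] * G22 + diag(th[5], r2)
    V[i1, i2] <- th[3] * G12
    V[i2, i1] <- t(V[i1, i2])
    V
  }
  eval_ll <- function(th, full = FALSE) {
    ch <- tryCatch(suppressWarnings(chol(build_V(th))),
                   error = function(e) NULL)
    if (is.null(ch)) return(list(ll = -Inf))
    Vsolve <- function(M) backsolve(ch, forwardsolve(t(ch), M))
    VinvX <- Vsolve(Xt)
    XtVinvX <- crossprod(Xt, VinvX)
    chX <- tryCatch(chol(XtVinvX), error = function(e) NULL)
    if (is.null(chX)) return(list(ll = -Inf))
    XtVinvX_inv <- chol2inv(chX)
    Vinvy <- drop(Vsolve(yt))
    XtVinvy <- crossprod(Xt, Vinvy)
    yPy <- sum(yt * Vinvy) - drop(crossprod(XtVinvy, XtVinvX_inv %*% XtVinvy))
    ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chX))) + yPy +
                    df1 * log(th[4]) + df2 * log(th[5]) +
                    rss1 / th[4] + rss2 / th[5])
    if (!full) return(list(ll = ll))
    P <- chol2inv(ch) - VinvX %*% XtVinvX_inv %*% t(VinvX)
    list(ll = ll, P = P)
  }
  derivs <- function(th, P) {
    r <- drop(P %*% yt)
    ra <- r[i1]; rb <- r[i2]
    P11 <- P[i1, i1]; P22 <- P[i2, i2]; P12 <- P[i1, i2]
    trP <- c(sum(P11 * G11), sum(P22 * G22), 2 * sum(P12 * G12),
             sum(diag(P11)) + df1 / th[4], sum(diag(P22)) + df2 / th[5])
    S <- matrix(0, q, 5)
    S[i1, 1] <- G11 %*% ra
    S[i2, 2] <- G22 %*% rb
    S[i1, 3] <- G12 %*% rb
    S[i2, 3] <- crossprod(G12, ra)
    S[i1, 4] <- ra
    S[i2, 5] <- rb
    yPVPy <- colSums(S * r) + c(0, 0, 0, rss1 / th[4]^2, rss2 / th[5]^2)
    AI <- 0.5 * crossprod(S, P %*% S)
    AI[4, 4] <- AI[4, 4] + 0.5 * rss1 / th[4]^3
    AI[5, 5] <- AI[5, 5] + 0.5 * rss2 / th[5]^3
    list(grad = 0.5 * (yPVPy - trP), AI = AI)
  }

  v1 <- stats::var(y1); v2 <- stats::var(y2)
  floor1 <- 1e-8 * v1; floor2 <- 1e-8 * v2
  theta <- c(g1 = v1 / 2, g2 = v2 / 2, g12 = 0, e1 = v1 / 2, e2 = v2 / 2)
  bent <- FALSE
  project <- function(th) {
    th[1] <- max(th[1], floor1); th[2] <- max(th[2], floor2)
    th[4] <- max(th[4], floor1); th[5] <- max(th[5], floor2)
    was_bent <- FALSE
    if (abs(th[3]) >= sqrt(th[1] * th[2])) {
      b <- bend_genetic_matrix(th[1], th[2], th[3])
      th[3] <- b[["sg12"]]
      was_bent <- TRUE
    }
    attr(th, "bent") <- was_bent
    th
  }
  theta <- project(theta)
  state <- eval_ll(theta, full = TRUE)
  ll <- state$ll
  ll_trace <- ll
  converged <- FALSE
  iter <- 0L
  AI_last <- NULL
  for (iter in seq_len(max_iter)) {
    dv <- derivs(theta, state$P)
    AI_last <- dv$AI
    step <- tryCatch(solve(dv$AI, dv$grad), error = function(e) dv$grad / q)
    accepted <- FALSE
    for (h in 0:10) {
      cand <- project(theta + step / 2^h)
      ll_new <- eval_ll(cand)$ll
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) {
        accepted <- TRUE
        break
      }
    }
    if (!accepted) {
      gstep <- dv$grad / max(sum(abs(dv$grad)), 1)
      for (h in 0:20) {
        cand <- project(theta + gstep / 2^h)
        ll_new <- eval_ll(cand)$ll
        if (is.finite(ll_new) && ll_new >= ll - 1e-12) {
          accepted <- TRUE
          break
        }
      }
    }
    if (!accepted) break
    delta <- ll_new - ll
    theta <- cand
    bent <- bent || isTRUE(attr(cand, "bent"))
    state <- eval_ll(theta, full = TRUE)
    ll <- state$ll
    ll_trace <- c(ll_trace, ll)
    if (abs(delta) < tol) {
      converged <- TRUE
      break
    }
  }
  degenerate <- theta[1] <= floor1 * 1.01 || theta[2] <= floor2 * 1.01
  rg <- NA_real_; se_rg <- NA_real_; reason <- NA_character_
  if (degenerate) {
    converged <- FALSE
    reason <- "degenerate genetic variance"
  } else {
    rg <- unname(theta[3] / sqrt(theta[1] * theta[2]))
    if (abs(rg) > 1) {
      b <- bend_genetic_matrix(theta[1], theta[2], theta[3])
      theta[3] <- b[["sg12"]]
      rg <- unname(theta[3] / sqrt(theta[1] * theta[2]))
      bent <- TRUE
    }
    rg <- max(min(rg, 1), -1)
    AI <- derivs(theta, state$P)$AI
    AIinv <- tryCatch(solve(AI), error = function(e) NULL)
    if (!is.null(AIinv)) {
      gvec <- c(-0.5 * rg / theta[1], -0.5 * rg / theta[2],
                1 / sqrt(theta[1] * theta[2]), 0, 0)
      v <- drop(t(gvec) %*% AIinv %*% gvec)
      if (is.finite(v) && v >= 0) se_rg <- sqrt(v)
    }
  }
  structure(
    list(sigma_g1_2 = unname(theta[1]), sigma_g2_2 = unname(theta[2]),
         sigma_g1g2 = unname(theta[3]), sigma_e1_2 = unname(theta[4]),
         sigma_e2_2 = unname(theta[5]), rg = rg, se_rg = se_rg,
         converged = converged, bent = bent, n_iter = iter,
         loglik = ll, ll_trace = ll_trace, reason = reason),
    class = "rg_estimate"
  )
}

#' Per-gene bivariate rG across an expression panel pair
#'
#' Runs [build_cross_grm()] and [reml_bivariate_rg()] for every shared gene
#' of two cohorts, using each gene's cis window (SNPs within `window_bp` of
#' the TSS on the gene's chromosome).
#'
#' @param expr1,expr2 [expression_panel()] objects sharing gene annotation.
#' @param geno1,geno2 [genotype_matrix()] objects for the two cohorts.
#' @param window_bp cis window half-width around the TSS (default 1e6).
#' @param maf_min MAF floor for GRM SNPs (default 0.01).
#' @param covariates1,covariates2 Optional fixed-effect covariates.
#' @param tol,max_iter Passed to [reml_bivariate_rg()].
#' @return A tibble with one row per gene: `gene_id`, `h2_1`, `h2_2`
#'   (variance-ratio heritabilities implied by the fit), `rg`, `se_rg`,
#'   `converged`, `bent`, `n_iter`.
#' @export
estimate_rg_panel <- function(expr1, expr2, geno1, geno2, window_bp = 1e6,
                              maf_min = 0.01, covariates1 = NULL,
                              covariates2 = NULL, tol = 1e-8,
                              max_iter = 100L) {
  shared <- intersect(expr1$genes$gene_id, expr2$genes$gene_id)
  purrr::map_dfr(shared, function(gid) {
    ann <- expr1$genes[expr1$genes$gene_id == gid, ]
    ids <- cis_snp_ids(geno1$snps, ann$chromosome[1], ann$tss[1], window_bp)
    ids <- intersect(ids, geno2$snps$snp_id)
    if (!length(ids)) {
      return(tibble::tibble())
    }
    grms <- build_cross_grm(geno1, geno2, ids, maf_min = maf_min)
    y1 <- expr1$values[, gid]
    y2 <- expr2$values[, gid]
    lowrank_ok <- is.null(covariates1) && is.null(covariates2) &&
      ncol(grms$factors$W1) + 1L < min(length(y1), length(y2))
    fit <- if (lowrank_ok) {
      reml_bivariate_lowrank(grms$factors$W1, grms$factors$W2, y1, y2,
                             tol, max_iter)
    } else {
      reml_bivariate_rg(grms$grm1, grms$grm2, grms$cross, y1, y2,
                        covariates1, covariates2, tol, max_iter)
    }
    tibble::tibble(
      gene_id = gid,
      h2_1 = fit$sigma_g1_2 / (fit$sigma_g1_2 + fit$sigma_e1_2),
      h2_2 = fit$sigma_g2_2 / (fit$sigma_g2_2 + fit$sigma_e2_2),
      rg = fit$rg, se_rg = fit$se_rg,
      converged = fit$converged, bent = fit$bent, n_iter = fit$n_iter,
      reason = fit$reason
    )
  })
}

#' Per-gene univariate h2 across an expression panel
#'
#' @param expr An [expression_panel()].
#' @param geno The cohort's [genotype_matrix()].
#' @param window_bp cis window half-width (default 1e6).
#' @param maf_min MAF floor (default 0.01).
#' @param covariates Optional fixed effects.
#' @param tol,max_iter Passed to [reml_univariate_h2()].
#' @return A tibble: `gene_id`, `sigma_g2`, `sigma_e2`, `h2`, `se`,
#'   `converged`, `n_iter`.
#' @export
estimate_h2_panel <- function(expr, geno, window_bp = 1e6, maf_min = 0.01,
                              covariates = NULL, tol = 1e-8, max_iter = 100L) {
  purrr::map_dfr(expr$genes$gene_id, function(gid) {
    ann <- expr$genes[expr$genes$gene_id == gid, ]
    ids <- cis_snp_ids(geno$snps, ann$chromosome[1], ann$tss[1], window_bp)
    if (!length(ids)) {
      return(tibble::tibble())
    }
    grm <- build_cis_grm(geno, ids, maf_min = maf_min)
    fit <- reml_univariate_h2(grm, expr$values[, gid], covariates, tol, max_iter)
    tibble::tibble(gene_id = gid, sigma_g2 = fit$sigma_g2,
                   sigma_e2 = fit$sigma_e2, h2 = fit$h2, se = fit$se,
                   converged = fit$converged, n_iter = fit$n_iter)
  })
}

#' Mean rG across genes at increasing h2 inclusion thresholds
#'
#' For each threshold, retains converged genes whose h2 (the minimum of the
#' two populations' estimates by default, or a single chosen population's)
#' exceeds the threshold, and reports the mean rG with its standard error.
#'
#' @param estimates Tibble from [estimate_rg_panel()] (columns `gene_id`,
#'   `h2_1`, `h2_2`, `rg`, `converged`).
#' @param h2_threshold_grid Numeric thresholds (default
#'   `seq(0, 0.5, 0.1)`).
#' @param h2_rule `"min"` (default), `"pop1"` or `"pop2"`: which h2 the
#'   threshold applies to.
#' @return A tibble: `threshold`, `n_genes`, `mean_rg`, `se_mean_rg`.
#' @export
aggregate_rg <- function(estimates, h2_threshold_grid = seq(0, 0.5, by = 0.1),
                         h2_rule = c("min", "pop1", "pop2")) {
  h2_rule <- match.arg(h2_rule)
  est <- estimates[estimates$converged & !is.na(estimates$rg), ]
  hv <- switch(h2_rule,
               min = pmin(est$h2_1, est$h2_2),
               pop1 = est$h2_1,
               pop2 = est$h2_2)
  out <- purrr::map_dfr(h2_threshold_grid, function(t) {
    keep <- hv > t
    n <- sum(keep)
    tibble::tibble(
      threshold = t, n_genes = n,
      mean_rg = if (n) mean(est$rg[keep]) else NA_real_,
      se_mean_rg = if (n > 1) stats::sd(est$rg[keep]) / sqrt(n) else NA_real_
    )
  })
  class(out) <- c("rg_aggregate", class(out))
  out
}
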