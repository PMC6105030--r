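# Independent oracles used to cross-check package computations.
# Each is written from the defining formula, not by calling package code.

# Elastic-net objective: (1/2n)||y - b0 - Xw||^2 + lambda(a|w|_1 + (1-a)|w|_2^2/2)
enet_objective <- function(y, X, b0, w, lambda, alpha) {
  n <- length(y)
  r <- y - b0 - drop(X %*% w)
  sum(r^2) / (2 * n) +
    lambda * (alpha * sum(abs(w)) + (1 - alpha) * sum(w^2) / 2)
}

# FISTA proximal-gradient solver for the same objective (unstandardized
# predictors), run to high precision. Independent of glmnet.
enet_fista <- function(y, X, lambda, alpha, iters = 20000) {
  n <- length(y)
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)
  yc <- y - mean(y)
  L <- max(eigen(crossprod(Xc) / n, symmetric = TRUE,
                 only.values = TRUE)$values) + lambda * (1 - alpha)
  w <- rep(0, ncol(X))
  z <- w
  t_k <- 1
  soft <- function(u, a) sign(u) * pmax(abs(u) - a, 0)
  for (i in seq_len(iters)) {
    grad <- -crossprod(Xc, yc - Xc %*% z) / n + lambda * (1 - alpha) * z
    w_new <- soft(z - grad / L, lambda * alpha / L)
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    z <- w_new + ((t_k - 1) / t_new) * (w_new - w)
    w <- w_new
    t_k <- t_new
  }
  b0 <- mean(y) - sum(xbar * w)
  list(intercept = b0, weights = w)
}

# Brute-force REML profile over h2 for y = mu + g + e, V = s_t(h2 K + (1-h2) I):
# dense evaluation of the restricted likelihood on a grid, no shortcuts.
reml_grid_oracle <- function(K, y, grid = seq(0, 1, by = 0.01)) {
  n <- length(y)
  X <- matrix(1, n, 1)
  ll <- vapply(grid, function(h2) {
    V0 <- h2 * K + (1 - h2) * diag(n)
    V0inv <- tryCatch(solve(V0), error = function(e) NULL)
    if (is.null(V0inv)) return(-Inf)
    XtVX <- crossprod(X, V0inv %*% X)
    P0 <- V0inv - V0inv %*% X %*% solve(XtVX) %*% t(X) %*% V0inv
    yPy <- drop(t(y) %*% P0 %*% y)
    st <- yPy / (n - 1)
    ld <- determinant(V0, logarithm = TRUE)$modulus
    -0.5 * ((n - 1) * log(st) + ld + log(det(XtVX)) + yPy / st)
  }, 0)
  grid[which.max(ll)]
}

# Weir-Cockerham (1984) two-population theta from genotype dosage vectors,
# written directly from the published component formulas.
wc_theta_oracle <- function(d1, d2) {
  n_i <- c(length(d1), length(d2))
  p_i <- c(mean(d1) / 2, mean(d2) / 2)
  h_i <- c(mean(d1 == 1), mean(d2 == 1))
  r <- 2
  n_bar <- mean(n_i)
  n_c <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
  p_bar <- sum(n_i * p_i) / (r * n_bar)
  s2 <- sum(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- sum(n_i * h_i) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  a / (a + b + cc)
}

# Exact two-sided Wilcoxon rank-sum p-value by exhaustive enumeration of
# all group assignments (no ties assumed).
wilcox_exact_oracle <- function(x, y) {
  vals <- c(x, y)
  n1 <- length(x)
  rk <- rank(vals)
  w_obs <- sum(rk[seq_len(n1)])
  combs <- utils::combn(length(vals), n1)
  w_all <- apply(combs, 2, function(idx) sum(rk[idx]))
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Greedy sliding-window LD pruning re-implemented with explicit loops.
ld_prune_oracle <- function(dos, window, r2_threshold) {
  kept <- integer(0)
  for (j in seq_len(ncol(dos))) {
    if (stats::sd(dos[, j]) == 0) {
      kept <- c(kept, j)
      next
    }
    poly_kept <- kept[apply(dos[, kept, drop = FALSE], 2, stats::sd) > 0]
    win <- utils::tail(poly_kept, window - 1L)
    ok <- TRUE
    for (k in win) {
      if (stats::cor(dos[, j], dos[, k])^2 > r2_threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, j)
  }
  kept
}
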