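# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All randomised operations in the package funnel through this so that a
# seed argument fully determines the output.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic stage seed from a master seed and a stage name, independent of
# stage ordering: a small string hash folded into [0, 2^31 - 2].
derive_seed <- function(master_seed, stage_name) {
  stopifnot(is.character(stage_name), length(stage_name) == 1L)
  codes <- utf8ToInt(stage_name)
  h <- as.double(master_seed) %% 2147483647
  for (k in codes) {
    h <- (h * 131 + k) %% 2147483647
  }
  as.integer(h)
}

assert_prob <- function(x, name, allow_zero = TRUE, allow_one = TRUE) {
  lo <- if (allow_zero) 0 else .Machine$double.eps
  hi <- if (allow_one) 1 else 1 - .Machine$double.eps
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < lo) || any(x > hi)) {
    stop(sprintf("`%s` must lie in %s0, 1%s", name,
                 if (allow_zero) "[" else "(",
                 if (allow_one) "]" else ")"), call. = FALSE)
  }
  invisible(x)
}

# Column standardization used for GRMs and PCA: centre to mean 0, scale to
# unit variance; zero-variance columns are flagged by the caller beforehand.
standardize_columns <- function(mat) {
  ctr <- colMeans(mat)
  sdv <- apply(mat, 2L, stats::sd)
  sweep(sweep(mat, 2L, ctr, "-"), 2L, sdv, "/")
}

# Residualize the columns of `mat` on covariate matrix `cov` (with intercept).
residualize <- function(mat, cov = NULL) {
  mat <- as.matrix(mat)
  if (is.null(cov) || ncol(as.matrix(cov)) == 0L) {
    return(sweep(mat, 2L, colMeans(mat), "-"))
  }
  X <- cbind(1, as.matrix(cov))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    stop("covariate matrix is rank deficient", call. = FALSE)
  }
  mat - X %*% qr.coef(qr_x, mat)
}
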