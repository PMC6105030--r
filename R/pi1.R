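# Storey pi0/pi1 estimation: the replication currency of the analysis.
# pi0(lambda) = #{p > lambda} / (m (1 - lambda)) estimates the null
# fraction under uniform null p-values; smoothing pi0(lambda) over a
# lambda grid and extrapolating to lambda -> 1 removes the contamination
# by alternatives. pi1 = 1 - pi0 is read as the expected true positive
# rate of a discovery set examined in a replication cohort.

#' Estimate the null proportion pi0 and true-positive rate pi1
#'
#' Computes `pi0(lambda)` on a grid and extrapolates to `lambda -> 1` with
#' a natural cubic smoothing spline (df = 3) evaluated at the largest grid
#' value, the standard qvalue-style recipe. For small collections
#' (`m < 100`) or when smoothing fails, falls back to the fixed-lambda
#' estimate at `lambda = 0.5`. Estimates are clamped to \[0, 1\] after
#' extrapolation (clamping is reported via `method`).
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param lambda_grid Grid inside (0, 1); default `seq(0.05, 0.95, 0.05)`.
#' @return A `pi1_estimate` object: list with `pi0`, `pi1`, `n_pvalues`,
#'   `method` (`"smoother"` or `"fixed"`), `lambda_used`.
#' @examples
#' est <- estimate_pi0(runif(500))
#' est$pi1
#' @export
estimate_pi0 <- function(p_values, lambda_grid = seq(0.05, 0.95, by = 0.05)) {
  if (!length(p_values)) {
    stop("`p_values` is empty", call. = FALSE)
  }
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  lambda_grid <- sort(unique(lambda_grid))
  if (any(lambda_grid <= 0) || any(lambda_grid >= 1)) {
    stop("`lambda_grid` must lie strictly inside (0, 1)", call. = FALSE)
  }
  m <- length(p_values)
  pi0_lambda <- vapply(lambda_grid, function(l) {
    sum(p_values > l) / (m * (1 - l))
  }, 0)
  method <- "smoother"
  lambda_used <- max(lambda_grid)
  pi0 <- NA_real_
  if (m >= 100 && length(lambda_grid) >= 4) {
    fit <- tryCatch(
      stats::smooth.spline(lambda_grid, pi0_lambda, df = 3),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      pi0 <- stats::predict(fit, x = lambda_used)$y
    }
  }
  if (!is.finite(pi0)) {
    method <- "fixed"
    lambda_used <- 0.5
    pi0 <- sum(p_values > lambda_used) / (m * (1 - lambda_used))
  }
  if (pi0 < 0 || pi0 > 1) {
    method <- paste0(method, "+clamped")
    pi0 <- min(max(pi0, 0), 1)
  }
  structure(
    list(pi0 = pi0, pi1 = 1 - pi0, n_pvalues = m,
         method = method, lambda_used = lambda_used),
    class = "pi1_estimate"
  )
}

#' @export
print.pi1_estimate <- function(x, ...) {
  cat(sprintf("<pi1_estimate> pi1 = %.3f (pi0 = %.3f), m = %d, %s at lambda = %.2f\n",
              x$pi1, x$pi0, x$n_pvalues, x$method, x$lambda_used))
  invisible(x)
}

#' Replication true-positive rate for a discovery set
#'
#' Restricts a discovery result table to units passing the discovery FDR
#' threshold that are also present in the replication collection, then
#' estimates pi1 from their replication p-values. Units are whatever key
#' the two tables share, typically `"snp_id:gene_id"` pairs for eQTL
#' replication or `gene_id` for prediction-model transfer.
#'
#' @param discovery Tibble with columns `unit` and `fdr` (e.g. built from a
#'   [map_cis_eqtls()] result via `paste(snp_id, gene_id, sep = ":")`).
#' @param replication_pvalues Tibble with columns `unit` and `p_value`.
#' @param discovery_fdr FDR threshold defining the discovery set
#'   (default 0.05).
#' @param ... Passed to [estimate_pi0()].
#' @return A `pi1_estimate` with an extra field `n_discovery` (units
#'   passing the threshold) and `n_overlap` (those present in replication).
#' @export
replication_pi1 <- function(discovery, replication_pvalues,
                            discovery_fdr = 0.05, ...) {
  stopifnot(all(c("unit", "fdr") %in% names(discovery)),
            all(c("unit", "p_value") %in% names(replication_pvalues)))
  passing <- unique(discovery$unit[discovery$fdr < discovery_fdr])
  idx <- match(passing, replication_pvalues$unit)
  found <- !is.na(idx)
  if (!any(found)) {
    stop("no shared units between discovery-passing set and replication",
         call. = FALSE)
  }
  est <- estimate_pi0(replication_pvalues$p_value[idx[found]], ...)
  est$n_discovery <- length(passing)
  est$n_overlap <- sum(found)
  est
}
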