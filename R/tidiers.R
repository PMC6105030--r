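# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.h2_estimate <- function(x, ...) {
  tibble::tibble(
    term = c("sigma_g2", "sigma_e2", "h2"),
    estimate = c(x$sigma_g2, x$sigma_e2, x$h2),
    std.error = c(NA_real_, NA_real_, x$se)
  )
}

#' @export
glance.h2_estimate <- function(x, ...) {
  tibble::tibble(h2 = x$h2, std.error = x$se, logLik = x$loglik,
                 converged = x$converged, n.iter = x$n_iter)
}

#' @export
tidy.rg_estimate <- function(x, ...) {
  tibble::tibble(
    term = c("sigma_g1_2", "sigma_g2_2", "sigma_g1g2",
             "sigma_e1_2", "sigma_e2_2", "rg"),
    estimate = c(x$sigma_g1_2, x$sigma_g2_2, x$sigma_g1g2,
                 x$sigma_e1_2, x$sigma_e2_2, x$rg),
    std.error = c(rep(NA_real_, 5), x$se_rg)
  )
}

#' @export
glance.rg_estimate <- function(x, ...) {
  tibble::tibble(rg = x$rg, std.error = x$se_rg, logLik = x$loglik,
                 converged = x$converged, bent = x$bent, n.iter = x$n_iter)
}

#' @export
tidy.pi1_estimate <- function(x, ...) {
  tibble::tibble(term = c("pi0", "pi1"), estimate = c(x$pi0, x$pi1))
}

#' @export
glance.pi1_estimate <- function(x, ...) {
  tibble::tibble(pi1 = x$pi1, pi0 = x$pi0, n.pvalues = x$n_pvalues,
                 method = x$method, lambda = x$lambda_used)
}

#' @export
tidy.prediction_models <- function(x, ...) {
  x$weights
}

#' @export
glance.prediction_models <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$performance, .data$alpha),
    n_genes = dplyr::n(),
    mean_r2 = mean(.data$r2, na.rm = TRUE),
    median_r2 = stats::median(.data$r2, na.rm = TRUE),
    mean_n_snps = mean(.data$n_snps_in_model),
    .groups = "drop"
  )
}

#' @export
tidy.transfer_evaluation <- function(x, ...) {
  x$correlations
}

#' @export
glance.transfer_evaluation <- function(x, ...) {
  dplyr::mutate(x$pi1, training = x$training_population,
                test = x$test_cohort)
}

#' Plot mean rG against the h2 inclusion threshold
#'
#' @param object An `rg_aggregate` tibble from [aggregate_rg()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rg_aggregate <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$threshold, y = .data$mean_rg)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_rg - 2 * .data$se_mean_rg,
      ymax = .data$mean_rg + 2 * .data$se_mean_rg
    )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "h2 inclusion threshold", y = "mean rG (+/- 2 SE)") +
    ggplot2::theme_minimal()
}

#' Plot transfer pi1 against the training-R2 inclusion threshold
#'
#' @param object A `transfer_evaluation` from [evaluate_transfer()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.transfer_evaluation <- function(object, ...) {
  ggplot2::ggplot(object$pi1,
                  ggplot2::aes(x = .data$r2_threshold, y = .data$pi1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      title = sprintf("%s -> %s", object$training_population, object$test_cohort),
      x = "training R2 inclusion threshold", y = "pi1"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the divergence-sweep mean FST by group and threshold
#'
#' @param object A tibble from [divergence_wilcoxon()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_divergence_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[c("threshold", "mean_fst_divergent", "mean_fst_similar")],
    -"threshold", names_to = "group", values_to = "mean_fst",
    names_prefix = "mean_fst_"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$threshold),
                                     y = .data$mean_fst,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "R2 difference threshold t", y = "mean model FST",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
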