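# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' Tidy a single-set test result
#'
#' One row per p-value method actually computed.
#'
#' @param x A `tegs_result` from [tegs_test()].
#' @param ... Unused.
#' @return Tibble with `set`, `method`, `p_value`.
#' @export
tidy.tegs_result <- function(x, ...) {
  methods <- c(perm = x$p_perm, satt = x$p_satt, mix = x$p_mix)
  methods <- methods[!is.na(methods)]
  tibble(set = x$set_name, method = names(methods), p_value = unname(methods))
}

#' One-row summary of a single-set test result
#'
#' @param x A `tegs_result` from [tegs_test()].
#' @param ... Unused.
#' @return One-row tibble with the statistic, all p-values, the Satterthwaite
#'   scale/df, and provenance (covariance kind, B, seed).
#' @export
glance.tegs_result <- function(x, ...) {
  tibble(set = x$set_name, n = x$n, p_genes = x$p, Q = x$Q_observed,
         p_perm = x$p_perm, p_satt = x$p_satt, p_mix = x$p_mix,
         kappa = x$kappa, nu = x$nu, B = x$B,
         covariance = x$covariance_kind,
         seed = if (is.null(x$seed)) NA_integer_ else x$seed)
}

#' Plot the permutation null of a test result
#'
#' Histogram of the permuted statistics with the observed value marked; run
#' [tegs_test()] with `keep_draws = TRUE`.
#'
#' @param object A `tegs_result` with kept draws.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tegs_result <- function(object, bins = 50, ...) {
  if (is.null(object$perm_Q)) {
    abort("No permutation draws kept; rerun tegs_test() with keep_draws = TRUE.")
  }
  df <- tibble(Q = object$perm_Q)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$Q)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$Q_observed, colour = "red",
                        linetype = "dashed") +
    ggplot2::labs(x = "permuted statistic Q",
                  y = "count",
                  title = sprintf("%s: Q = %.3g, p_perm = %.3g",
                                  object$set_name, object$Q_observed, object$p_perm)) +
    ggplot2::theme_minimal()
}

#' Plot size/power across working covariances
#'
#' @param object A `tegs_experiment` from [run_size_power_experiment()].
#' @param ... Unused.
#' @return A ggplot of rejection rates (with Monte Carlo error bars) by
#'   working covariance and p-value method.
#' @export
autoplot.tegs_experiment <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$covariance, y = .data$rejection_rate,
                               fill = .data$method)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$rejection_rate - .data$mc_se,
                                        ymax = .data$rejection_rate + .data$mc_se),
                           position = ggplot2::position_dodge(width = 0.8), width = 0.2) +
    ggplot2::geom_hline(yintercept = unique(object$alpha), linetype = "dotdash") +
    ggplot2::labs(x = "working covariance", y = "rejection proportion") +
    ggplot2::theme_minimal()
}

#' Plot an analytic power curve
#'
#' @param object A `tegs_power_curve` from [power_curve()].
#' @param ... Unused.
#' @return A ggplot of power against the effect-size index, one line per
#'   sample size.
#' @export
autoplot.tegs_power_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$effect_index, y = .data$power,
                               colour = factor(.data$n))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "effect index  sum|beta| / mean variance", y = "power",
                  colour = "n") +
    ggplot2::theme_minimal()
}
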