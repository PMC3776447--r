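#' Describe a power calculation problem
#'
#' Bundles the design (phenotype vector), the working covariance `V`, the true
#' (or pilot-estimated) covariance `Sigma`, the per-gene effect vector and the
#' test size. `Sigma` and `V` may come from pilot data via
#' [build_working_covariance()] / [estimate_unstructured_ridge()].
#'
#' @param x Phenotype design vector (e.g. `rep(0:1, c(n1, n2))`), or a
#'   [phenotype()].
#' @param V Working covariance (p-by-p positive definite).
#' @param Sigma True covariance of the expression errors (p-by-p positive
#'   definite).
#' @param beta Per-gene effect vector (length p), e.g. from [make_beta()].
#' @param alpha Size of the test, in (0, 1).
#' @return Object of class `power_problem`.
#' @examples
#' pp <- power_problem(rep(0:1, each = 10), V = make_cov_cs(10, 0.5),
#'                     Sigma = make_cov_cs(10, 0.5),
#'                     beta = make_beta(10, 2, 2, 0.5))
#' analytic_power(pp)
#' @export
power_problem <- function(x, V, Sigma, beta, alpha = 0.05) {
  x <- phenotype(x)$x
  V <- validate_covariance(V)
  Sigma <- validate_covariance(Sigma)
  if (is.list(beta) && !is.null(beta$beta)) beta <- beta$beta
  beta <- as.numeric(beta)
  p <- nrow(V)
  if (nrow(Sigma) != p || length(beta) != p) {
    abort("`V`, `Sigma` and `beta` must all have the same gene dimension.")
  }
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  if (var(x) <= 0) abort("Design phenotype is constant.")
  structure(list(x = x, V = V, Sigma = Sigma, beta = beta, alpha = alpha),
            class = "power_problem")
}

#' Theoretical null moments of the statistic
#'
#' With `c = sum_i (x_i - xbar)^2` and `M = c V^-1 Sigma V^-1` (the covariance
#' of the weighted score vector under the null), the null mean of `Q` is
#' `tr(M)` and the null variance is `2 tr(M^2)` — the p-dimensional reduction
#' of the stacked-design trace formulas.
#'
#' @param problem A [power_problem()].
#' @return List with `E` and `Var`.
#' @export
theoretical_null_moments <- function(problem) {
  stopifnot(inherits(problem, "power_problem"))
  M <- score_cov_matrix(problem)
  list(E = sum(diag(M)), Var = 2 * sum(M * M))
}

# c V^-1 Sigma V^-1, symmetrized.
score_cov_matrix <- function(problem) {
  cc <- sum((problem$x - mean(problem$x))^2)
  A <- chol_solve(problem$V, problem$Sigma)       # V^-1 Sigma
  M <- cc * t(chol_solve(problem$V, t(A)))        # c V^-1 Sigma V^-1
  (M + t(M)) / 2
}

#' Theoretical mean of the statistic under the alternative
#'
#' `E_HA(Q) = E_H0(Q) + c^2 beta' V^-2 beta`, the null mean plus the
#' noncentral shift contributed by the effect vector.
#'
#' @param problem A [power_problem()].
#' @return Scalar mean.
#' @export
alternative_mean <- function(problem) {
  stopifnot(inherits(problem, "power_problem"))
  cc <- sum((problem$x - mean(problem$x))^2)
  w <- chol_solve(problem$V, problem$beta)
  theoretical_null_moments(problem)$E + cc^2 * sum(w^2)
}

#' Analytic power of the gene set test
#'
#' Matches the null distribution of `Q` to a scaled chi-square
#' `kappa chi^2_nu` by its first two theoretical moments, solves
#' `E_HA(Q) = (nu + delta) kappa` for the noncentrality `delta` (floored at
#' 0), and returns `Pr(chi^2_nu(delta) > chi^2_{nu, 1 - alpha})`.
#'
#' @param problem A [power_problem()].
#' @return Power in `[alpha, 1]`; exactly `alpha` when `beta = 0`.
#' @export
analytic_power <- function(problem) {
  stopifnot(inherits(problem, "power_problem"))
  mom <- theoretical_null_moments(problem)
  if (mom$Var <= 0) abort("Null variance of Q is zero; the design is degenerate.")
  kappa <- mom$Var / (2 * mom$E)
  nu <- 2 * mom$E^2 / mom$Var
  delta <- max(0, alternative_mean(problem) / kappa - nu)
  crit <- qchisq(1 - problem$alpha, df = nu)
  pchisq(crit, df = nu, ncp = delta, lower.tail = FALSE)
}

#' Power curve over effect scalings and sample sizes
#'
#' Sweeps a grid of multiplicative effect scalings (and optionally balanced
#' two-group sample sizes) and returns the analytic power at each point.
#'
#' @param V,Sigma,beta,alpha As in [power_problem()].
#' @param beta_scale Numeric vector of multipliers applied to `beta`.
#' @param n Vector of total sample sizes (balanced two-group designs); each
#'   must be even.
#' @return Tibble with `n`, `beta_scale`, `effect_index`
#'   (`sum |beta_j| / mean diag(Sigma)`) and `power`; class `tegs_power_curve`
#'   for [autoplot()].
#' @examples
#' power_curve(make_cov_cs(10, 0.5), make_cov_cs(10, 0.5),
#'             make_beta(10, 2, 2, 0.5), beta_scale = c(0.5, 1, 2), n = c(20, 50))
#' @export
power_curve <- function(V, Sigma, beta, beta_scale = seq(0, 2, by = 0.25),
                        n = 20, alpha = 0.05) {
  if (is.list(beta) && !is.null(beta$beta)) beta <- beta$beta
  grid <- tidyr::expand_grid(n = n, beta_scale = beta_scale)
  sigma_bar <- mean(diag(Sigma))
  out <- purrr::pmap(grid, function(n, beta_scale) {
    if (n %% 2 != 0) abort("Balanced designs require even n; supply x directly otherwise.")
    pp <- power_problem(rep(0:1, each = n / 2), V, Sigma, beta * beta_scale, alpha)
    tibble(n = n, beta_scale = beta_scale,
           effect_index = sum(abs(beta * beta_scale)) / sigma_bar,
           power = analytic_power(pp))
  })
  structure(dplyr::bind_rows(out), class = c("tegs_power_curve", class(tibble())))
}
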