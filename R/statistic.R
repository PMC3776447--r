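#' Center responses and phenotype under the null
#'
#' Under the no-effect null the maximum likelihood estimate of the per-gene
#' intercepts is the plain sample mean, whatever covariance is assumed, so the
#' null-centered design subtracts per-gene overall means from the responses
#' and the mean from the phenotype.
#'
#' @param expr Samples-by-genes matrix (or data frame).
#' @param pheno [phenotype()] or coercible vector.
#' @return Object of class `centered_design`: list with `centered_responses`
#'   (n-by-p), `centered_x` (length n), `x`, `kind`, and, for binary
#'   phenotypes, `group_means` (p-by-2 matrix of the group mean profiles).
#' @export
center_under_null <- function(expr, pheno) {
  Y <- validate_expression(expr)
  pheno <- validate_phenotype(pheno, n = nrow(Y))
  x <- pheno$x
  Yc <- sweep(Y, 2, colMeans(Y))
  group_means <- NULL
  if (pheno$kind == "binary") {
    group_means <- cbind(`0` = colMeans(Y[x == 0, , drop = FALSE]),
                         `1` = colMeans(Y[x == 1, , drop = FALSE]))
  }
  structure(list(centered_responses = Yc, centered_x = x - mean(x), x = x,
                 kind = pheno$kind, group_means = group_means),
            class = "centered_design")
}

as_centered_design <- function(design, pheno = NULL) {
  if (inherits(design, "centered_design")) return(design)
  if (is.null(pheno)) abort("Supply a `centered_design` (see center_under_null()).")
  center_under_null(design, pheno)
}

#' The TEGS variance component score statistic
#'
#' Computes `Q = || V^-1 t ||^2` with `t = sum_i (x_i - xbar) (Y_i - Ybar)`,
#' the p-dimensional reduction of the quadratic score form
#' `Y'(I-H) Vn^-1 X X' Vn^-1 (I-H) Y` of the stacked multivariate regression
#' (no np-by-np matrix is ever formed). Large `Q` indicates that the
#' phenotype shifts the joint expression profile of the set.
#'
#' @param design A `centered_design` from [center_under_null()].
#' @param V Positive definite p-by-p working covariance.
#' @return Nonnegative scalar `Q`.
#' @examples
#' d <- center_under_null(matrix(c(0, 2), 2, 1), phenotype(c(0, 1)))
#' tegs_statistic(d, diag(1))  # 1
#' @export
tegs_statistic <- function(design, V) {
  design <- as_centered_design(design)
  V <- validate_covariance(V)
  if (nrow(V) != ncol(design$centered_responses)) {
    abort("Working covariance dimension does not match the number of genes.")
  }
  t_vec <- crossprod(design$centered_responses, design$centered_x)
  U <- chol_solve(V, t_vec)
  sum(U^2)
}

#' Two-group closed form of the TEGS statistic
#'
#' For a binary phenotype the statistic reduces to
#' `(n1 n2 / n)^2 * d' V^-2 d` with `d` the difference of the two group mean
#' profiles: a covariance-weighted aggregate of the per-gene group contrasts.
#' Equal to [tegs_statistic()] exactly.
#'
#' @inheritParams tegs_statistic
#' @return Nonnegative scalar `Q`.
#' @export
tegs_two_group <- function(design, V) {
  design <- as_centered_design(design)
  if (design$kind != "binary" || is.null(design$group_means)) {
    abort("The two-group closed form requires a binary phenotype.")
  }
  V <- validate_covariance(V)
  n1 <- sum(design$x == 0); n2 <- sum(design$x == 1); n <- n1 + n2
  d <- design$group_means[, 2] - design$group_means[, 1]
  U <- chol_solve(V, d)
  (n1 * n2 / n)^2 * sum(U^2)
}

#' Global test statistic (working independence)
#'
#' The TEGS statistic under working independence `V = I`, which coincides with
#' the global test of Goeman et al. (2004) (and SKAT with a linear kernel):
#' the unweighted sum of squared per-gene group contrasts.
#'
#' @inheritParams tegs_statistic
#' @return Nonnegative scalar `Q`.
#' @export
global_test_statistic <- function(design) {
  design <- as_centered_design(design)
  t_vec <- crossprod(design$centered_responses, design$centered_x)
  sum(t_vec^2)
}

#' Mixture-of-chi-square null weights
#'
#' Under the null the statistic is distributed as `sum_j lambda_j chi^2_1`,
#' where the `lambda_j` are the eigenvalues of `c V^-1 Sigma V^-1` with
#' `c = sum_i (x_i - xbar)^2` (for `V = Sigma` this is `c Sigma^-1` applied to
#' `Sigma`, i.e. `c` times the identity scale). Their sum equals the
#' theoretical null mean of `Q`.
#'
#' @inheritParams tegs_statistic
#' @param Sigma True (or assumed) positive definite covariance of the errors.
#' @return Numeric vector of nonnegative weights, decreasing.
#' @export
null_mixture_weights <- function(design, V, Sigma) {
  design <- as_centered_design(design)
  V <- validate_covariance(V)
  Sigma <- validate_covariance(Sigma)
  cc <- sum(design$centered_x^2)
  Vinv_Sigma <- chol_solve(V, Sigma)
  M <- cc * t(chol_solve(V, t(Vinv_Sigma)))   # c V^-1 Sigma V^-1
  M <- (M + t(M)) / 2
  w <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  pmax(w, 0)
}

#' Residualize expression on covariates by ridge regression
#'
#' Removes covariate effects gene-by-gene before testing the phenotype: each
#' gene is regressed on an unpenalized intercept plus the covariates with an
#' L2 penalty on the covariate coefficients (needed when p is large relative
#' to n), and the residuals replace the raw expression.
#'
#' @param expr Samples-by-genes matrix (or data frame).
#' @param covariates n-by-K numeric matrix of covariates (no intercept
#'   column).
#' @param ridge_penalty Nonnegative L2 penalty on the covariate coefficients;
#'   0 gives ordinary least squares residualization.
#' @return Samples-by-genes matrix of covariate-adjusted expression.
#' @export
adjust_for_covariates <- function(expr, covariates, ridge_penalty = 0) {
  Y <- validate_expression(expr)
  Z <- as.matrix(covariates)
  if (!is.numeric(Z) || nrow(Z) != nrow(Y)) {
    abort("`covariates` must be a numeric matrix with one row per sample.")
  }
  if (ridge_penalty < 0) abort("`ridge_penalty` must be nonnegative.")
  G <- cbind(1, Z)
  K <- ncol(G)
  pen <- diag(c(0, rep(ridge_penalty, K - 1)), K)   # intercept unpenalized
  A <- crossprod(G) + pen
  if (ridge_penalty == 0 && qr(G)$rank < K) {
    abort("Covariate matrix (with intercept) is rank deficient; use a positive ridge penalty.")
  }
  coefs <- solve(A, crossprod(G, Y))
  out <- Y - G %*% coefs
  dimnames(out) <- dimnames(Y)
  out
}
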