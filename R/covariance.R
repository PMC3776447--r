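#' Specify a working covariance
#'
#' The test statistic weights the per-gene group contrasts by the inverse of a
#' working covariance `V` for the within-set expression errors. `V` need not
#' equal the true covariance for the test to be valid; the closer it is, the
#' higher the power.
#'
#' Available structures:
#' \describe{
#'   \item{`indpt`}{working independence, `V = I` (equivalent to the global
#'     test of Goeman et al. 2004).}
#'   \item{`unstr`}{ridge-stabilized unstructured sample covariance of the
#'     residuals: the `ridge_percentile`-th percentile of the sample variances
#'     is added to the diagonal.}
#'   \item{`cpsym`}{compound symmetry (exchangeable) derived from the ridge
#'     estimator.}
#'   \item{`f2`}{factor-analysis covariance with `n_factors` factors, from the
#'     eigendecomposition of the ridge estimator.}
#'   \item{`f-adpt`}{factor-analysis covariance with the number of factors
#'     chosen to explain `variance_fraction` of total variance.}
#'   \item{`supplied`}{a user-supplied positive definite matrix (e.g. a known
#'     or pilot-estimated covariance), used as-is.}
#' }
#'
#' @param kind One of `"indpt"`, `"unstr"`, `"cpsym"`, `"f2"`, `"f-adpt"`,
#'   `"supplied"`.
#' @param ridge_percentile Percentile (0-100) of the sample variances added to
#'   the diagonal of the unstructured estimator; default 5.
#' @param variance_fraction For `f-adpt`: cumulative eigenvalue fraction the
#'   retained factors must reach (default 0.80).
#' @param n_factors For `f2`: number of factors (default 2).
#' @param supplied_matrix For `kind = "supplied"`: the covariance matrix.
#' @return An object of class `working_cov_spec`.
#' @examples
#' working_cov_spec("f2")
#' working_cov_spec("supplied", supplied_matrix = diag(5))
#' @export
working_cov_spec <- function(kind = c("indpt", "unstr", "cpsym", "f2", "f-adpt", "supplied"),
                             ridge_percentile = 5, variance_fraction = 0.80,
                             n_factors = 2, supplied_matrix = NULL) {
  kind <- match.arg(kind)
  if (ridge_percentile <= 0 || ridge_percentile >= 100) {
    abort("`ridge_percentile` must lie in (0, 100).")
  }
  if (variance_fraction <= 0 || variance_fraction > 1) {
    abort("`variance_fraction` must lie in (0, 1].")
  }
  if (n_factors < 1) abort("`n_factors` must be a positive integer.")
  if (kind == "supplied") {
    if (is.null(supplied_matrix)) abort("kind = 'supplied' requires `supplied_matrix`.")
    supplied_matrix <- validate_covariance(supplied_matrix, kind = "supplied")
  }
  structure(list(kind = kind, ridge_percentile = ridge_percentile,
                 variance_fraction = variance_fraction,
                 n_factors = as.integer(n_factors),
                 supplied_matrix = supplied_matrix),
            class = "working_cov_spec")
}

as_working_cov_spec <- function(cov) {
  if (inherits(cov, "working_cov_spec")) return(cov)
  if (is.matrix(cov)) return(working_cov_spec("supplied", supplied_matrix = cov))
  if (is.character(cov) && length(cov) == 1) return(working_cov_spec(cov))
  abort("`cov` must be a working_cov_spec, a structure name, or a covariance matrix.")
}

#' @export
print.working_cov_spec <- function(x, ...) {
  cat(sprintf("<working_cov_spec> kind = %s\n", x$kind))
  invisible(x)
}

# Symmetry + positive definiteness checks for covariance inputs/outputs.
validate_covariance <- function(V, kind = NULL, require_pd = TRUE) {
  if (!is.matrix(V) || !is.numeric(V) || nrow(V) != ncol(V)) {
    abort("Covariance must be a square numeric matrix.")
  }
  scale <- max(abs(V), 1e-300)
  if (max(abs(V - t(V))) > 1e-10 * scale) {
    abort("Covariance matrix is not symmetric (beyond 1e-10 relative tolerance).")
  }
  V <- (V + t(V)) / 2
  if (require_pd) {
    ok <- tryCatch({ chol(V); TRUE }, error = function(e) FALSE)
    if (!ok) abort("Covariance matrix is not positive definite.")
  }
  if (!is.null(kind)) attr(V, "kind") <- kind
  V
}

#' Per-gene regression residuals
#'
#' Regresses each gene's expression on `(1, x)` by ordinary least squares and
#' returns the residual matrix. For a binary phenotype this is exactly
#' group-mean centering.
#'
#' @param expr Samples-by-genes matrix (or data frame).
#' @param pheno [phenotype()] or coercible vector.
#' @return List with `residuals` (n-by-p matrix) and `dof_used` (parameters
#'   removed per gene, always 2).
#' @export
compute_residuals <- function(expr, pheno) {
  Y <- validate_expression(expr)
  pheno <- validate_phenotype(pheno, n = nrow(Y))
  x <- pheno$x
  xc <- x - mean(x)
  Yc <- sweep(Y, 2, colMeans(Y))
  slopes <- crossprod(Yc, xc)[, 1] / sum(xc^2)
  res <- Yc - outer(xc, slopes)
  dimnames(res) <- dimnames(Y)
  list(residuals = res, dof_used = 2L)
}

as_residual_matrix <- function(res) {
  if (is.list(res) && !is.null(res$residuals)) res$residuals else as.matrix(res)
}

#' Ridge-stabilized unstructured covariance estimator
#'
#' The sample covariance of the residual columns (divisor `n - 1`), stabilized
#' by adding the `ridge_percentile`-th percentile of the sample variances to
#' the diagonal. The ridge term guarantees positive definiteness even when
#' `p >= n`.
#'
#' @param res Residuals from [compute_residuals()] (or a bare matrix).
#' @param ridge_percentile Percentile (0-100) of the diagonal added back;
#'   default 5.
#' @return p-by-p covariance matrix with `attr(,"kind") = "unstr"`.
#' @export
estimate_unstructured_ridge <- function(res, ridge_percentile = 5) {
  E <- as_residual_matrix(res)
  n <- nrow(E)
  if (n < 3) abort("At least 3 samples are required to estimate a covariance.")
  S <- crossprod(E) / (n - 1)
  if (max(diag(S)) <= 0) abort("All residuals are zero; no variability to estimate.")
  ridge <- unname(quantile(diag(S), ridge_percentile / 100, type = 7))
  diag(S) <- diag(S) + ridge
  out <- validate_covariance(S, kind = "unstr")
  attr(out, "ridge") <- ridge
  out
}

#' Compound symmetry (exchangeable) covariance from the ridge estimator
#'
#' The common pairwise covariance is the mean of the off-diagonal entries of
#' the ridge unstructured estimator; the common variance is the mean of its
#' diagonal, making the result exactly exchangeable.
#'
#' @param ridge_cov Output of [estimate_unstructured_ridge()].
#' @return p-by-p exchangeable covariance matrix, `attr(,"kind") = "cpsym"`.
#' @export
estimate_compound_symmetry <- function(ridge_cov) {
  V <- validate_covariance(ridge_cov, require_pd = FALSE)
  p <- nrow(V)
  if (p < 2) abort("Compound symmetry requires at least 2 genes.")
  dm <- mean(diag(V))
  om <- (sum(V) - sum(diag(V))) / (p * (p - 1))
  out <- matrix(om, p, p)
  diag(out) <- dm
  dimnames(out) <- dimnames(V)
  # exchangeable eigenvalues: dm + (p-1) om and dm - om
  if (dm + (p - 1) * om <= 0 || dm - om <= 0) {
    abort("Compound symmetry estimate is not positive definite.")
  }
  validate_covariance(out, kind = "cpsym")
}

#' Factor-analysis covariance from the ridge estimator
#'
#' Keeps the top `k` eigencomponents of the ridge unstructured estimator
#' (`k = n_factors` for `f2`; for `f-adpt`, the smallest `k` whose cumulative
#' eigenvalue fraction reaches `variance_fraction`) and restores the input
#' diagonal with a gene-specific uniqueness term, floored at
#' `1e-8 * mean(diag)` to keep the result positive definite.
#'
#' @param ridge_cov Output of [estimate_unstructured_ridge()].
#' @param spec A [working_cov_spec()] with kind `"f2"` or `"f-adpt"`.
#' @param max_factors Optional cap on the adaptive number of factors
#'   (typically `min(p, n - 1)`, the rank of the residual covariance).
#' @return p-by-p covariance matrix; the number of factors used is stored in
#'   `attr(,"n_factors")`.
#' @export
estimate_factor_covariance <- function(ridge_cov, spec = working_cov_spec("f2"),
                                       max_factors = NULL) {
  V <- validate_covariance(ridge_cov)
  p <- nrow(V)
  eg <- eigen(V, symmetric = TRUE)  # decreasing eigenvalues
  if (spec$kind == "f-adpt") {
    frac <- cumsum(eg$values) / sum(eg$values)
    k <- which(frac >= spec$variance_fraction)[1]
    if (!is.null(max_factors)) k <- min(k, max_factors)
  } else {
    k <- spec$n_factors
  }
  if (k > p) abort(sprintf("Number of factors (%d) exceeds the number of genes (%d).", k, p))
  U <- eg$vectors[, seq_len(k), drop = FALSE]
  low <- U %*% (eg$values[seq_len(k)] * t(U))
  D <- pmax(diag(V) - diag(low), 1e-8 * mean(diag(V)))
  out <- low
  diag(out) <- diag(low) + D
  dimnames(out) <- dimnames(V)
  out <- validate_covariance(out, kind = if (spec$kind == "f-adpt") "f-adpt" else "f2")
  attr(out, "n_factors") <- k
  out
}

#' Estimate a working covariance from data
#'
#' Dispatcher over the working-covariance menu: computes per-gene residuals,
#' the ridge unstructured estimator, and the requested derived structure.
#'
#' @param expr Samples-by-genes matrix (or data frame).
#' @param pheno [phenotype()] or coercible vector.
#' @param spec A [working_cov_spec()], structure name, or covariance matrix.
#' @return p-by-p working covariance matrix with a `"kind"` attribute.
#' @examples
#' sim <- simulate_gene_set(n = 20, n1 = 10, beta = make_beta(5, 0, 0, 0),
#'                          Sigma = make_cov_cs(5, 0.5), seed = 1)
#' V <- build_working_covariance(sim$expr, sim$pheno, "cpsym")
#' @export
build_working_covariance <- function(expr, pheno, spec = working_cov_spec("unstr")) {
  spec <- as_working_cov_spec(spec)
  Y <- validate_expression(expr)
  p <- ncol(Y)
  if (spec$kind == "indpt") {
    out <- diag(p)
    dimnames(out) <- list(colnames(Y), colnames(Y))
    return(validate_covariance(out, kind = "indpt"))
  }
  if (spec$kind == "supplied") {
    V <- spec$supplied_matrix
    if (nrow(V) != p) {
      abort(sprintf("Supplied covariance dimension (%d) does not match gene count (%d).",
                    nrow(V), p))
    }
    return(validate_covariance(V, kind = "supplied"))
  }
  res <- compute_residuals(Y, pheno)
  ridge <- estimate_unstructured_ridge(res, spec$ridge_percentile)
  switch(spec$kind,
    unstr  = ridge,
    cpsym  = estimate_compound_symmetry(ridge),
    f2     = estimate_factor_covariance(ridge, spec),
    `f-adpt` = estimate_factor_covariance(
      ridge, spec, max_factors = min(p, nrow(Y) - 1L))
  )
}
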