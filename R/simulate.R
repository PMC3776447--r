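# Synthetic-data generators and the size/power simulation harness.

#' Compound symmetry covariance
#'
#' Unit diagonal, constant off-diagonal `rho`.
#'
#' @param p Number of genes.
#' @param rho Common correlation, in `(-1/(p-1), 1)`.
#' @return p-by-p covariance matrix.
#' @export
make_cov_cs <- function(p, rho) {
  if (rho <= -1 / (p - 1) || rho >= 1) {
    abort(sprintf("rho = %g is outside the positive definite range (-1/(p-1), 1).", rho))
  }
  out <- matrix(rho, p, p)
  diag(out) <- 1
  validate_covariance(out, kind = "cs")
}

#' First-order autoregressive covariance
#'
#' Entry `(j, k)` is `r^|j - k|`, unit diagonal.
#'
#' @param p Number of genes.
#' @param r Lag-1 autocorrelation, `|r| < 1`.
#' @return p-by-p covariance matrix.
#' @export
make_cov_ar1 <- function(p, r) {
  if (abs(r) >= 1) abort("`r` must satisfy |r| < 1.")
  out <- r^abs(outer(seq_len(p), seq_len(p), `-`))
  validate_covariance(out, kind = "ar1")
}

#' Random two-factor covariance with unit diagonal
#'
#' `Sigma = P1 P1' + P2 P2' + diag(u)`: two random Gaussian factor loadings,
#' rescaled so the rank-2 part carries `factor_share` of the unit diagonal on
#' average, with the uniqueness vector `u` filling the diagonal to exactly 1
#' (entries of `u` kept at least 0.05 by shrinking the factor part when
#' needed).
#'
#' @param p Number of genes.
#' @param factor_share Average share of variance carried by the two factors,
#'   in (0, 1); default 0.5.
#' @param seed Optional integer seed (same seed, same matrix).
#' @return p-by-p covariance matrix with unit diagonal.
#' @export
make_cov_twofactor <- function(p, factor_share = 0.5, seed = NULL) {
  if (factor_share <= 0 || factor_share >= 1) abort("`factor_share` must lie in (0, 1).")
  if (!is.null(seed)) set.seed(seed)
  P <- matrix(rnorm(2 * p), p, 2)
  low <- tcrossprod(P)
  low <- low * (factor_share / mean(diag(low)))
  if (max(diag(low)) > 0.95) low <- low * (0.95 / max(diag(low)))
  u <- 1 - diag(low)
  out <- low
  diag(out) <- 1
  out <- validate_covariance(out, kind = "f2-true")
  attr(out, "uniqueness") <- u
  out
}

#' Synthetic unstructured covariance fixture
#'
#' A synthetic stand-in for an unstructured real-data covariance: the sample
#' covariance of 34 pseudo-samples drawn from a heterogeneous-variance
#' three-factor model, stabilized by adding the 5th percentile of its diagonal
#' to the diagonal (the same ridge rule the estimator uses).
#'
#' @param p Number of genes (at least 2).
#' @param seed Optional integer seed.
#' @return p-by-p covariance matrix; the pre-ridge sample covariance is kept
#'   in `attr(,"pre_ridge")`.
#' @export
make_cov_unstructured_fixture <- function(p, seed = NULL) {
  if (p < 2) abort("`p` must be at least 2.")
  if (!is.null(seed)) set.seed(seed)
  n_pseudo <- 34
  L <- matrix(rnorm(3 * p, sd = 0.6), p, 3)
  sds <- stats::runif(p, 0.4, 1.6)
  Z <- matrix(rnorm(n_pseudo * 3), n_pseudo, 3) %*% t(L) +
    matrix(rnorm(n_pseudo * p), n_pseudo, p) %*% diag(sds, p)
  S <- stats::cov(Z)
  ridge <- unname(quantile(diag(S), 0.05, type = 7))
  out <- S
  diag(out) <- diag(out) + ridge
  out <- validate_covariance(out, kind = "uns-fixture")
  attr(out, "pre_ridge") <- S
  attr(out, "ridge") <- ridge
  out
}

#' Sparse signed effect vector
#'
#' The first `count_neg` genes get effect `-magnitude`, the next `count_pos`
#' get `+magnitude`, the rest 0. Positions are fixed (leading entries): the
#' test is equivariant to gene order, so placement is immaterial.
#'
#' @param p Number of genes.
#' @param count_neg,count_pos Numbers of negative / positive effects
#'   (`count_neg + count_pos <= p`).
#' @param magnitude Common absolute effect size.
#' @return Object of class `effect_vector`: list with `beta` (length p) and
#'   `tau` (0 iff the configuration is null).
#' @examples
#' make_beta(40, 5, 25, 1.0)
#' @export
make_beta <- function(p, count_neg, count_pos, magnitude) {
  if (count_neg < 0 || count_pos < 0 || count_neg + count_pos > p) {
    abort("`count_neg + count_pos` must be between 0 and p.")
  }
  beta <- c(rep(-magnitude, count_neg), rep(magnitude, count_pos),
            rep(0, p - count_neg - count_pos))
  structure(list(beta = beta,
                 tau = if (all(beta == 0)) 0 else magnitude^2),
            class = "effect_vector")
}

as_beta_vector <- function(beta, p = NULL) {
  b <- if (is.list(beta) && !is.null(beta$beta)) beta$beta else as.numeric(beta)
  if (!is.null(p) && length(b) != p) abort("Effect vector length does not match p.")
  b
}

#' Simulate one gene set
#'
#' Draws `Y_i = x_i beta + eps_i` with `eps_i ~ MVN(0, Sigma)` (per-gene
#' intercepts are 0 without loss of generality) for a two-group design of
#' `n1` samples with `x = 0` followed by `n - n1` with `x = 1`.
#'
#' @param n Total samples.
#' @param n1 Samples in the `x = 0` group.
#' @param beta [make_beta()] effect (or numeric vector), length p.
#' @param Sigma True p-by-p covariance of the errors.
#' @param seed Optional integer seed.
#' @return List with `expr` (n-by-p matrix) and `pheno` ([phenotype()]).
#' @export
simulate_gene_set <- function(n, n1, beta, Sigma, seed = NULL) {
  Sigma <- validate_covariance(Sigma)
  p <- nrow(Sigma)
  b <- as_beta_vector(beta, p)
  if (n1 < 1 || n1 >= n) abort("`n1` must lie strictly between 0 and n.")
  if (!is.null(seed)) set.seed(seed)
  x <- rep(c(0, 1), c(n1, n - n1))
  E <- matrix(rnorm(n * p), n, p) %*% chol(Sigma)
  Y <- outer(x, b) + E
  rownames(Y) <- paste0("S", seq_len(n))
  colnames(Y) <- colnames(Sigma) %g% paste0("G", seq_len(p))
  list(expr = Y, pheno = phenotype(x))
}

#' Describe one size/power simulation cell
#'
#' @param n,n1 Sample sizes (total and group `x = 0`).
#' @param Sigma True covariance (from one of the `make_cov_*` generators or
#'   user-supplied).
#' @param beta [make_beta()] effect; an all-zero effect gives a size (type I
#'   error) cell.
#' @param replicates Number of simulated datasets.
#' @param B Permutations per dataset (at least 100).
#' @param alpha Nominal test size.
#' @param seed Integer seed for the whole cell.
#' @return Object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(n, n1, Sigma, beta, replicates = 2000,
                                B = 500, alpha = 0.05, seed = 1) {
  Sigma <- validate_covariance(Sigma)
  b <- as_beta_vector(beta, nrow(Sigma))
  if (replicates < 1) abort("`replicates` must be at least 1.")
  if (B < 100) abort("`B` must be at least 100.")
  structure(list(n = n, n1 = n1, p = nrow(Sigma), Sigma = Sigma, beta = b,
                 replicates = as.integer(replicates), B = as.integer(B),
                 alpha = alpha, seed = as.integer(seed)),
            class = "simulation_scenario")
}

# Normalize a work_covs argument: character vector (with "true" meaning the
# generating covariance, supplied) or named list of specs/matrices.
normalize_work_covs <- function(work_covs, Sigma) {
  if (is.character(work_covs)) {
    work_covs <- stats::setNames(as.list(work_covs), work_covs)
  }
  if (is.null(names(work_covs)) || any(!nzchar(names(work_covs)))) {
    abort("`work_covs` must be named.")
  }
  lapply(work_covs, function(w) {
    if (identical(w, "true")) working_cov_spec("supplied", supplied_matrix = Sigma)
    else as_working_cov_spec(w)
  })
}

#' Run a size/power simulation cell
#'
#' For each replicate, simulates a dataset under the scenario, then computes
#' the test under every requested working covariance on the *same* data and
#' the *same* permutation draw (so comparisons across working covariances are
#' paired), collecting permutation and Satterthwaite p-values.
#'
#' @param scenario A [simulation_scenario()].
#' @param work_covs Character vector or named list of working covariances;
#'   the label `"true"` uses the scenario's generating covariance as a
#'   supplied `V`.
#' @param methods Subset of `c("perm", "satt")`.
#' @param keep_pvalues Also return the per-replicate p-values (in the
#'   `"pvalues"` attribute, a long tibble).
#' @return Tibble (class `tegs_experiment`) with one row per
#'   covariance-method pair: rejection proportion at `alpha`, its binomial
#'   Monte Carlo standard error, and the effect-size index
#'   `sum |beta_j| / sigma2_bar` (mean true gene variance).
#' @examples
#' sc <- simulation_scenario(n = 20, n1 = 10, Sigma = make_cov_cs(5, 0.5),
#'                           beta = make_beta(5, 0, 0, 0),
#'                           replicates = 20, B = 100, seed = 1)
#' run_size_power_experiment(sc, c("true", "indpt"))
#' @export
run_size_power_experiment <- function(scenario, work_covs,
                                      methods = c("perm", "satt"),
                                      keep_pvalues = FALSE) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  methods <- match.arg(methods, c("perm", "satt"), several.ok = TRUE)
  specs <- normalize_work_covs(work_covs, scenario$Sigma)
  R <- scenario$replicates; B <- scenario$B
  n <- scenario$n; n1 <- scenario$n1
  nv <- length(specs)
  p_perm <- p_satt <- matrix(NA_real_, R, nv, dimnames = list(NULL, names(specs)))
  set.seed(scenario$seed)
  cholS <- chol(scenario$Sigma)
  x <- rep(c(0, 1), c(n1, n - n1))
  for (r in seq_len(R)) {
    Y <- outer(x, scenario$beta) + matrix(rnorm(n * scenario$p), n) %*% cholS
    colnames(Y) <- paste0("G", seq_len(scenario$p))
    rownames(Y) <- paste0("S", seq_len(n))
    idx <- permutation_indices(n, B)
    for (v in seq_len(nv)) {
      eng <- tegs_perm_Q(Y, x, idx, specs[[v]])
      Qo <- eng$Q[1]; Qp <- eng$Q[-1]
      if ("perm" %in% methods) p_perm[r, v] <- (1 + sum(Qp >= Qo)) / (B + 1)
      if ("satt" %in% methods) {
        p_satt[r, v] <- satterthwaite_pvalue(Qo, Qp)$p
      }
    }
  }
  effect_index <- sum(abs(scenario$beta)) / mean(diag(scenario$Sigma))
  summarize <- function(pm, method) {
    dplyr::bind_rows(lapply(colnames(pm), function(v) {
      rate <- mean(pm[, v] < scenario$alpha)
      tibble(covariance = v, method = method,
             rejection_rate = rate,
             mc_se = sqrt(rate * (1 - rate) / R),
             replicates = R, B = B, n = n, p = scenario$p,
             alpha = scenario$alpha, effect_index = effect_index)
    }))
  }
  out <- dplyr::bind_rows(
    if ("perm" %in% methods) summarize(p_perm, "perm"),
    if ("satt" %in% methods) summarize(p_satt, "satt"))
  if (keep_pvalues) {
    long <- dplyr::bind_rows(
      if ("perm" %in% methods)
        tidyr::pivot_longer(as_tibble(p_perm) |> dplyr::mutate(replicate = dplyr::row_number()),
                            -"replicate", names_to = "covariance", values_to = "p") |>
          dplyr::mutate(method = "perm"),
      if ("satt" %in% methods)
        tidyr::pivot_longer(as_tibble(p_satt) |> dplyr::mutate(replicate = dplyr::row_number()),
                            -"replicate", names_to = "covariance", values_to = "p") |>
          dplyr::mutate(method = "satt"))
    attr(out, "pvalues") <- long
  }
  structure(out, class = c("tegs_experiment", class(out)))
}

# ---------------------------------------------------------------------------
# Multiple gene sets

# Per-set effect layout used by the multi-set designs: 20 sets, ten of 10
# genes and ten of 40; sets 1-4 and 11-14 are under the alternative; the
# total number of signal genes is 104.
multiset_beta_table <- function() {
  tibble(
    set = sprintf("SET%02d", 1:20),
    p = rep(c(10L, 40L), each = 10),
    count_neg = c(1L, 2L, 1L, 2L, rep(0L, 6), 2L, 5L, 2L, 5L, rep(0L, 6)),
    count_pos = c(3L, 6L, 3L, 6L, rep(0L, 6), 8L, 25L, 8L, 25L, rep(0L, 6)),
    magnitude = c(0.5, 0.5, 1.0, 1.0, rep(0, 6), 0.5, 0.5, 1.0, 1.0, rep(0, 6)))
}

#' Describe a multi-gene-set simulation
#'
#' Twenty gene sets (ten of 10 genes, ten of 40), eight under the
#' alternative, with 104 signal genes in total. Setting 1: sets mutually
#' independent, two-factor covariance within each set. Setting 2: sets
#' 1-3, 4-6, 7-9, 11-13, 14-16 and 17-19 are correlated (a shared two-factor
#' structure spans each block; synthetic, seeded). Setting 3: as setting 2
#' plus 4500 independent unit-variance null genes outside all sets (5000
#' genes in total).
#'
#' @param setting 1, 2 or 3.
#' @param n Total samples (balanced two groups).
#' @param factor_share Factor share of the within-block two-factor
#'   covariances.
#' @param seed Integer seed.
#' @return Object of class `multiset_scenario`.
#' @export
multiset_scenario <- function(setting = 1, n = 20, factor_share = 0.5, seed = 1) {
  if (!setting %in% 1:3) abort("`setting` must be 1, 2 or 3.")
  bt <- multiset_beta_table()
  blocks <- if (setting == 1) lapply(1:20, identity)
            else c(list(1:3, 4:6, 7:9, 10L, 11:13, 14:16, 17:19, 20L))
  structure(list(setting = setting, n = as.integer(n),
                 beta_table = bt, correlated_blocks = blocks,
                 extra_null_genes = if (setting == 3) 4500L else 0L,
                 factor_share = factor_share, seed = as.integer(seed)),
            class = "multiset_scenario")
}

#' Simulate a multi-gene-set dataset
#'
#' Builds the block covariance of the scenario (within-set or within-block
#' two-factor structures, independent across blocks), simulates expression
#' for a balanced two-group design, appends any extra null genes, and returns
#' the data together with a GMT-compatible set collection. Extra null genes
#' are generated after the in-set genes, so settings 2 and 3 share the
#' in-set data for the same seed.
#'
#' @param scenario A [multiset_scenario()].
#' @return List with `expr`, `pheno`, `sets` and `beta` (the full effect
#'   vector over all genes).
#' @examples
#' sim <- simulate_multiset(multiset_scenario(setting = 1, seed = 3))
#' dim(sim$expr)
#' @export
simulate_multiset <- function(scenario) {
  stopifnot(inherits(scenario, "multiset_scenario"))
  bt <- scenario$beta_table
  n <- scenario$n
  set.seed(scenario$seed)
  x <- rep(c(0, 1), c(n %/% 2, n - n %/% 2))
  # covariance per block, then data block by block (independent blocks)
  block_cols <- list()
  Y_blocks <- list()
  beta_all <- numeric(0)
  gene_counter <- 0L
  for (bl in scenario$correlated_blocks) {
    p_bl <- sum(bt$p[bl])
    Sig <- make_cov_twofactor(p_bl, scenario$factor_share)
    betas <- unlist(lapply(bl, function(k) {
      as_beta_vector(make_beta(bt$p[k], bt$count_neg[k], bt$count_pos[k], bt$magnitude[k]))
    }))
    E <- matrix(rnorm(n * p_bl), n) %*% chol(Sig)
    Y_blocks[[length(Y_blocks) + 1]] <- outer(x, betas) + E
    block_cols[[length(block_cols) + 1]] <- gene_counter + seq_len(p_bl)
    beta_all <- c(beta_all, betas)
    gene_counter <- gene_counter + p_bl
  }
  Y <- do.call(cbind, Y_blocks)
  if (scenario$extra_null_genes > 0) {
    Y <- cbind(Y, matrix(rnorm(n * scenario$extra_null_genes), n))
    beta_all <- c(beta_all, rep(0, scenario$extra_null_genes))
  }
  colnames(Y) <- sprintf("G%04d", seq_len(ncol(Y)))
  rownames(Y) <- paste0("S", seq_len(n))
  # map sets to their gene columns, in set order 1..20
  sets <- vector("list", 20)
  for (i in seq_along(scenario$correlated_blocks)) {
    bl <- scenario$correlated_blocks[[i]]
    offs <- c(0L, cumsum(bt$p[bl]))
    for (j in seq_along(bl)) {
      sets[[bl[j]]] <- colnames(Y)[block_cols[[i]][(offs[j] + 1):offs[j + 1]]]
    }
  }
  names(sets) <- bt$set
  list(expr = Y, pheno = phenotype(x), sets = sets, beta = beta_all)
}
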