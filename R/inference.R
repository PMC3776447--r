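# Null-distribution machinery: permutation engine driver, Satterthwaite scaled
# chi-square, normal-mixture refinement, q-values, and the user-facing
# tegs_test() / tegs_run() drivers.

kind_code <- c(unstr = 1L, cpsym = 2L, f2 = 3L, `f-adpt` = 4L)

# Observed + permuted statistics under one working-covariance spec.
# Y: validated n x p matrix; x: numeric phenotype; idx: n x B permutation
# index matrix. Returns Q (length B + 1, observed first) and the retry count.
# For the fixed-V structures (indpt/supplied) V does not depend on x and the
# whole sweep collapses to two matrix products; for the estimated structures
# V is re-estimated inside every permutation (it is a covariance conditional
# on x), via the compiled engine.
tegs_perm_Q <- function(Y, x, idx, spec) {
  spec <- as_working_cov_spec(spec)
  n <- nrow(Y); p <- ncol(Y); B <- ncol(idx)
  Yc <- sweep(Y, 2, colMeans(Y))
  Xall <- cbind(x, matrix(x[idx], n, B))
  if (spec$kind %in% c("indpt", "supplied")) {
    V <- build_working_covariance(Y, phenotype(x), spec)
    Tm <- crossprod(Yc, Xall - mean(x))
    Q <- colSums(chol_solve(V, Tm)^2)
    return(list(Q = unname(Q), retries = 0L))
  }
  if (spec$kind == "f2" && spec$n_factors > p) {
    abort(sprintf("n_factors (%d) exceeds the number of genes (%d).", spec$n_factors, p))
  }
  code <- kind_code[[spec$kind]]
  maxf <- min(p, n - 1L)
  Q <- perm_engine_cpp(Yc, Xall, code, spec$ridge_percentile / 100,
                       spec$n_factors, spec$variance_fraction, maxf)
  if (!is.finite(Q[1])) {
    abort("Working covariance estimation failed for the observed phenotype.")
  }
  failures <- 0L
  repeat {
    bad <- which(!is.finite(Q))
    if (!length(bad)) break
    failures <- failures + length(bad)
    if (failures > max(1, 0.01 * B)) {
      abort(sprintf("Covariance estimation failed in %d permutations (> 1%% of B = %d).",
                    failures, B))
    }
    redraw <- matrix(x[vapply(bad, function(i) sample.int(n), integer(n))],
                     nrow = n)
    Q[bad] <- perm_engine_cpp(Yc, redraw, code, spec$ridge_percentile / 100,
                              spec$n_factors, spec$variance_fraction, maxf)
  }
  if (failures > 0) {
    inform(sprintf("%d permutation(s) retried after covariance estimation failure.", failures))
  }
  list(Q = unname(Q), retries = failures)
}

#' Satterthwaite scaled chi-square p-value
#'
#' Approximates the permutation null of the quadratic statistic by a scaled
#' chi-square `kappa * chi^2_nu`, with `kappa = Var(Q) / (2 E(Q))` and
#' `nu = 2 E(Q)^2 / Var(Q)` estimated from the permutation draws (sample mean
#' and unbiased variance). Allows much smaller p-values than the permutation
#' rank at the same number of permutations.
#'
#' @param Q_obs Observed statistic.
#' @param draws Numeric vector of permuted statistics (or a list with a
#'   `Q_values` element).
#' @return List with `kappa`, `nu` and `p` (upper tail of `chi^2_nu` at
#'   `Q_obs / kappa`).
#' @examples
#' satterthwaite_pvalue(20, list(Q_values = rchisq(1000, 5) * 2))
#' @export
satterthwaite_pvalue <- function(Q_obs, draws) {
  Qb <- if (is.list(draws)) draws$Q_values else draws
  E <- mean(Qb); Vr <- var(Qb)
  if (!is.finite(Vr) || Vr <= 0) {
    abort("Permutation draws have zero variance; use the permutation p-value instead.")
  }
  kappa <- Vr / (2 * E)
  nu <- 2 * E^2 / Vr
  list(kappa = kappa, nu = nu,
       p = pchisq(Q_obs / kappa, df = nu, lower.tail = FALSE))
}

# Two-component univariate normal mixture by EM. Initialization: median split
# plus random-split restarts; loglik tolerance 1e-8; variance floor 1e-6.
fit_normal_mixture <- function(z, n_restarts = 10, max_iter = 10000,
                               tol = 1e-8, var_floor = 1e-6) {
  z <- z[is.finite(z)]
  m <- length(z)
  if (m < 4) abort("Too few values to fit a two-component mixture.")
  run_em <- function(assign1) {
    pi1 <- mean(assign1); pi1 <- min(max(pi1, 0.05), 0.95)
    mu <- c(mean(z[assign1 >= 0.5]), mean(z[assign1 < 0.5]))
    s2 <- c(var(z[assign1 >= 0.5]), var(z[assign1 < 0.5]))
    s2[!is.finite(s2) | s2 < var_floor] <- var_floor
    pi_a <- c(pi1, 1 - pi1)
    ll_trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      d1 <- pi_a[1] * dnorm(z, mu[1], sqrt(s2[1]))
      d2 <- pi_a[2] * dnorm(z, mu[2], sqrt(s2[2]))
      tot <- d1 + d2
      tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
      ll <- sum(log(tot))
      ll_trace <- c(ll_trace, ll)
      if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
      ll_old <- ll
      r1 <- d1 / tot
      w1 <- sum(r1); w2 <- m - w1
      if (w1 < 1e-8 || w2 < 1e-8) break
      mu <- c(sum(r1 * z) / w1, sum((1 - r1) * z) / w2)
      s2 <- c(sum(r1 * (z - mu[1])^2) / w1, sum((1 - r1) * (z - mu[2])^2) / w2)
      s2 <- pmax(s2, var_floor)
      pi_a <- c(w1, w2) / m
    }
    list(pi = pi_a, mu = mu, sigma2 = s2, loglik = ll_old,
         loglik_trace = ll_trace, converged = converged)
  }
  fits <- list(run_em(as.numeric(z <= stats::median(z))))
  for (r in seq_len(n_restarts)) {
    fits[[r + 1]] <- run_em(as.numeric(stats::runif(m) < stats::runif(1, 0.2, 0.8)))
  }
  ok <- vapply(fits, function(f) isTRUE(f$converged) && all(is.finite(f$mu)), logical(1))
  if (!any(ok)) {
    warn("Normal-mixture EM did not converge; falling back to a single normal fit.")
    mu <- mean(z); s2 <- max(var(z), var_floor)
    return(structure(list(pi = c(1, 0), mu = c(mu, mu), sigma2 = c(s2, s2),
                          loglik = sum(dnorm(z, mu, sqrt(s2), log = TRUE)),
                          loglik_trace = numeric(0), converged = FALSE),
                     class = "normal_mixture_fit"))
  }
  best <- fits[ok][[which.max(vapply(fits[ok], `[[`, numeric(1), "loglik"))]]
  structure(best, class = "normal_mixture_fit")
}

#' Normal-mixture refined p-value
#'
#' Refines the Satterthwaite approximation in the extreme tail: the probit
#' transforms of the per-permutation scaled chi-square p-values are modelled
#' by a two-component normal mixture fitted by maximum likelihood (EM), and
#' the reported p-value is the lower-tail mixture probability at the probit of
#' the observed Satterthwaite p-value (small p-values map to very negative
#' probits).
#'
#' @param p_obs_satt Observed Satterthwaite p-value.
#' @param satt_p_values Per-permutation Satterthwaite p-values (or a list with
#'   a `satt_p_values` element).
#' @param ... Passed to the internal EM fitter (`n_restarts`, `max_iter`,
#'   `tol`, `var_floor`).
#' @return List with `fit` (class `normal_mixture_fit`) and `p`.
#' @export
normal_mixture_pvalue <- function(p_obs_satt, satt_p_values, ...) {
  pb <- if (is.list(satt_p_values)) satt_p_values$satt_p_values else satt_p_values
  B <- length(pb)
  clamp <- function(p) pmin(pmax(p, 1 / (10 * B)), 1 - 1 / (10 * B))
  z <- qnorm(clamp(pb))
  fit <- fit_normal_mixture(z, ...)
  z_obs <- qnorm(clamp(p_obs_satt))
  p <- fit$pi[1] * pnorm(z_obs, fit$mu[1], sqrt(fit$sigma2[1])) +
    fit$pi[2] * pnorm(z_obs, fit$mu[2], sqrt(fit$sigma2[2]))
  list(fit = fit, p = p)
}

#' @export
print.normal_mixture_fit <- function(x, ...) {
  cat(sprintf("<normal_mixture_fit> pi = (%.3f, %.3f), mu = (%.3f, %.3f), sigma = (%.3f, %.3f)%s\n",
              x$pi[1], x$pi[2], x$mu[1], x$mu[2], sqrt(x$sigma2[1]), sqrt(x$sigma2[2]),
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' q-values for a vector of p-values
#'
#' Storey q-values with the null proportion estimated at a fixed lambda
#' (default 0.5); `pi0 = 1` (or `method = "bh"`) gives the Benjamini-Hochberg
#' adjusted p-values. Monotonicity in the sorted p-values is enforced by a
#' cumulative minimum.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param method `"storey"` or `"bh"`.
#' @param lambda Tuning point for the Storey null-proportion estimate.
#' @param pi0 Optional override of the estimated null proportion.
#' @return Vector of q-values, same length and order as `p`.
#' @examples
#' qvalues(c(0.001, 0.01, 0.2, 0.8), method = "bh")
#' @export
qvalues <- function(p, method = c("storey", "bh"), lambda = 0.5, pi0 = NULL) {
  method <- match.arg(method)
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  if (method == "bh") pi0 <- 1
  if (is.null(pi0)) {
    # floored at 1/m: with few sets the tail estimate can hit zero, which
    # would report an FDR of exactly 0
    pi0 <- min(1, max(mean(p > lambda, na.rm = TRUE) / (1 - lambda),
                      1 / length(p)))
  }
  pmin(pi0 * p.adjust(p, method = "BH"), 1)
}

#' Test one gene set for a phenotype effect
#'
#' The workhorse single-set test: computes the variance component score
#' statistic under a chosen working covariance and estimates its null
#' distribution by permuting the phenotype, re-estimating the working
#' covariance within every permutation. p-values are reported from the
#' permutation rank (`(1 + #\{Q_b >= Q_obs\}) / (B + 1)`), the Satterthwaite
#' scaled chi-square moment approximation, and (optionally) the normal-mixture
#' tail refinement.
#'
#' @param expr Samples-by-genes matrix or data frame (the genes of one set).
#' @param pheno [phenotype()] or coercible vector (binary 0/1 or numeric).
#' @param cov Working covariance: a structure name (`"indpt"`, `"unstr"`,
#'   `"cpsym"`, `"f2"`, `"f-adpt"`), a [working_cov_spec()], or a p-by-p
#'   matrix (used as supplied, e.g. a known covariance).
#' @param B Number of permutations (at least `min_B`).
#' @param seed Integer seed making the permutation draw reproducible; `NULL`
#'   uses the current RNG state.
#' @param methods Character subset of `c("perm", "satt", "mix")`, or `"all"`.
#' @param set_name Label carried into the result.
#' @param keep_draws Keep the permuted statistics (and per-permutation
#'   Satterthwaite p-values) in the result.
#' @param min_B Floor on `B` below which p-values are refused (default 100).
#' @return Object of class `tegs_result`; see [tidy.tegs_result()] and
#'   [glance.tegs_result()].
#' @examples
#' sim <- simulate_gene_set(n = 20, n1 = 10, beta = make_beta(10, 2, 3, 0.8),
#'                          Sigma = make_cov_cs(10, 0.5), seed = 7)
#' res <- tegs_test(sim$expr, sim$pheno, cov = "f2", B = 200, seed = 1)
#' glance(res)
#' @export
tegs_test <- function(expr, pheno, cov = "f2", B = 1000, seed = NULL,
                      methods = c("perm", "satt"), set_name = "gene_set",
                      keep_draws = FALSE, min_B = 100) {
  Y <- validate_expression(expr, strict = TRUE)
  pheno <- validate_phenotype(pheno, n = nrow(Y), strict = TRUE)
  spec <- as_working_cov_spec(cov)
  if ("all" %in% methods) methods <- c("perm", "satt", "mix")
  methods <- match.arg(methods, c("perm", "satt", "mix"), several.ok = TRUE)
  if ("mix" %in% methods && !"satt" %in% methods) methods <- c(methods, "satt")
  if (B < min_B) {
    abort(sprintf("B = %d is below the reporting floor of %d permutations.", B, min_B))
  }
  if (!is.null(seed)) set.seed(seed)
  idx <- permutation_indices(nrow(Y), B)
  eng <- tegs_perm_Q(Y, pheno$x, idx, spec)
  Q_obs <- eng$Q[1]
  Q_perm <- eng$Q[-1]

  p_perm <- p_satt <- p_mix <- kappa <- nu <- NA_real_
  mixture_fit <- NULL
  satt_pb <- NULL
  if ("perm" %in% methods) {
    p_perm <- (1 + sum(Q_perm >= Q_obs)) / (B + 1)
  }
  if ("satt" %in% methods) {
    st <- satterthwaite_pvalue(Q_obs, Q_perm)
    kappa <- st$kappa; nu <- st$nu; p_satt <- st$p
  }
  if ("satt" %in% methods && (keep_draws || "mix" %in% methods)) {
    satt_pb <- pchisq(Q_perm / kappa, df = nu, lower.tail = FALSE)
  }
  if ("mix" %in% methods) {
    mx <- normal_mixture_pvalue(p_satt, satt_pb)
    mixture_fit <- mx$fit
    p_mix <- mx$p
  }
  structure(list(set_name = set_name, Q_observed = Q_obs,
                 p_perm = p_perm, p_satt = p_satt, p_mix = p_mix,
                 kappa = kappa, nu = nu, B = B, seed = seed,
                 covariance_kind = spec$kind, n = nrow(Y), p = ncol(Y),
                 retries = eng$retries,
                 perm_Q = if (keep_draws) Q_perm else NULL,
                 satt_p_values = if (keep_draws) satt_pb else NULL,
                 mixture_fit = mixture_fit),
            class = "tegs_result")
}

#' @export
print.tegs_result <- function(x, ...) {
  cat(sprintf("TEGS test of '%s' (%d genes, %d samples), working covariance: %s\n",
              x$set_name, x$p, x$n, x$covariance_kind))
  cat(sprintf("  Q = %.4g, B = %d permutations\n", x$Q_observed, x$B))
  if (!is.na(x$p_perm)) cat(sprintf("  p (permutation)      = %.4g\n", x$p_perm))
  if (!is.na(x$p_satt)) {
    cat(sprintf("  p (scaled chi-square) = %.4g  [kappa = %.3g, nu = %.3g]\n",
                x$p_satt, x$kappa, x$nu))
  }
  if (!is.na(x$p_mix)) cat(sprintf("  p (normal mixture)   = %.4g\n", x$p_mix))
  invisible(x)
}

#' Test every gene set in a collection
#'
#' Runs [tegs_test()] on each set of a collection against the same phenotype,
#' and adjusts the resulting p-values for multiple comparisons with q-values.
#' Each set gets its own deterministic permutation stream derived from `seed`,
#' so a set's p-value does not depend on which other sets (or how many
#' off-set genes) are present.
#'
#' @param expr Samples-by-genes matrix or data frame holding all measured
#'   genes.
#' @param pheno [phenotype()] or coercible vector.
#' @param sets Named list of gene-id vectors (see [read_gmt()]).
#' @param cov,B,seed,methods,min_B As in [tegs_test()].
#' @param min_set_size Sets with fewer measured genes are dropped
#'   (see [align_and_filter()]).
#' @param qvalue_method `"storey"` or `"bh"` (see [qvalues()]); q-values are
#'   computed on the permutation p-values when present, otherwise on the
#'   Satterthwaite ones.
#' @param keep_draws Keep the full per-set [tegs_test()] results (with
#'   permutation draws) in the `"results"` attribute, e.g. for null-draw
#'   audit dumps.
#' @return A tibble (class `tegs_run`) with one row per retained set:
#'   `set`, `p_genes`, `Q`, `p_perm`, `p_satt`, `p_mix`, `kappa`, `nu`,
#'   `q_value`.
#' @examples
#' sim <- simulate_gene_set(n = 20, n1 = 10, beta = make_beta(8, 2, 2, 1),
#'                          Sigma = make_cov_cs(8, 0.3), seed = 2)
#' sets <- list(S1 = paste0("G", 1:4), S2 = paste0("G", 5:8))
#' tegs_run(sim$expr, sim$pheno, sets, cov = "indpt", B = 200, seed = 9)
#' @export
tegs_run <- function(expr, pheno, sets, cov = "f2", B = 1000, seed = NULL,
                     min_set_size = 4, methods = c("perm", "satt"),
                     qvalue_method = c("storey", "bh"), min_B = 100,
                     keep_draws = FALSE) {
  qvalue_method <- match.arg(qvalue_method)
  Y <- validate_expression(expr, strict = TRUE)
  pheno <- validate_phenotype(pheno, n = nrow(Y), strict = TRUE)
  kept <- align_and_filter(Y, sets, min_set_size = min_set_size)
  if (length(kept) == 0) {
    return(structure(tibble(set = character(0), p_genes = integer(0),
                            Q = numeric(0), p_perm = numeric(0),
                            p_satt = numeric(0), p_mix = numeric(0),
                            kappa = numeric(0), nu = numeric(0),
                            q_value = numeric(0)),
                     removed = attr(kept, "removed"),
                     class = c("tegs_run", class(tibble()))))
  }
  if (!is.null(seed)) set.seed(seed)
  set_seeds <- sample.int(.Machine$integer.max - 1L, length(kept))
  results <- purrr::map2(names(kept), set_seeds, function(nm, sd) {
    tegs_test(Y[, kept[[nm]], drop = FALSE], pheno, cov = cov, B = B,
              seed = sd, methods = methods, set_name = nm, min_B = min_B,
              keep_draws = keep_draws)
  })
  out <- dplyr::bind_rows(purrr::map(results, function(res) {
    tibble(set = res$set_name, p_genes = res$p, Q = res$Q_observed,
           p_perm = res$p_perm, p_satt = res$p_satt, p_mix = res$p_mix,
           kappa = res$kappa, nu = res$nu)
  }))
  p_for_q <- if (all(is.na(out$p_perm))) out$p_satt else out$p_perm
  out$q_value <- qvalues(p_for_q, method = qvalue_method)
  structure(out, removed = attr(kept, "removed"),
            results = if (keep_draws) stats::setNames(results, names(kept)) else NULL,
            class = c("tegs_run", class(out)))
}
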