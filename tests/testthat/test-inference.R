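test_that("Satterthwaite moment matching follows the printed formulas", {
  # draws with exact sample mean 10 and unbiased variance 40 -> kappa 2, nu 5
  qb <- c(10, 10, 10 - sqrt(60), 10 + sqrt(60))
  st <- satterthwaite_pvalue(20, qb)
  expect_equal(mean(qb), 10, tolerance = 1e-12)
  expect_equal(var(qb), 40, tolerance = 1e-12)
  expect_equal(st$kappa, 2, tolerance = 1e-12)
  expect_equal(st$nu, 5, tolerance = 1e-12)
  # chi-square tail oracle at Q/kappa = 10 on 5 df
  expect_equal(st$p, pchisq(10, 5, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(st$p, 0.07523525, tolerance = 1e-6)

  # first two moments of kappa * chi2_nu reproduce (E, Var) by construction
  expect_equal(st$kappa * st$nu, 10, tolerance = 1e-12)
  expect_equal(2 * st$kappa^2 * st$nu, 40, tolerance = 1e-12)

  expect_error(satterthwaite_pvalue(1, rep(2, 50)), "zero variance")
})

test_that("permutation p-value matches exhaustive enumeration for n = 4", {
  set.seed(41)
  Y <- matrix(rnorm(4 * 3), 4, 3, dimnames = list(paste0("S", 1:4), paste0("G", 1:3)))
  x <- c(0, 0, 1, 1)
  V <- diag(3)
  d_obs <- center_under_null(Y, phenotype(x))
  Q_obs <- tegs_statistic(d_obs, V)
  # all C(4,2) = 6 labelings
  labelings <- combn(4, 2)
  Q_all <- apply(labelings, 2, function(ones) {
    xx <- rep(0, 4); xx[ones] <- 1
    tegs_statistic(center_under_null(Y, phenotype(xx)), V)
  })
  p_exact <- mean(Q_all >= Q_obs - 1e-12)
  res <- tegs_test(Y, x, cov = "indpt", B = 4000, seed = 42, methods = "perm")
  expect_lt(abs(res$p_perm - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 4000) + 1e-3)
})

test_that("results are reproducible given a seed and respect the B floor", {
  sim <- simulate_gene_set(16, 8, make_beta(6, 1, 2, 0.5), make_cov_cs(6, 0.3),
                           seed = 43)
  r1 <- tegs_test(sim$expr, sim$pheno, cov = "unstr", B = 150, seed = 7,
                  methods = "all", keep_draws = TRUE)
  r2 <- tegs_test(sim$expr, sim$pheno, cov = "unstr", B = 150, seed = 7,
                  methods = "all", keep_draws = TRUE)
  expect_identical(r1$perm_Q, r2$perm_Q)
  expect_identical(r1$p_perm, r2$p_perm)
  expect_identical(r1$p_mix, r2$p_mix)
  expect_error(tegs_test(sim$expr, sim$pheno, B = 50), "floor")
  expect_true(r1$p_perm > 0 && r1$p_perm <= 1)
  expect_true(all(r1$perm_Q >= 0))
})

test_that("a median observed statistic gives a permutation p-value near one half", {
  sim <- simulate_gene_set(20, 10, make_beta(8, 0, 0, 0), make_cov_cs(8, 0.2),
                           seed = 44)
  res <- tegs_test(sim$expr, sim$pheno, cov = "indpt", B = 1000, seed = 45,
                   methods = "perm", keep_draws = TRUE)
  rank_based <- (1 + sum(res$perm_Q >= res$Q_observed)) / (1000 + 1)
  expect_identical(res$p_perm, rank_based)
})

test_that("normal mixture on uniform per-permutation p-values recovers N(0,1) and p_obs", {
  set.seed(46)
  B <- 2000
  pb <- (seq_len(B) - 0.5) / B        # exactly uniform grid
  out <- normal_mixture_pvalue(0.3, pb)
  # mixture mean and variance close to standard normal
  mu_mix <- sum(out$fit$pi * out$fit$mu)
  var_mix <- sum(out$fit$pi * (out$fit$sigma2 + out$fit$mu^2)) - mu_mix^2
  expect_lt(abs(mu_mix), 0.1)
  expect_lt(abs(var_mix - 1), 0.15)
  expect_lt(abs(out$p - 0.3), 0.05)

  # symmetric case: p_obs = 0.5 maps to probit 0, the mixture center
  out2 <- normal_mixture_pvalue(0.5, pb)
  expect_lt(abs(out2$p - 0.5), 0.05)
})

test_that("EM log-likelihood is non-decreasing and matches an independent fitter", {
  set.seed(47)
  z <- c(rnorm(400, -1, 0.8), rnorm(200, 1.5, 1.2))
  fit <- tegs:::fit_normal_mixture(z)
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik_trace) >= -1e-9))
  expect_equal(sum(fit$pi), 1, tolerance = 1e-12)

  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  mc <- mclust::Mclust(z, G = 2, modelNames = "V", verbose = FALSE)
  expect_lt(abs(fit$loglik - mc$loglik), 0.5)   # same optimum up to EM wiggle
})

test_that("q-values reduce to Benjamini-Hochberg and stay monotone", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  # textbook BH: p_(i) * m / i with cumulative minimum from the largest
  m <- length(p)
  bh_hand <- rev(cummin(rev(sort(p) * m / seq_len(m))))[order(order(p))]
  expect_equal(qvalues(p, method = "bh"), pmin(bh_hand, 1), tolerance = 1e-12)
  expect_equal(qvalues(p, pi0 = 1), qvalues(p, method = "bh"), tolerance = 1e-12)

  expect_identical(qvalues(rep(1, 5)), rep(1, 5))
  expect_identical(qvalues(numeric(0)), numeric(0))

  o <- order(p)
  expect_true(all(diff(qvalues(p)[o]) >= -1e-12))
})

test_that("tegs_run returns one calibrated row per retained set with q-values", {
  set.seed(48)
  sim <- simulate_gene_set(20, 10, make_beta(12, 0, 4, 1.2), make_cov_cs(12, 0.3),
                           seed = 49)
  sets <- list(SIGNAL = paste0("G", 1:6), NULLSET = paste0("G", 7:12),
               TINY = paste0("G", 1:2))
  out <- tegs_run(sim$expr, sim$pheno, sets, cov = "indpt", B = 200, seed = 50)
  expect_s3_class(out, "tegs_run")
  expect_identical(out$set, c("SIGNAL", "NULLSET"))
  expect_identical(out$p_genes, c(6L, 6L))
  expect_true(all(out$q_value >= out$p_perm - 1e-12 | out$q_value <= 1))
  expect_lt(out$p_perm[out$set == "SIGNAL"], out$p_perm[out$set == "NULLSET"])
  expect_identical(attr(out, "removed")$set, "TINY")

  # deterministic per-set streams: same seed, same p-values
  out2 <- tegs_run(sim$expr, sim$pheno, sets, cov = "indpt", B = 200, seed = 50)
  expect_identical(out$p_perm, out2$p_perm)
})

test_that("permutation and Satterthwaite p-values agree on average under the null", {
  sc <- simulation_scenario(n = 20, n1 = 10, Sigma = make_cov_cs(6, 0.4),
                            beta = make_beta(6, 0, 0, 0),
                            replicates = 60, B = 300, seed = 51)
  out <- run_size_power_experiment(sc, "true", keep_pvalues = TRUE)
  pv <- attr(out, "pvalues")
  wide <- tidyr::pivot_wider(pv, names_from = "method", values_from = "p")
  expect_lt(mean(abs(wide$perm - wide$satt)), 0.05)
  expect_lt(abs(mean(wide$perm) - 0.5), 0.1)
})

test_that("tidiers and autoplot methods produce well-formed output", {
  sim <- simulate_gene_set(16, 8, make_beta(5, 1, 1, 0.5), make_cov_cs(5, 0.2),
                           seed = 52)
  res <- tegs_test(sim$expr, sim$pheno, cov = "f2", B = 150, seed = 53,
                   methods = c("perm", "satt"), keep_draws = TRUE)
  td <- tidy(res)
  expect_identical(td$method, c("perm", "satt"))
  gl <- glance(res)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$covariance, "f2")
  expect_s3_class(autoplot(res), "ggplot")

  sc <- simulation_scenario(n = 16, n1 = 8, Sigma = make_cov_cs(4, 0.2),
                            beta = make_beta(4, 0, 0, 0), replicates = 5,
                            B = 100, seed = 54)
  ex <- run_size_power_experiment(sc, c("indpt", "true"))
  expect_s3_class(autoplot(ex), "ggplot")
  pc <- power_curve(make_cov_cs(4, 0.2), make_cov_cs(4, 0.2),
                    make_beta(4, 1, 1, 0.5), beta_scale = c(0, 1), n = c(20, 40))
  expect_s3_class(autoplot(pc), "ggplot")
})
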