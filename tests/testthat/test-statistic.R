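test_that("null centering uses plain sample means whatever covariance is assumed", {
  inst <- random_instance(8, 3, seed = 20)
  d <- center_under_null(inst$Y, phenotype(inst$x))
  expect_equal(unname(colSums(d$centered_responses)), rep(0, 3), tolerance = 1e-8)
  expect_equal(sum(d$centered_x), 0, tolerance = 1e-12)

  # GLS intercept oracle: alpha-hat = (J' Sn^-1 J)^-1 J' Sn^-1 Y equals the
  # sample mean for any PD Sigma
  Sigma <- random_pd(3, seed = 21)
  n <- 8; p <- 3
  J <- do.call(rbind, replicate(n, diag(p), simplify = FALSE))
  Sn_inv <- kronecker(diag(n), solve(Sigma))
  Yv <- as.vector(t(inst$Y))
  alpha_gls <- solve(t(J) %*% Sn_inv %*% J, t(J) %*% Sn_inv %*% Yv)
  expect_equal(c(alpha_gls), unname(colMeans(inst$Y)), tolerance = 1e-10)

  # constant genes center to zero
  dz <- center_under_null(matrix(5, 6, 2), phenotype(rep(c(0, 1), 3)))
  expect_true(all(dz$centered_responses == 0))
})

test_that("the statistic matches hand evaluation and vanishes when it must", {
  # p = 1, V = 1, x = (0,1), Y = (0,2): Ybar = 1, U = 1 -> Q = 1
  d <- center_under_null(matrix(c(0, 2), 2, 1), phenotype(c(0, 1)))
  expect_equal(tegs_statistic(d, diag(1)), 1, tolerance = 1e-12)

  # identical profiles across samples -> Q = 0
  d0 <- center_under_null(matrix(rep(c(1, 2, 3), each = 6), 6, 3),
                          phenotype(rep(c(0, 1), 3)))
  expect_equal(tegs_statistic(d0, random_pd(3, seed = 22)), 0, tolerance = 1e-20)
})

test_that("the p-dimensional reduction equals the literal stacked evaluation (np <= 60)", {
  cases <- list(c(4, 3), c(5, 4), c(6, 4), c(6, 6), c(6, 10), c(10, 6),
                c(12, 5), c(4, 15), c(20, 3))
  for (cs in cases) {
    for (binary in c(TRUE, FALSE)) {
      inst <- random_instance(cs[1], cs[2], binary = binary,
                              seed = 100 + cs[1] * cs[2] + binary)
      V <- random_pd(cs[2])
      d <- center_under_null(inst$Y, phenotype(inst$x))
      expect_equal(tegs_statistic(d, V), stacked_Q(inst$Y, inst$x, V),
                   tolerance = 1e-9,
                   label = sprintf("n=%d p=%d binary=%s", cs[1], cs[2], binary))
    }
  }
})

test_that("two-group closed form and global test agree with the general statistic", {
  # p = 1, V = 1, groups {0}, {2}: (1*1/2)^2 * (-2)^2 = 1
  d <- center_under_null(matrix(c(0, 2), 2, 1), phenotype(c(0, 1)))
  expect_equal(tegs_two_group(d, diag(1)), 1, tolerance = 1e-12)

  # zero mean difference -> 0
  dz <- center_under_null(matrix(c(1, 2, 2, 1), 4, 1), phenotype(c(0, 0, 1, 1)))
  expect_equal(tegs_two_group(dz, diag(1)), 0, tolerance = 1e-20)

  for (s in 1:20) {
    inst <- random_instance(10, 5, seed = 200 + s)
    V <- random_pd(5)
    d <- center_under_null(inst$Y, phenotype(inst$x))
    q_gen <- tegs_statistic(d, V)
    expect_equal(tegs_two_group(d, V), q_gen, tolerance = 1e-10)
    expect_equal(global_test_statistic(d), tegs_statistic(d, diag(5)),
                 tolerance = 1e-12)
  }

  dnum <- center_under_null(random_instance(8, 3, binary = FALSE, seed = 23)$Y,
                            phenotype(rnorm(8), kind = "numeric"))
  expect_error(tegs_two_group(dnum, diag(3)), "binary")
})

test_that("Q is invariant to constant profile shifts and scales as c^2 with fixed V", {
  inst <- random_instance(12, 4, seed = 24)
  V <- random_pd(4)
  d1 <- center_under_null(inst$Y, phenotype(inst$x))
  shifted <- sweep(inst$Y, 2, c(10, -3, 0.5, 100), `+`)
  d2 <- center_under_null(shifted, phenotype(inst$x))
  expect_equal(tegs_statistic(d2, V), tegs_statistic(d1, V), tolerance = 1e-9)
  expect_equal(global_test_statistic(d2), global_test_statistic(d1),
               tolerance = 1e-9)

  d3 <- center_under_null(3 * inst$Y, phenotype(inst$x))
  expect_equal(tegs_statistic(d3, V), 9 * tegs_statistic(d1, V), tolerance = 1e-9)
})

test_that("permuting genes and V together leaves Q unchanged", {
  inst <- random_instance(10, 6, seed = 25)
  V <- random_pd(6)
  perm <- c(3, 6, 1, 5, 2, 4)
  d <- center_under_null(inst$Y, phenotype(inst$x))
  dp <- center_under_null(inst$Y[, perm], phenotype(inst$x))
  expect_equal(tegs_statistic(dp, V[perm, perm]), tegs_statistic(d, V),
               tolerance = 1e-10)
})

test_that("mixture null weights have the closed form and trace identity", {
  # V = Sigma = I, x = (0,0,1,1): c = n1 n2 / n = 1, all weights 1
  d <- center_under_null(random_instance(4, 3, seed = 26)$Y,
                         phenotype(c(0, 0, 1, 1)))
  w <- null_mixture_weights(d, diag(3), diag(3))
  expect_equal(w, rep(1, 3), tolerance = 1e-10)

  # sum of weights equals the theoretical null mean (trace identity)
  for (s in 1:5) {
    inst <- random_instance(12, 5, seed = 300 + s)
    V <- random_pd(5); Sigma <- random_pd(5)
    d <- center_under_null(inst$Y, phenotype(inst$x))
    w <- null_mixture_weights(d, V, Sigma)
    pp <- power_problem(inst$x, V, Sigma, rep(0, 5))
    expect_equal(sum(w), theoretical_null_moments(pp)$E, tolerance = 1e-8)
    expect_true(all(w >= 0))
  }
})

test_that("weighted chi-square tail probabilities agree with permutation p-values", {
  # Gaussian null data, known Sigma used both to generate and as V: the
  # mixture law with the exact weights should match the permutation null
  # within Monte Carlo error.
  set.seed(27)
  n <- 60; p <- 5
  Sigma <- make_cov_cs(p, 0.4)
  sim <- simulate_gene_set(n, n / 2, make_beta(p, 0, 0, 0), Sigma)
  d <- center_under_null(sim$expr, sim$pheno)
  Q_obs <- tegs_statistic(d, Sigma)
  w <- null_mixture_weights(d, Sigma, Sigma)
  draws <- colSums(w * matrix(rchisq(p * 2e5, df = 1), p))  # MC mixture oracle
  p_mixture <- mean(draws >= Q_obs)
  res <- tegs_test(sim$expr, sim$pheno, cov = Sigma, B = 2000, seed = 28,
                   methods = "perm")
  expect_lt(abs(res$p_perm - p_mixture), 0.05)
})

test_that("covariate ridge residualization matches direct normal-equations solves", {
  set.seed(29)
  n <- 10
  Z <- cbind(rnorm(n), runif(n))
  Y <- matrix(rnorm(n * 2), n, 2)

  # penalty 0: OLS residuals
  G <- cbind(1, Z)
  ols <- Y - G %*% solve(crossprod(G), crossprod(G, Y))
  expect_equal(unname(adjust_for_covariates(Y, Z, 0)), unname(ols),
               tolerance = 1e-10)

  # direct solve of the penalized normal equations (intercept unpenalized)
  lam <- 2.5
  A <- crossprod(G) + diag(c(0, lam, lam))
  oracle <- Y - G %*% solve(A, crossprod(G, Y))
  expect_equal(unname(adjust_for_covariates(Y, Z, lam)), unname(oracle),
               tolerance = 1e-10)

  # penalty -> infinity: coefficients -> 0, residuals -> centered Y
  big <- adjust_for_covariates(Y, Z, 1e12)
  expect_equal(unname(big), unname(sweep(Y, 2, colMeans(Y))), tolerance = 1e-4)

  expect_error(adjust_for_covariates(Y, Z, -1), "nonnegative")
})
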