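# Shared fixtures and independent oracles, built in code.

random_pd <- function(p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(p * p), p)
  crossprod(A) / p + diag(p) * 0.5
}

random_instance <- function(n, p, binary = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Y <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("S", 1:n), paste0("G", 1:p)))
  x <- if (binary) sample(rep(c(0, 1), length.out = n)) else rnorm(n)
  list(Y = Y, x = x)
}

# Literal stacked np-dimensional evaluation of the quadratic score form:
# Q = || X' Vn^-1 (I - H) Y ||^2 with J, X, H, Vn built explicitly.
stacked_Q <- function(Y, x, V) {
  n <- nrow(Y); p <- ncol(Y)
  J <- do.call(rbind, replicate(n, diag(p), simplify = FALSE))
  X <- do.call(rbind, lapply(seq_len(n), function(i) x[i] * diag(p)))
  H <- tcrossprod(J) / n
  Vn_inv <- kronecker(diag(n), solve(V))
  Yv <- as.vector(t(Y))
  A <- t(X) %*% Vn_inv %*% (diag(n * p) - H) %*% Yv
  sum(A^2)
}

# Literal stacked trace formulas for the null moments and the alternative
# mean shift.
stacked_moments <- function(x, V, Sigma) {
  n <- length(x); p <- nrow(V)
  J <- do.call(rbind, replicate(n, diag(p), simplify = FALSE))
  X <- do.call(rbind, lapply(seq_len(n), function(i) x[i] * diag(p)))
  H <- tcrossprod(J) / n
  IH <- diag(n * p) - H
  Vn_inv <- kronecker(diag(n), solve(V))
  Sn <- kronecker(diag(n), Sigma)
  A <- IH %*% Vn_inv %*% X %*% t(X) %*% Vn_inv %*% IH
  list(E = sum(diag(A %*% Sn)), Var = 2 * sum(diag(A %*% Sn %*% A %*% Sn)))
}

stacked_alt_shift <- function(x, V, beta) {
  n <- length(x); p <- nrow(V)
  X <- do.call(rbind, lapply(seq_len(n), function(i) x[i] * diag(p)))
  J <- do.call(rbind, replicate(n, diag(p), simplify = FALSE))
  H <- tcrossprod(J) / n
  Vn_inv <- kronecker(diag(n), solve(V))
  v <- t(X) %*% Vn_inv %*% (diag(n * p) - H) %*% X %*% beta
  sum(v^2)
}

write_fixture_files <- function(dir, n = 16, p = 12, seed = 42) {
  set.seed(seed)
  x <- rep(c(0, 1), each = n / 2)
  Y <- outer(x, c(rep(1, 4), rep(0, p - 4))) + matrix(rnorm(n * p), n, p)
  rownames(Y) <- paste0("S", 1:n)
  colnames(Y) <- paste0("G", 1:p)
  gct <- file.path(dir, "expr.gct")
  cls <- file.path(dir, "pheno.cls")
  gmt <- file.path(dir, "sets.gmt")
  write_gct(Y, gct)
  write_cls(phenotype(x, labels = c("N", "D")), cls)
  sets <- list(SIGNAL = paste0("G", 1:4),
               NULLSET = paste0("G", 5:10),
               TINY = paste0("G", 11:12),          # below min_set_size
               PARTIAL = c(paste0("G", 7:10), "ABSENT1"))
  write_gmt(sets, gmt)
  list(gct = gct, cls = cls, gmt = gmt, Y = Y, x = x, sets = sets)
}
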