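# Internal helpers shared across modules.

# Coerce expression input (matrix or samples-by-genes data frame) to a
# numeric matrix with sample/gene dimnames.
as_expression_matrix <- function(expr, arg = "expr") {
  if (is.data.frame(expr)) {
    id_col <- which(!vapply(expr, is.numeric, logical(1)))
    if (length(id_col) > 1) {
      abort(sprintf("`%s` has %d non-numeric columns; at most one sample-id column is allowed.",
                    arg, length(id_col)))
    }
    if (length(id_col) == 1) {
      ids <- as.character(expr[[id_col]])
      expr <- as.matrix(expr[, -id_col, drop = FALSE])
      rownames(expr) <- ids
    } else {
      expr <- as.matrix(expr)
    }
  }
  if (!is.matrix(expr) || !is.numeric(expr)) {
    abort(sprintf("`%s` must be a numeric matrix or a samples-by-genes data frame.", arg))
  }
  if (is.null(rownames(expr))) rownames(expr) <- paste0("S", seq_len(nrow(expr)))
  if (is.null(colnames(expr))) colnames(expr) <- paste0("G", seq_len(ncol(expr)))
  expr
}

validate_expression <- function(expr, strict = FALSE) {
  expr <- as_expression_matrix(expr)
  if (anyNA(expr) || any(!is.finite(expr))) {
    abort("Expression matrix contains missing or non-finite values.")
  }
  if (ncol(expr) < 1) abort("Expression matrix must have at least one gene.")
  if (anyDuplicated(colnames(expr))) abort("Duplicate gene ids in expression matrix.")
  if (anyDuplicated(rownames(expr))) abort("Duplicate sample ids in expression matrix.")
  if (strict && nrow(expr) < 4) {
    abort("At least 4 samples are required for gene set testing.")
  }
  expr
}

is_binary01 <- function(x) all(x %in% c(0, 1))

# Draw B permutations of 1..n as an n x B integer index matrix.
permutation_indices <- function(n, B) {
  matrix(vapply(seq_len(B), function(b) sample.int(n), integer(n)), nrow = n)
}

chol_solve <- function(V, b) {
  ch <- chol(V)
  backsolve(ch, forwardsolve(t(ch), b))
}

`%g%` <- function(a, b) if (is.null(a)) b else a
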