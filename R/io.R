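#' Construct a phenotype
#'
#' A phenotype is the independent variable of the multivariate regression: one
#' value per sample, either binary (0/1 group membership, e.g. disease status)
#' or numeric (a continuous exposure).
#'
#' @param x Numeric vector, one value per sample, or a two-level
#'   factor/character vector (first level maps to 0).
#' @param kind `"binary"` or `"numeric"`. Guessed from `x` when omitted:
#'   values confined to {0, 1} (or a two-level factor) are treated as binary.
#' @param labels Optional length-2 character vector naming the 0 and 1 groups.
#' @return An object of class `tegs_pheno`: a list with elements `x`, `kind`
#'   and `labels`.
#' @examples
#' phenotype(c(0, 0, 1, 1))
#' phenotype(c("N", "N", "D", "D"))
#' @export
phenotype <- function(x, kind = NULL, labels = NULL) {
  if (inherits(x, "tegs_pheno")) return(x)
  if (is.factor(x) || is.character(x)) {
    lev <- unique(as.character(x))
    if (length(lev) != 2) {
      abort(sprintf("Categorical phenotype must have exactly 2 classes, got %d.", length(lev)))
    }
    labels <- labels %g% lev
    x <- as.numeric(match(as.character(x), lev) - 1)
    kind <- "binary"
  }
  if (!is.numeric(x)) abort("`x` must be numeric or a two-level factor/character vector.")
  if (anyNA(x) || any(!is.finite(x))) abort("Phenotype contains missing or non-finite values.")
  if (is.null(kind)) kind <- if (is_binary01(x) && length(unique(x)) == 2) "binary" else "numeric"
  kind <- match.arg(kind, c("binary", "numeric"))
  if (kind == "binary" && !is_binary01(x)) {
    abort("Binary phenotype values must lie in {0, 1}.")
  }
  structure(list(x = as.numeric(x), kind = kind, labels = labels),
            class = "tegs_pheno")
}

#' @export
print.tegs_pheno <- function(x, ...) {
  cat(sprintf("<tegs_pheno> %s, n = %d", x$kind, length(x$x)))
  if (x$kind == "binary") {
    cat(sprintf(" (n1 = %d, n2 = %d)", sum(x$x == 0), sum(x$x == 1)))
  }
  cat("\n")
  invisible(x)
}

# Validity of a phenotype paired with an expression matrix.
validate_phenotype <- function(pheno, n = NULL, strict = FALSE) {
  pheno <- phenotype(pheno)
  x <- pheno$x
  if (!is.null(n) && length(x) != n) {
    abort(sprintf("Phenotype length (%d) does not match sample count (%d).", length(x), n))
  }
  if (var(x) <= 0) abort("Phenotype is constant; the design is degenerate.")
  if (strict && pheno$kind == "binary") {
    if (sum(x == 0) < 2 || sum(x == 1) < 2) {
      abort("Each phenotype group must contain at least 2 samples.")
    }
  }
  pheno
}

# ---------------------------------------------------------------------------
# GCT (v1.2): genes as rows on disk; samples as rows in memory.

#' Read a GCT v1.2 expression file
#'
#' GCT stores genes as rows; the returned matrix is transposed to the
#' samples-by-genes orientation used throughout the package.
#'
#' @param path Path to a GCT file.
#' @return Numeric matrix, samples as rows, genes as columns; gene descriptions
#'   (second GCT column) are kept in the `"descriptions"` attribute.
#' @export
read_gct <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || trimws(lines[1]) != "#1.2") {
    abort(sprintf("Malformed GCT header in %s: first line must be '#1.2'.", path))
  }
  dims <- strsplit(trimws(lines[2]), "[ \t]+")[[1]]
  if (length(dims) < 2 || anyNA(suppressWarnings(as.integer(dims[1:2])))) {
    abort(sprintf("Malformed GCT dimension line in %s.", path))
  }
  n_genes <- as.integer(dims[1]); n_samples <- as.integer(dims[2])
  header <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  if (length(header) != n_samples + 2) {
    abort(sprintf("GCT header declares %d samples but column header has %d sample fields.",
                  n_samples, length(header) - 2))
  }
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n_genes) {
    abort(sprintf("GCT dimension mismatch: header declares %d genes, body has %d rows.",
                  n_genes, length(body)))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  gene_ids <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(gene_ids)) {
    abort(sprintf("Duplicate gene ids in %s: %s", path,
                  paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", ")))
  }
  descriptions <- vapply(fields, `[[`, character(1), 2)
  vals <- matrix(NA_real_, n_genes, n_samples)
  for (i in seq_len(n_genes)) {
    row <- fields[[i]]
    if (length(row) != n_samples + 2) {
      abort(sprintf("GCT row %d has %d value fields, expected %d.",
                    i, length(row) - 2, n_samples))
    }
    v <- suppressWarnings(as.numeric(row[-(1:2)]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      abort(sprintf("Non-numeric expression value at GCT row %d (gene %s), sample column %d.",
                    i, gene_ids[i], j))
    }
    vals[i, ] <- v
  }
  out <- t(vals)
  rownames(out) <- header[-(1:2)]
  colnames(out) <- gene_ids
  attr(out, "descriptions") <- stats::setNames(descriptions, gene_ids)
  validate_expression(out)
}

#' Write a GCT v1.2 expression file
#'
#' @param expr Samples-by-genes matrix (or data frame).
#' @param path Output path.
#' @param descriptions Optional named character vector of gene descriptions.
#' @export
write_gct <- function(expr, path, descriptions = NULL) {
  expr <- as_expression_matrix(expr)
  descriptions <- descriptions %g% attr(expr, "descriptions") %g%
    stats::setNames(rep("na", ncol(expr)), colnames(expr))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(ncol(expr), nrow(expr), sep = "\t"),
               paste(c("Name", "Description", rownames(expr)), collapse = "\t")), con)
  body <- vapply(seq_len(ncol(expr)), function(j) {
    paste(c(colnames(expr)[j], unname(descriptions[colnames(expr)[j]]),
            format(expr[, j], digits = 17, trim = TRUE, scientific = FALSE)),
          collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# CLS: categorical ("n k 1" / "# labels" / tokens) and numeric ("#numeric").

#' Read a CLS phenotype file
#'
#' Supports the categorical dialect (two classes only; the first-listed class
#' maps to 0) and the continuous `#numeric` dialect.
#'
#' @param path Path to a CLS file.
#' @return A [phenotype()] object.
#' @export
read_cls <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) abort(sprintf("Malformed CLS file %s: expected 3 lines.", path))
  if (grepl("^#numeric", trimws(lines[1]), ignore.case = TRUE)) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[3]), "[ \t]+")[[1]]))
    if (anyNA(vals)) abort(sprintf("Non-numeric value in continuous CLS file %s.", path))
    return(phenotype(vals, kind = "numeric"))
  }
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "[ \t]+")[[1]]))
  if (length(hdr) < 2 || anyNA(hdr[1:2])) {
    abort(sprintf("Malformed CLS header in %s.", path))
  }
  n <- hdr[1]; k <- hdr[2]
  if (k != 2) {
    abort(sprintf("CLS file %s declares %d classes; only 2-class phenotypes are supported.",
                  path, k))
  }
  labels <- strsplit(trimws(sub("^#", "", lines[2])), "[ \t]+")[[1]]
  labels <- labels[nzchar(labels)]
  if (length(labels) != 2) abort(sprintf("CLS label line in %s must name 2 classes.", path))
  tokens <- strsplit(trimws(lines[3]), "[ \t]+")[[1]]
  if (length(tokens) != n) {
    abort(sprintf("CLS file %s declares %d samples but has %d class tokens.",
                  path, n, length(tokens)))
  }
  if (all(tokens %in% labels)) {
    x <- match(tokens, labels) - 1
  } else if (all(grepl("^[0-9]+$", tokens))) {
    idx <- as.integer(tokens)
    if (!all(idx %in% c(0, 1))) {
      abort(sprintf("CLS numeric class tokens in %s must be 0 or 1.", path))
    }
    x <- idx
  } else {
    bad <- setdiff(unique(tokens), labels)
    abort(sprintf("CLS class tokens in %s do not match declared labels: %s",
                  path, paste(bad, collapse = ", ")))
  }
  phenotype(as.numeric(x), kind = "binary", labels = labels)
}

#' Write a CLS phenotype file
#'
#' @param pheno A [phenotype()] (or coercible vector).
#' @param path Output path.
#' @export
write_cls <- function(pheno, path) {
  pheno <- phenotype(pheno)
  con <- file(path, "w")
  on.exit(close(con))
  if (pheno$kind == "binary") {
    labels <- pheno$labels %g% c("CLASS0", "CLASS1")
    writeLines(c(paste(length(pheno$x), 2, 1),
                 paste("#", labels[1], labels[2]),
                 paste(labels[pheno$x + 1], collapse = " ")), con)
  } else {
    writeLines(c("#numeric", "#score",
                 paste(format(pheno$x, digits = 17, trim = TRUE), collapse = " ")), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# GMT gene set collections: a named list of character vectors, with set
# descriptions in the "descriptions" attribute (the shape fgsea-style tools
# use).

#' Read a GMT gene set file
#'
#' @param path Path to a GMT file (`name TAB description TAB gene ids...`).
#' @return Named list of character gene-id vectors, in file order, with a
#'   `"descriptions"` attribute. Duplicate gene ids within a set are dropped
#'   with a warning; duplicate set names are an error.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short)) {
    abort(sprintf("GMT line %d in %s has fewer than 3 tab-separated fields.", short[1], path))
  }
  nm <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(nm)) {
    abort(sprintf("Gene set name(s) defined more than once in %s: %s", path,
                  paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  sets <- lapply(seq_along(fields), function(i) {
    g <- fields[[i]][-(1:2)]
    g <- g[nzchar(g)]
    if (anyDuplicated(g)) {
      warn(sprintf("Set '%s': %d duplicate gene id(s) dropped.", nm[i], sum(duplicated(g))))
      g <- unique(g)
    }
    g
  })
  names(sets) <- nm
  attr(sets, "descriptions") <- stats::setNames(vapply(fields, `[[`, character(1), 2), nm)
  sets
}

#' Write a GMT gene set file
#'
#' @param sets Named list of character gene-id vectors.
#' @param path Output path.
#' @param descriptions Optional named character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %g% attr(sets, "descriptions") %g%
    stats::setNames(rep("na", length(sets)), names(sets))
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, unname(descriptions[nm]), sets[[nm]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# TSV fallbacks for users without GCT/CLS files.

#' Read expression from a plain TSV file
#'
#' Expects a header row of gene ids and a first column of sample ids
#' (samples as rows).
#'
#' @param path Path to a tab-separated file.
#' @return Samples-by-genes numeric matrix.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_expression(as_expression_matrix(df))
}

#' Read a phenotype from a plain TSV/one-column file
#'
#' Accepts either a single column of values or a two-column `sample TAB value`
#' layout (header optional in the one-column case).
#'
#' @param path Path to the file.
#' @return A [phenotype()] object.
#' @export
read_phenotype_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  col <- df[[ncol(df)]]
  if (is.numeric(col)) phenotype(col) else phenotype(as.character(col))
}

# ---------------------------------------------------------------------------

#' Restrict gene sets to the measured genes and drop small sets
#'
#' Genes absent from the expression matrix are removed from each set (with a
#' logged count); sets falling below `min_set_size` measured genes are dropped,
#' mirroring the usual exclusion of very small sets (fewer than four probes)
#' in gene set analyses.
#'
#' @param expr Samples-by-genes expression matrix (or data frame).
#' @param sets Named list of gene-id vectors (see [read_gmt()]).
#' @param min_set_size Minimum number of measured genes a set must retain
#'   (default 4).
#' @return The filtered collection, with a `"removed"` attribute: a tibble of
#'   dropped sets and their measured sizes.
#' @export
align_and_filter <- function(expr, sets, min_set_size = 4) {
  expr <- as_expression_matrix(expr)
  genes <- colnames(expr)
  trimmed <- lapply(sets, function(g) g[g %in% genes])
  n_dropped_genes <- sum(lengths(sets) - lengths(trimmed))
  if (n_dropped_genes > 0) {
    inform(sprintf("%d gene id(s) in the collection are absent from the expression matrix and were dropped.",
                   n_dropped_genes))
  }
  keep <- lengths(trimmed) >= min_set_size
  removed <- tibble(set = names(sets)[!keep],
                    n_measured = unname(lengths(trimmed)[!keep]))
  out <- trimmed[keep]
  desc <- attr(sets, "descriptions")
  if (!is.null(desc)) attr(out, "descriptions") <- desc[names(out)]
  attr(out, "removed") <- removed
  if (length(out) == 0) warn("No gene set passed the size filter; the collection is empty.")
  out
}

# ---------------------------------------------------------------------------
# Square covariance TSV (gene-id header) for audit dumps.

#' Write a covariance matrix as a square TSV with gene-id header
#'
#' @param V p-by-p covariance matrix with gene dimnames.
#' @param path Output path.
#' @export
write_covariance_tsv <- function(V, path) {
  V <- validate_covariance(V, require_pd = FALSE)
  ids <- colnames(V) %g% paste0("G", seq_len(ncol(V)))
  df <- data.frame(gene = ids, V, check.names = FALSE)
  colnames(df) <- c("gene", ids)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a covariance matrix written by [write_covariance_tsv()]
#'
#' @param path Path to the TSV.
#' @return p-by-p symmetric matrix with gene dimnames.
#' @export
read_covariance_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  V <- as.matrix(df[, -1, drop = FALSE])
  dimnames(V) <- list(ids, ids)
  validate_covariance(V, require_pd = FALSE)
}
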