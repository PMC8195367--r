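#' Gene x miRNA x cancer correlation tensor
#'
#' Constructs the labelled 3-way array at the heart of the method: frontal
#' slice k holds the gene-by-miRNA Pearson correlation matrix of cancer k.
#'
#' @param values Numeric p x q x M array.
#' @param gene_ids,mirna_ids,cancer_ids Axis labels (lengths p, q, M).
#' @param sample_counts Optional integer vector of per-cancer sample sizes.
#' @param built_from_data Logical; when `TRUE` entries are checked to lie in
#'   \[-1, 1\]. Residual tensors after deflation set this to `FALSE`.
#'
#' @return A `correlation_tensor` (3-D array with dimnames and attributes).
#' @export
correlation_tensor <- function(values, gene_ids = NULL, mirna_ids = NULL,
                               cancer_ids = NULL, sample_counts = NULL,
                               built_from_data = TRUE) {
  values <- as.array(values)
  if (length(dim(values)) != 3) abort("`values` must be a 3-way array")
  d <- dim(values)
  gene_ids <- as.character(gene_ids %||% dimnames(values)[[1]] %||% paste0("g", seq_len(d[1])))
  mirna_ids <- as.character(mirna_ids %||% dimnames(values)[[2]] %||% paste0("m", seq_len(d[2])))
  cancer_ids <- as.character(cancer_ids %||% dimnames(values)[[3]] %||% paste0("c", seq_len(d[3])))
  if (length(gene_ids) != d[1] || length(mirna_ids) != d[2] || length(cancer_ids) != d[3])
    abort("axis label lengths must match tensor dimensions")
  if (anyDuplicated(gene_ids) || anyDuplicated(mirna_ids) || anyDuplicated(cancer_ids))
    abort("axis labels must be unique")
  if (!all(is.finite(values))) abort("tensor entries must be finite")
  if (isTRUE(built_from_data) && (max(values) > 1 + 1e-8 || min(values) < -1 - 1e-8))
    abort("correlation entries outside [-1, 1]; use built_from_data = FALSE for raw tensors")
  dimnames(values) <- list(gene_ids, mirna_ids, cancer_ids)
  structure(values,
            sample_counts = sample_counts,
            built_from_data = isTRUE(built_from_data),
            class = c("correlation_tensor", "array"))
}

#' @export
print.correlation_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<correlation_tensor> %d genes x %d miRNAs x %d cancers%s\n",
              d[1], d[2], d[3],
              if (!isTRUE(attr(x, "built_from_data"))) " (residual/raw)" else ""))
  invisible(x)
}

# strip class/attrs for fast array math
tensor_values <- function(A) {
  a <- unclass(A)
  attr(a, "sample_counts") <- NULL
  attr(a, "built_from_data") <- NULL
  a
}

#' Build the correlation tensor from matched expression pairs
#'
#' For each cancer, computes the exact sample Pearson correlation matrix
#' between genes and miRNAs, `crossprod(X, Y) / (n - 1)` on standardized
#' columns, and stacks the per-cancer matrices into frontal slices. All
#' cancers must share one gene axis and one miRNA axis (same ids, same
#' order); mismatches are an error rather than a silent intersection (see
#' [align_expression_pairs()] for an explicit intersection helper).
#'
#' @param pairs A list of lists/tibble rows, each with elements `cancer_id`,
#'   `x` (samples x genes) and `y` (samples x miRNAs); `x`, `y` may be plain
#'   matrices or [expression_matrix()] objects.
#' @param scale_correlation If `TRUE` (default) slices are Pearson
#'   correlations; if `FALSE` the raw crossproduct convention
#'   `t(X) %*% Y` is kept.
#'
#' @return A [correlation_tensor()].
#' @export
build_correlation_tensor <- function(pairs, scale_correlation = TRUE) {
  if (length(pairs) < 1) abort("need at least one cancer pair")
  xs <- lapply(pairs, function(p) {
    x <- p$x
    if (!inherits(x, "expression_matrix")) x <- expression_matrix(x)
    x
  })
  ys <- lapply(pairs, function(p) {
    y <- p$y
    if (!inherits(y, "expression_matrix")) y <- expression_matrix(y)
    y
  })
  cancer_ids <- vapply(pairs, function(p) as.character(p$cancer_id), character(1))
  if (anyDuplicated(cancer_ids)) abort("duplicate cancer ids")
  genes <- colnames(xs[[1]]); mirnas <- colnames(ys[[1]])
  for (i in seq_along(pairs)) {
    if (!identical(colnames(xs[[i]]), genes)) {
      miss <- union(setdiff(genes, colnames(xs[[i]])), setdiff(colnames(xs[[i]]), genes))
      abort(paste0("gene axis mismatch in cancer '", cancer_ids[i],
                   "': ", paste(head(miss, 5), collapse = ", ")))
    }
    if (!identical(colnames(ys[[i]]), mirnas)) {
      miss <- union(setdiff(mirnas, colnames(ys[[i]])), setdiff(colnames(ys[[i]]), mirnas))
      abort(paste0("miRNA axis mismatch in cancer '", cancer_ids[i],
                   "': ", paste(head(miss, 5), collapse = ", ")))
    }
    if (nrow(xs[[i]]) != nrow(ys[[i]]))
      abort(paste0("sample count mismatch within cancer '", cancer_ids[i], "'"))
    if (nrow(xs[[i]]) < 3)
      abort(paste0("cancer '", cancer_ids[i], "' has fewer than 3 samples"))
  }
  p <- length(genes); q <- length(mirnas); M <- length(pairs)
  A <- array(0, dim = c(p, q, M))
  n_i <- integer(M)
  for (i in seq_len(M)) {
    x <- xs[[i]]; y <- ys[[i]]
    if (!is_standardized(x)) x <- standardize_columns(x)
    if (!is_standardized(y)) y <- standardize_columns(y)
    n_i[i] <- nrow(x)
    slab <- crossprod(unclass(x), unclass(y))
    if (scale_correlation) slab <- slab / (n_i[i] - 1)
    A[, , i] <- slab
  }
  if (scale_correlation) A <- pmin(pmax(A, -1), 1)  # guard fp drift at +/-1
  correlation_tensor(A, genes, mirnas, cancer_ids, sample_counts = n_i,
                     built_from_data = scale_correlation)
}

#' Align expression pairs onto shared gene/miRNA axes
#'
#' Convenience helper that restricts every cancer's matrices to the
#' intersection of gene ids and of miRNA ids across cancers, in a common
#' (sorted) order, so that [build_correlation_tensor()] accepts them.
#'
#' @param pairs As in [build_correlation_tensor()].
#' @return The pairs list with matrices subset to the shared axes.
#' @export
align_expression_pairs <- function(pairs) {
  genes <- Reduce(intersect, lapply(pairs, function(p) colnames(as.matrix(p$x))))
  mirnas <- Reduce(intersect, lapply(pairs, function(p) colnames(as.matrix(p$y))))
  if (length(genes) == 0 || length(mirnas) == 0)
    abort("empty gene or miRNA intersection across cancers")
  genes <- sort(genes); mirnas <- sort(mirnas)
  lapply(pairs, function(p) {
    x <- as.matrix(p$x); y <- as.matrix(p$y)
    list(cancer_id = p$cancer_id,
         x = expression_matrix(x[, genes, drop = FALSE]),
         y = expression_matrix(y[, mirnas, drop = FALSE]))
  })
}

#' Turn a correlation tensor into a long tibble
#'
#' @param x A [correlation_tensor()].
#' @param ... Unused.
#' @return A tibble with columns `gene`, `mirna`, `cancer`, `correlation`.
#' @method tidy correlation_tensor
#' @export
tidy.correlation_tensor <- function(x, ...) {
  d <- dim(x)
  tibble::tibble(
    gene = rep(dimnames(x)[[1]], times = d[2] * d[3]),
    mirna = rep(rep(dimnames(x)[[2]], each = d[1]), times = d[3]),
    cancer = rep(dimnames(x)[[3]], each = d[1] * d[2]),
    correlation = as.vector(tensor_values(x))
  )
}
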