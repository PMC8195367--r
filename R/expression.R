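#' Expression matrix container
#'
#' A thin wrapper around a numeric samples x features matrix carrying unique
#' sample and feature identifiers and a flag recording whether columns have
#' been standardized (mean 0, unit sample standard deviation).
#'
#' @param values Numeric matrix, samples in rows, features in columns.
#' @param sample_ids Character vector of unique row identifiers.
#' @param feature_ids Character vector of unique column identifiers.
#' @param standardized Logical; whether columns are already standardized.
#'
#' @return An `expression_matrix` object (a matrix with dimnames and a
#'   `standardized` attribute).
#' @export
expression_matrix <- function(values, sample_ids = rownames(values),
                              feature_ids = colnames(values),
                              standardized = FALSE) {
  values <- as.matrix(values)
  if (!is.numeric(values)) abort("`values` must be a numeric matrix.")
  sample_ids <- as.character(sample_ids %||% paste0("sample_", seq_len(nrow(values))))
  feature_ids <- as.character(feature_ids %||% paste0("feature_", seq_len(ncol(values))))
  if (length(sample_ids) != nrow(values))
    abort("row count does not match the number of sample ids")
  if (length(feature_ids) != ncol(values))
    abort("column count does not match the number of feature ids")
  if (anyDuplicated(sample_ids))
    abort(paste0("duplicate sample ids: ",
                 paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")))
  if (anyDuplicated(feature_ids))
    abort(paste0("duplicate feature ids: ",
                 paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", ")))
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(values, standardized = isTRUE(standardized),
            class = c("expression_matrix", "matrix", "array"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d samples x %d features%s\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "standardized"))) " (standardized)" else ""))
  invisible(x)
}

is_standardized <- function(x) isTRUE(attr(x, "standardized"))

#' Standardize expression columns
#'
#' Centers every column to mean zero and scales it to unit sample standard
#' deviation (denominator n - 1), the form the correlation-tensor algebra
#' assumes: for standardized X and Y, crossprod(X, Y) / (n - 1) is exactly the
#' matrix of Pearson correlations.
#'
#' @param x An [expression_matrix()] or plain numeric matrix (samples x
#'   features).
#'
#' @return An [expression_matrix()] with the `standardized` flag set.
#' @export
#'
#' @examples
#' e <- expression_matrix(matrix(rnorm(40), 10, 4,
#'                        dimnames = list(paste0("s", 1:10), paste0("g", 1:4))))
#' colMeans(standardize_columns(e))
standardize_columns <- function(x) {
  if (!inherits(x, "expression_matrix")) x <- expression_matrix(x)
  if (nrow(x) < 3) abort("standardization needs at least 3 samples")
  sds <- apply(x, 2, sd)
  if (any(sds == 0 | !is.finite(sds))) {
    bad <- colnames(x)[sds == 0 | !is.finite(sds)]
    abort(paste0("constant (zero-variance) feature(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  values <- scale(unclass(x), center = TRUE, scale = sds)
  attr(values, "scaled:center") <- NULL
  attr(values, "scaled:scale") <- NULL
  expression_matrix(values, rownames(x), colnames(x), standardized = TRUE)
}
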