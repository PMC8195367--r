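#' Module supports as index lists
#'
#' Converts a `tscca_module` (or explicit index sets) to the canonical
#' support triple used by the statistics layer.
#' @noRd
as_support <- function(module) {
  if (inherits(module, "tscca_module"))
    list(I = module$I, J = module$J, K = module$K)
  else if (is.list(module) && all(c("I", "J", "K") %in% names(module)))
    list(I = module$I, J = module$J, K = module$K)
  else abort("module must be a tscca_module or list(I =, J =, K =)")
}

#' Modularity of a tri-cluster
#'
#' The mean absolute correlation over the module's gene x miRNA x cancer
#' sub-tensor. For a tensor of true correlations this lies in \[0, 1\]; a
#' high score means the module's genes and miRNAs are strongly co-expressed
#' across its cancers.
#'
#' @param C A [correlation_tensor()] or 3-way array.
#' @param I,J,K Nonempty integer (or label) index sets for genes, miRNAs,
#'   cancers.
#' @return A scalar.
#' @export
modularity_score <- function(C, I, J, K) {
  a <- tensor_values(C)
  if (length(I) == 0 || length(J) == 0 || length(K) == 0)
    abort("index sets must be nonempty")
  mean(abs(a[I, J, K, drop = FALSE]))
}

#' Whole-slice baseline modularity
#'
#' Modularity with all genes, all miRNAs, and a single cancer: the
#' background co-expression level of that cancer.
#'
#' @param C A [correlation_tensor()].
#' @param cancer Cancer index or label.
#' @return A scalar.
#' @export
basic_modularity <- function(C, cancer) {
  a <- tensor_values(C)
  modularity_score(C, seq_len(dim(a)[1]), seq_len(dim(a)[2]), cancer)
}

#' Permutation test for module modularity
#'
#' Compares the module's modularity against size-matched random modules:
#' each null module samples |I| genes, |J| miRNAs and |K| cancers uniformly
#' without replacement from the full axes. The p-value uses the add-one
#' estimator (1 + #\{null >= observed\}) / (1 + n_perm).
#'
#' @param C A [correlation_tensor()].
#' @param module A `tscca_module` or `list(I =, J =, K =)` of integer
#'   indices.
#' @param n_perm Number of null draws.
#' @param seed Integer seed (required; permutation nulls must be
#'   reproducible).
#' @return A tibble row with `score`, `p_value`, `n_perm`, `seed`, plus the
#'   null scores in attribute `"null_scores"`.
#' @export
permutation_test_modularity <- function(C, module, n_perm = 1000, seed) {
  if (missing(seed)) abort("`seed` is required")
  if (n_perm < 1) abort("`n_perm` must be >= 1")
  s <- as_support(module)
  a <- tensor_values(C)
  d <- dim(a)
  if (length(s$I) > d[1] || length(s$J) > d[2] || length(s$K) > d[3])
    abort("module larger than a tensor axis")
  obs <- modularity_score(C, s$I, s$J, s$K)
  null_scores <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    mean(abs(a[sample.int(d[1], length(s$I)),
               sample.int(d[2], length(s$J)),
               sample.int(d[3], length(s$K)), drop = FALSE]))
  }, numeric(1)))
  p <- (1 + sum(null_scores >= obs)) / (1 + n_perm)
  out <- tibble::tibble(score = obs, p_value = p, n_perm = n_perm, seed = seed)
  attr(out, "null_scores") <- null_scores
  out
}

#' Co-expression modularity of a feature subset
#'
#' Mean absolute Pearson correlation over all unordered distinct pairs of
#' features in the subset (diagonal excluded) — the within-module gene-gene
#' or miRNA-miRNA cooperativity score.
#'
#' @param E An [expression_matrix()] (standardized) or numeric matrix.
#' @param features Indices or names of >= 2 columns.
#' @return A scalar in \[0, 1\].
#' @export
coexpression_modularity <- function(E, features) {
  E <- as.matrix(E)
  if (length(features) < 2) abort("need at least 2 features")
  R <- abs(cor(E[, features, drop = FALSE]))
  mean(R[upper.tri(R)])
}

#' Permutation test for co-expression modularity
#'
#' Null draws resample equally many features uniformly from all columns.
#'
#' @inheritParams coexpression_modularity
#' @inheritParams permutation_test_modularity
#' @return A tibble row as in [permutation_test_modularity()].
#' @export
permutation_test_coexpression <- function(E, features, n_perm = 1000, seed) {
  if (missing(seed)) abort("`seed` is required")
  E <- as.matrix(E)
  obs <- coexpression_modularity(E, features)
  m <- length(if (is.character(features)) match(features, colnames(E)) else features)
  null_scores <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    coexpression_modularity(E, sample.int(ncol(E), m))
  }, numeric(1)))
  p <- (1 + sum(null_scores >= obs)) / (1 + n_perm)
  out <- tibble::tibble(score = obs, p_value = p, n_perm = n_perm, seed = seed)
  attr(out, "null_scores") <- null_scores
  out
}

#' Overlap test between two modules
#'
#' Observed statistic: the pooled number of shared elements across the three
#' axes, |I_a ∩ I_b| + |J_a ∩ J_b| + |K_a ∩ K_b|. The null resamples both
#' modules' supports independently and uniformly with sizes fixed; the
#' p-value is the add-one right tail. Per-axis overlaps are reported too.
#'
#' @param module_a,module_b `tscca_module`s or `list(I =, J =, K =)`.
#' @param axis_sizes Integer vector `c(p, q, M)` of the shared universes.
#' @inheritParams permutation_test_modularity
#' @param alpha Significance threshold for the `significant` flag.
#' @return A tibble row with observed overlaps (pooled and per-axis),
#'   `p_value` and `significant`.
#' @export
module_overlap_test <- function(module_a, module_b, axis_sizes,
                                n_perm = 1000, seed, alpha = 0.05) {
  if (missing(seed)) abort("`seed` is required")
  a <- as_support(module_a); b <- as_support(module_b)
  sizes_ok <- function(s) length(s$I) <= axis_sizes[1] &&
    length(s$J) <= axis_sizes[2] && length(s$K) <= axis_sizes[3]
  if (!sizes_ok(a) || !sizes_ok(b)) abort("module exceeds axis universe")
  obs_axes <- c(genes = length(intersect(a$I, b$I)),
                mirnas = length(intersect(a$J, b$J)),
                cancers = length(intersect(a$K, b$K)))
  obs <- sum(obs_axes)
  na <- c(length(a$I), length(a$J), length(a$K))
  nb <- c(length(b$I), length(b$J), length(b$K))
  null_scores <- with_seed(seed, vapply(seq_len(n_perm), function(r) {
    sum(vapply(1:3, function(ax) {
      length(intersect(sample.int(axis_sizes[ax], na[ax]),
                       sample.int(axis_sizes[ax], nb[ax])))
    }, numeric(1)))
  }, numeric(1)))
  p <- (1 + sum(null_scores >= obs)) / (1 + n_perm)
  tibble::tibble(
    overlap = obs,
    overlap_genes = obs_axes[["genes"]],
    overlap_mirnas = obs_axes[["mirnas"]],
    overlap_cancers = obs_axes[["cancers"]],
    p_value = p, n_perm = n_perm, seed = seed,
    significant = p < alpha)
}

#' Modularity screen over a fitted module set
#'
#' Runs [permutation_test_modularity()] for every module of a fit against
#' the tensor it was fitted to, with a Bonferroni-style family threshold
#' (the family size defaults to the number of modules).
#'
#' @param fit A `tscca_fit`.
#' @param C The [correlation_tensor()] the fit was computed from.
#' @inheritParams permutation_test_modularity
#' @param alpha Family-wise level; each module is flagged significant when
#'   `p_value < alpha / family_size`.
#' @param family_size Bonferroni family size (default: number of modules).
#' @return A tibble with one row per module.
#' @export
modularity_screen <- function(fit, C, n_perm = 1000, seed, alpha = 0.05,
                              family_size = NULL) {
  if (missing(seed)) abort("`seed` is required")
  family_size <- family_size %||% max(1L, fit$r)
  rows <- purrr::imap(fit$modules, function(m, j) {
    res <- permutation_test_modularity(C, m, n_perm = n_perm, seed = seed + j)
    dplyr::mutate(res, module = j, singular_value = m$d, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out, significant = .data$p_value < alpha / family_size)
}

# run expr under a seed without clobbering the caller's RNG stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
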