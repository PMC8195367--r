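#' Tidy a fitted module set
#'
#' One row per nonzero factor weight: `module`, `axis` (gene/mirna/cancer),
#' `element_id`, `weight`.
#'
#' @param x A `tscca_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy tscca_fit
#' @export
tidy.tscca_fit <- function(x, ...) {
  if (length(x$modules) == 0)
    return(tibble::tibble(module_id = integer(0), axis = character(0),
                          element_id = character(0), weight = numeric(0)))
  rows <- purrr::imap(x$modules, function(m, j) {
    tibble::tibble(
      module_id = as.integer(j),
      axis = rep(c("gene", "mirna", "cancer"),
                 c(length(m$I), length(m$J), length(m$K))),
      element_id = c(m$gene_ids[m$I], m$mirna_ids[m$J], m$cancer_ids[m$K]),
      weight = c(m$u[m$I], m$v[m$J], m$w[m$K]))
  })
  dplyr::bind_rows(rows)
}

#' Per-module summary of a fit
#'
#' @param x A `tscca_fit`.
#' @param ... Unused.
#' @return A tibble: one row per module with its singular value, support
#'   sizes, iteration count and convergence flag.
#' @export
module_summary <- function(x, ...) {
  dplyr::mutate(glance_modules(x),
                iterations = vapply(x$modules, function(m) as.integer(m$iterations), integer(1)),
                converged = vapply(x$modules, function(m) isTRUE(m$converged), logical(1)))
}

#' One-row summary of a fit
#'
#' @param x A `tscca_fit`.
#' @param ... Unused.
#' @return A tibble row: module count, sparsity budgets, total singular
#'   value mass, residual Frobenius norm, and whether all modules converged.
#' @method glance tscca_fit
#' @export
glance.tscca_fit <- function(x, ...) {
  tibble::tibble(
    r = x$r,
    k_u = x$k[["k_u"]], k_v = x$k[["k_v"]], k_w = x$k[["k_w"]],
    total_d = sum(x$d),
    residual_fnorm = sqrt(sum(tensor_values(x$residual)^2)),
    converged = all(vapply(x$modules, function(m) isTRUE(m$converged), logical(1))))
}

#' Heatmap of the cancer-weight matrix W
#'
#' Rows are cancers, columns modules; tile fill is the signed cancer weight
#' of each module. The figure mirrors the standard presentation of which
#' cancers drive which modules.
#'
#' @param object A `tscca_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tscca_fit
#' @export
autoplot.tscca_fit <- function(object, ...) {
  W <- object$W
  df <- tibble::tibble(
    cancer = factor(rep(rownames(W), ncol(W)), levels = rev(rownames(W))),
    module = factor(rep(colnames(W), each = nrow(W)), levels = colnames(W)),
    weight = as.vector(W))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$module, y = .data$cancer,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B",
                                  midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "w") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Null-distribution plot for a permutation test
#'
#' Histogram of the permutation null scores with the observed statistic
#' marked.
#'
#' @param result A result of [permutation_test_modularity()],
#'   [permutation_test_coexpression()] or [degree_aware_edge_test()]
#'   (anything carrying a `null_scores` attribute and a `score`/`observed`
#'   column).
#' @return A ggplot object.
#' @export
plot_permutation_null <- function(result) {
  nulls <- attr(result, "null_scores")
  if (is.null(nulls)) abort("result carries no null_scores attribute")
  obs <- if ("score" %in% names(result)) result$score[1] else result$observed[1]
  ggplot2::ggplot(tibble::tibble(null = nulls), ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = obs, colour = "#B2182B", linewidth = 1) +
    ggplot2::labs(x = "null statistic", y = "count") +
    ggplot2::theme_minimal()
}
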