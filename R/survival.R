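#' Validate a survival table
#'
#' @param data Data frame with columns `sample_id`, `time` (days or any
#'   unit; the log-rank test is unit-invariant), `event` (1 = death
#'   observed, 0 = censored).
#' @return A validated tibble.
#' @export
survival_table <- function(data) {
  data <- tibble::as_tibble(data)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(data)))
    abort("survival table needs columns sample_id, time, event")
  data$sample_id <- as.character(data$sample_id)
  if (anyDuplicated(data$sample_id)) abort("duplicate sample ids in survival table")
  if (any(!is.finite(data$time)) || any(data$time < 0))
    abort("survival times must be finite and nonnegative")
  if (!all(data$event %in% c(0, 1))) abort("event must be 0 (censored) or 1 (death)")
  data[need]
}

#' First-principal-component sample scores
#'
#' Projects samples onto the leading eigenvector of the feature covariance
#' of a module's joint gene + miRNA expression sub-matrix. The loading
#' vector's sign is fixed so its largest-magnitude entry is positive (the
#' downstream median split is sign-invariant).
#'
#' @param E Numeric samples x features matrix (>= 2 features, >= 3 samples),
#'   columns standardized.
#' @return Named numeric vector of per-sample scores.
#' @export
module_pc1 <- function(E) {
  E <- as.matrix(E)
  if (ncol(E) < 2) abort("need at least 2 features")
  if (nrow(E) < 3) abort("need at least 3 samples")
  pc <- prcomp(E, center = TRUE, scale. = FALSE)
  if (pc$sdev[1] <= 0) abort("rank-0 input: no variation to summarize")
  load1 <- pc$rotation[, 1]
  if (load1[which.max(abs(load1))] < 0) load1 <- -load1
  scores <- drop(scale(E, center = TRUE, scale = FALSE) %*% load1)
  names(scores) <- rownames(E)
  scores
}

#' Median-split log-rank test
#'
#' Splits samples at the median of a prognostic score (ties at the median go
#' to the low group), then compares the two groups' survival with the
#' standard two-group log-rank test (chi-square with 1 df).
#'
#' @param scores Named numeric vector (names = sample ids).
#' @param surv A [survival_table()]. Samples missing from either side are
#'   dropped (count reported in the result).
#' @return A tibble row: `statistic`, `p_value`, `n_low`, `n_high`,
#'   `n_dropped`.
#' @export
median_split_logrank <- function(scores, surv) {
  surv <- survival_table(surv)
  ids <- intersect(names(scores), surv$sample_id)
  n_dropped <- (length(scores) - length(ids)) + (nrow(surv) - length(ids))
  if (length(ids) < 4) abort("fewer than 4 matched samples")
  s <- scores[ids]
  surv <- surv[match(ids, surv$sample_id), ]
  grp <- ifelse(s <= median(s), "low", "high")
  if (length(unique(grp)) < 2) abort("median split produced an empty group")
  if (sum(surv$event) == 0) abort("no events observed; log-rank test undefined")
  sd_fit <- survival::survdiff(survival::Surv(surv$time, surv$event) ~ grp)
  stat <- sd_fit$chisq
  tibble::tibble(statistic = stat,
                 p_value = pchisq(stat, df = 1, lower.tail = FALSE),
                 n_low = sum(grp == "low"), n_high = sum(grp == "high"),
                 n_dropped = n_dropped)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate correction, order-preserving,
#' monotone, capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Prognostic screen of modules across cancers
#'
#' For every (module, cancer-in-module-support) pair, computes a prognostic
#' score per sample — the joint gene + miRNA PC1 at `level = "module"`, or
#' each single miRNA's expression at `level = "mirna"` — median-splits,
#' log-rank tests, and BH-adjusts all p-values as one family. The
#' significant pairs (adjusted p < `alpha`) form the module-cancer bipartite
#' edge list.
#'
#' @param fit A `tscca_fit`.
#' @param expression Named list: cancer id -> `list(x = genes matrix,
#'   y = miRNAs matrix)` (samples x features, sample ids as rownames).
#' @param clinical Named list: cancer id -> [survival_table()].
#' @param level `"module"` or `"mirna"`.
#' @param alpha Threshold on adjusted p for the `significant` flag.
#' @param all_cancers If `TRUE`, test every cancer with data rather than
#'   only those in each module's support.
#' @return A tibble ordered by (module, cancer): `module`, `cancer`,
#'   (`mirna` at miRNA level), `statistic`, `p_value`, `adjusted_p`,
#'   `n_low`, `n_high`, `significant`.
#' @export
survival_screen <- function(fit, expression, clinical,
                            level = c("module", "mirna"), alpha = 0.05,
                            all_cancers = FALSE) {
  level <- match.arg(level)
  rows <- list()
  for (j in seq_len(fit$r)) {
    m <- fit$modules[[j]]
    cancers <- if (all_cancers) names(expression) else m$cancer_ids[m$K]
    for (ca in sort(cancers)) {
      if (is.null(expression[[ca]]) || is.null(clinical[[ca]])) {
        warn(sprintf("no expression/clinical data for cancer '%s'; pair skipped", ca))
        next
      }
      x <- as.matrix(expression[[ca]]$x); y <- as.matrix(expression[[ca]]$y)
      genes <- intersect(m$gene_ids[m$I], colnames(x))
      mirnas <- intersect(m$mirna_ids[m$J], colnames(y))
      if (level == "module") {
        E <- cbind(x[, genes, drop = FALSE], y[, mirnas, drop = FALSE])
        if (ncol(E) < 2) next
        res <- tryCatch(median_split_logrank(module_pc1(E), clinical[[ca]]),
                        error = function(e) NULL)
        if (!is.null(res))
          rows[[length(rows) + 1]] <- dplyr::mutate(res, module = j, cancer = ca,
                                                    .before = 1)
      } else {
        for (mi in sort(mirnas)) {
          sc <- setNames(y[, mi], rownames(y))
          res <- tryCatch(median_split_logrank(sc, clinical[[ca]]),
                          error = function(e) NULL)
          if (!is.null(res))
            rows[[length(rows) + 1]] <- dplyr::mutate(res, module = j, cancer = ca,
                                                      mirna = mi, .before = 1)
        }
      }
    }
  }
  if (length(rows) == 0)
    return(tibble::tibble(module = integer(0), cancer = character(0),
                          statistic = numeric(0), p_value = numeric(0),
                          adjusted_p = numeric(0), significant = logical(0)))
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, .data$module, .data$cancer)
  out$adjusted_p <- bh_adjust(out$p_value)
  out$significant <- out$adjusted_p < alpha
  out
}

#' Significant module-cancer bipartite edges
#'
#' @param screen A [survival_screen()] result.
#' @return Tibble `module`, `cancer`, `adjusted_p` for significant pairs.
#' @export
survival_edges <- function(screen) {
  dplyr::select(dplyr::filter(screen, .data$significant),
                "module", "cancer", "adjusted_p")
}
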