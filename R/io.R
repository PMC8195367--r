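read_tsv_strict <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) abort(paste0("empty file: ", path))
  strsplit(lines, "\t", fixed = TRUE)
}

#' Read an expression matrix from TSV
#'
#' Expects a header line; the first column holds feature ids (genomics
#' convention, `orientation = "features_as_rows"`, the default) or sample
#' ids (`"samples_as_rows"`). The result is always in canonical samples x
#' features orientation. Parsing is strict: any non-numeric cell is an
#' error naming its row and column, ragged rows and duplicate ids are
#' errors, and nothing is imputed.
#'
#' @param path TSV file path.
#' @param orientation `"features_as_rows"` or `"samples_as_rows"`.
#' @return An [expression_matrix()] (not standardized).
#' @export
read_expression_tsv <- function(path,
                                orientation = c("features_as_rows", "samples_as_rows")) {
  orientation <- match.arg(orientation)
  rows <- read_tsv_strict(path)
  header <- rows[[1]]
  ncol_expected <- length(header)
  col_ids <- header[-1]
  body <- rows[-1]
  if (length(body) == 0) abort("no data rows")
  row_ids <- character(length(body))
  values <- matrix(NA_real_, length(body), ncol_expected - 1)
  for (i in seq_along(body)) {
    r <- body[[i]]
    if (length(r) != ncol_expected)
      abort(sprintf("ragged row %d: expected %d fields, found %d",
                    i + 1, ncol_expected, length(r)))
    row_ids[i] <- r[1]
    num <- suppressWarnings(as.numeric(r[-1]))
    bad <- which(is.na(num))
    if (length(bad) > 0)
      abort(sprintf("non-numeric cell at row %d, column %d ('%s')",
                    i + 1, bad[1] + 1, r[bad[1] + 1]))
    values[i, ] <- num
  }
  if (anyDuplicated(row_ids)) abort("duplicate row ids")
  if (anyDuplicated(col_ids)) abort("duplicate column ids")
  if (orientation == "features_as_rows") {
    expression_matrix(t(values), sample_ids = col_ids, feature_ids = row_ids)
  } else {
    expression_matrix(values, sample_ids = row_ids, feature_ids = col_ids)
  }
}

#' Write an expression matrix to TSV
#'
#' @param x An [expression_matrix()] or numeric matrix (samples x features).
#' @param path Destination.
#' @param orientation Layout to write (default features as rows).
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path,
                                 orientation = c("features_as_rows", "samples_as_rows")) {
  orientation <- match.arg(orientation)
  x <- as.matrix(x)
  vals <- if (orientation == "features_as_rows") t(x) else x
  df <- data.frame(id = rownames(vals), format(vals, digits = 17, trim = TRUE,
                                               scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- if (orientation == "features_as_rows") "feature_id" else "sample_id"
  names(df)[-1] <- colnames(vals)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read an edge list
#'
#' Two-column TSV, one edge per line; lines starting with `#` are comments.
#' Duplicate edges collapse; for undirected lists (a, b) and (b, a) collapse
#' to one unordered pair.
#'
#' @param path TSV file path.
#' @param directed Logical.
#' @return A list: `edges` (tibble from, to), `n_edges`, `nodes`.
#' @export
read_edge_list <- function(path, directed = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad) > 0)
    abort(sprintf("edge line %d does not have exactly 2 fields", bad[1]))
  from <- trimws(vapply(parts, `[`, character(1), 1))
  to <- trimws(vapply(parts, `[`, character(1), 2))
  if (any(!nzchar(from)) || any(!nzchar(to))) abort("empty edge endpoint")
  if (!directed) {
    a <- pmin(from, to); b <- pmax(from, to)
    from <- a; to <- b
  }
  keep <- !duplicated(paste(from, to, sep = "\r"))
  edges <- tibble::tibble(from = from[keep], to = to[keep])
  list(edges = edges, n_edges = nrow(edges),
       nodes = sort(unique(c(edges$from, edges$to))))
}

#' Write an edge list to TSV
#' @param edges Tibble/data frame with columns from, to.
#' @param path Destination.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  readr::write_tsv(tibble::as_tibble(edges)[, c("from", "to")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Read a gene or miRNA set
#'
#' Accepts one-id-per-line text or GMT (set name, description, then
#' members); GMT files may carry several sets, returned as a named list.
#'
#' @param path File path.
#' @param format `"auto"` (GMT when any line has >= 3 tab-separated
#'   fields), `"list"`, or `"gmt"`.
#' @return Character vector (list format) or named list of character
#'   vectors (GMT).
#' @export
read_gene_set <- function(path, format = c("auto", "list", "gmt")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "auto")
    format <- if (any(lengths(parts) >= 3)) "gmt" else "list"
  if (format == "list") {
    unique(trimws(unlist(parts)))
  } else {
    sets <- lapply(parts, function(r) unique(trimws(r[-(1:2)])))
    names(sets) <- vapply(parts, `[`, character(1), 1)
    sets
  }
}

#' Read a miRNA family table
#'
#' Two-column TSV (family_id, member miRNA), one membership per line.
#'
#' @param path TSV file path.
#' @return Named list: family id -> character vector of member miRNAs.
#' @export
read_family_table <- function(path) {
  parts <- strsplit(readLines(path, warn = FALSE), "\t", fixed = TRUE)
  parts <- parts[lengths(parts) > 0]
  bad <- which(lengths(parts) != 2)
  if (length(bad) > 0)
    abort(sprintf("family line %d does not have exactly 2 fields", bad[1]))
  fam <- trimws(vapply(parts, `[`, character(1), 1))
  mem <- trimws(vapply(parts, `[`, character(1), 2))
  lapply(split(mem, fam), unique)
}

#' Read a clinical survival table
#'
#' Three-column TSV with header: sample id, time (nonnegative), event
#' (0 = censored, 1 = death observed).
#'
#' @param path TSV file path.
#' @return A validated [survival_table()] tibble.
#' @export
read_survival_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), readr::col_double(), readr::col_double()),
    progress = FALSE)
  names(df) <- c("sample_id", "time", "event")
  survival_table(df)
}

#' Write module tables
#'
#' Emits two TSVs: `<prefix>_summary.tsv` (module_id, singular_value,
#' n_genes, n_mirnas, n_cancers) and `<prefix>_members.tsv` (long format:
#' module_id, axis, element_id, weight; nonzero weights only). The pair
#' round-trips through [read_module_tables()] at 1e-12.
#'
#' @param fit A `tscca_fit`.
#' @param prefix Output path prefix.
#' @return The two file paths, invisibly.
#' @export
write_module_tables <- function(fit, prefix) {
  summary_path <- paste0(prefix, "_summary.tsv")
  members_path <- paste0(prefix, "_members.tsv")
  readr::write_tsv(glance_modules(fit), summary_path)
  long <- tidy(fit)
  long$weight <- format(long$weight, digits = 17, trim = TRUE, scientific = TRUE)
  readr::write_tsv(long, members_path)
  invisible(c(summary = summary_path, members = members_path))
}

glance_modules <- function(fit) {
  tibble::tibble(
    module_id = seq_len(fit$r),
    singular_value = fit$d,
    n_genes = vapply(fit$modules, function(m) length(m$I), integer(1)),
    n_mirnas = vapply(fit$modules, function(m) length(m$J), integer(1)),
    n_cancers = vapply(fit$modules, function(m) length(m$K), integer(1)))
}

#' Read module tables back
#'
#' Restores factors and supports (not residual/iteration metadata) from a
#' [write_module_tables()] pair.
#'
#' @param prefix Path prefix used at write time.
#' @param dims `c(p, q, M)` tensor dimensions.
#' @param gene_ids,mirna_ids,cancer_ids Axis labels.
#' @return A `tscca_fit`-like list with `modules`, `d`, `W`, `r`.
#' @export
read_module_tables <- function(prefix, dims, gene_ids, mirna_ids, cancer_ids) {
  summary_path <- paste0(prefix, "_summary.tsv")
  members_path <- paste0(prefix, "_members.tsv")
  smry <- readr::read_tsv(summary_path, col_types = "idiii", progress = FALSE)
  long <- readr::read_tsv(members_path, col_types = "iccd", progress = FALSE)
  modules <- lapply(seq_len(nrow(smry)), function(j) {
    mj <- long[long$module_id == smry$module_id[j], ]
    u <- numeric(dims[1]); v <- numeric(dims[2]); w <- numeric(dims[3])
    gi <- mj[mj$axis == "gene", ]; mi <- mj[mj$axis == "mirna", ]
    ci <- mj[mj$axis == "cancer", ]
    u[match(gi$element_id, gene_ids)] <- gi$weight
    v[match(mi$element_id, mirna_ids)] <- mi$weight
    w[match(ci$element_id, cancer_ids)] <- ci$weight
    structure(list(u = u, v = v, w = w, d = smry$singular_value[j],
                   I = which(u != 0), J = which(v != 0), K = which(w != 0),
                   iterations = NA_integer_, converged = NA,
                   gene_ids = gene_ids, mirna_ids = mirna_ids,
                   cancer_ids = cancer_ids), class = "tscca_module")
  })
  W <- vapply(modules, function(m) m$w, numeric(dims[3]))
  W <- matrix(W, nrow = dims[3], dimnames = list(cancer_ids, NULL))
  list(modules = modules, d = smry$singular_value, W = W, r = nrow(smry))
}

#' Write a correlation tensor to a long-format TSV container
#'
#' A plain-text, language-portable representation: one row per tensor cell
#' (gene, mirna, cancer, correlation), full double precision. Round-trips
#' at 1e-12 (in practice exactly).
#'
#' @param tensor A [correlation_tensor()].
#' @param path Destination.
#' @return `path`, invisibly.
#' @export
write_tensor_tsv <- function(tensor, path) {
  long <- tidy.correlation_tensor(tensor)
  long$correlation <- format(long$correlation, digits = 17, trim = TRUE,
                             scientific = TRUE)
  writeLines(sprintf("# correlation_tensor %d %d %d built_from_data=%d",
                     dim(tensor)[1], dim(tensor)[2], dim(tensor)[3],
                     as.integer(isTRUE(attr(tensor, "built_from_data")))), path)
  readr::write_tsv(long, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a correlation tensor from its TSV container
#'
#' @param path File written by [write_tensor_tsv()].
#' @return A [correlation_tensor()].
#' @export
read_tensor_tsv <- function(path) {
  header <- readLines(path, n = 1)
  if (!grepl("^# correlation_tensor ", header)) abort("not a tensor container file")
  meta <- strsplit(sub("^# correlation_tensor ", "", header), " ")[[1]]
  d <- as.integer(meta[1:3])
  bfd <- grepl("built_from_data=1", header)
  long <- readr::read_tsv(path, skip = 1, col_types = "cccd", progress = FALSE)
  genes <- unique(long$gene); mirnas <- unique(long$mirna)
  cancers <- unique(long$cancer)
  if (length(genes) != d[1] || length(mirnas) != d[2] || length(cancers) != d[3] ||
      nrow(long) != prod(d))
    abort("tensor container is inconsistent with its header")
  a <- array(long$correlation, dim = d)
  correlation_tensor(a, genes, mirnas, cancers, built_from_data = bfd)
}
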