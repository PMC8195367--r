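#' Right-tailed hypergeometric set enrichment
#'
#' Over-representation of an annotation inside a member set: the p-value is
#' P(X >= overlap) drawing |member_set| elements without replacement from a
#' background in which |annotation ∩ background| are annotated. Fold
#' enrichment is the density ratio (overlap / set size) over
#' (annotated / background).
#'
#' @param member_set Character vector (e.g. a module's genes); must lie
#'   inside `background`.
#' @param annotation_set Character vector (e.g. known cancer genes);
#'   restricted to `background` before testing.
#' @param background Character vector, the analysis universe.
#' @return A tibble row with `overlap`, `set_size`,
#'   `annotated_in_background`, `background_size`, `fold_enrichment`,
#'   `p_value`.
#' @export
hypergeometric_enrichment <- function(member_set, annotation_set, background) {
  member_set <- unique(as.character(member_set))
  background <- unique(as.character(background))
  out_of_bg <- setdiff(member_set, background)
  if (length(out_of_bg) > 0)
    abort(paste0("member(s) not in background: ",
                 paste(head(out_of_bg, 5), collapse = ", ")))
  ann <- intersect(unique(as.character(annotation_set)), background)
  x <- length(intersect(member_set, ann))
  m <- length(ann); n <- length(background) - m; k <- length(member_set)
  p <- phyper(x - 1, m, n, k, lower.tail = FALSE)
  fold <- if (k > 0 && m > 0)
    (x / k) / (m / length(background)) else NA_real_
  tibble::tibble(overlap = x, set_size = k, annotated_in_background = m,
                 background_size = length(background),
                 fold_enrichment = fold, p_value = p)
}

count_edges_within <- function(nodes, edges_a, edges_b) {
  sum(edges_a %in% nodes & edges_b %in% nodes)
}

#' Edge-density enrichment of a node set
#'
#' Tests whether a node set spans more edges than expected by chance under a
#' hypergeometric model on edge slots. `gene_gene` mode: slots are unordered
#' node pairs within the set vs within the background. `mirna_gene` mode:
#' slots are (miRNA, gene) ordered pairs; supply `node_set`/`background` as
#' lists with elements `mirnas` and `genes`.
#'
#' @param node_set Character vector (gene_gene) or
#'   `list(mirnas =, genes =)` (mirna_gene).
#' @param edges Two-column matrix or data frame of edges over the
#'   background.
#' @param background Same shape as `node_set`, the universe.
#' @param mode `"gene_gene"` or `"mirna_gene"`.
#' @param null `"hypergeometric"` (default; edge slots drawn without
#'   replacement, the classical over-representation model) or `"exact"`
#'   (gene_gene only: exhaustive enumeration of all same-size node sets,
#'   the exact random-module null; feasible only for small backgrounds).
#' @return A tibble row as in [hypergeometric_enrichment()] where `overlap`
#'   counts edges inside the set and `fold_enrichment` is the density ratio.
#' @export
edge_enrichment <- function(node_set, edges, background,
                            mode = c("gene_gene", "mirna_gene"),
                            null = c("hypergeometric", "exact")) {
  mode <- match.arg(mode)
  null <- match.arg(null)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2) abort("`edges` must have two columns")
  e1 <- as.character(edges[[1]]); e2 <- as.character(edges[[2]])
  if (mode == "gene_gene") {
    node_set <- unique(as.character(node_set))
    background <- unique(as.character(background))
    if (length(setdiff(node_set, background)) > 0)
      abort("node set not contained in background")
    if (length(setdiff(c(e1, e2), background)) > 0)
      abort("edge endpoint(s) outside background")
    x <- count_edges_within(node_set, e1, e2)
    m <- length(e1)                                  # edges in background
    pop <- choose(length(background), 2)             # pair slots
    draws <- choose(length(node_set), 2)
  } else {
    if (!is.list(node_set) || !all(c("mirnas", "genes") %in% names(node_set)))
      abort("mirna_gene mode needs node_set = list(mirnas =, genes =)")
    bm <- unique(as.character(background$mirnas))
    bg <- unique(as.character(background$genes))
    sm <- unique(as.character(node_set$mirnas))
    sg <- unique(as.character(node_set$genes))
    if (length(setdiff(sm, bm)) > 0 || length(setdiff(sg, bg)) > 0)
      abort("node set not contained in background")
    if (length(setdiff(e1, bm)) > 0 || length(setdiff(e2, bg)) > 0)
      abort("edge endpoint(s) outside background")
    x <- sum(e1 %in% sm & e2 %in% sg)
    m <- length(e1)
    pop <- length(bm) * length(bg)
    draws <- length(sm) * length(sg)
  }
  if (null == "exact") {
    if (mode != "gene_gene") abort("exact null is implemented for gene_gene mode only")
    if (choose(length(background), length(node_set)) > 5e5)
      abort("background too large for exact enumeration")
    sets <- utils::combn(background, length(node_set))
    counts <- apply(sets, 2, count_edges_within, edges_a = e1, edges_b = e2)
    p <- mean(counts >= x)
  } else {
    p <- phyper(x - 1, m, pop - m, draws, lower.tail = FALSE)
  }
  fold <- if (draws > 0 && m > 0) (x / draws) / (m / pop) else NA_real_
  tibble::tibble(overlap = x, set_size = draws, annotated_in_background = m,
                 background_size = pop, fold_enrichment = fold, p_value = p)
}

#' Degree-aware permutation test for edge enrichment
#'
#' Replaces the hypergeometric null — which ignores that hub nodes collect
#' edges — by resampling: each member of the node set is swapped for a
#' uniformly chosen background node from the same degree bin, without
#' replacement within each bin (degree bins are log-spaced over the
#' background degree distribution; bins too thin to supply a draw are
#' widened downward with a warning). The statistic is the within-set edge
#' count; the p-value is the add-one right tail over `n_perm` draws.
#'
#' @param node_set,edges,background As in [edge_enrichment()] gene_gene
#'   mode.
#' @param n_perm Number of null draws.
#' @param seed Integer seed.
#' @param bins Number of logarithmic degree bins.
#' @return A tibble row with `observed` (edge count), `p_value`, `n_perm`,
#'   `seed`, plus null counts in attribute `"null_scores"`.
#' @export
degree_aware_edge_test <- function(node_set, edges, background,
                                   n_perm = 1000, seed, bins = 10) {
  if (missing(seed)) abort("`seed` is required")
  node_set <- unique(as.character(node_set))
  background <- unique(as.character(background))
  if (length(setdiff(node_set, background)) > 0)
    abort("node set not contained in background")
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  e1 <- as.character(edges[[1]]); e2 <- as.character(edges[[2]])
  deg <- table(factor(c(e1, e2), levels = background))
  deg <- as.numeric(deg)
  names(deg) <- background

  # log-spaced breaks over positive degrees; degree-0 nodes form their own bin
  pos <- deg[deg > 0]
  if (length(pos) == 0) {
    bin_of <- setNames(rep(1L, length(background)), background)
  } else {
    lo <- log(min(pos)); hi <- log(max(pos) + 1)
    brk <- unique(c(-Inf, exp(seq(lo, hi, length.out = bins + 1))))
    bin_of <- setNames(as.integer(cut(deg, breaks = brk, include.lowest = TRUE)),
                       background)
  }
  obs <- count_edges_within(node_set, e1, e2)
  # per-bin member counts; a bin with fewer candidates than members is
  # widened downward until it can supply the draw (with a warning)
  set_bins <- bin_of[node_set]
  need <- table(set_bins)
  pools <- lapply(names(need), function(b) {
    b0 <- as.integer(b)
    pool <- background[bin_of == b0]
    lo <- b0
    while (length(pool) < need[[b]] && lo > 1) {
      lo <- lo - 1
      pool <- background[bin_of >= lo & bin_of <= b0]
    }
    if (length(pool) < need[[b]]) pool <- background
    if (lo < as.integer(b))
      warn(sprintf("degree bin %s too thin; widened to bins %d-%s", b, lo, b))
    pool
  })
  counts <- as.integer(need)
  null_scores <- with_seed(seed, vapply(seq_len(n_perm), function(r) {
    drawn <- unlist(lapply(seq_along(pools), function(i)
      pools[[i]][sample.int(length(pools[[i]]), counts[i])]))
    count_edges_within(drawn, e1, e2)
  }, numeric(1)))
  p <- (1 + sum(null_scores >= obs)) / (1 + n_perm)
  out <- tibble::tibble(observed = obs, p_value = p, n_perm = n_perm, seed = seed,
                        bins = bins)
  attr(out, "null_scores") <- null_scores
  out
}

#' miRNA family cooperativity test
#'
#' Statistic: the maximum number of module miRNAs falling in one family
#' (with the binary "at least two in a family" indicator). The null
#' resamples equally many miRNAs uniformly from the universe; the p-value is
#' the add-one right tail on the statistic.
#'
#' @param mirnas Character vector, the module's miRNAs.
#' @param families Named list: family id -> character vector of members.
#' @param universe Character vector of all candidate miRNAs.
#' @param n_perm Number of null draws.
#' @param seed Integer seed.
#' @return A tibble row with `max_in_family`, `cooperative` (statistic >= 2),
#'   `top_family`, `p_value`, `n_perm`, `seed`.
#' @export
family_cooperativity <- function(mirnas, families, universe, n_perm = 1000, seed) {
  if (missing(seed)) abort("`seed` is required")
  mirnas <- unique(as.character(mirnas))
  universe <- unique(as.character(universe))
  if (length(mirnas) > length(universe)) abort("universe smaller than module")
  stat <- function(set) {
    if (length(families) == 0) return(c(1, NA_integer_))
    counts <- vapply(families, function(f) length(intersect(set, f)), numeric(1))
    counts <- pmax(counts, as.numeric(length(set) > 0))  # floor at 1 for nonempty set
    c(unname(max(counts)), unname(which.max(counts)))
  }
  ob <- stat(mirnas)
  null_scores <- with_seed(seed, vapply(seq_len(n_perm), function(r) {
    stat(universe[sample.int(length(universe), length(mirnas))])[1]
  }, numeric(1)))
  p <- (1 + sum(null_scores >= ob[1])) / (1 + n_perm)
  out <- tibble::tibble(
    max_in_family = ob[1],
    cooperative = ob[1] >= 2,
    top_family = if (!is.na(ob[2]) && length(families) > 0) names(families)[ob[2]] else NA_character_,
    p_value = p, n_perm = n_perm, seed = seed)
  attr(out, "null_scores") <- null_scores
  out
}

#' Three-layer miRNA-gene regulatory subnetwork
#'
#' Builds the mixed graph on a module's miRNAs and genes — directed
#' miRNA -> gene edges plus undirected gene-gene edges, both restricted to
#' module members — and returns its largest connected component (undirected
#' connectivity; ties broken by size then by lexicographically smallest node
#' label). Component genes split into the direct layer (targeted by at least
#' one component miRNA) and the indirect layer (reached only through other
#' genes).
#'
#' @param genes,mirnas Character vectors, the module's members.
#' @param mirna_gene_edges Two-column (miRNA, gene) data frame/matrix.
#' @param gene_gene_edges Two-column (gene, gene) data frame/matrix.
#' @return A list of class `three_layer_network`: `mirnas`, `direct_genes`,
#'   `indirect_genes`, `edges` (tibble: from, to, type), and `counts`.
#' @export
extract_three_layer_network <- function(genes, mirnas, mirna_gene_edges,
                                        gene_gene_edges) {
  genes <- unique(as.character(genes))
  mirnas <- unique(as.character(mirnas))
  mg <- as.data.frame(mirna_gene_edges, stringsAsFactors = FALSE)
  gg <- as.data.frame(gene_gene_edges, stringsAsFactors = FALSE)
  mg <- mg[as.character(mg[[1]]) %in% mirnas & as.character(mg[[2]]) %in% genes, , drop = FALSE]
  gg <- gg[as.character(gg[[1]]) %in% genes & as.character(gg[[2]]) %in% genes &
             as.character(gg[[1]]) != as.character(gg[[2]]), , drop = FALSE]
  edges <- tibble::tibble(
    from = c(as.character(mg[[1]]), as.character(gg[[1]])),
    to = c(as.character(mg[[2]]), as.character(gg[[2]])),
    type = rep(c("mirna_gene", "gene_gene"), c(nrow(mg), nrow(gg))))
  # collapse duplicate edges (gene-gene treated as unordered)
  key <- ifelse(edges$type == "gene_gene",
                paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to), "gg"),
                paste(edges$from, edges$to, "mg"))
  edges <- edges[!duplicated(key), , drop = FALSE]

  empty <- function() structure(list(
    mirnas = character(0), direct_genes = character(0),
    indirect_genes = character(0), edges = edges[0, ],
    counts = c(mirnas = 0L, direct_genes = 0L, indirect_genes = 0L, edges = 0L)),
    class = "three_layer_network")
  if (nrow(edges) == 0) return(empty())

  g <- igraph::graph_from_data_frame(edges[, c("from", "to")], directed = FALSE)
  comp <- igraph::components(g)
  sizes <- comp$csize
  best_size <- max(sizes)
  cand <- which(sizes == best_size)
  if (length(cand) > 1) {
    # tie: smallest lexicographic node label within the component
    min_label <- vapply(cand, function(ci)
      min(names(comp$membership)[comp$membership == ci]), character(1))
    cand <- cand[order(min_label)][1]
  }
  nodes <- names(comp$membership)[comp$membership == cand[1]]
  keep <- edges$from %in% nodes & edges$to %in% nodes
  edges <- edges[keep, , drop = FALSE]
  comp_mirnas <- intersect(nodes, mirnas)
  comp_genes <- intersect(nodes, genes)
  direct <- unique(edges$to[edges$type == "mirna_gene"])
  direct_genes <- intersect(comp_genes, direct)
  indirect_genes <- setdiff(comp_genes, direct_genes)
  structure(list(
    mirnas = sort(comp_mirnas),
    direct_genes = sort(direct_genes),
    indirect_genes = sort(indirect_genes),
    edges = edges,
    counts = c(mirnas = length(comp_mirnas),
               direct_genes = length(direct_genes),
               indirect_genes = length(indirect_genes),
               edges = nrow(edges))),
    class = "three_layer_network")
}

#' @export
print.three_layer_network <- function(x, ...) {
  cat(sprintf("<three_layer_network> %d miRNAs -> %d direct genes -> %d indirect genes (%d edges)\n",
              x$counts["mirnas"], x$counts["direct_genes"],
              x$counts["indirect_genes"], x$counts["edges"]))
  invisible(x)
}
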