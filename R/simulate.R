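#' Simulation configuration
#'
#' Describes a planted-module correlation tensor. The default is the
#' benchmark design used throughout the package's tests: a 300 x 30 x 4
#' tensor with three 100-gene x 10-miRNA modules, each co-expressed in two
#' of the four slices with opposite signs (block means +/- 0.5, sd 0.2),
#' background noise N(0, 0.2^2), and a fourth slice of pure noise.
#'
#' @param p,q,M Numbers of genes, miRNAs, cancers.
#' @param blocks List of planted blocks, each
#'   `list(genes =, mirnas =, cancer =, mean =, sd =)` with `genes`/`mirnas`
#'   integer index ranges and a single `cancer` slice index. Several blocks
#'   with the same (genes, mirnas) ranges in different slices form one
#'   planted module.
#' @param noise_sd Background standard deviation.
#' @param seed Integer seed.
#' @param shuffle If `TRUE`, gene and miRNA orders are randomly permuted
#'   (consistently across slices; the truth tracks the permutation).
#' @param clip If `TRUE`, entries are clipped to \[-1, 1\]; default `FALSE`
#'   keeps the raw normal draws.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(p = 300, q = 30, M = 4,
                              blocks = default_blocks(),
                              noise_sd = 0.2, seed, shuffle = FALSE,
                              clip = FALSE) {
  if (missing(seed)) abort("`seed` is required")
  for (b in blocks) {
    if (max(b$genes) > p || max(b$mirnas) > q || b$cancer > M ||
        min(b$genes) < 1 || min(b$mirnas) < 1 || b$cancer < 1)
      abort("block ranges must lie within the tensor dimensions")
    if (b$sd < 0) abort("block sd must be nonnegative")
  }
  # overlapping blocks on one slice would overwrite each other
  for (k in seq_len(M)) {
    bs <- Filter(function(b) b$cancer == k, blocks)
    if (length(bs) > 1) {
      for (i in seq_len(length(bs) - 1)) for (j in seq(i + 1, length(bs))) {
        if (length(intersect(bs[[i]]$genes, bs[[j]]$genes)) > 0 &&
            length(intersect(bs[[i]]$mirnas, bs[[j]]$mirnas)) > 0)
          abort(sprintf("overlapping blocks on slice %d", k))
      }
    }
  }
  structure(list(p = p, q = q, M = M, blocks = blocks, noise_sd = noise_sd,
                 seed = seed, shuffle = shuffle, clip = clip),
            class = "simulation_config")
}

#' The default planted-block design
#'
#' Three modules over four slices: module 1 (genes 1-100 x miRNAs 1-10) in
#' slices 1 (+0.5) and 2 (-0.5); module 2 (genes 101-200 x miRNAs 11-20) in
#' slices 1 (-0.5) and 3 (+0.5); module 3 (genes 201-300 x miRNAs 21-30) in
#' slices 2 (+0.5) and 3 (-0.5); slice 4 pure noise. All block sds 0.2.
#'
#' @return A list of block specifications for [simulation_config()].
#' @export
default_blocks <- function() {
  list(
    list(genes = 1:100, mirnas = 1:10, cancer = 1, mean = 0.5, sd = 0.2),
    list(genes = 101:200, mirnas = 11:20, cancer = 1, mean = -0.5, sd = 0.2),
    list(genes = 1:100, mirnas = 1:10, cancer = 2, mean = -0.5, sd = 0.2),
    list(genes = 201:300, mirnas = 21:30, cancer = 2, mean = 0.5, sd = 0.2),
    list(genes = 101:200, mirnas = 11:20, cancer = 3, mean = 0.5, sd = 0.2),
    list(genes = 201:300, mirnas = 21:30, cancer = 3, mean = -0.5, sd = 0.2)
  )
}

# group blocks sharing a (genes, mirnas) footprint into planted modules
blocks_to_truth <- function(blocks) {
  keys <- vapply(blocks, function(b)
    paste(min(b$genes), max(b$genes), min(b$mirnas), max(b$mirnas)), character(1))
  lapply(split(seq_along(blocks), factor(keys, levels = unique(keys))), function(ix) {
    list(genes = blocks[[ix[1]]]$genes,
         mirnas = blocks[[ix[1]]]$mirnas,
         cancers = sort(unique(vapply(blocks[ix], function(b) b$cancer, numeric(1)))))
  })
}

#' Generate a planted-module correlation tensor
#'
#' Background entries are N(0, noise_sd^2); each block overwrites its cells
#' with N(mean, sd^2) draws. Returns the tensor together with the planted
#' truth (one module per distinct gene x miRNA footprint, its cancer set
#' pooling all slices the footprint appears in, signs absorbed by the
#' factor model).
#'
#' @param config A [simulation_config()].
#' @return List with `tensor` (a [correlation_tensor()], flagged raw unless
#'   `clip = TRUE`), `truth` (list of planted modules), and `permutations`
#'   (gene/miRNA orderings when shuffled, else `NULL`).
#' @export
simulate_tensor <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  out <- with_seed(config$seed, {
    a <- array(rnorm(config$p * config$q * config$M, 0, config$noise_sd),
               dim = c(config$p, config$q, config$M))
    for (b in config$blocks) {
      nb <- length(b$genes) * length(b$mirnas)
      a[b$genes, b$mirnas, b$cancer] <-
        if (b$sd == 0) b$mean else rnorm(nb, b$mean, b$sd)
    }
    perms <- NULL
    if (isTRUE(config$shuffle))
      perms <- list(genes = sample.int(config$p), mirnas = sample.int(config$q))
    list(a = a, perms = perms)
  })
  a <- out$a
  truth <- blocks_to_truth(config$blocks)
  if (!is.null(out$perms)) {
    # position i of the new tensor holds old feature perms$genes[i]
    a <- a[out$perms$genes, out$perms$mirnas, , drop = FALSE]
    inv_g <- order(out$perms$genes); inv_m <- order(out$perms$mirnas)
    truth <- lapply(truth, function(t) {
      list(genes = sort(inv_g[t$genes]), mirnas = sort(inv_m[t$mirnas]),
           cancers = t$cancers)
    })
  }
  if (isTRUE(config$clip)) a <- pmin(pmax(a, -1), 1)
  tensor <- correlation_tensor(a, built_from_data = isTRUE(config$clip))
  list(tensor = tensor, truth = unname(truth), permutations = out$perms)
}

#' Shuffle the gene and miRNA axes of a tensor
#'
#' Applies one random gene permutation and one miRNA permutation
#' consistently to all slices and to the planted truth. Invertible via the
#' returned permutations.
#'
#' @param tensor A [correlation_tensor()].
#' @param truth Planted-truth list (as from [simulate_tensor()]).
#' @param seed Integer seed.
#' @return List `tensor`, `truth`, `permutations`.
#' @export
shuffle_tensor <- function(tensor, truth, seed) {
  d <- dim(tensor)
  perms <- with_seed(seed, list(genes = sample.int(d[1]), mirnas = sample.int(d[2])))
  a <- tensor_values(tensor)[perms$genes, perms$mirnas, , drop = FALSE]
  inv_g <- order(perms$genes); inv_m <- order(perms$mirnas)
  truth <- lapply(truth, function(t) {
    list(genes = sort(inv_g[t$genes]), mirnas = sort(inv_m[t$mirnas]),
         cancers = t$cancers)
  })
  list(tensor = correlation_tensor(a, built_from_data = attr(tensor, "built_from_data")),
       truth = truth, permutations = perms)
}

#' Generate matched expression data with planted co-expression modules
#'
#' Draws one latent factor per planted module and cancer, loading it onto
#' the module's genes and miRNAs so that the empirical gene-miRNA
#' correlations inside each block approximate the configured block means;
#' everything else is independent noise. Lets the full pipeline — from
#' expression through the correlation tensor to module recovery — run
#' end-to-end on synthetic data.
#'
#' @param config A [simulation_config()] (block means must satisfy
#'   |mean| < 1).
#' @param n_samples Samples per cancer (>= 10).
#' @param seed Integer seed.
#' @return List `pairs` (input for [build_correlation_tensor()]) and
#'   `truth`.
#' @export
simulate_expression <- function(config, n_samples = 200, seed) {
  if (missing(seed)) abort("`seed` is required")
  if (n_samples < 10) abort("need at least 10 samples per cancer")
  for (b in config$blocks)
    if (abs(b$mean) >= 1) abort("infeasible target correlation |mean| >= 1")
  truth <- blocks_to_truth(config$blocks)
  pairs <- with_seed(seed, lapply(seq_len(config$M), function(k) {
    X <- matrix(rnorm(n_samples * config$p), n_samples, config$p)
    Y <- matrix(rnorm(n_samples * config$q), n_samples, config$q)
    for (b in config$blocks) {
      if (b$cancer != k) next
      rho <- abs(b$mean)
      z <- rnorm(n_samples)
      lam <- sqrt(rho)
      sg <- 1; sm <- sign(b$mean)
      # x = lam*z + sqrt(1-rho)*eps gives cor(x, y) = rho within the block
      X[, b$genes] <- sg * lam * z +
        sqrt(1 - rho) * matrix(rnorm(n_samples * length(b$genes)), n_samples)
      Y[, b$mirnas] <- sm * lam * z +
        sqrt(1 - rho) * matrix(rnorm(n_samples * length(b$mirnas)), n_samples)
    }
    rownames(X) <- rownames(Y) <- sprintf("c%d_s%03d", k, seq_len(n_samples))
    colnames(X) <- paste0("g", seq_len(config$p))
    colnames(Y) <- paste0("m", seq_len(config$q))
    list(cancer_id = paste0("c", k), x = expression_matrix(X),
         y = expression_matrix(Y))
  }))
  list(pairs = pairs, truth = unname(truth))
}

# modules as sets of (gene, mirna, cancer) cell triples, encoded as integers
module_cells <- function(m, dims) {
  s <- if (!is.null(m$genes)) list(I = m$genes, J = m$mirnas, K = m$cancers)
  else as_support(m)
  g <- as.integer(s$I); mi <- as.integer(s$J); ca <- as.integer(s$K)
  as.vector(outer(outer(g, (mi - 1L) * dims[1], "+"),
                  (ca - 1L) * dims[1] * dims[2], "+"))
}

#' Recovery score of predicted tri-clusters
#'
#' Mean, over true modules, of the best Jaccard index between the true
#' module's cell set (gene, miRNA, cancer triples) and any predicted
#' module's cell set. 1 means every true module is found exactly.
#'
#' @param truth,predicted Lists of modules: either planted-truth entries
#'   (`genes`, `mirnas`, `cancers`) or `tscca_module`s / `list(I, J, K)`.
#' @param dims Tensor dimensions `c(p, q, M)`.
#' @return A scalar in \[0, 1\].
#' @export
recovery_score <- function(truth, predicted, dims) {
  if (length(truth) == 0) abort("empty truth")
  t_cells <- lapply(truth, module_cells, dims = dims)
  p_cells <- lapply(predicted, module_cells, dims = dims)
  if (length(p_cells) == 0) return(0)
  mean(vapply(t_cells, function(tc) {
    max(vapply(p_cells, function(pc) {
      inter <- length(intersect(tc, pc))
      inter / (length(tc) + length(pc) - inter)
    }, numeric(1)))
  }, numeric(1)))
}

# exact maximum-weight one-to-one matching by branch and bound (small n)
max_matching_weight <- function(Wt) {
  n <- nrow(Wt); m <- ncol(Wt)
  if (n == 0 || m == 0) return(0)
  best <- 0
  recurse <- function(i, used, acc) {
    if (i > n) { best <<- max(best, acc); return(invisible()) }
    # bound: remaining rows can add at most their row maxima
    ub <- acc + sum(apply(Wt[i:n, , drop = FALSE], 1, max))
    if (ub <= best) return(invisible())
    recurse(i + 1, used, acc)                 # leave row i unmatched
    for (j in seq_len(m)) if (!used[j] && Wt[i, j] > 0) {
      used[j] <- TRUE
      recurse(i + 1, used, acc + Wt[i, j])
      used[j] <- FALSE
    }
  }
  recurse(1, rep(FALSE, m), 0)
  best
}

#' Clustering error of predicted tri-clusters
#'
#' One minus the weight of a maximum one-to-one matching between true and
#' predicted modules (weight = shared cell count) divided by the size of
#' the union of all cells in truth and prediction. 0 means a perfect
#' reconstruction; lower is better.
#'
#' @inheritParams recovery_score
#' @return A scalar in \[0, 1\].
#' @export
ce_score <- function(truth, predicted, dims) {
  if (length(truth) == 0) abort("empty truth")
  t_cells <- lapply(truth, module_cells, dims = dims)
  p_cells <- lapply(predicted, module_cells, dims = dims)
  all_cells <- unique(c(unlist(t_cells), unlist(p_cells)))
  if (length(p_cells) == 0) return(1)
  Wt <- outer(seq_along(t_cells), seq_along(p_cells),
              Vectorize(function(i, j) length(intersect(t_cells[[i]], p_cells[[j]]))))
  1 - max_matching_weight(Wt) / length(all_cells)
}
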