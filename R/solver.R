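#' k-sparse projection
#'
#' Keeps the k entries of z with the largest absolute values and zeroes the
#' rest. Ties at the k-th magnitude are broken by lowest index, so runs are
#' bit-reproducible.
#'
#' @param z Numeric vector.
#' @param k Integer, 1 <= k <= length(z).
#' @return Numeric vector of the same length with at most k nonzeros.
#' @export
#'
#' @examples
#' ksparse_project(c(-6, 4, 5, 2, -1, 3), 3)
ksparse_project <- function(z, k) {
  if (!is.numeric(z) || length(z) == 0) abort("`z` must be a nonempty numeric vector")
  if (length(k) != 1 || k < 1 || k > length(z) || k != round(k))
    abort("`k` must be an integer in [1, length(z)]")
  keep <- order(-abs(z), seq_along(z))[seq_len(k)]
  out <- numeric(length(z))
  out[keep] <- z[keep]
  names(out) <- names(z)
  out
}

#' Closed-form solution of the k-sparse unit-vector subproblem
#'
#' Returns the unit vector with at most k nonzeros maximizing the inner
#' product with z: the k-sparse projection of z, normalized.
#'
#' @inheritParams ksparse_project
#' @return Unit-norm numeric vector with at most k nonzeros.
#' @export
solve_subproblem <- function(z, k) {
  pz <- ksparse_project(z, k)
  nrm <- sqrt(sum(pz^2))
  if (nrm == 0)
    abort("degenerate score vector (all zero); perturb the tensor or lower k",
          class = "tscca_degenerate")
  pz / nrm
}

#' Trilinear objective
#'
#' The triple mode contraction of the tensor with (u, v, w):
#' sum over i of w_i * t(u) %*% A_i %*% v. At a fitted factor triple this is
#' the module's singular value d.
#'
#' @param A A [correlation_tensor()] or p x q x M array.
#' @param u,v,w Numeric vectors of lengths p, q, M.
#' @return A scalar.
#' @export
tscca_objective <- function(A, u, v, w) {
  a <- tensor_values(A)
  d <- dim(a)
  if (length(u) != d[1] || length(v) != d[2] || length(w) != d[3])
    abort("factor lengths must match tensor dimensions")
  sum(w * slice_scores(a, u, v))
}

# z_w: per-slice bilinear forms t(u) A_i v, computed without copying slices
slice_scores <- function(a, u, v) {
  d <- dim(a)
  uv <- as.vector(outer(u, v))               # p*q
  colSums(matrix(a, d[1] * d[2], d[3]) * uv)
}

# gauge: flip (u, v) jointly so the largest-|.| entry of v is positive
apply_gauge <- function(u, v) {
  j <- which.max(abs(v))
  if (v[j] < 0) list(u = -u, v = -v) else list(u = u, v = v)
}

#' Rank-1 sparse tensor CCA
#'
#' Fits one sparse factor triple (u, v, w) with at most `k_u`, `k_v`, `k_w`
#' nonzeros by block-coordinate descent: each block update is the exact
#' k-sparse subproblem solution, so the trilinear objective never decreases
#' once all three blocks satisfy their budgets. Initialization: w uniform
#' with unit norm; (u, v) from the leading singular pair of the w-weighted
#' slice sum. The initializer is dense, so the first two entries of the
#' objective trace (before v and w have been projected) may sit above the
#' first feasible iterate; from the third entry on the trace is monotone.
#'
#' @param A A [correlation_tensor()] or 3-way array.
#' @param k_u,k_v,k_w Sparsity budgets for genes, miRNAs, cancers.
#' @param tol Convergence tolerance on the max-norm change of the factors.
#' @param max_iter Iteration cap.
#' @param restarts Number of additional random restarts (best objective
#'   kept); 0 uses only the spectral initialization.
#' @param seed Seed for the random restarts (required if `restarts > 0`).
#' @param init Optional list(u =, v =, w =) initial factors overriding the
#'   default initialization.
#'
#' @return A `tscca_module` list: `u`, `v`, `w`, `d`, supports `I`, `J`, `K`
#'   (integer indices of nonzeros), `iterations`, `converged`, and
#'   `objective_trace` (objective after every block update).
#' @export
tscca_rank1 <- function(A, k_u, k_v, k_w, tol = 1e-6, max_iter = 1000,
                        restarts = 0, seed = NULL, init = NULL) {
  a <- tensor_values(A)
  d3 <- dim(a)
  p <- d3[1]; q <- d3[2]; M <- d3[3]
  check_budget <- function(k, n, nm) {
    if (length(k) != 1 || k < 1 || k > n || k != round(k))
      abort(sprintf("`%s` must be an integer in [1, %d]", nm, n))
  }
  check_budget(k_u, p, "k_u"); check_budget(k_v, q, "k_v"); check_budget(k_w, M, "k_w")
  if (!all(is.finite(a))) abort("tensor must be finite")

  inits <- list()
  if (is.null(init)) {
    w0 <- rep(1 / sqrt(M), M)
    C0 <- weighted_slice_sum(a, w0)
    sv <- svd(C0, nu = 1, nv = 1)
    inits[[1]] <- list(u = sv$u[, 1], v = sv$v[, 1], w = w0)
  } else {
    inits[[1]] <- init
  }
  if (restarts > 0) {
    if (is.null(seed)) abort("`seed` is required when restarts > 0")
    rng <- local_rng(seed)
    for (r in seq_len(restarts)) {
      u <- rng$norm(p); v <- rng$norm(q); w <- rng$norm(M)
      inits[[r + 1]] <- list(u = u / sqrt(sum(u^2)), v = v / sqrt(sum(v^2)),
                             w = w / sqrt(sum(w^2)))
    }
  }

  best <- NULL
  for (ini in inits) {
    fit <- tryCatch(bcd_rank1(a, ini, k_u, k_v, k_w, tol, max_iter),
                    tscca_degenerate = function(e) if (length(inits) > 1) NULL else stop(e))
    if (!is.null(fit) && (is.null(best) || fit$d > best$d)) best <- fit
  }
  if (is.null(best))
    abort("all initializations hit a degenerate score vector", class = "tscca_degenerate")
  labels <- dimnames(a)
  structure(c(best, list(
    gene_ids = labels[[1]], mirna_ids = labels[[2]], cancer_ids = labels[[3]],
    k = c(k_u = k_u, k_v = k_v, k_w = k_w))),
    class = "tscca_module")
}

weighted_slice_sum <- function(a, w) {
  d <- dim(a)
  matrix(matrix(a, d[1] * d[2], d[3]) %*% w, d[1], d[2])
}

bcd_rank1 <- function(a, init, k_u, k_v, k_w, tol, max_iter) {
  u <- init$u; v <- init$v; w <- init$w
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    u_old <- u; v_old <- v; w_old <- w
    C <- weighted_slice_sum(a, w)
    u <- solve_subproblem(drop(C %*% v), k_u)
    trace <- c(trace, sum(w * slice_scores(a, u, v)))
    v <- solve_subproblem(drop(crossprod(C, u)), k_v)
    trace <- c(trace, sum(w * slice_scores(a, u, v)))
    zw <- slice_scores(a, u, v)
    w <- solve_subproblem(zw, k_w)
    trace <- c(trace, sum(w * zw))
    if (max(max(abs(u - u_old)), max(abs(v - v_old)), max(abs(w - w_old))) < tol) {
      converged <- TRUE
      break
    }
  }
  g <- apply_gauge(u, v)
  u <- g$u; v <- g$v
  d <- sum(w * slice_scores(a, u, v))
  list(u = u, v = v, w = w, d = d,
       I = which(u != 0), J = which(v != 0), K = which(w != 0),
       iterations = iter, converged = converged, objective_trace = trace)
}

# minimal deterministic RNG scope: does not disturb the caller's RNG state
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  }
  list(norm = function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    x <- rnorm(n)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    x
  })
}

#' @export
print.tscca_module <- function(x, ...) {
  cat(sprintf("<tscca_module> d = %.4g | %d genes, %d miRNAs, %d cancers | %d iterations%s\n",
              x$d, length(x$I), length(x$J), length(x$K), x$iterations,
              if (!x$converged) " (not converged)" else ""))
  invisible(x)
}

#' Multi-module sparse tensor CCA by deflation
#'
#' Extracts `r` sparse rank-1 modules sequentially: after each fit the tensor
#' is deflated by `d * outer(u, v, w)` and the solver is rerun on the
#' residual. The cancer-weight matrix W collects the r cancer factors as
#' columns.
#'
#' @inheritParams tscca_rank1
#' @param r Number of modules to extract.
#' @param ... Passed to [tscca_rank1()] (`tol`, `max_iter`, `restarts`,
#'   `seed`).
#'
#' @return A `tscca_fit` with elements `modules` (list of `tscca_module`),
#'   `d` (singular values in extraction order), `W` (M x r cancer-weight
#'   matrix), `residual` (a [correlation_tensor()] flagged as residual),
#'   `k`, and `r`.
#' @export
#'
#' @examples
#' sim <- simulate_tensor(simulation_config(seed = 1))
#' fit <- tscca(sim$tensor, r = 3, k_u = 100, k_v = 10, k_w = 2)
#' glance(fit)
tscca <- function(A, r, k_u, k_v, k_w, ...) {
  if (length(r) != 1 || r < 1 || r != round(r)) abort("`r` must be a positive integer")
  a <- tensor_values(A)
  labels <- dimnames(a)
  modules <- vector("list", r)
  found <- 0
  for (j in seq_len(r)) {
    m <- tryCatch(tscca_rank1(a, k_u, k_v, k_w, ...),
                  tscca_degenerate = function(e) NULL)
    if (is.null(m)) {
      warn(sprintf("residual became degenerate after %d module(s); returning those", found))
      break
    }
    modules[[j]] <- m
    found <- j
    a <- a - m$d * outer(outer(m$u, m$v), m$w)
  }
  modules <- modules[seq_len(found)]
  W <- if (found > 0) vapply(modules, function(m) m$w, numeric(dim(a)[3])) else
    matrix(0, dim(a)[3], 0)
  W <- matrix(W, nrow = dim(a)[3])
  rownames(W) <- labels[[3]]
  colnames(W) <- if (found > 0) paste0("module_", seq_len(found)) else character(0)
  structure(list(
    modules = modules,
    d = vapply(modules, function(m) m$d, numeric(1)),
    W = W,
    residual = correlation_tensor(a, labels[[1]], labels[[2]], labels[[3]],
                                  built_from_data = FALSE),
    k = c(k_u = k_u, k_v = k_v, k_w = k_w),
    r = found),
    class = "tscca_fit")
}

#' @export
print.tscca_fit <- function(x, ...) {
  cat(sprintf("<tscca_fit> %d module(s), k = (%d, %d, %d)\n",
              x$r, x$k["k_u"], x$k["k_v"], x$k["k_w"]))
  if (x$r > 0)
    cat("  singular values:", paste(signif(x$d, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Rank-1 sparse CCA on a single correlation matrix
#'
#' The single-cancer baseline: identical to [tscca_rank1()] applied to the
#' one-slice tensor with `k_w = 1`.
#'
#' @param Z Numeric genes x miRNAs correlation matrix.
#' @inheritParams tscca_rank1
#' @param ... Passed to [tscca_rank1()].
#' @return A `tscca_module` with `K = 1`.
#' @export
scca_rank1 <- function(Z, k_u, k_v, ...) {
  Z <- as.matrix(Z)
  A <- array(Z, dim = c(nrow(Z), ncol(Z), 1))
  dimnames(A) <- list(rownames(Z) %||% paste0("g", seq_len(nrow(Z))),
                      colnames(Z) %||% paste0("m", seq_len(ncol(Z))),
                      "slice_1")
  tscca_rank1(A, k_u = k_u, k_v = k_v, k_w = 1, ...)
}
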