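test_that("k-sparse projection keeps the k largest magnitudes", {
  expect_equal(ksparse_project(c(-6, 4, 5, 2, -1, 3), 3), c(-6, 4, 5, 0, 0, 0))
  z <- c(1, -3, 2)
  expect_equal(ksparse_project(z, 2), c(0, -3, 2))
  expect_equal(ksparse_project(z, 3), z)
  # ties at the k-th magnitude resolve to the lowest index
  expect_equal(ksparse_project(c(2, 1, 1), 2), c(2, 1, 0))
  # zeros never get promoted: exactly min(k, nnz) nonzeros
  expect_equal(sum(ksparse_project(c(0, 5, 0, 0), 3) != 0), 1)
  expect_error(ksparse_project(c(1, 2), 0), "k")
  expect_error(ksparse_project(c(1, 2), 3), "k")
})

test_that("subproblem solution is the normalized projection and attains the enumeration optimum", {
  expect_equal(solve_subproblem(c(3, 4, 0), 2), c(0.6, 0.8, 0))
  z <- c(-6, 4, 5, 2, -1, 3)
  expect_equal(solve_subproblem(z, 3), c(-6, 4, 5, 0, 0, 0) / sqrt(77))
  expect_error(solve_subproblem(rep(0, 4), 2), class = "tscca_degenerate")

  set.seed(101)
  for (rep in 1:50) {
    n <- sample(3:8, 1)
    k <- sample(seq_len(min(4, n)), 1)
    z <- rnorm(n)
    u <- solve_subproblem(z, k)
    expect_equal(sum(u^2), 1, tolerance = 1e-12)
    expect_lte(sum(u != 0), k)
    expect_equal(sum(u * z), best_subproblem_value(z, k), tolerance = 1e-12)
  }
})

test_that("trilinear objective matches a triple-loop oracle and is multilinear", {
  A <- random_tensor(4, 3, 2, seed = 7)
  set.seed(8)
  u <- rnorm(4); v <- rnorm(3); w <- rnorm(2)
  expect_equal(tscca_objective(A, u, v, w), objective_loop(A, u, v, w),
               tolerance = 1e-12)
  expect_equal(tscca_objective(A, 2 * u, v, w), 2 * tscca_objective(A, u, v, w),
               tolerance = 1e-12)
  # coordinate extraction on a single slice
  B <- correlation_tensor(array(matrix(c(0.9, 0, 0, 0.2), 2), c(2, 2, 1)))
  expect_equal(tscca_objective(B, c(1, 0), c(1, 0), 1), 0.9)
  expect_error(tscca_objective(A, u[-1], v, w), "dimension")
})

test_that("rank-1 solver exactly recovers a planted sparse rank-1 tensor", {
  pl <- planted_rank1(8, 6, 3, I = c(2, 5), J = c(1, 4), K = 2, d = 3, seed = 3)
  m <- tscca_rank1(pl$A, k_u = 2, k_v = 2, k_w = 1)
  expect_equal(m$d, 3, tolerance = 1e-8)
  expect_equal(sort(m$I), pl$I)
  expect_equal(sort(m$J), pl$J)
  expect_equal(sort(m$K), pl$K)
  expect_equal(m$u, pl$u, tolerance = 1e-8)
  expect_equal(m$v, pl$v, tolerance = 1e-8)
  expect_equal(abs(m$w), abs(pl$w), tolerance = 1e-8)
})

test_that("with one slice and full budgets the solver reaches the dense SVD optimum", {
  set.seed(77)
  for (rep in 1:10) {
    Z <- matrix(rnorm(24), 6, 4)
    A <- array(Z, dim = c(6, 4, 1))
    m <- tscca_rank1(A, k_u = 6, k_v = 4, k_w = 1)
    expect_equal(m$d, svd(Z)$d[1], tolerance = 1e-8)
  }
})

test_that("objective trace is non-decreasing and invariants hold at the fixed point", {
  for (s in 1:5) {
    A <- random_tensor(6, 5, 3, seed = 100 + s)
    m <- tscca_rank1(A, k_u = 3, k_v = 2, k_w = 2)
    # the first two trace entries still involve the dense (infeasible)
    # spectral initializer; monotonicity is guaranteed from the first fully
    # k-sparse iterate onward
    feasible_diffs <- diff(m$objective_trace)[-(1:2)]
    expect_true(all(feasible_diffs >= -1e-12))
    expect_equal(sum(m$u^2), 1, tolerance = 1e-8)
    expect_equal(sum(m$v^2), 1, tolerance = 1e-8)
    expect_equal(sum(m$w^2), 1, tolerance = 1e-8)
    expect_lte(length(m$I), 3)
    expect_lte(length(m$J), 2)
    expect_lte(length(m$K), 2)
    expect_gte(m$d, 0)
    # gauge: dominant miRNA loading is positive
    expect_gt(m$v[which.max(abs(m$v))], 0)
  }
})

test_that("each returned factor is optimal against random same-sparsity alternatives", {
  A <- random_tensor(6, 5, 3, seed = 42)
  m <- tscca_rank1(A, k_u = 3, k_v = 2, k_w = 2)
  set.seed(999)
  for (r in 1:200) {
    u <- numeric(6); idx <- sample(6, 3); u[idx] <- rnorm(3); u <- u / sqrt(sum(u^2))
    v <- numeric(5); idx <- sample(5, 2); v[idx] <- rnorm(2); v <- v / sqrt(sum(v^2))
    w <- numeric(3); idx <- sample(3, 2); w[idx] <- rnorm(2); w <- w / sqrt(sum(w^2))
    expect_lte(tscca_objective(A, u, m$v, m$w), m$d + 1e-10)
    expect_lte(tscca_objective(A, m$u, v, m$w), m$d + 1e-10)
    expect_lte(tscca_objective(A, m$u, m$v, w), m$d + 1e-10)
  }
})

test_that("solver never exceeds the exhaustive support-enumeration optimum", {
  A <- random_tensor(5, 4, 3, seed = 13, sd = 0.3)
  m <- tscca_rank1(A, k_u = 2, k_v = 2, k_w = 2, restarts = 10, seed = 5)
  # global optimum: enumerate all 2/2/2 supports, dense ALS on each sub-tensor
  best <- -Inf
  for (I in utils::combn(5, 2, simplify = FALSE))
    for (J in utils::combn(4, 2, simplify = FALSE))
      for (K in utils::combn(3, 2, simplify = FALSE))
        best <- max(best, dense_trilinear_max(unclass(A)[I, J, K]))
  expect_lte(m$d, best + 1e-6)

  # a signal-dominated instance is solved to global optimality
  pl <- planted_rank1(5, 4, 3, I = c(1, 3), J = c(2, 4), K = c(1, 2), d = 5, seed = 9)
  noisy <- correlation_tensor(unclass(pl$A) + unclass(random_tensor(5, 4, 3, 14, sd = 0.05)),
                              built_from_data = FALSE)
  m2 <- tscca_rank1(noisy, k_u = 2, k_v = 2, k_w = 2)
  best2 <- -Inf
  for (I in utils::combn(5, 2, simplify = FALSE))
    for (J in utils::combn(4, 2, simplify = FALSE))
      for (K in utils::combn(3, 2, simplify = FALSE))
        best2 <- max(best2, dense_trilinear_max(unclass(noisy)[I, J, K]))
  expect_equal(m2$d, best2, tolerance = 1e-6)
})

test_that("gauge is stable under consistent sign flips of the tensor", {
  A <- random_tensor(6, 5, 3, seed = 21)
  m1 <- tscca_rank1(A, k_u = 3, k_v = 2, k_w = 2)
  m2 <- tscca_rank1(correlation_tensor(-unclass(A), built_from_data = FALSE),
                    k_u = 3, k_v = 2, k_w = 2)
  # negation is absorbed by w (or jointly by (u,v), normalized by the gauge)
  expect_equal(m2$d, m1$d, tolerance = 1e-6)
  expect_equal(abs(m2$u), abs(m1$u), tolerance = 1e-6)
  expect_equal(abs(m2$v), abs(m1$v), tolerance = 1e-6)
  expect_equal(abs(m2$w), abs(m1$w), tolerance = 1e-6)
})

test_that("deflation recovers orthogonal planted modules in order and telescopes", {
  p1 <- planted_rank1(10, 8, 4, I = 1:3, J = 1:2, K = 1:2, d = 5, seed = 31)
  p2 <- planted_rank1(10, 8, 4, I = 6:8, J = 5:6, K = 3:4, d = 2, seed = 32)
  A <- correlation_tensor(unclass(p1$A) + unclass(p2$A), built_from_data = FALSE)
  fit <- tscca(A, r = 2, k_u = 3, k_v = 2, k_w = 2)
  expect_equal(fit$d, c(5, 2), tolerance = 1e-8)
  expect_equal(sort(fit$modules[[1]]$I), p1$I)
  expect_equal(sort(fit$modules[[2]]$I), p2$I)
  expect_lt(sqrt(sum(unclass(fit$residual)^2)), 1e-8)

  # reconstruction: sum of rank-1 terms plus residual equals the input
  recon <- Reduce(`+`, lapply(fit$modules, function(m)
    m$d * outer(outer(m$u, m$v), m$w))) + unclass(fit$residual)
  expect_equal(as.vector(recon), as.vector(unclass(A)), tolerance = 1e-10)
})

test_that("multi-module extraction with r = 1 equals a single rank-1 fit", {
  A <- random_tensor(6, 5, 3, seed = 55)
  fit <- tscca(A, r = 1, k_u = 3, k_v = 2, k_w = 2)
  m <- tscca_rank1(A, k_u = 3, k_v = 2, k_w = 2)
  expect_identical(fit$modules[[1]]$u, m$u)
  expect_identical(fit$modules[[1]]$d, m$d)
  expect_identical(fit$W[, 1], setNames(m$w, dimnames(A)[[3]]))
})

test_that("single-matrix sparse CCA is the one-slice special case", {
  set.seed(66)
  Z <- matrix(rnorm(30), 6, 5)
  m1 <- scca_rank1(Z, k_u = 3, k_v = 2)
  A <- array(Z, dim = c(6, 5, 1))
  m2 <- tscca_rank1(A, k_u = 3, k_v = 2, k_w = 1)
  expect_identical(m1$u, m2$u)
  expect_identical(m1$v, m2$v)
  expect_identical(m1$d, m2$d)
  # full budgets give the leading singular pair
  mfull <- scca_rank1(Z, k_u = 6, k_v = 5)
  expect_equal(mfull$d, svd(Z)$d[1], tolerance = 1e-8)
  # planted single-matrix block is recovered
  set.seed(67)
  Zb <- matrix(rnorm(200 * 20, 0, 0.2), 200, 20)
  Zb[1:40, 1:5] <- rnorm(200, 0.5, 0.2)
  mb <- scca_rank1(Zb, k_u = 40, k_v = 5)
  expect_setequal(mb$I, 1:40)
  expect_setequal(mb$J, 1:5)
})

test_that("tidy/glance/summary views expose the fit faithfully", {
  pl <- planted_rank1(8, 6, 3, I = c(2, 5), J = c(1, 4), K = 2, d = 3, seed = 3)
  fit <- tscca(pl$A, r = 1, k_u = 2, k_v = 2, k_w = 1)
  td <- tidy(fit)
  expect_equal(nrow(td), 2 + 2 + 1)
  expect_setequal(unique(td$axis), c("gene", "mirna", "cancer"))
  gl <- glance(fit)
  expect_equal(gl$r, 1)
  expect_lt(gl$residual_fnorm, 1e-8)
  ms <- module_summary(fit)
  expect_equal(ms$n_genes, 2L)
  expect_true(ms$converged)
  expect_s3_class(autoplot(fit), "ggplot")
})
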