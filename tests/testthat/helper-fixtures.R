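# Shared fixtures: everything is generated in code under fixed seeds.

# a random labelled tensor (not a correlation tensor; raw values)
random_tensor <- function(p, q, M, seed, sd = 1) {
  set.seed(seed)
  correlation_tensor(array(rnorm(p * q * M, 0, sd), dim = c(p, q, M)),
                     built_from_data = FALSE)
}

# sparse rank-1 tensor d * (u o v o w) with given supports
planted_rank1 <- function(p, q, M, I, J, K, d = 3, seed = 1) {
  set.seed(seed)
  u <- numeric(p); v <- numeric(q); w <- numeric(M)
  u[I] <- rnorm(length(I)); u <- u / sqrt(sum(u^2))
  v[J] <- rnorm(length(J)); v <- v / sqrt(sum(v^2))
  w[K] <- abs(rnorm(length(K))); w <- w / sqrt(sum(w^2))
  g <- tscca:::apply_gauge(u, v)
  A <- correlation_tensor(d * outer(outer(g$u, g$v), w), built_from_data = FALSE)
  list(A = A, u = g$u, v = g$v, w = w, d = d, I = sort(I), J = sort(J), K = sort(K))
}

# independent trilinear-objective oracle: plain triple loop
objective_loop <- function(a, u, v, w) {
  a <- unclass(a)
  tot <- 0
  for (i in seq_along(u)) for (j in seq_along(v)) for (k in seq_along(w))
    tot <- tot + a[i, j, k] * u[i] * v[j] * w[k]
  tot
}

# exhaustive best k-sparse value of max_u u'z (unit norm, |supp| <= k)
best_subproblem_value <- function(z, k) {
  supports <- utils::combn(length(z), k)
  max(apply(supports, 2, function(S) sqrt(sum(z[S]^2))))
}

# dense rank-(1,1,1) trilinear maximum of a small tensor by ALS restarts
dense_trilinear_max <- function(a, n_restarts = 12, iters = 200) {
  a <- unclass(a)
  d <- dim(a)
  best <- -Inf
  set.seed(420)
  for (r in seq_len(n_restarts)) {
    u <- rnorm(d[1]); u <- u / sqrt(sum(u^2))
    v <- rnorm(d[2]); v <- v / sqrt(sum(v^2))
    w <- rnorm(d[3]); w <- w / sqrt(sum(w^2))
    for (it in seq_len(iters)) {
      zu <- vapply(seq_len(d[1]), function(i) sum(a[i, , ] * outer(v, w)), numeric(1))
      u <- zu / sqrt(sum(zu^2))
      zv <- vapply(seq_len(d[2]), function(j) sum(a[, j, ] * outer(u, w)), numeric(1))
      v <- zv / sqrt(sum(zv^2))
      zw <- vapply(seq_len(d[3]), function(k) sum(a[, , k] * outer(u, v)), numeric(1))
      w <- zw / sqrt(sum(zw^2))
    }
    val <- abs(sum(a * outer(outer(u, v), w)))
    best <- max(best, val)
  }
  best
}

# random undirected edge set over labelled nodes
random_graph <- function(nodes, n_edges, seed) {
  set.seed(seed)
  all_pairs <- t(utils::combn(nodes, 2))
  pick <- sample.int(nrow(all_pairs), n_edges)
  tibble::tibble(from = all_pairs[pick, 1], to = all_pairs[pick, 2])
}

# synthetic survival cohort; hazard optionally depends on a group label
survival_cohort <- function(n, seed, hazard_ratio = 1, group = NULL) {
  set.seed(seed)
  if (is.null(group)) group <- rep(0, n)
  rate <- 0.01 * hazard_ratio^group
  time <- stats::rexp(n, rate)
  cens <- stats::rexp(n, 0.005)
  tibble::tibble(sample_id = paste0("s", seq_len(n)),
                 time = pmin(time, cens),
                 event = as.numeric(time <= cens))
}

# two-group log-rank statistic from first principles (O-E / V over event times)
logrank_oracle <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- group == unique(group)[1]
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

default_sim <- function(seed) simulate_tensor(simulation_config(seed = seed))

# per-slice sparse CCA baseline: r modules per frontal slice via deflation
scca_per_slice <- function(tensor, r = 3, k_u = 100, k_v = 10) {
  a <- unclass(tensor)
  M <- dim(a)[3]
  preds <- list()
  for (k in seq_len(M)) {
    fit <- tryCatch(
      tscca(array(a[, , k], dim = c(dim(a)[1], dim(a)[2], 1)),
            r = r, k_u = k_u, k_v = k_v, k_w = 1),
      error = function(e) NULL)
    if (is.null(fit)) next
    for (m in fit$modules)
      preds[[length(preds) + 1]] <- list(I = m$I, J = m$J, K = k)
  }
  preds
}

# all injective assignments of k rows into n columns (ordered k-tuples)
combinat_perms <- function(n, k) {
  if (k == 1) return(as.list(seq_len(n)))
  out <- list()
  for (i in seq_len(n)) {
    rest <- combinat_perms(n - 1, k - 1)
    for (r in rest) {
      avail <- setdiff(seq_len(n), i)
      out[[length(out) + 1]] <- c(i, avail[r])
    }
  }
  out
}

# latent-factor expression + matched cohort; fake single-module fit for screens
make_survival_fixture <- function(seed, hazard_ratio) {
  set.seed(seed)
  n <- 80
  x <- matrix(rnorm(n * 6), n, 6, dimnames = list(paste0("s", 1:n), paste0("g", 1:6)))
  y <- matrix(rnorm(n * 2), n, 2, dimnames = list(paste0("s", 1:n), paste0("m", 1:2)))
  # one latent factor drives module features so PC1 tracks it
  z <- rnorm(n)
  x[, 1:3] <- 0.9 * z + 0.4 * x[, 1:3]
  y[, 1] <- 0.9 * z + 0.4 * y[, 1]
  grp <- as.numeric(z > median(z))
  clin <- survival_cohort(n, seed = seed + 1, hazard_ratio = hazard_ratio, group = grp)
  list(x = x, y = y, clin = clin)
}

fake_fit <- function() {
  structure(list(
    modules = list(structure(list(
      u = c(rep(0.5, 3), rep(0, 3)), v = c(1, 0), w = 1, d = 1,
      I = 1:3, J = 1, K = 1, iterations = 1, converged = TRUE,
      gene_ids = paste0("g", 1:6), mirna_ids = paste0("m", 1:2),
      cancer_ids = "ca"), class = "tscca_module")),
    d = 1, W = matrix(1, 1, 1, dimnames = list("ca", "module_1")),
    k = c(k_u = 3, k_v = 1, k_w = 1), r = 1L), class = "tscca_fit")
}

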