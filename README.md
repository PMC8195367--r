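# tscca

Sparse canonical correlation analysis on a gene × miRNA × cancer correlation
tensor, for discovering miRNA–gene co-expression modules that are shared by,
or specific to, subsets of cancer types.

## The problem and the method

Matched mRNA and miRNA expression profiles are now available for dozens of
cancer types. Within one cancer, sparse CCA can find a small set of genes and
miRNAs whose expression is strongly correlated; but run per cancer it cannot
say which co-expression patterns recur across cancers and which are
cancer-specific. `tscca` addresses this by working on the third-order tensor
**A** ∈ ℝ^(p×q×M) whose frontal slice *k* is the Pearson correlation matrix
between the *p* genes and *q* miRNAs in cancer *k*, and solving

maximize over u, v, w:  A ×̄₁ u ×̄₂ v ×̄₃ w
subject to ‖u‖₀ ≤ k_u, ‖v‖₀ ≤ k_v, ‖w‖₀ ≤ k_w, ‖u‖₂ = ‖v‖₂ = ‖w‖₂ = 1,

an ℓ₀-constrained rank-1 tensor approximation. Each block update has a closed
form: the score vector (e.g. z_u = (Σ_k w_k A_k) v) is projected onto its k
largest absolute entries and renormalized, so block-coordinate descent is
exact per block and the trilinear objective is monotone over the feasible
iterates. The nonzero entries of (u, v, w) define one cancer–miRNA–gene
module; its objective value d (the "singular value") measures module
strength. Deflating A ← A − d·(u∘v∘w) and refitting yields an ordered module
set and the M × r cancer-weight matrix W.

Around the solver the package implements the companion statistics used to
validate such modules:

* **modularity** — mean |correlation| over a module's sub-tensor, with a
  size-matched permutation null (`modularity_score()`,
  `permutation_test_modularity()`, `modularity_screen()`);
* **annotation enrichment** — right-tailed hypergeometric tests for cancer
  gene/miRNA sets, edge-density enrichment in PPI and miRNA-target networks
  with both hypergeometric and degree-aware permutation nulls, miRNA-family
  cooperativity (`hypergeometric_enrichment()`, `edge_enrichment()`,
  `degree_aware_edge_test()`, `family_cooperativity()`);
* **regulatory structure** — the largest connected three-layer
  miRNA → gene → gene subnetwork of a module
  (`extract_three_layer_network()`);
* **prognosis** — per-(module, cancer) median split of the joint PC1
  expression score, log-rank tests and Benjamini–Hochberg correction
  (`survival_screen()`);
* **a simulation benchmark** — planted-block correlation tensors with the
  canonical 300 × 30 × 4 three-module design, plus the tri-cluster agreement
  metrics Recovery (higher is better) and Clustering Error (lower is better)
  (`simulate_tensor()`, `recovery_score()`, `ce_score()`).

All results come back as tibbles, fits support `tidy()`, `glance()` and
`autoplot()`, and every stochastic routine takes an explicit seed.

## Worked example

Simulate the benchmark tensor (three planted 100-gene × 10-miRNA modules,
each active with opposite signs in two of four cancers, noise sd 0.2), fit
three sparse factors at the oracle sparsity, and score the result:

```r
library(tscca)

cfg <- simulation_config(seed = 42)
sim <- simulate_tensor(cfg)
fit <- tscca(sim$tensor, r = 3, k_u = 100, k_v = 10, k_w = 2,
             restarts = 5, seed = 1)
fit
#> <tscca_fit> 3 module(s), k = (100, 10, 2)
#>   singular values: 22.52, 22.51, 22.33

module_summary(fit)
#> # A tibble: 3 × 7
#>   module_id singular_value n_genes n_mirnas n_cancers iterations converged
#>       <int>          <dbl>   <int>    <int>     <int>      <int> <lgl>
#> 1         1           22.5     100       10         2          7 TRUE
#> 2         2           22.5     100       10         2          6 TRUE
#> 3         3           22.3     100       10         2          6 TRUE

modularity_screen(fit, sim$tensor, n_perm = 1000, seed = 42)[, c("module", "score", "p_value", "significant")]
#> # A tibble: 3 × 4
#>   module score  p_value significant
#>    <int> <dbl>    <dbl> <lgl>
#> 1      1 0.502 0.000999 TRUE
#> 2      2 0.502 0.000999 TRUE
#> 3      3 0.499 0.000999 TRUE

recovery_score(sim$truth, fit$modules, dim(sim$tensor))
#> [1] 1
ce_score(sim$truth, fit$modules, dim(sim$tensor))
#> [1] 0
```

Each recovered module's mean absolute within-module correlation (~0.5, the
planted block mean) far exceeds every one of 1000 size-matched random
modules (p = 1/1001, the minimum attainable), and the fitted supports
reproduce the planted truth exactly (Recovery 1, CE 0). `autoplot(fit)` draws
the cancer-by-module heatmap of W.

A command-line pipeline (subcommands `build-tensor`, `fit`, `annotate`,
`survival`, `simulate`, `evaluate`) is installed at
`system.file("cli", "tscca.R", package = "tscca")`.

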