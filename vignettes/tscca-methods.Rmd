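---
title: "Sparse tensor CCA for multi-cancer miRNA-gene modules: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse tensor CCA for multi-cancer miRNA-gene modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tscca)
```

## The model

Let $X_k \in \mathbb{R}^{n_k \times p}$ and $Y_k \in \mathbb{R}^{n_k \times q}$
be the matched gene and miRNA expression matrices of cancer $k = 1, \dots, M$,
each column standardized to mean 0 and sample standard deviation 1
(denominator $n_k - 1$). The frontal slices of the tensor
$\mathcal{A} \in \mathbb{R}^{p \times q \times M}$ are then the exact sample
Pearson correlation matrices $A_k = X_k^\top Y_k / (n_k - 1)$. We divide by
$n_k - 1$ — rather than keeping the raw cross-product — so that slices are
comparable across cancers with very different sample sizes and so that the
modularity statistic below is a genuine mean absolute correlation in
$[0, 1]$; `build_correlation_tensor(..., scale_correlation = FALSE)` restores
the raw convention.

One module is a rank-1, $\ell_0$-constrained approximation of
$\mathcal{A}$:

$$\max_{u, v, w} \; \mathcal{A} \bar\times_1 u \bar\times_2 v \bar\times_3 w
\quad \text{s.t.} \quad \|u\|_0 \le k_u,\; \|v\|_0 \le k_v,\; \|w\|_0 \le k_w,
\quad \|u\|_2 = \|v\|_2 = \|w\|_2 = 1 .$$

The nonzero genes of $u$, miRNAs of $v$ and cancers of $w$ form the module;
the optimum $d$ of the trilinear form is the module's singular value. The
constraint set couples a combinatorial support choice with a unit sphere, but
each block subproblem has a closed form: for a score vector $z$ (e.g.
$z_u = (\sum_k w_k A_k) v$) the optimum is $\Pi(z, k) / \|\Pi(z, k)\|_2$,
where $\Pi$ zeroes all but the $k$ largest-magnitude entries. Ties at the
$k$-th magnitude are broken toward the lowest index, which makes runs
bit-reproducible.

## The solver and its numerical behaviour

`tscca_rank1()` alternates the three exact block updates. Initialization
follows the classical recipe: $w$ uniform with unit norm, and $(u, v)$ the
leading singular pair of $C = \sum_k w_k A_k$ (computed by LAPACK `svd()`,
which is deterministic, so the default fit needs no seed). Because that
initializer is dense — hence infeasible for the $\ell_0$ budgets — the first
two logged objective values can sit above the first feasible iterate; from
the moment all three blocks satisfy their budgets the objective trace is
non-decreasing, each update being a per-block global maximizer. The trace is
returned with every fit and is asserted monotone (from the third entry) in
the test suite.

Convergence is declared when the max-norm change of all three factors drops
below `tol` (default `1e-6`, cap `max_iter = 1000`); on the benchmark tensors
fits converge in well under 20 iterations. Two identifiability conventions
are fixed: $d \ge 0$ (automatic, since the $w$-update returns
$d = \|\Pi(z_w, k_w)\|_2$), and the joint sign of $(u, v)$ is flipped so that
the largest-magnitude entry of $v$ is positive. The sign *pattern* of $w$ is
left untouched — negative cancer weights are meaningful (they mark cancers
where the module's gene-miRNA correlations are reversed).

The objective is nonconvex and block-coordinate descent only guarantees a
block-wise optimum. A concrete failure mode arises in the benchmark design
itself: a module that appears with means $+0.5$ and $-0.5$ in two slices
contributes *zero* to the uniform-$w$ weighted sum $C$, so the spectral
initializer carries no information about it and, on a minority of random
tensors, the deflated fit stalls in a local optimum that splits or repeats
another module. `restarts = n` reruns the fit from $n$ seeded random unit
triples and keeps the best objective; 5 restarts were always sufficient in
our benchmark runs. The default remains `restarts = 0` so that a plain call
is deterministic without any seed.

A zero score vector mid-iteration (possible on exactly rank-deficient
inputs) raises a classed error rather than silently re-randomizing; with
restarts enabled the failing start is simply discarded.

`tscca()` extracts $r$ modules by deflation,
$\mathcal{A} \leftarrow \mathcal{A} - d \, (u \circ v \circ w)$, and returns
the ordered modules, the $M \times r$ cancer-weight matrix $W$, and the
residual tensor. Deflation telescopes exactly (the test suite reconstructs
the input to $10^{-10}$), but residual entries need not stay in $[-1, 1]$;
the residual is therefore flagged as not-built-from-data. `scca_rank1()` is
the single-matrix special case ($M = 1$, $k_w = 1$) and is used as the
per-cancer baseline.

### Parameters that matter

| parameter | meaning | default | rationale |
|---|---|---|---|
| `k_u` | max genes per module | none (required) | ~100 matches module sizes typical for pan-cancer co-expression studies |
| `k_v` | max miRNAs per module | none (required) | ~10; miRNA families are small |
| `k_w` | max cancers per module | none (required) | set to the expected breadth of sharing; 2 is the oracle value of the benchmark design |
| `tol` | factor max-norm stop | `1e-6` | changes of this size alter no support |
| `max_iter` | iteration cap | `1000` | fits converge in ≤ ~20 iterations in practice |
| `restarts` | extra seeded random starts | `0` | determinism by default; 5 recommended for sign-mixed designs |

Sparsity levels are configuration, not estimation: the package deliberately
exposes them as plain arguments and ships no automatic selection procedure.

## Statistical battery

**Modularity.** For supports $(I, J, K)$,
$\mathrm{Modularity} = \frac{1}{|I||J||K|} \sum_{i \in I, j \in J, k \in K} |C_{ijk}|$,
in $[0, 1]$ on correlation tensors. Its permutation null redraws size-matched
supports uniformly; p-values use the add-one estimator
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{\mathrm{perm}})$, which can
never return 0. `modularity_screen()` applies a Bonferroni threshold
$\alpha / \text{family size}$ across a fit's modules, with the family size
configurable.

**Overlap between modules.** The statistic pools shared elements across the
three axes; the null resamples both supports independently with sizes fixed.
More than one null construction is defensible here; uniform resampling was
chosen as the least-assuming one. In the single-axis case it provably
reduces to the hypergeometric law, which the tests verify.

**Enrichment.** Set enrichment is the right-tailed hypergeometric test with
the analysis universe (the $p$ genes / $q$ miRNAs that entered the tensor) as
the default background — the background can and should be overridden when
annotations cover only part of the universe. Edge enrichment treats
unordered gene pairs (or ordered miRNA × gene pairs) as draws; this
"edge-slot" hypergeometric is the classical approximation, and an
`null = "exact"` mode enumerates all same-size node sets for small
backgrounds, which the tests compare against an independent enumeration. The
degree-aware variant replaces members with same-degree-bin background nodes
(10 log-spaced bins, widened downward when too thin) to acknowledge that hub
genes collect edges under any random set; on regular graphs it provably
coincides with uniform resampling, which is how its calibration is tested.

**miRNA families.** The cooperativity statistic is the largest number of
module miRNAs inside one family, tested against uniform resampling of
equally many miRNAs. A module with no family repeated has statistic 1.

**Three-layer networks.** Module miRNA→gene edges and gene–gene edges are
restricted to module members; the largest connected component (undirected
connectivity; ties broken by size, then smallest node label) is returned
with genes classified as directly targeted vs reached only through other
genes. Directedness matters only for layer assignment, not connectivity —
otherwise a "largest connected subnetwork" would not be well defined on the
mixed graph.

**Survival.** Per (module, cancer-in-support) pair the prognostic score is
the first principal component of the joint standardized gene + miRNA
sub-matrix (sign fixed so the dominant loading is positive; the median split
is sign-invariant anyway). Samples at the median go to the low group — the
convention matters under heavy score ties and is therefore fixed and
documented. The two-group log-rank test is delegated to
`survival::survdiff()` and verified in the tests against a from-scratch
O−E/V implementation; time units are irrelevant to the statistic. All pairs
of one screen form a single Benjamini–Hochberg family. Note that BH is *not*
idempotent on arbitrary already-adjusted vectors (only constant-tail vectors
are fixed points); the tests assert the correct contracts (monotonicity,
permutation equivariance, cap at 1).

## The simulation generator

`simulation_config()` defaults to the canonical benchmark: a
$300 \times 30 \times 4$ tensor, background $N(0, 0.2^2)$, three
$100 \times 10$ planted modules each present in two slices with opposite
block means $\pm 0.5$ (sd $0.2$), and a fourth slice of pure noise. The truth
pools a module's two slices into one cancer set — the factor model absorbs
the sign into $w$. Entries are raw normal draws by default (they can stray
outside $[-1, 1]$ in the tails); `clip = TRUE` produces a valid correlation
tensor when one is required. `simulate_expression()` generates matched
expression matrices whose *empirical* correlation tensor carries the same
blocks, via one latent factor per block with loadings $\sqrt{|\rho|}$, so the
whole pipeline can run end-to-end from TSV files.

What the generator deliberately does **not** emulate: heavy-tailed
expression, sample-size imbalance across cancers, correlated background
(gene-gene co-expression outside modules), overlapping modules, and
missingness. Passing the benchmark therefore demonstrates correctness of the
optimization and scoring machinery, not robustness to real TCGA-scale data
pathologies.

**Scoring.** Modules are compared as sets of (gene, miRNA, cancer) cells.
Recovery is the mean over true modules of the best Jaccard index against any
prediction (1 = every true module found exactly). Clustering Error is
$1 - \text{(max one-to-one matching weight)} / |\text{union of all cells}|$
(0 = perfect; lower is better). The exact matching is computed by branch and
bound, which the tests verify against exhaustive assignment enumeration.
These are the standard tri-cluster conventions; because more than one
convention circulates in the tri-clustering literature, the definitions
(including CE's direction — lower is better) are fixed and documented here.

**Benchmark sizes.** The acceptance suite runs 20 seeded replicates of the
default generator (solver at oracle sparsity $k = (100, 10, 2)$, 5 restarts),
plus 300-replicate calibration loops at $n_{\mathrm{perm}} = 200$ for each
permutation test; these sizes keep the whole suite at a couple of minutes on
one core while leaving Monte-Carlo error well inside the asserted bounds.

## Design choices that were genuinely open

* **Scaling of slices** — correlations, not raw cross-products (above).
* **Oracle $k_w$ for the benchmark** — each planted module spans exactly two
  slices, so the size-matched solver budget is $k_w = 2$.
* **HDF5 vs text for tensor persistence** — the tensor container is a
  long-format TSV with a one-line header: language-portable, diff-able, and
  lossless at full double precision (round-trip asserted at $10^{-12}$).
* **Strict axis matching** — assembling the tensor across cancers errors on
  any gene/miRNA axis mismatch instead of silently intersecting;
  `align_expression_pairs()` performs the intersection explicitly when the
  user wants it.
* **Missing values are rejected**, never imputed: imputation belongs to
  preprocessing, upstream of this tool.
* **miRNA identifiers are opaque strings**; no harmonization between mature
  and precursor forms is attempted.
* **Median ties go to the low survival group**; group sizes can differ by
  more than one under ties, which is reported rather than hidden.
* **The per-miRNA survival screen** is restricted to cancers in the module's
  support by default (`all_cancers = TRUE` lifts the restriction).

## Known limitations

* Block-coordinate descent offers no global-optimality certificate; use
  restarts for designs with sign-mixed modules (the objective value makes
  competing fits directly comparable).
* The deflation residual is not itself a correlation tensor; downstream
  statistics should always be computed against the *original* tensor.
* The hypergeometric edge-enrichment null ignores degree structure — that is
  precisely why the degree-aware permutation variant exists; the two can
  disagree strongly on hub-dominated modules, and the permutation variant
  should be preferred there.
* Modularity compares a module against *size-matched random* modules; it does
  not correct for the background co-expression level of a cancer, which is
  why `basic_modularity()` is reported alongside.
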