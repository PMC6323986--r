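# netenrich

Functional-association networks link proteins that contribute to a shared
biological function, with each link scored by an approximate confidence on a
scale of zero to one, integrated across seven independent evidence channels
(genomic neighborhood, gene fusion, phylogenetic co-occurrence,
co-expression, experiments, curated databases, text mining). `netenrich` is
an R toolkit for two analyses that such networks enable:

1. **Data-driven network modules.** Tightly connected regions of the network
   broadly correspond to functional units, including ones not yet annotated
   in any pathway database. The package computes the confidence-weighted
   **diffusion state distance** (DSD) between all protein pairs — the L1
   distance between expected visit-count profiles of random walks that
   preferentially follow high-confidence edges — clusters the distance
   matrix with **average linkage (UPGMA)**, and emits every cluster with
   between 5 and 200 members as a gene set in its own classification
   framework.

2. **Value-based gene-set enrichment.** For genome-wide input where every
   gene carries a numeric value (log fold change, abundance, a statistic),
   each gene set is tested with the **Aggregate Fold Change (AFC)** test:
   the observed statistic is the mean value over the set's genes, compared
   against means of randomly drawn same-size gene sets from the submitted
   list (enumerated exhaustively when feasible, Monte-Carlo with add-one
   correction otherwise). Large sets, for which subset randomization is
   prohibitively slow, fall back to a two-sided rank-based
   **Kolmogorov–Smirnov** test. Classical hypergeometric
   over-representation analysis is included for plain gene lists. Multiple
   testing is corrected with **Benjamini–Hochberg separately within each
   classification framework** (GO-like collections, network modules,
   per-publication sets), never pooled across frameworks.

Who is it for: anyone with a weighted protein-association edge list (e.g. a
STRING-style download) and a genome-scale measurement, who wants module
discovery and enrichment without a web service — plus a synthetic-data
generator so the whole pipeline is testable offline.

## The statistics in brief

For a network with confidence-weighted adjacency `W`, the walk matrix is
`P = D^-1 W` and the DSD between nodes `u, v` is

```
DSD(u, v) = || (e_u - e_v) (I - P + W_pi)^{-1} ||_1
```

where every row of `W_pi` is the stationary distribution of `P`. This is
the k → ∞ limit of `|| He_k(u) - He_k(v) ||_1` with
`He_k(u) = Σ_{t≤k} e_u P^t`; the finite-k form is kept as an independent
numerical oracle. DSD is a metric on every connected network.

For a gene set S with k genes present in the value table v, AFC tests
`mean(v[S])` against the null of size-k subsets drawn uniformly without
replacement from the submitted genes; the two-sided p doubles the smaller
tail. Monte-Carlo p-values use `p = (1 + #extreme) / (1 + n_perm)`.

## Worked example

```r
library(netenrich)

sim  <- make_modular_network(block_sizes = c(20, 20), seed = 7)
mods <- discover_modules(sim$network)          # DSD -> UPGMA -> 5..200 filter
v    <- make_value_table(sim$network$nodes, planted = sim$blocks[[1]],
                         delta = 2, sd = 1, seed = 8)
res  <- run_enrichment(v, mods$modules, n_perm = 10000, seed = 9)
print(res, n = 4)
```

```
Enrichment results: 17 sets across 1 framework(s)
        framework set_id n_members_in_input statistic direction method
1 network_modules    M15                 20    1.9127        up    AFC
2 network_modules    M16                 20    0.1694      down    AFC
3 network_modules    M13                  9    2.2359        up    AFC
4 network_modules    M14                 17    0.2209      down    AFC
      p_raw    q_bh
1 0.0002000 0.00170
2 0.0002000 0.00170
3 0.0007999 0.00425
4 0.0009999 0.00425
```

Module `M15` is the recovered planted block: its 20 members average a value
of 1.91 (the planted mean shift was 2), and no random same-size set reached
that mean in 10,000 permutations, so the add-one-corrected two-sided p is
2/10,001 and the framework-wise BH q is well below 0.05. The complementary
block `M16` is reported as depleted ("down") relative to the mixed input,
as expected when half the input carries a positive shift.

A command-line interface wrapping the same functions ships in
`inst/scripts/netenrich.R` with subcommands `simulate`, `cluster`,
`enrich`, and `ora` (exit codes: 0 success, 2 input error, 3 numerical
failure); every run writes a `manifest.json` sufficient to reproduce its
outputs exactly.

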