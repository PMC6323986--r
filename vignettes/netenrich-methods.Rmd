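---
title: "Methods: network modules and value-based enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network modules and value-based enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netenrich)
```

This vignette is the package's own account of its methods: the models and
their assumptions, the parameters that matter, the numerical choices, and
what the synthetic benchmarks do and do not demonstrate.

## The network model

An association network links proteins that jointly contribute to a
function; a link does not require physical contact. Evidence arrives
through seven independent channels (genomic neighborhood, gene fusion,
phylogenetic co-occurrence, co-expression, experiments, curated databases,
text mining), each scored as a confidence in [0, 1], optionally split into
a direct and a transferred (cross-organism) sub-score. Absent evidence is
scored 0, never missing.

**Channel combination.** Channels are integrated by the noisy-OR rule: each
enabled score is corrected for the prior probability `p` of a random pair
being linked, `s' = max(0, (s - p)/(1 - p))`, and the combined confidence
is `S = 1 - (1 - p) * prod(1 - s'_i)`. This treats channels as independent
witnesses: the association is "false" only if every channel's corrected
evidence fails. The rule is permutation-invariant, monotone in every
enabled score, reduces to the identity for a single channel, and never
falls below the strongest enabled channel at prior 0. The default prior is
0 — it keeps small examples analytic and defers the organism-specific prior
to configuration. How direct and transferred sub-scores are merged within a
channel is a convention rather than a published constant; here a
transferred sub-score simply enters the same noisy-OR product as one more
independent term, which is associative with the cross-channel combination.

**Two constants are fixed, not tunable.** Curated-database associations
bypass benchmark calibration and all receive the uniform confidence 0.900,
and the "highest" confidence preset filters at 0.900. The presets "high"
(0.700), "medium" (0.400) and "low" (0.150) are conventional defaults and
can be overridden.

**Dialects.** Edge lists are accepted with integer scores 0–1000 (download
dialect, divided by 1000) or floats in [0, 1]; auto-detection picks the
integer dialect iff any score exceeds 1. Self-loop rows are skipped with a
warning rather than failing the whole file, since they are occasionally
produced by upstream identifier mapping.

## Diffusion state distance

For walk matrix `P = D^-1 W` (rows normalized by weighted degree), the
k-step diffusion state of node `u` is `He_k(u) = sum_{t=0..k} e_u P^t`, the
vector of expected visit counts. The finite-k DSD is the L1 distance
between diffusion states; its limit has the closed form

`DSD(u, v) = || (e_u - e_v)(I - P + W_pi)^{-1} ||_1`,

with `W_pi` the rank-one matrix whose rows are the stationary distribution
(proportional to weighted degree, since the confidence walk is reversible).
The converged form is the default because it is parameter-free and exact up
to the linear solve; the finite-k recursion is retained as an independent
oracle, and the two agree to better than 1e-6 at k = 10^4 on the test
graphs (up to 50 nodes). Confidence weighting means walks preferentially
traverse high-confidence edges; uniform rescaling of all weights cancels in
the row normalization and leaves DSD unchanged.

Numerical choices:

* The dense solve is used up to 5,000 nodes. Above that, the fundamental
  matrix is built column-wise by damped Richardson iteration
  (`x <- x + 0.5 (b - Ax)`, tolerance 1e-8): for a reversible walk the
  operator's spectrum lies in (0, 2], so the damped iteration converges on
  every connected network, bipartite ones included (where the plain
  power-series recursion would oscillate).
* Disconnected input is an error, never imputed with infinite distances:
  the caller restricts to the largest connected component explicitly
  (`largest_component()`), so the restriction is a visible, logged step.
* Whether to apply a confidence cutoff before DSD is left to the caller
  (`discover_modules(cutoff = ...)`); the default uses the full score
  range, and the manifest records the choice.

## Module discovery

The DSD matrix is clustered agglomeratively with unweighted average linkage
(UPGMA), which is monotone (merge heights never decrease). Every internal
node of the dendrogram whose leaf set has between `min_size = 5` and
`max_size = 200` members becomes one gene set — all hierarchy levels are
eligible, not a single cut, so the collection is nested and multi-scale;
the laminar structure is harmless downstream because enrichment corrects
within the framework. Below 5 members a module carries too little signal
for set-level testing; above 200 it is too unspecific to interpret. The
clustering step is delegated to `stats::hclust`, whose tie handling is
deterministic; exact distance ties are vanishingly rare on real-valued DSD
matrices, and the oracle tests avoid them by construction. Identical member
sets are deduplicated keeping the lowest-height instance.

## Enrichment statistics

**Aggregate Fold Change (AFC).** The statistic for set S is the mean of the
user's values over `S ∩ input`; the null is the mean of equally sized sets
drawn uniformly without replacement **from the submitted gene list** — not
from any larger universe, so the test asks "is this set's average extreme
relative to the data the user actually submitted". When
`choose(n, k) <= exhaustive_limit` (default 100,000) the null is enumerated
exactly; otherwise `n_perm` (default 10,000) Monte-Carlo draws are used
with the add-one correction `p = (1 + #extreme)/(1 + n_perm)`, which keeps
p-values positive and unbiased against optional stopping. Sidedness is not
a published constant; the package reports both one-sided tails and a
two-sided p equal to twice the smaller tail, capped at 1, with the smaller
tail as the reported direction. Adding a constant to all values shifts the
statistic but no p-value.

**KS fallback.** For sets whose effective size exceeds
`large_set_threshold` (default 1,000, chosen so exhaustive/Monte-Carlo AFC
stays tractable at desktop scale), values are converted to ranks (ties get
the average rank) and in-set ranks are compared to out-of-set ranks with a
two-sided two-sample Kolmogorov–Smirnov test, exact when
`k(n-k) <= 10^4`. Whether the published fallback is two-sample or
one-sample against the pooled rank distribution is ambiguous; two-sample is
the default here, and the one-sample variant (in-set ECDF against the
pooled-rank ECDF, exhaustive p when feasible) is available as
`mode = "one_sample"`. Neither mode claims numeric equality with any
external service. The two differ visibly in corner cases: a single in-set
gene at the extreme rank of 10 gives D = 1 two-sample but D = 0.9
one-sample.

**ORA.** For plain gene lists, the upper-tail hypergeometric probability of
the observed overlap, with the set intersected with the declared background
first.

**Correction.** Benjamini–Hochberg is applied separately within each
classification framework and never across frameworks: frameworks overlap
heavily (a GO term, a network module and a publication set may cover the
same genes), and pooling would couple their corrections. The library never
thresholds significance; filtering (e.g. `q < 0.05`) belongs to the
reporting layer.

## The synthetic generator

`make_modular_network()` draws a planted-partition graph: within-block
pairs are edges with probability `p_in = 0.8` carrying Beta(8, 2)
confidences, all other pairs with `p_out = 0.05` carrying Beta(2, 8). The
Beta shapes mimic the bounded, skewed shape of confidence scores without
claiming any database's empirical distribution. The defaults — two blocks
of 20 at 0.8/0.05 — are the study condition for module recovery: strongly
separated modules that a correct pipeline must find (best-match Jaccard
≥ 0.9 in at least 95% of 50 seeded replicates in the acceptance suite).
`make_value_table()` plants enrichment signal: background values
Normal(0, sd), planted values Normal(delta, sd); the power condition is
delta = 2, sd = 1, 20 planted genes among 1,000, and delta = 0 yields the
null used for the type-I check (observed AFC rejection rate at nominal 0.05
must lie in [0.03, 0.07] over 2,000 random size-20 sets).

What the generator does **not** emulate: organism-scale graphs (tens of
millions of proteins), empirical confidence-score distributions, hub/degree
heterogeneity, overlapping or nested true modules, and correlated gene
values. Passing the synthetic benchmarks therefore shows the pipeline is
correct and well-calibrated under clean, favorable conditions — not that
module recovery at these rates transfers to real proteomes.

## Problem sizes and runtime choices

The shipped tests run DSD oracles on graphs of up to 50 nodes with the
finite-k check at k = 10^4; exact-vs-Monte-Carlo AFC agreement on
`choose(16, 4) = 1,820` subsets at 10^5 draws; the type-I simulation with
2,000 sets at 999 permutations each; power and module-recovery conditions
with 50 seeded replicates. These sizes make every acceptance property
rerunnable on a single CPU in well under an hour while keeping the
Monte-Carlo standard errors far below the tested tolerances.

## Known limitations

* DSD requires connectivity; networks with many small components lose all
  cross-component information after restriction.
* Dense DSD is O(n^3)/O(n^2) memory; organism-scale use needs the iterative
  path and patience, or a pre-filter by confidence.
* Identifier matching is exact-string and case-sensitive by design:
  namespace mismatches fail loudly with examples from both sides rather
  than silently shrinking sets.
* AFC assumes exchangeability of genes under the null; correlated values
  (co-regulated genes) inflate its type-I error, as for any subset
  randomization test.
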