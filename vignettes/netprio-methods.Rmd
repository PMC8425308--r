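---
title: "Network-based gene prioritization and how netprio benchmarks it"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based gene prioritization and how netprio benchmarks it}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netprio)
library(dplyr)
```

## The problem

Given a protein–gene interaction (PGI) network and a handful of genes
already known to cause a disease (the *seed genes*), which other genes are
good candidates? All the prioritizers in this package rest on the
guilt-by-association premise: genes near known disease genes in the
network tend to share function, so variation in them can produce similar
phenotypes. The package implements seven seed-based prioritizers spanning
the three mechanistic families in common use — propagation, embedding, and
seed-association heuristics — plus a degree-centrality baseline, and the
benchmarking harness needed to decide which of them to trust for a given
disease. Whether that premise holds for *your* disease is an empirical
question; the harness exists because the answer differs by disease.

## Data model

A network is a simple undirected graph over opaque string ids: adjacency
`A` (sparse, symmetric, zero diagonal), degree `k` = row sums, `n` nodes
and `m` edges. Scored edge tables (STRING-style confidence scores) are cut
to binary edges with `score_threshold` at load time. Zero-degree nodes are
kept in the node set but never receive propagation mass other than
restart; they are logged, not dropped.

The heterogeneous network adds a bipartite gene–disease association layer
`A_PD` (n × d) and a disease–disease similarity layer `A_DD` (d × d),
combined as the expanded adjacency

$$A^{expand} = \begin{bmatrix} A & A_{PD} \\ A_{PD}^T & A_{DD} \end{bmatrix},$$

on which heterogeneous variants run unchanged, treating disease nodes as
ordinary vertices.

## The prioritizers

**RWR.** Random walk with restart iterates
$p_t = (1-r)\,W p_{t-1} + r\,p_0$ with $W = A D_k^{-1}$ column-stochastic
and $p_0$ uniform over the seeds, until the L1 change is below $10^{-8}$.
The converged probability is the score. The restart probability `r`
defaults to 0.5, with the conventional tuning grid 0.1–0.9 in steps of 0.2
available (`rwr_grid()`). Columns of zero degree are *dangling*: the walk
mass sitting on them is returned to the restart distribution each step, so
total probability is conserved. **RWRH** is the same fixed point on the
column-normalized expanded adjacency (whole-matrix normalization; restart
mass on seed genes only by default, with an optional split onto the query
disease node).

**N2V / N2VH.** node2vec samples `n_walks` second-order random walks of
length `l` per node, with return bias `1/p` and in–out bias `1/q`, and
trains a skip-gram (negative-sampling) embedding treating walks as
sentences. A gene's score is its maximum cosine similarity to any seed
vector. Defaults: 20 walks × 80 steps, p = q = 1, 128 dimensions, window
10, 5 epochs, 5 negative samples, all exposed. The skip-gram trainer is
compiled code, single-threaded, and fully deterministic under its seed;
walks that hit a dead end stop early rather than restart. Window size and
epoch count have no canonical value in the gene-prioritization literature;
the defaults above are the word2vec conventions.

**DIAMOnD.** Grows a module outward from the seeds. At each step every
non-seed node adjacent to the current set is scored by the hypergeometric
probability of its observed number of links to the set,

$$p = \frac{\binom{|S_t|}{k_{st}}\binom{n-|S_t|}{k-k_{st}}}{\binom{n}{k}},$$

and the lowest-p node joins; its step is its rank. This implementation
evaluates the *point* mass ("connecting exactly"), with the original
upper-tail statistic behind `tail = TRUE`. The seed-weighted variant
(weight α ≥ 1 on original seeds) inflates the counts by (α−1)|S| and
(α−1)k_s. Ties in p are broken by higher connectivity to the seed set and
then lexicographic id — deterministic and counted. Genes never selected
within `max_steps` (default 5000) have no rank; when a complete ranking is
required (e.g. hits@10%) they are placed behind all selections with a
shared averaged tail rank, and the raw `na` is preserved in reports.

**GenePanda.** Uses the degree-adjusted distance
$d^{adj}_{ij} = d_{ij}/\sqrt{k_i k_j}$ (geodesic over geometric-mean
degree) and scores a gene by the mean adjusted distance to the whole
network minus the mean adjusted distance to the seeds — positive when a
gene sits closer to the seeds than to the network at large. Distances are
computed on the largest connected component (real interactomes are ~99%
one component); nodes outside it are unranked and a seed outside it is an
error.

**IDLP.** Learns a gene–disease matrix Y by alternating label propagation:
update the gene network with current knowledge of the associations
(`A* = A_norm + γ Y Yᵀ`), propagate (`Y = β (I − αA*)^{-1} A_PD`), update
the disease-similarity network (`A_DD* = A_DD_norm + γ' Yᵀ Y`), propagate
on the disease side (`Y = β' A_PD (I − α'A_DD*)^{-1}`). A query-disease
column (1 at seeds) is appended to `A_PD` before iterating, and a zero
row/column is added to the similarity layer so the disease-side product is
conformable; Y starts from uniform(0,1) noise under a recorded seed, runs
a fixed 20 iterations by default, and the query column of Y is the score.

Two numerical points deserve emphasis. First, the update equations as
conventionally printed in the label-propagation literature admit a
resolvent-free reading; both are provided (`literal = TRUE` for the
resolvent-free form), the resolvent reading being the default because it
is the closed form of iterated propagation. Second, a propagation operator
must have spectral radius ≤ 1. The raw update `A_norm + γ Y Yᵀ` violates
this as soon as ‖Y‖² exceeds (1/α − 1)/γ, at which point the resolvent
amplifies instead of smoothing and the alternation enters a limit cycle —
we observed exactly this on 30-gene fixtures with α = 0.5, γ = 0.1.
`idlp()` therefore symmetrically re-normalizes the updated matrices before
each propagation (the same K^{-1/2} M K^{-1/2} normalization the raw
layers receive), which restores geometric convergence; the per-iteration
Frobenius change is returned as an attribute so convergence is always
inspectable. The raw behaviour is available with `renormalize = FALSE`.
Hyperparameters default to α = α' = 0.5, β = β' = 1, γ = γ' = 0.1; no
published values exist for them.

**Degree baseline.** Score = degree, seed-independent. Any seed-based
method has to beat it to be worth running.

## Ranking conventions

Scores are ranked descending with *average* (fractional) ranks for ties —
the convention under which two equal-degree genes at the same position
share, say, rank 7505.5 rather than an arbitrary order. Rank sums are then
invariant (`n(n+1)/2`), which the tests exploit. During cross-validation
the remaining seeds are excluded from the candidate list before ranking
(configurable), so a left-out gene competes only against actual
candidates.

## Pathway modularity

`two_community_modularity()` scores a node subset against the rest of the
network as two communities: Q = sᵀBs/(4m) with s = −1 inside the subset,
B_ij = A_ij − k_i k_j/(2m) off the diagonal. The default zeroes B's
diagonal; this deviates from the standard Newman matrix (B_ii =
−k_i²/(2m)) by the constant Σk²/(8m²) in Q, so *contrasts* between
pathways are identical under either convention and the standard diagonal
is available via `diagonal = "standard"`. Which convention a given
published analysis used is often ambiguous; both are exposed for that
reason.

## The benchmarking harness

**LOOCV.** Each seed is left out in turn, the algorithm runs on the rest,
and the left-out gene's rank is the fold metric; median and mean summarize
(midpoint convention for even counts, hence `.5` medians). On a
heterogeneous network the (query disease, left-out gene) association edge
is removed for the duration of the fold — otherwise the disease layer
hands the answer back — and restored bitwise afterwards; the tests assert
both directions. Folds in which an algorithm assigns no rank (DIAMOnD past
its step budget) are reported `na` and summarized both ways: over
available folds, and with `na` counted at worst-case rank.

**Random-seed experiments.** Prioritizers can look good by ranking hub
genes well no matter what the seeds are. Drawing many random seed sets
(reference protocol: 1000 trials × 10 seeds) and taking each node's median
rank across trials isolates this seed-independent component; its Spearman
correlation with degree is the degree-bias diagnostic, and a degree-decile
table supports plotting. Embeddings are trained once per network and
re-scored per trial, since training does not see the seeds.

**GWAS validation.** SNPs are mapped to genes by position (±1000 bp around
the gene region, 1-based inclusive; BED input converted on read; a SNP may
map to several overlapping genes). For the top-N ranked genes the pooled
SNP p-values are Benjamini–Hochberg adjusted (the "FDR-adjusted" procedure
is BH, recorded in the output metadata), and each gene's pass/fail
indicator vector is tested against zero with a one-sample t-test; test
p < 0.05 calls the gene validated. That t-test is degenerate for constant
indicator vectors and single-SNP genes; those cases are resolved
deterministically (all-zero → never validated; all-one or a sole passing
SNP → validated) and flagged. Separately, externally confirmed genes are
summarized by median rank and hits within the top 10% of predictions.

## Synthetic fixtures and what they do (not) show

`simulate_modular_network()` overlays Bernoulli(p_within) modules on a
preferential-attachment backbone. Defaults — 500 genes, attachment 10
(mean degree ≈ 20, matching the density and heavy tail of curated human
interactomes), one 30-node module at p_within = 0.5, 10 seeds drawn from
the module — are the conditions under which all stochastic properties are
evaluated. `simulate_hetero_fixture()` adds 20 background diseases (GDA
density 0.01, similarity density 0.2) and a query disease associated with
exactly the seed genes. `simulate_gwas()` plants uniform p ≤ 10⁻⁸ SNPs in
designated genes among uniform nulls on a toy genome.

These fixtures reproduce the *structural* premises the algorithms rely on
(heavy-tailed degrees, dense functional modules, a disease layer that
shortcuts between associated genes, GWAS signal localized at true genes).
They do not emulate database-specific edge semantics, literature bias in
association layers, linkage disequilibrium, or the 19k-gene scale of real
interactomes. A passing suite therefore certifies the algorithms and
harness are implemented correctly and behave as the theory predicts under
controlled conditions — not that any particular algorithm will win on a
given real disease. That question is what the harness itself is for.

On these fixtures the expected qualitative results, which the test suite
recomputes, are: propagation methods rediscover left-out module seeds
within the top 10% of genes and far ahead of the degree baseline; the
restart walk's random-seed median ranks correlate strongly and negatively
with degree while the embedding's barely correlate; and GWAS validation
recovers exactly the planted genes at BH FDR 0.05.

## Problem sizes and numerical choices

The suite runs everything at desk scale by design: oracle comparisons use
50 random graphs of ≤ 50 nodes (dense closed-form solves), the rescan
oracle for DIAMOnD uses ≤ 100 nodes, distance oracles ≤ 200, the planted
module study 20 replicates of the 500-gene fixture, and the degree-bias
study one 600-gene scale-free network with 200 trials — large enough for
stable Spearman estimates, small enough to keep embedding training to a
couple of minutes. Convergence tolerances: RWR stops at L1 change < 1e−8
(with a 10 000-iteration safeguard that errors, reporting the residual,
rather than returning silently); oracle agreement is asserted at 1e−6 for
iterative-vs-closed-form and 1e−12 for exact combinatorial identities. All
randomness funnels through explicit integer seeds: R's RNG for fixtures
and trials, a dedicated splitmix/xorshift stream in the compiled walk
sampler and trainer so results are bit-reproducible regardless of R's RNG
state.

## Known limitations

- DIAMOnD recomputes candidate p-values per step with an incremental
  link-count update; it is quadratic in selections × neighbourhood size
  and intended for ≤ 5000 steps, as in the reference protocol.
- IDLP solves dense linear systems (O(n³) per iteration); fine at fixture
  scale, slow on full interactomes — the reference protocol's fixed
  20 iterations exists for the same reason.
- The GWAS validation t-test is the published procedure, kept as
  specified; a binomial or gene-level association test would be more
  defensible statistically and is deliberately not substituted.
- The heterogeneous embedding (N2VH) retrains per LOOCV fold because the
  expanded graph changes with the removed association edge; expect it to
  dominate fold runtime.
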