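---
title: "Detecting condition-specific modules in multi-condition networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting condition-specific modules in multi-condition networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(7)
```

## The problem

Gene networks built under different biological conditions — disease stages,
subtypes, treatments — share their gene set but not their wiring. A
*condition-specific module* is a gene set that is densely interconnected in
one condition's network and only sparsely connected in all the others;
such modules are candidate drivers of what distinguishes that condition.
Single-network community detection cannot find them: a module that is dense
everywhere is a perfectly good community but carries no condition
information.

`mogacsm` treats the conditions as a multiplex network
$G = \{G_1, \dots, G_M\}$: $M$ weighted undirected layers over one ordered
vertex set $V$, $|V| = n$, with symmetric nonnegative weights $w^m_{ij}$ and
no self-loops.

## Objectives and the Pareto front

The quality of a hard partition $\{C_1,\dots,C_k\}$ of $V$ inside layer $m$
is its (weighted) Newman–Girvan modularity

$$Q_m = \frac{1}{2W_m} \sum_{ij} \left( w^m_{ij} -
\frac{s^m_i s^m_j}{2W_m} \right) \delta(c_i, c_j),$$

with $s^m_i$ the node strengths and $2W_m$ the total weight. For a target
condition $m$ the package maximizes the $M$-dimensional objective vector

$$F_m = Q_m, \qquad F_i = 1 - Q_i \;\; (i \neq m),$$

so a good solution is modular in the target layer and as non-modular as
possible in every other layer. With several objectives there is generally no
single best partition, only a *Pareto front* of nondominated trade-offs:
vector $a$ dominates $b$ when $a_i \ge b_i$ everywhere and $a_i > b_i$
somewhere. The search returns the whole front; the reported solution is the
front member with maximum $F_m$, i.e. maximum modularity in the target
layer, with ties broken toward fewer modules.

Modularity on an edgeless layer is undefined ($2W_m = 0$); the package
raises an error rather than inventing a value. Weighted modularity
(strengths in place of degrees) is used throughout so binary benchmark
layers and weighted co-expression layers run through the same code; Q of a
partition that lumps everything into one module is exactly 0, a useful
sanity anchor.

## Encoding and decoding

Individuals use the locus-based adjacency representation: a genotype
$P = (g_1, \dots, g_n)$ assigns every node $i$ one of its neighbors $g_i$ in
the *target* layer. The encoded partition is the set of connected components
of the undirected edge set $\{(i, g_i)\}$, computed with a disjoint-set
forest (union by rank, path compression; implemented in C++ since decoding
sits in the innermost loop). Component labels are assigned 1..k in order of
the smallest node index each component contains, so decoding is
deterministic and label-stable.

Two degenerate choices had to be fixed. A node isolated in the target layer
has no neighbor to point to; it carries the self-locus $g_i = i$ and decodes
to a singleton module, the only convention that keeps decoding total.
Feasibility is defined against the target layer only, not the union of
layers: modules are sought as subgraphs of $G_m$.

## The evolutionary loop

The optimizer is a standard elitist multi-objective GA in the NSGA-II
family:

1. **Initialization** — each locus drawn uniformly from its node's
   neighbors in the target layer.
2. **Parent selection** — binary tournament on (nondomination rank,
   crowding distance).
3. **Uniform crossover** (probability 0.8) — a random binary mask picks
   each child locus from one parent; feasibility is inherited.
4. **Point mutation** (probability 0.2) — one uniformly chosen locus is
   resampled from its node's neighbors. A single-locus change keeps
   offspring near their parents, which is what lets the search refine a
   partition; resampling many loci at once turns the GA into a random walk
   and measurably flattens the benchmark curve.
5. **Replacement** — parents and offspring are pooled, nondominated-sorted,
   and truncated back to the population size by (rank, crowding); 10% of
   each generation's reproduction slots are unmodified copies of the
   current best individuals ("elite reproduction"). Because selection is
   elitist and the best-$F_m$ member always sits on the retained boundary
   of the front, the best target-layer Q is non-decreasing across
   generations — asserted per run in the tests.

Termination is a fixed generation count; no convergence-based early stop.
All randomness flows from one seeded generator per run and the seed is
recorded in the run log, so every result file can be regenerated
bit-identically.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `population_size` | 100 | individuals per generation (unstated in the source study; standard NSGA-II practice) |
| `generations` | 500 | generational cycles |
| `crossover_rate` | 0.8 | probability a child is produced by uniform crossover |
| `mutation_rate` | 0.2 | probability an offspring gets a point mutation |
| `elite_fraction` | 0.10 | share of reproduction slots filled by elite copies |
| `seed` | none | run seed; drawn and recorded when absent |

The crossover/mutation/elitism values are the published study conditions; a
high crossover rate with a low mutation rate is the usual GA recommendation
and the benchmark curves are flat in a wide neighborhood of these values.

## The benchmark generator

The classic planted-partition construction: $n = 128$ nodes in $k = 4$
equal communities, expected total degree 16, expected external degree
`kout`. Edges are Bernoulli with
$p_{in} = (16 - k_{out})/(n/k - 1)$ and $p_{out} = k_{out}/(n - n/k)$.
As `kout` grows from 1 to 8 the communities blur and detection gets harder;
at `kout = 8` half of every node's edges leave its community and the
planted partition's own expected modularity is
$(16-8)/16 - 1/4 = 0.25$. Generation is Bernoulli (expected degree) rather
than exactly regular — the construction is described by its *average*
degree, and the realized mean degree is within 5% of 16 across seeds.

Each benchmark multiplex pairs the planted graph (layer 1, the target) with
one or more *size-matched random companions*: Erdős–Rényi $G(n, m)$ graphs
with exactly the same node and edge counts but no structure. "Size-matched"
is matched node+edge counts, not degree-matched: the companion's role is to
carry no modular signal, and a degree-preserving shuffle of a near-regular
planted graph is available through `degree_preserving_shuffle()` if a
stricter companion is wanted. Recovery is measured by the modularity of the
selected solution in the planted layer and by NMI against the ground truth.

What the generator does *not* emulate about real co-expression data:
weighted and heavy-tailed degree distributions, correlated layers (real
conditions share most of their wiring), and modules of heterogeneous size.
Passing the benchmark therefore shows the optimizer recovers planted
structure under noise, not that any particular biological network will
yield clean modules.

## Significance of specific modules

Observed modules are tested against a permutation null: every layer is
randomized by degree-preserving double-edge swaps (default 10× the edge
count, the standard mixing heuristic; on weighted layers each edge carries
its weight along, preserving both the degree sequence and the weight
multiset), the full GA is re-run on each randomized multiplex, and the
modules it finds are scored. The per-module score is the density
difference

$$s(C) = d_m(C) - \frac{1}{M-1}\sum_{i \neq m} d_i(C),$$

where $d_i(C)$ is the mean pairwise weight of $C$ in layer $i$ — this
score is this package's construction (the permutation framework needs *a*
score and the source study does not define one; density difference is the
quantity its stage-specific figures actually display). Empirical p-values
use the add-one formula $p = (1 + \#\{null \ge obs\})/(1 + |null|)$, which
cannot return 0 from finitely many permutations, and are
Benjamini–Hochberg adjusted; $q \le 0.05$ is called significant. Under a
structureless multiplex the pipeline's p-values are approximately uniform
and BH flags essentially nothing — this calibration is part of the test
suite.

## Expression features

For downstream classification, modules are summarized per sample by their
*activity score*: genes are z-scored across samples (sample standard
deviation, $n-1$; the convention is recorded here because either choice is
defensible and the source is silent), and a module's score in sample $j$
is the mean z-scored expression of its genes. One column per module yields
the sample × module feature matrix. A plain co-expression layer builder is
included (absolute Pearson correlation, zero diagonal, optional hard
threshold); partial-correlation filtering of indirect edges is deliberately
out of scope and the threshold is documented as not being such a filter.

## Numerical and design choices

- Duplicate edges in an input file (either orientation) are an error, not
  averaged: silent averaging hides upstream data bugs.
- Weights are used as given; binary networks are just $w \in \{0,1\}$.
- Crowding distance: boundary members get $+\infty$ per objective; an
  objective with zero range across the front contributes nothing.
- Ties in final selection: maximum $F_m$, then fewer modules, then lowest
  index — fully deterministic.
- The swap-based shuffler counts *successful* swaps and caps attempts at
  100× the requested count, warning if the budget is exhausted (only
  pathological degree sequences get near the cap).
- `generations = 0` short-circuits to the best random individual, which
  gives a cheap control for how much the evolution itself contributes.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run the benchmark at its
native size (n = 128, 4 communities, degree 16) with the GA at its full
default parameters — 10 independent runs per noise level in the tests, 20
in the script — and the layer-count robustness check at the same defaults
with 5 runs per setting. The null-calibration check uses a 64-node
two-layer random multiplex with a deliberately small GA (population 30, 60
generations) and 50 randomizations: the null needs the same procedure, not
the same polish. Because population evaluation is sparse C++, a default
benchmark run costs a few seconds and the whole suite minutes on one core;
the measured endpoints are mean Q ≈ 0.68 at `kout = 1` and ≈ 0.20 at
`kout = 8`.

## Known limitations

- Hard, non-overlapping modules only; one condition per run.
- The GA is stochastic: at high noise (`kout ≥ 6`) run-to-run spread in Q
  is a few hundredths, and the search undershoots the planted partition's
  modularity (≈ 0.20 recovered vs 0.25 planted at `kout = 8`) — report
  means over seeds, not single runs.
- Many companion layers weaken Pareto selection: with 10 structureless
  layers the objective vector carries 10 noise coordinates, the chance that
  one solution dominates another decays roughly like $2^{-M}$, most of the
  population ties at rank 0, and optimization pressure on the target layer
  comes mostly from crowding boundaries. Recovered Q at `kout = 3`
  therefore drops by roughly 0.07–0.09 going from 2 to 10 random layers at
  default settings (and further at reduced population) — a known
  many-objective limitation of plain dominance sorting.
- Dense $n \times n$ layer storage: fine for thousands of genes, not for
  $10^5$-node graphs.
- Significance re-runs the GA per randomization; 100 randomizations at
  realistic sizes is hours of compute. Reduce the GA budget for the null
  runs (the null needs the same *procedure*, not the same polish) or the
  randomization count, and note that fewer randomizations coarsens the
  attainable p-values.

## A worked example

```{r example, eval = FALSE}
library(mogacsm)

bench <- make_benchmark_multiplex(benchmark_spec(kout = 1, seed = 11))
res <- run_moga_csm(bench$multiplex, m = 1,
                    ga_params(population_size = 50, generations = 300,
                              seed = 42))
res
#> MOGA-CSM result: target layer 1, Q_target = 0.6955, 4 module(s), ...
nmi(res$partition, bench$planted)
#> [1] 1
```
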