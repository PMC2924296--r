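---
title: "Quantifying indirect effects and mediator proteins in interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying indirect effects and mediator proteins in interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medianet)
```

## The problem

Proteins implicated in different diseases are often not directly linked in
the protein–protein interaction (PPI) network, yet their disease phenotypes
co-occur or interact clinically. One mechanistic reading is that influence
travels *indirectly*, through shared interaction partners. `medianet`
makes that reading quantitative: it scores every walk-based indirect effect
between two sets of disease proteins and decomposes the two-step effects
over the individual mediator proteins that carry them, so the mediators can
be ranked and compared against classical centrality and against functional
annotation.

## The effect model and its assumptions

The analysis network is an undirected, unweighted simple graph: no
self-interactions, no duplicate records, no edge weights. Influence is
assumed to spread from every neighbour of a protein with equal probability,
which fixes the one-step effect of source $j$ on receiver $i$ at

$$a^1_{ij} = \begin{cases} 1/D_i & \{i,j\} \in E \\ 0 & \text{otherwise,}\end{cases}$$

where $D_i$ is the receiver's degree. The direction convention matters and
is a common source of bugs: $a_{ij}$ is the effect **of $j$ on $i$** and is
set by the *receiver's* degree. The effect matrix is therefore
receiver-row indexed, and each row of a non-isolated receiver sums to 1 —
each protein has one unit of incoming influence, split among its
neighbours. `effect_matrix()` preserves this conservation law to machine
precision for every step count, and the test suite asserts it at `1e-12`.

Indirect effects are multiplicative along a pathway and additive across
pathways, so the $n$-step effect matrix is exactly the $n$-th matrix power
of $a^1$. Two consequences are worth spelling out:

- The sum runs over *walks*, not simple paths, so for even $n$ the diagonal
  $a^n_{ii}$ is non-zero (a walk can bounce back). Diagonal entries are kept
  in the matrix but excluded from every summary index — topological
  importance, set-level effects and mutual dependence all measure effects
  *on other nodes*.
- Degrees are always taken in the single analysis network passed to the
  function. Mediation between disease modules can therefore be scored in
  the full PPI network or in the DPIP subnetwork, and the two give
  different numbers; the package defaults to whatever network the caller
  supplies, and the command-line driver defaults to the full input graph.

On top of $a^n$ the package computes the topological importance
$TI^n_j = \sum_{i \ne j} a^n_{ij}$, the aggregate set effect
$A^n_{D1;D2} = \sum_{i \in D2}\sum_{j \in D1, j \ne i} a^n_{ij}$, and the
two-direction mediator contribution
$M^2_k(i,j) = (1/D_k)(1/D_j) + (1/D_k)(1/D_i)$ for a common neighbour $k$.
The $M^2$ values decompose the symmetric two-step effect exactly:
summed over all common neighbours of $i$ and $j$ they equal
$a^2_{ij} + a^2_{ji}$, an identity the tests verify against the
matrix-power route on every fixture.

Two conventions were genuinely open and are resolved as follows, with both
options exposed:

- **Step averaging in $TI^n$.** Part of the index's literature averages the
  per-step totals over lengths $1..n$; the prose definition used here sums
  effects at exactly $n$ steps. `topological_importance()` defaults to
  `mode = "exact_n"` and offers `"cumulative_mean"`.
- **Directionality of set effects.** $A^n$ is directional (sources on
  receivers); column sums of the contribution matrix identify the most
  influenced receiver-set protein, row/column choice via
  `most_influenced(side = )`. A symmetric total is simply the sum of the
  two directed calls.

## Disease subnetworks

A disease annotation maps protein ids to free-form disease-class labels; a
protein with at least one label is a disease protein (DP) and is never
reclassified as an interacting partner (IP), even when it neighbours other
DPs. IPs are the non-disease neighbours of DPs; everything else is
`other`. From a PPI graph and an annotation, `build_dpip()` keeps DPs and
IPs with only the DP-incident edges (no IP–IP links by construction), and
`build_ip()` keeps the IPs with exactly the IP–IP links the DPIP network
discards — so the two edge sets are disjoint and jointly cover every edge
that does not touch an `other` node. `disease_pair_linkage()` classifies
each label pair as directly linked, indirectly linked (a two-step path
joins the sets) or unlinked, with shared multi-label proteins reported
separately and excluded from the path test.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `n` (step count) | 2 | walk length for effects; two-step effects are the analysis focus, since longer walks are increasingly hard to interpret mechanistically |
| `mode` in `topological_importance()` | `"exact_n"` | step-averaging convention, see above |
| analysis network | caller's graph (`--network ppi` in the CLI) | which degrees enter the effect model |
| `top` in `rank_mediators()` | all (CLI: 11) | how many ranked mediators to keep for downstream functional comparison |
| `sparse` in `effect_matrix()` | auto above 3000 nodes | dense and sparse code paths give identical values; the switch is purely a memory/speed trade |

Ties in every ranking (centrality ranks, mediator ranks) use competition
ranking — tied values share the best applicable rank — with deterministic
lexicographic tie-breaks on protein id where a single winner is needed.

## The synthetic data generator

Real interactome analyses of this kind depend on particular database
snapshots of curated interactions and disease-gene catalogues, which are
neither small nor stable. The package therefore ships two code-generated
data sources:

- `toy_disease_network()` — a fixed 13-node network with two disease
  proteins (degrees 3 and 7) and two mediators (degrees 2 and 5), chosen as
  the minimal topology consistent with a full set of hand-checkable
  values: every one-step, pathway, two-step, mutual-dependence and
  mediator-contribution number on it reduces to small rational arithmetic
  (1/2, 1/7, 1/14, 1/35, 1/10, 7/30, 1/3, 1/15 + 1/35 ≈ 0.095, 5/21 ≈
  0.238).
- `random_disease_network()` — Erdős–Rényi $G(n,p)$ graphs with disease
  labels planted on disjoint random subsets, bit-reproducible from a single
  integer seed (the caller's RNG stream is saved and restored).

What these emulate is the *combinatorial* structure of the problem —
arbitrary overlap of disease sets, isolated proteins, disconnected
components, mediator sharing. What they do not emulate is the heavy-tailed
degree distribution, the clustering and the ascertainment bias of curated
interactomes. Passing tests therefore demonstrate correctness of the
computations, not robustness of biological conclusions drawn from any
particular database.

## Validation strategy and numerical choices

Every non-trivial computation has an independent brute-force oracle in the
package itself: `brute_force_effect()` enumerates all walks explicitly and
`brute_force_betweenness()` enumerates shortest paths by iterative-deepening
search; both are guarded to 13 nodes because enumeration is combinatorial.
The test suite checks matrix powers against walk enumeration, and the
shortest-path betweenness against path enumeration, on 200 seeded random
graphs of 5–10 nodes with edge probabilities 0.2 and 0.5 at step counts
1–3 — sizes chosen so exhaustive enumeration stays exact and the whole
suite runs in about two minutes — plus conservation at steps 1–4 and the
$M^2$ decomposition identity on every fixture. Correlations go through
`stats::cor` and are cross-checked against a from-the-definition
implementation.

Degenerate inputs are handled explicitly rather than silently: normalized
degree requires $N \ge 2$ and normalized betweenness $N \ge 3$; isolated
receivers get all-zero effect rows; an all-zero contribution matrix makes
`most_influenced()` return `NA` with a warning, and an influence
decomposition with no influence at all is flagged `defined = FALSE` instead
of dividing by zero. Overlapping disease sets skip self-pairs with a
warning. TSV exports round to 6 significant digits (4 in the wide
strength matrix, matching the usual presentation of such tables); all
in-memory values are full double precision.

## Limitations

- Weighted or directed interaction networks are out of scope; the effect
  model assumes uniform spreading over neighbours.
- The package consumes enrichment P-values (e.g. a DAVID-style export) for
  the mediation-versus-function comparison but does not compute enrichment
  itself.
- No noise filtering of interaction records beyond deduplication and
  self-loop removal is attempted; curation quality is the caller's
  responsibility.
- Walk-based effects at large $n$ mix in substantial back-and-forth
  redundancy; the indices are most interpretable at $n = 2$, which is the
  default everywhere.
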