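---
title: "Coalescent embedding: mapping networks into hyperbolic space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coalescent embedding: mapping networks into hyperbolic space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 5.5)
library(hypercoal)
```

## The latent-geometry picture

Many real networks — protein interactomes, brain connectomes, the Internet
AS graph — behave as if their nodes occupied positions in a hidden
hyperbolic plane: heavy-tailed degrees correspond to radial positions
(popularity), clustering to angular proximity (similarity), and efficient
greedy navigation to the congruence between topology and geometry. In the
native disk representation of the hyperbolic plane with curvature
$K = -\zeta^2$, a node is a pair $(r, \theta)$ and distances follow the
hyperbolic law of cosines

$$\cosh(\zeta h_{ij}) = \cosh(\zeta r_i)\cosh(\zeta r_j)
  - \sinh(\zeta r_i)\sinh(\zeta r_j)\cos\Delta\theta_{ij}.$$

*Coalescent embedding* infers $(r, \theta)$ for every node of a bare
(unweighted, undirected, connected) graph in four steps, none of which
requires tuning or labels:

1. **Pre-weighting** — guess distance-like edge weights from topology.
   The repulsion–attraction rules are local:
   $x^{RA1}_{ij} = (d_i + d_j + d_i d_j)/(1 + CN_{ij})$ and
   $x^{RA2}_{ij} = (1 + e_i + e_j + e_i e_j)/(1 + CN_{ij})$, where $d$ is
   degree, $CN_{ij}$ the number of common neighbours and
   $e_i = d_i - CN_{ij} - 1$ the endpoint's external degree on that edge.
   Hub pairs without shared neighbours repel (they dominate distant
   regions); shared neighbours attract. The global alternative weights
   each edge by its betweenness centrality (EBC): bridges proxy long
   geodesics.
2. **Nonlinear dimension reduction** — embed a distance kernel.
   Isomap (ISO) double-centers the squared weighted-shortest-path kernel
   in the classical-MDS sense and decomposes it by singular values;
   noncentered Isomap (ncISO) decomposes the raw kernel and discards the
   first axis (it points at the manifold center). Minimum curvilinear
   embedding (MCE/ncMCE) replaces geodesics by path sums over the minimum
   spanning tree — a hierarchical, tree-like notion of distance that suits
   hyperbolic geometry — and retains a single axis (the first, or the
   second for the noncentered variant). Laplacian eigenmaps (LE) skips
   kernels entirely: pre-weights pass through the heat function
   $\tilde x = e^{-x^2/t}$ with $t$ fixed at the squared mean pre-weight,
   and the generalized eigenproblem $Lv = \lambda Dv$ supplies the
   eigenvectors of the 2nd–3rd smallest eigenvalues (the first is the
   constant null vector).
3. **Angular coordinates** — the embedded points *coalesce* along a
   circular (2D manifold reducers) or linear (MCE/ncMCE) pattern ordered
   like the latent angles. Circular adjustment (CA) reads angles off the
   plane, or rescales 1D scores onto $[0, 2\pi(n-1)/n]$; equidistant
   adjustment (EA) keeps only the circular order and respaces nodes
   uniformly, trading short-range angular noise for an even spread.
4. **Radial coordinates** — nodes are ranked by decreasing degree and the
   rank-$i$ node receives $r_i = \frac{2}{\zeta}[\beta\ln i +
   (1-\beta)\ln n]$ with $\beta = 1/(\gamma - 1)$, mirroring the
   popularity-fading trajectory of a growing geometric network whose
   degree exponent is $\gamma$ (fitted from the degree sequence when not
   supplied).

The pipeline is deterministic: there is no random stage after the input.

```{r pipeline}
net <- generate_pso(100, m = 4, temp = 0.1, gamma = 2.5, seed = 42)
emb <- embed_network(net$edges, preweight = "RA1", reducer = "ncMCE",
                     adjust = "EA", gamma = 2.5)
c(hd = hd_correlation(net$coords, tidy(emb)),
  cscore = c_score(net$coords$theta, tidy(emb)$theta))
```

## The synthetic generator

`generate_pso()` grows networks by the popularity–similarity-optimization
(PSO) model, the package's ground-truth source. At time $i$ a node appears
at radius $(2/\zeta)\ln i$ with a uniform angle; every older node $j$
fades outward to $r_j(i) = \beta r_j + (1-\beta) r_i$. At temperature
$T = 0$ the newcomer links to the $\min(i-1, m)$ hyperbolically closest
nodes (ties to the earliest-born); at $T > 0$ it repeatedly samples a
not-yet-linked node uniformly and accepts it with the Fermi–Dirac
probability $p(h) = 1/(1 + e^{(h - R_i)/2T})$ until it holds
$\min(i-1, m)$ links. Parameters and defaults:

| parameter | meaning | default |
|---|---|---|
| `m` | half the average degree | 2 |
| `temp` | clustering control, $[0, 1)$; clustering is maximal at 0 | 0 |
| `gamma` | degree exponent $1 + 1/\beta$ | 2.5 |
| `zeta` | $\sqrt{-K}$; rescales radii only | 1 |

The defaults mirror the conditions under which the method family is
usually exercised: $\gamma = 2.5$ is the canonical mid-range exponent and
$T = 0$ is the cleanest geometric regime; the evaluation suite sweeps
$m \in \{4, 6\}$ and $T \in \{0.1, \dots, 0.9\}$ explicitly rather than
through defaults.

Three implementation notes, each chosen once and kept:

* **Disk radius $R_i$.** The Fermi–Dirac rule needs the current disk
  radius, $R_i = r_i - \frac{2}{\zeta}\ln\!\big[\tfrac{2T(1 -
  i^{-(1-\beta)})}{\sin(T\pi)\, m (1-\beta)}\big]$ (with the $\beta \to 1$
  limit $\ln i$ replacing the fraction), the standard normalization that
  keeps the expected degree near $2m$. Its $\sin(T\pi)$ factor confines
  the probabilistic branch to $T < 1$, which covers the whole evaluation
  range; `temp >= 1` is rejected rather than silently extrapolated.
* **Sampling without stalls.** The literal accept/reject loop is
  distribution-identical to successive weighted sampling without
  replacement with weights $p$ (the first acceptance lands on $j$ with
  probability $p_j/\sum p$, and the argument recurses on the shrunken
  pool), which is how the package draws the link set. This matters
  numerically: at low $T$ the probability of a far node underflows to
  zero, where a literal loop can stall essentially forever; underflowed
  candidates are ranked by distance instead, the limiting behaviour of
  the rule.
* **Determinism.** All randomness flows through R's RNG from the single
  `seed` argument; equal seeds give bit-identical networks.

What the generator does *not* emulate: community structure, degree–degree
correlations beyond those the model induces, weighted or directed edges,
and the finite-size behaviour of any particular real system. Passing the
synthetic benchmarks therefore demonstrates geometry *recovery under the
model's own assumptions*, not performance guarantees on arbitrary real
networks.

A caution that the test suite surfaces explicitly: at realistic sizes
(thousands of nodes) the canonical power-law fit (`fit_degree_exponent()`,
the Clauset KS-minimization procedure, cross-checked against igraph's
plfit) reads the degree exponent of PSO networks as $\approx 2.8$ when
the planted asymptotic exponent is $2.5$ — the KS-selected cutoff lands
at $k_{\min} = m$, where the finite-size bulk still bends. This is a
property of finite samples from the model, not an estimator defect (the
same estimator recovers i.i.d. discrete power-law samples to within a few
percent), and it is why `embed_network()` accepts a user-supplied
`gamma` wherever the generative exponent is known.

## The HyperMap baseline

`hypermap_embed()` implements the maximum-likelihood comparator: nodes
are replayed in descending-degree order, radii follow the same fading
closed form, and each node's angle maximizes the Bernoulli likelihood of
its observed links over a grid of $n$ candidate angles under the same
Fermi–Dirac connection probability. The likelihood model is undefined at
$T = 0$ (the probability degenerates to a step), so zero temperature is
rejected. Log-likelihoods are accumulated with probabilities clamped to
$[10^{-12}, 1 - 10^{-12}]$ to avoid underflow of the product form.

## Evaluation suite

* `hd_correlation()` — Pearson correlation of all pairwise hyperbolic
  distances, truth vs reconstruction; invariant under rotations and
  reflections of either set.
* `c_score()` — fraction of node pairs whose shorter angular direction
  agrees, maximized over the two clock orientations of the inferred
  circle. Separations of exactly $\pi$ have no shorter side; they are
  counted as agreement when both representations sit at exactly $\pi$
  and otherwise read as counter-clockwise — a measure-zero convention
  that keeps the score deterministic.
* `align_angles()` — for visualization: the best of 360 one-degree
  rotations of the inferred angles and of their reflection, judged by
  plain linear correlation with the true angles; the C-score is
  unaffected by construction.
* `greedy_routing()` — forwards a packet for every ordered pair to the
  neighbour hyperbolically closest to the destination (ties to the
  lowest node id). Because that next-hop map is memoryless given the
  destination, revisiting *any* node implies an endless loop, so the
  packet is dropped on any revisit — the immediate bounce-back of the
  classic drop rule being the usual case, and the generalization being
  outcome-equivalent while guaranteeing termination. The GR-score
  averages $sp_{ij}/p_{ij}$ over ordered pairs with 0 for drops.
* `geometric_weights()` — Louvain-style community detectors accept a
  weighted adjacency; observed edges are weighted $1/(1 + HD_{ij})$ and,
  optionally, non-observed pairs $1/(1 + HSP_{ij})$. "The sum of
  hyperbolic distances over the shortest path" is read as the path
  minimizing that sum (a weighted shortest path on the HD-weighted
  graph); a `hsp_basis = "hops"` switch sums distances along a
  minimum-hop path instead, for comparison, since either reading is
  defensible.
* `nmi()` — normalized mutual information with natural logs; the
  adjusted variant subtracts the expected mutual information under the
  permutation model and is auto-selected when $N/n_T \le 100$, i.e.
  whenever communities are not vanishingly few relative to nodes.

## Numerical and design choices

* **Centering.** "Centering the kernel" is implemented as classical-MDS
  double centering of the *squared* distance kernel,
  $B = -\tfrac12 J (D \circ D) J$, the construction Isomap inherits from
  MDS; the noncentered variants decompose the raw kernel. Distance-matrix
  (unsquared) centering was regression-compared once on PSO benchmarks
  and changed HD-correlations only marginally; the squared form is kept
  as the principled choice.
* **Decompositions** use dense LAPACK (`svd()`, `eigen()`): exact,
  deterministic, and cheap at the sizes the package targets (hundreds to
  a few thousand nodes). Each retained axis is oriented so its
  largest-magnitude loading is positive, fixing the sign ambiguity so
  that repeated runs are bit-identical; metrics are reflection-invariant
  regardless.
* **LE heat scale** $t$ is the squared mean of the pre-weights (the
  literal reading), not the mean of squares.
* **1D rescaling** maps the extreme scores to $0$ and $2\pi(n-1)/n$, not
  $2\pi$, so the two ends of the linearized pattern do not collide on
  the circle. Equidistant adjustment breaks angle ties by ascending node
  id; degree ties in the radial ranking likewise.
* **User weights.** A `weight` column on the input bypasses
  pre-weighting: weights are taken as distances directly.
* **Degenerate inputs.** Disconnected graphs, constant 1D scores,
  zero-entropy partitions (unadjusted NMI) and zero-variance distance
  vectors raise errors rather than returning silently meaningless
  numbers.

## Problem sizes in the shipped checks

The test suite and the acceptance script rerun the scientific claims at
desk scale, chosen so the whole suite completes in a couple of minutes:
embedding-quality checks use $n = 100$, $m = 4$ PSO networks (10 seeds);
the coalescent-vs-HyperMap comparison uses $n = 200$ over
$m \in \{4, 6\} \times T \in \{0.1, 0.3, 0.6, 0.9\}$ (5 seeds each);
exponent recovery uses $n = 5000$ (10 seeds). The HyperMap gap grows
with network size, so the scaled comparison is a conservative rendition
of the full-size one.

## Limitations

* Only 2D and 3D ambient spaces; MCE/ncMCE and equidistant adjustment
  are 2D-only by construction.
* Radial coordinates come from a single degree-ranked formula; the
  package never optimizes radii against the likelihood, which is why
  HyperMap retains an edge in greedy-routing navigability even where the
  coalescent variants dominate distance recovery.
* `hypermap_embed()` is the plain likelihood replay (no common-neighbour
  likelihood, speed-up heuristics or correction sweeps).
* Community detection itself is out of scope: `geometric_weights()`
  produces the weighted adjacency and standard igraph detectors consume
  it.
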