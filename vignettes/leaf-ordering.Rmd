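---
title: "Modular leaf ordering: methods, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular leaf ordering: methods, conventions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leaforder)
```

## The problem

An agglomerative hierarchical clustering of *n* items is a binary tree of
*n − 1* merges, each at a dissimilarity ("height") at which two clusters
were joined. Drawing it as a dendrogram — and permuting the rows or columns
of a heat map by its leaf order — requires choosing an orientation for
every merge: left child or right child first. Any of the 2^(n−1)
assignments is consistent with the same hierarchy, so the drawn order is a
free parameter, and different choices give strikingly different visual
impressions of the same clustering.

`leaforder` implements one family of heuristics — modular leaf ordering —
together with the baselines it is naturally compared against, and the
metrics that make the comparison quantitative.

## The ordering methods

All five methods operate on a `merge_tree` and change only the left/right
orientation of internal nodes; topology and heights are untouched. This is
the central invariant of the package and is tested property-style on random
trees.

**Default orientation** (`order_default`) re-states the convention of
standard dendrogram drawing: when two leaves merge, the one earlier in the
input matrix goes left; when a leaf merges with a subtree, the leaf goes
left; when two subtrees merge, the one whose own merge was tighter goes
left. It is the baseline for the ink metrics, and `agglomerate()` returns
trees already in this orientation so that the default method is a fixed
point.

**Modular ordering** (`order_molo`) compares, at every merge, a per-subtree
*key*: the minimum (`criterion = "min"`) or the mean (`criterion = "avg"`)
of all merge heights inside the child's subtree. The child with the smaller
key goes left. We give leaves the key +∞, which has two consequences worth
spelling out:

* a bare leaf joining a subtree always goes right — the companion rule of
  the method — so the singleton's long branch does not hang over the nested
  structure to its left, and every subtree silhouette grows rightward in
  merge order, giving the characteristic right-triangular shape;
* when two leaves merge, both keys are infinite, the comparison ties, and
  the existing orientation is kept. The leaf-leaf case is not covered by
  the two stated rules, and "keep the input orientation" is the only choice
  that is stable, deterministic and consistent with default drawings of
  leaf pairs; unifying both rules through the infinite sentinel makes rule
  one a corollary of rule two rather than a special case.

All ties keep the current orientation, which makes `order_molo` idempotent —
re-running it never changes the result — and means that the post-condition
`key(left) ≤ key(right)` at every node characterizes its output. A further
consequence, checked in the tests, is that the globally tightest merge is
reachable from the root by always descending left.

The `avg` variant exists because a minimum is a fragile summary: a loose
cluster that happens to contain one tight pair gets the same key as a
uniformly tight cluster. Averaging all preceding merge heights prioritizes
clusters that are tight throughout. The average is unweighted over the
subtree's internal nodes; weighting by subtree size would be a different,
also defensible, statistic, but the unweighted mean is the simplest reading
of "average distance of the preceding merges" and is what we fixed.

**Endpoint-greedy ordering** (`order_gw`) is the classic bottom-up
Gruvaeus–Wainer-style heuristic: each subtree exposes its outermost leaves,
and at every merge the four combinations of mirroring either child are
scored by the distance between the two leaves that become adjacent across
the join. The original description leaves the algorithmic details open; we
fixed a deterministic tie order (no mirror, mirror left only, mirror right
only, mirror both) so results are reproducible.

**Optimal leaf ordering** (`order_olo`) minimizes the Hamiltonian path
length — the sum of distances between consecutive leaves — exactly, over
all 2^(n−1) admissible orders, with the standard dynamic program over
(subtree, leftmost leaf, rightmost leaf) states. It is cubic in *n*; the
default guard refuses more than 2000 leaves and points the user to the
linear-time heuristics. Ties resolve toward the input orientation. Because
reversing a whole order leaves its path length unchanged, the root is never
flipped; child flips are recovered from the dynamic-programming traceback.

## Metrics

`line_length()` needs a coordinate convention to be meaningful, and we state
it explicitly: leaves at x = 1..n with unit spacing, heights in raw
dissimilarity units, internal nodes horizontally at the midpoint of their
children's positions. Each merge then contributes two vertical risers
(child height up to merge height) and one horizontal connector. The riser
total is a function of the heights alone, so it is identical across all
orientations of a tree — any difference in total ink between two orderings
of the same clustering lives entirely in the connectors. That decomposition
is asserted exhaustively over all orientations of small trees and spot
checked at n = 200. Because absolute totals depend on the (arbitrary) unit
choice, the robust comparison is `data_ink_ratio()`, the ratio of a
method's total to the default orientation's total, which is invariant to
uniform rescaling of either axis.

`anti_robinson_events()` needs a formula where the literature names only a
concept; we count, over all position triples i < j < k of the reordered
matrix, one event for each of `d(i,j) > d(i,k)` and `d(j,k) > d(i,k)` — a
two-sided, unweighted per-triple count, invariant under order reversal. The
implementation is vectorized per pair; the test oracle is a literal triple
loop.

## Clustering conventions

`agglomerate()` implements single, complete and average linkage with
Lance–Williams updates; average linkage is the unweighted mean over
cross-cluster pairs (UPGMA). Ties in the minimum inter-cluster distance are
broken by merging the lexicographically smallest pair of node ids, so runs
are reproducible even on degenerate inputs such as equidistant points. The
test suite checks heights and memberships against a from-scratch reference
that recomputes every cluster distance over the original matrix.

The correlation-based dissimilarity is `1 − r` by default — the convention
of the heat-map tools this package interoperates with — with `(1 − r)/2`
available by option for users who want the range pinned to [0, 1].
Zero-variance rows have no defined correlation and are reported by name
rather than silently propagating `NA`.

Two degenerate-input decisions: duplicate observations (zero distance)
produce zero-height merges, which are permitted with a warning rather than
rejected, since real tables do contain duplicated rows (the bundled iris
table among them); and non-monotone height sequences — possible in
externally produced trees — are counted by `validate_merge_tree()` as
diagnostics instead of being errors, because single-linkage ties and
foreign software legitimately produce them.

## Serialization

Merge tables use the common linkage convention (leaves 0..n−1 in input
order, merges n..2n−3 in merge order, child columns ordered left/right) so
orientation survives a round trip. Newick export maps node heights to
branch lengths (parent height minus child height); parsing is delegated to
`ape`, which preserves child order in both directions, and heights are
recovered as maximum leaf depth minus node depth. A Newick string does not
carry input indices, so a parsed tree numbers its leaves by order of
appearance; round trips therefore preserve leaf order, topology and
heights, which is the contract the tests pin down.

## Rendering

SVG was chosen as the output format because it can be generated
deterministically: fixed two-decimal coordinate formatting, stable element
order, no timestamps, so identical inputs give byte-identical documents and
figures can be regression-tested as text. Each merge is one polyline (two
risers plus connector), mirroring the ink metric's geometry exactly. In
limited display space, leaf labels are dropped once the canvas allots fewer
than 4 px per leaf (configurable), which reproduces the dense-figure
comparison mode. The heat map uses a blue–white–red diverging ramp with
explicit limits (pass `c(-1, 1)` for signed association scores) and an
optional categorical annotation strip between the row dendrogram and the
cells.

## Synthetic data and what the tests do not show

`make_gaussian_clusters()` draws isotropic Gaussian clusters on a center
grid; defaults (spacing 10, unit spread, two dimensions) give visibly
separated but touching clusters, the regime in which ordering methods
actually differ. The recovery checks use spacing 100 with spread 0.1, where
complete linkage must split the two true clusters at the root; that is a
correctness check of the pipeline, not a claim about hard instances. The
generator emulates the simulation style of small demonstration sets; it
does not emulate heavy-tailed noise, unequal cluster sizes, correlated
attributes or the high-dimensional, strongly non-Gaussian structure of real
expression matrices. Passing tests show the algorithms honor their
contracts on such data — not that any ordering is "best" for a given real
dataset, which remains a judgment about the analysis goal.

The ten-point `fig2_toy()` configuration is engineered so that one small
complete-linkage tree contains all three merge types; its coordinates are
this package's own invention and carry no empirical meaning.

## Problem sizes and numerical choices

The test suite works at the scales where exhaustive oracles are feasible:
flip enumeration to n ≤ 10 (1024 orders), naive-linkage cross-checks to
n ≤ 15, orientation invariants to n = 200, and the 150-observation iris
pipeline end to end; these sizes keep the whole suite in the tens of
seconds while still covering every code path at both small and moderate n.
Floating-point ties in the dynamic program are resolved by first-index
scans; distance symmetry is enforced to 1e−12 and tiny negative
correlations clamped to zero; comparisons against oracles use tolerances of
1e−9 to 1e−12, well below any data scale used.

## Known limitations

* Multifurcating trees and trees without heights are out of scope; the data
  model is strictly binary with heights on internal nodes.
* Ward, centroid and median linkage are not provided.
* `order_olo` stores per-node endpoint cost matrices, so memory is
  quadratic and time cubic in n; beyond a few thousand leaves use the
  modular or endpoint-greedy methods.
* Absolute line-length totals are only comparable under this package's
  layout convention; compare ratios, not totals, across software.
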