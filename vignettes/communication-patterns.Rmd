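---
title: "Clustering, searching and comparing cell-cell communication patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering, searching and comparing cell-cell communication patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multicomm)
```

## The model

Upstream inference tools score, for every interacting pair of molecules
(typically a ligand and its receptor), the communication each ordered pair
of cell types could exchange through it. `multicomm` treats each such score
matrix as the adjacency matrix of a directed weighted graph over the cell
types — one **layer** — and the collection of layers as a multiplex
network: many graphs, one shared node set. Edges run from the cell type
expressing the ligand (or partner P1, when the pair has no intrinsic
direction) to the one expressing the receptor (or P2). An edge exists iff
its weight is strictly positive; upstream tools already zero out
non-significant interactions, so no additional threshold is applied.
Self-edges (autocrine signalling) are legitimate and retained. All-zero
matrices are rejected at construction: they carry no communication, and two
empty layers would make the dissimilarity below undefined (empty edge-set
union).

Per layer, each cell type gets a send/receive balance
$\Delta_i = \sum_j w_{ij} - \sum_j w_{ji}$ (weighted out-degree minus
in-degree). The sign convention is chosen so that net *senders* are
positive (drawn red in all figures) and net receivers negative (blue);
self-edges add the same amount to both degrees and cancel. Summed over
nodes, $\Delta$ vanishes identically — in IEEE double arithmetic the
computed sum carries a rounding residual of order $10^{-15}$, which is what
the tests assert (at $10^{-12}$). $\Delta$ is reported in the raw units of
the upstream scores, not normalized by node count or total weight: the
magnitudes stay interpretable against the input, and any normalization is a
display decision better left to the caller.

## The dissimilarity measure

For layers $\alpha, \beta$, with $E_\alpha$ the set of directed cell-type
pairs carrying positive weight,

$$d_{\alpha\beta} \;=\; \frac{1}{|E_\alpha \cup E_\beta|}
  \sum_{(i,j)} s_{ij}, \qquad
  s_{ij} = \begin{cases}
    \dfrac{|w^\alpha_{ij} - w^\beta_{ij}|}{w^\alpha_{ij} + w^\beta_{ij}}
      & w^\alpha_{ij} + w^\beta_{ij} > 0 \\[4pt]
    0 & \text{otherwise.}
  \end{cases}$$

The condition on $s$ deserves a note. Requiring the *product*
$w^\alpha w^\beta \neq 0$ instead would zero the score on every unshared
edge, so two edge-disjoint layers would come out *identical* ($d = 0$) —
the opposite of what a Jaccard-style measure must say, and useless for
clustering. We therefore score a cell whenever *either* weight is positive:
a matched edge with equal weights contributes 0, an unshared edge
contributes 1, and

* $d = 0$ iff the weight matrices agree on the union,
* $d = 1$ iff the edge sets are disjoint,
* $d$ is invariant under rescaling both layers by one positive constant,
* on binarized layers $d$ is exactly the classical Jaccard distance of the
  directed edge sets.

Direction matters: an edge A→B in one layer and B→A in the other is a full
mismatch ($d = 1$), which is the biologically meaningful reading — the same
cells, communicating the opposite way. Self-edges are ordinary members of
$E$; nothing in the sum excludes them. The pairwise matrix is computed once
per unordered pair and mirrored, so symmetry and the zero diagonal are
exact, not approximate; range membership is validated at $10^{-12}$.

## Clustering layers into communication patterns

Layers are clustered on the dissimilarity matrix with average-linkage
(UPGMA) hierarchical clustering (`stats::hclust`), and the tree is cut with
a **hybrid dynamic tree cut** in the Dynamic Hybrid style, implemented in
this package (`cutree_hybrid()`). The procedure, briefly:

1. A reference height (the 5% quantile of merge heights) and a cut height
   (99% of the way from the reference to the top) bound the part of the
   tree considered.
2. Walking the merges below the cut height, basic branches grow; when two
   branches meet, a branch that is too small (fewer than
   `min_cluster_size` members) or too diffuse (mean within-core
   dissimilarity above a bound) is absorbed into its sibling, otherwise
   both are kept as cluster candidates.
3. A surviving branch is a cluster if it has at least `min_cluster_size`
   members, a tight core (the core is the first $m/2 + 1 + \sqrt{\cdot}$
   members to have joined), and a gap between its attachment height and its
   core scatter.
4. A PAM-like second stage assigns leftover objects to the cluster with
   the smallest mean dissimilarity, when that distance is below the cut
   height and (by default) the cluster lies in the same sub-tree; whole
   branches that failed only the size criterion are re-assigned as blocks.
   Objects that fit nowhere keep label **0** (unassigned) and are excluded
   from average patterns — they are reported, never silently dropped.

`deep_split` (0–4, default 0) maps to the maximum tolerated core scatter
(0.64 … 0.95 of the height range above the reference) with the minimum gap
at 3/4 of the remaining headroom; 0 is the most conservative setting and
yields the coarsest, best-separated clusters. `min_cluster_size` defaults
to 6. On instances with fewer merges below the cut height than
`min_cluster_size`, everything is unassigned — the smallest meaningful
problem size. Cluster labels are numbered by decreasing size with ties
broken by the earliest member index, so numbering is stable under
permutation of the input layers (the partition itself is
permutation-equivariant; this is tested).

Each cluster is summarised by its **average pattern**: the arithmetic mean
of the member weight matrices and of the member $\Delta$ vectors. Since
$\Delta$ is linear in the weights, the mean balance equals the balance of
the mean matrix; the package computes one and asserts the other in its
tests.

### Embedding

For visual overviews the layers are embedded in 2-D from the precomputed
dissimilarity matrix — UMAP (via uwot) when available, classical metric MDS
(`stats::cmdscale`) otherwise; the result records which method ran in its
`"method"` attribute, and both are deterministic given the seed. The UMAP
neighborhood size defaults to `min(5, L - 1)`: one less than the default
minimum cluster size, so neighborhoods never span more than the smallest
pattern the tree cut would report — larger neighborhoods can bridge
well-separated patterns in small datasets. The embedding is presentation
only; no downstream computation reads it.

## Pattern search and condition comparison

**Search** compares a user-drawn binary adjacency (1 = edge required) to
every layer *after binarizing the layer on edge presence*: only the shape
of the communication pattern matters, never the weights, so the ranking is
by classical Jaccard distance of directed edge sets, ascending — exact
matches first. Ties are broken lexicographically by pair id so output is
deterministic. All layers are returned; thresholding is left to the caller.

**Comparison** of two conditions matches layers by pair id (whitespace
trimmed, case preserved) across two networks over the identical cell-type
set, computes the *weighted* dissimilarity per shared pair — the
comparison step inherits the general measure, not the search-specific
binarization — and sorts descending: the pairs that change most come
first. Pairs present in only one condition are reported in their own lists
rather than being assigned a score: "absent" and "maximally changed" are
different claims, and conflating them is a modelling decision the user
must opt into (`exclusive_as_max = TRUE`, or `--exclusive-as-max` on the
command line, folds them in at $d = 1$). No significance test is attached
to the ranking; the measure orders change but does not calibrate a null.

## The synthetic-data generator

`generate_network()` produces networks with planted structure: $K$ distinct
binary archetype patterns over $N$ cell types; per archetype a fixed number
of member layers, each obtained by flipping every cell of the archetype
independently with probability `edge_flip_prob` (symmetric in both
directions, keeping expected density stable) and weighting surviving edges
with lognormal draws (default $\mu = 0$, $\sigma = 0.5$ — positive,
right-skewed values mimicking mean-expression scores; $\sigma = 0$ gives
the noiseless limit of constant weights). Members that lose every edge are
redrawn, as the real pipeline never emits empty layers. Generation is
bit-reproducible given the spec and its seed.

The defaults used throughout the tests reflect a small embryo-scale
dataset: 5 cell types, archetypes of ~8 directed edges (30% density),
6–10 members per archetype, 10% edge-flip noise. What the generator
emulates is the *grouped-pattern structure* the clustering step assumes;
what it does not emulate: correlated dropout (flips are i.i.d. across
cells and layers), weight correlation between related ligand–receptor
pairs, compositional coupling between layers, or the permutation-test
discreteness of real CellPhoneDB scores. Passing the planted-recovery
tests therefore shows the pipeline recovers grouped patterns under
independent noise — not that any particular biological dataset has such
structure.

`perturb_network()` complements it for comparison tests: in selected
layers, a chosen fraction of edges is moved (weights intact) to cells that
were empty, so the rewired fraction dials the expected dissimilarity from
0 to exactly 1.

## Numerical and interface choices

* Edge presence is `weight > 0`, strictly; no epsilon.
* All tabular writers print doubles with `%.17g`, so text round-trips are
  bit-stable and repeated runs with the same seed are byte-identical
  (asserted for the cluster workflow).
* The long edge-list format carries a `# cell_types:` header (cell types
  with no edges survive the round trip) and a `directional` column; plain
  four-column files are accepted.
* CellPhoneDB input: the v2 significant-means dialect is the default
  (missing value = not significant = weight 0); a means + p-values dialect
  thresholds at `p <= 0.05` by default. Which upstream column should be
  the weight is a genuinely open choice, so both dialects are explicit
  rather than one being silently canonical. Direction comes from the
  receptor flags: exactly one receptor makes the layer directional
  (ligand-expresser sends); none or both fall back to P1→P2 as the columns
  read. Multi-subunit complexes are opaque labels.
* Errors are classed (usage / format / validity / I-O) and the
  command-line wrapper maps them to distinct exit codes (2/3/4/5).

## Problem sizes and oracles in the test suite

The suite is built around independent oracles on small instances: a
cell-by-cell brute-force evaluation of the dissimilarity (120+ random
pairs, $N \le 5$, agreement to $10^{-12}$), a hand-rolled $O(L^3)$ UPGMA
(25 random matrices, $L \le 10$, heights to $10^{-10}$), set-theoretic
Jaccard for binarized layers and search (100+ instances), conservation and
linearity of $\Delta$ on 1000 random layers, and planted-archetype
recovery (mean adjusted Rand index $\ge 0.9$ over 20 seeds for each of
$K = 2, 3, 4$ at 10% noise). The tree cut is additionally checked on
fixtures whose correct output is derivable from the algorithm's
definition: well-separated planted blocks at $K = 2\ldots4$ (exact
recovery), sub-minimum instances (all unassigned), and outliers with and
without the PAM stage. These sizes keep the whole suite under half a
minute while exercising every code path at full tolerance.

## Known limitations

* The tree cut follows the published Dynamic Hybrid algorithm's semantics
  but is an independent implementation; on adversarial dendrograms its
  branch-absorption order may differ from other implementations in
  borderline cases, while the cluster criteria (size, core scatter, gap)
  and the PAM stage semantics are as described above.
* The dissimilarity treats layers symmetrically and has no notion of
  weight *scale* differences between whole datasets; when comparing
  conditions produced by different pipelines, normalize weights upstream.
* Cluster-count behaviour inherits the conservative bias of
  `deep_split = 0`: sub-patterns tighter than the core-scatter bound are
  merged, by design.
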