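# multicomm

Multiplex-network analysis of cell–cell communication.

Tools such as CellPhoneDB take single-cell RNA-seq data and emit, for every
ligand–receptor (or other interacting) pair, a matrix scoring the
communication it could mediate between each ordered pair of cell types.
`multicomm` is for the step after that: making sense of hundreds of such
matrices at once. Each interacting pair becomes one **layer** of a multiplex
network whose nodes are the cell types — a directed weighted graph with
edges running sender (ligand-expressing) → receiver (receptor-expressing).
On top of this representation the package provides:

* **unsupervised clustering** of interacting pairs into shared
  communication patterns,
* **pattern search** — rank all pairs by similarity to a user-drawn binary
  communication pattern,
* **differential comparison** of the same pairs across two biological
  conditions (e.g. diagnosis vs. post-treatment).

## The dissimilarity at the core

For two layers α and β with non-negative weight matrices *w*ᵅ, *w*ᵝ over
the same cell types, every directed cell-type pair (i, j) with
*w*ᵅᵢⱼ + *w*ᵝᵢⱼ > 0 contributes

    s_ij = |wᵅ_ij − wᵝ_ij| / (wᵅ_ij + wᵝ_ij)

and the layer dissimilarity is the mean contribution over the union of the
two edge sets:

    d(α, β) = Σ_ij s_ij / |E_α ∪ E_β|

This is a weighted, directed modification of the Jaccard distance:
d = 0 iff the layers are identical, d = 1 iff their edge sets are disjoint,
and on binarized layers it reduces exactly to the classical Jaccard
distance of directed edge sets. Layers are clustered by average-linkage
hierarchical clustering of this matrix, cut with a hybrid dynamic tree cut
(deepSplit 0, minimum cluster size 6 by default); each cluster is
summarised by the arithmetic mean of its members' weight matrices and of
the per-node send/receive balance Δ = weighted out-degree − in-degree
(positive = net sender, drawn red; negative = net receiver, blue).

## Worked example

A small synthetic CellPhoneDB-style table ships with the package: 14
interactions over 5 cell types, built around two communication programs
(`ExE` broadcasting to every other tissue; everything converging on
`Blood`) plus two mutual-signalling pairs that belong to neither.

```r
library(multicomm)
tbl <- system.file("extdata", "synthetic_significant_means.txt",
                   package = "multicomm")
net <- records_to_layers(read_cellphonedb(tbl))
net
#> <multiplex communication network> 14 layers over 5 cell types
#> cell types: Blood, EmbA, EmbB, EmbC, ExE

dm <- pairwise_dissimilarity(net)
cl <- hybrid_tree_cut(hierarchical_linkage(dm), dm)
cl
#> <layer clustering> 2 cluster(s), 12 of 14 layers assigned
#> cluster
#> 1 2
#> 6 6

split(names(cl$labels), cl$labels)
#> $`0`
#> [1] "Cdh1:Cdh1"   "Efna1:Epha4"
#> $`1`
#> [1] "Bmp4:Bmpr1a"  "Lefty1:Tdgf1" "Wnt3:Fzd5"  "Fgf8:Fgfr1"  "Nodal:Acvr2a" "Kitl:Kit"
#> $`2`
#> [1] "Vegfa:Kdr"  "Dll1:Notch1"  "Jag1:Notch2" "Cxcl12:Cxcr4" "Angpt1:Tek"  "Epo:Epor"
```

The cut recovers both planted programs and leaves the two pairs that fit
neither unassigned (label 0). The cluster-1 average pattern confirms what
the cluster means biologically — one strong net sender, everyone else
receiving:

```r
round(average_pattern(net, cl, 1)$mean_delta, 2)
#> Blood  EmbA  EmbB  EmbC   ExE
#> -2.10 -1.69 -1.01 -1.56  6.36
```

Searching for "a signal sent by ExE to all other tissues" ranks the six
broadcast pairs first, at dissimilarity exactly 0:

```r
q <- matrix(0, 5, 5, dimnames = list(net$cell_types, net$cell_types))
q["ExE", setdiff(net$cell_types, "ExE")] <- 1
search_pattern(net, pattern_query(q, net$cell_types))
#>   rank      pair_id dissimilarity
#> 1    1  Bmp4:Bmpr1a     0.0000000
#> 2    2   Fgf8:Fgfr1     0.0000000
#> 3    3     Kitl:Kit     0.0000000
#> ...
#> 7    7   Angpt1:Tek     0.8571429
```

Two conditions are compared with `compare_conditions(net_a, net_b)`, which
ranks the shared pairs from most to least changed and reports
condition-exclusive pairs separately.

The same workflows are scriptable from a shell:

```sh
Rscript inst/cli/multicomm.R cluster --input network.tsv --out results/
Rscript inst/cli/multicomm.R search  --input network.tsv --pattern query.csv --out results/
Rscript inst/cli/multicomm.R compare --input d0.tsv --input-b d29.tsv --out results/
```

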