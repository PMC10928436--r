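# mirdisnet

Signed miRNA-based disease similarity networks in R.

Many complex diseases dysregulate overlapping sets of microRNAs, and the
*direction* of that dysregulation (up or down in diseased tissue) carries
information that plain shared-gene counts discard. `mirdisnet` turns a curated
table of literature-derived miRNA–disease association records — the dialect of
the Human MicroRNA Disease Database (HMDD), where each record says "miRNA *j*
was up-/down-regulated in disease *i* in study *k*" — into a **signed disease
network**, and runs the statistics that make such a network interpretable:
does the network cluster by disease class, are disease relationships
internally consistent (structurally balanced), and is a focal disease's
neighborhood enriched for an unexpected disease class? The package is aimed at
network-medicine practitioners who want a reproducible, fully tested version
of this analysis, including a synthetic data generator with planted ground
truth for validating every stage.

## The model

Each disease *i* is a vector over the *M* curated miRNAs. The weight of miRNA
*j* in disease *i* sums the record directions and penalizes promiscuous
miRNAs by their **disease spectrum width** (DSW) — the number of distinct
diseases *n_j* the miRNA is recorded in — with an IDF-style term:

```
w_ij = sum_{k=1..R_ij} P_ijk * log(N / n_j)        P_ijk in {+1, -1}
```

where *R_ij* counts the records linking the pair, and *N* is the total number
of diseases; pairs with no records have *w_ij* = 0, and pan-disease miRNAs
(*n_j* = *N*) are annihilated. Disease similarity is the **Tanimoto
coefficient** of the two vectors,

```
S_xy = d_x . d_y / (||d_x||^2 + ||d_y||^2 - d_x . d_y)
```

which for real vectors lies in [-1/3, 1], shrinks when the two vectors differ
in norm (damping well-studied vs. sparsely-studied artifacts), and is exactly
0 when the diseases share no miRNA. Diseases with |S| strictly above a
threshold (default 0.05) are connected by an edge signed by S. The statistics
suite then provides: BFS network distances with an intra- vs. inter-class
pooled-variance t-test; link-sign 2x2 contingency with an exact Fisher test
(point-probability convention); a signed-triangle census classifying each
3-clique as coherent (0 or 2 negative edges) or incoherent, with a
record-shuffle randomization null; and a degree-preserving double-edge-swap
null for neighbor-class enrichment of a focal disease.

## Worked example

```r
library(mirdisnet)

# synthetic dataset with planted class structure: 3 classes x 20 diseases,
# 150 miRNAs, 90% within-class miRNA sharing, 90% sign concordance
sy <- generate_dataset(generator_config(seed = 42))
sy$dataset
#> Curated miRNA-disease association dataset
#>   698 records over 60 diseases and 111 miRNAs
#>   462 unique (disease, miRNA, direction) pairs: 219 up, 243 down

net <- build_network(pairwise_similarity(build_weight_matrix(sy$dataset)),
                     threshold = 0.05)
net
#> Signed disease network: 60 nodes, 241 edges (184 positive, 57 negative),
#> threshold 0.05

round(degree_summary(net)$means, 2)
#>     degree pos_degree neg_degree
#>       8.03       6.13       1.90

# positive links concentrate inside classes
fisher_exact_2x2(link_sign_contingency(net, sy$classes))$p
#> [1] 2.717671e-17

# triangle coherence against the record-shuffle null
coherence_ratio_test(sy$dataset, n_reps = 200, seed = 43)
#> Randomization test of coherent/incoherent triangle ratio
#>   observed = 9.6957; null mean = 3.1649 over 200 replicates (seed 43)
#>   empirical p = 0.004975 (one-sided, add-one corrected)

disease_neighborhood_report(net, pairwise_similarity(
  build_weight_matrix(sy$dataset)), "Disease 01-01",
  k = 3)$top_similar[, c("disease", "similarity")]
#>         disease similarity
#> 1 Disease 01-13  0.1422417
#> 2 Disease 01-08  0.1234431
```

The planted structure is recovered: diseases of a class sit closer together,
positive edges concentrate within classes (Fisher p = 2.7e-17), and the
observed coherent-to-incoherent triangle ratio (9.7) far exceeds the shuffle
null (mean 3.2, empirical p at 0.005 with 200 replicates).

Real HMDD-style data run through the same functions
(`parse_hmdd_tsv()` → `curate()` → `build_weight_matrix()` → ...), or in one
command via `run_pipeline()` / the `inst/cli/mirdisnet.R` script, which write
the network (GraphML + edge TSV), all statistics tables and a reproducibility
manifest.

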