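---
title: "Methods: signed miRNA-based disease networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signed miRNA-based disease networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirdisnet)
```

## The model and its assumptions

`mirdisnet` quantifies disease–disease relationships from literature-derived
miRNA–disease association records in which each record carries a direction:
the miRNA was observed up- or down-regulated in diseased tissue. Three
modelling assumptions drive the design:

1. **Record multiplicity is evidence.** The weight of miRNA $j$ in disease
   $i$ sums over all $R_{ij}$ records, $w_{ij} = \sum_k P_{ijk} \log(N/n_j)$
   with $P_{ijk} \in \{+1,-1\}$, so repeated independent observations
   strengthen (or, if conflicting, cancel) the signal. Deduplication to
   unique (disease, miRNA, direction) pairs happens only in the descriptive
   pair census, never in the weight model.
2. **Promiscuous miRNAs are less informative.** The penalty $\log(N/n_j)$,
   an IDF analogue over the miRNA's *disease spectrum width* $n_j$,
   down-weights miRNAs associated with many diseases. Its limiting case is a
   deliberate feature: a miRNA recorded in *every* disease contributes
   nothing ($\log 1 = 0$), and a pair with no records has weight exactly 0.
3. **Norm differences matter.** Similarity is the Tanimoto coefficient
   $S_{xy} = d_x\!\cdot\!d_y / (\lVert d_x\rVert^2 + \lVert d_y\rVert^2 -
   d_x\!\cdot\!d_y)$ rather than the cosine: diseases studied with very
   different intensity get damped similarity even when directions agree.

On real vectors the Tanimoto coefficient is bounded in $[-1/3, 1]$, not
$[-1, 1]$: the minimum $-1/3$ is attained at $y = -x$. The package follows
the defining formula and documents this range rather than renormalizing;
the sign semantics (positive iff the dot product is positive) are unchanged.

The network connects two diseases iff $|S_{xy}|$ *strictly* exceeds the
threshold, with the edge signed by $S_{xy}$. Every curated disease is a node,
so diseases without a supra-threshold partner remain as isolated nodes rather
than disappearing.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `threshold` | 0.05 | minimum absolute similarity for an edge. Without it the network is near-complete (any shared miRNA gives nonzero similarity) and distances degenerate to 1. Strict inequality; ties at the threshold are excluded. |
| `log_base` | $e$ | base of the DSW penalty. The similarity matrix is provably invariant to it (a base change rescales all weights by one positive constant, and Tanimoto is scale-invariant), so it only affects reported raw weights. Asserted numerically for bases $e$, 2, 10. |
| `n_reps` (coherence) | 200 | record-shuffle replicates. The empirical p-value is add-one corrected, so its floor is $1/(n_\mathrm{reps}+1)$. |
| `n_reps` (enrichment) | 99 | rewired-network replicates. |
| `swaps_per_edge` | 10 | attempted double-edge swaps per edge per replicate; enough attempted swaps to decorrelate edge placement in networks of the sizes used here. |

## Null models

**Record shuffle (coherence test).** Several randomization schemes are
defensible for a bipartite association collection. The implemented null
permutes the miRNA field across curated records while
diseases and directions stay fixed. This preserves exactly: each disease's
record count, the multiset of per-miRNA record counts, and the global
direction multiset — so the null destroys only the miRNA-to-disease wiring.
These conservation laws are asserted on every replicate. Note that each
miRNA's disease spectrum width $n_j$ is *recomputed* per replicate (it is not
invariant under the shuffle, since distinct-disease counts depend on the
wiring); weights, similarities, the network and the triangle census are all
rebuilt from scratch each round.

The coherence statistic is the ratio of coherent (0 or 2 negative edges) to
incoherent (1 or 3) triangles. When any replicate — or the observed network —
has no incoherent triangles the ratio is unusable, and the test falls back to
the coherent *share* (coherent / total) for all replicates; replicates with
no triangles at all count as less extreme than any observed value.

**Degree-preserving rewiring (enrichment test).** Each replicate restarts
from the observed network and attempts `swaps_per_edge` × |E| double edge
swaps $(a,b),(c,d) \to (a,d),(c,b)$, rejecting self-loops and multi-edges.
Each edge's sign and similarity travel with it, so the signed edge multiset
is conserved while the unsigned degree sequence is preserved exactly
(asserted per replicate); a node's positive/negative degree *composition*
may change, which is intended — the null asks where edges attach, not what
sign they carry. The rewiring is hand-written rather than delegated because
the package needs edge attributes to follow their edges deterministically.

**Empirical p-values** are one-sided with add-one correction,
$(1 + \#\{\text{replicates} \ge \text{observed}\})/(1 + n_\mathrm{reps})$,
so a reported p can never be 0; extreme outcomes are reported at the floor.

## Statistical conventions

- **Distance test:** classic pooled-variance two-sample Student's t-test (not
  Welch), treating the finite pairwise distances as independent observations;
  this independence is a simplification inherent to the approach and is
  flagged in the output by reporting both group sizes. Unreachable pairs are
  excluded and counted. Degenerate zero-variance groups follow a documented
  rule: equal means give $t=0, p=1$; unequal means give $t=\pm\infty, p=0$.
- **Fisher's exact test:** two-sided by the point-probability method — the
  sum of hypergeometric probabilities of all margin-preserving tables whose
  point probability does not exceed the observed one (with a $1+10^{-7}$
  relative guard against floating-point ties). Tables with a zero margin are
  degenerate with $p=1$. The odds ratio is the sample ratio $ad/bc$. No
  multiple-testing correction is applied across pairwise class tests; raw
  p-values are reported.
- **Triangle census:** an exact internal enumerator (igraph supplies the
  vertex triples; sign classification is the package's) reporting all four
  sign multisets $\{+++, ++-, +--, ---\}$; a cubic brute-force loop serves as
  the independent oracle in the tests.
- **Clustering coefficients** are computed on the unsigned skeleton (no
  signed variant is used); nodes of degree
  < 2 report `NaN`.
- **Determinism:** every stochastic function takes an explicit seed and uses
  a local RNG stream (the caller's RNG state is saved and restored); node
  orderings are lexicographic everywhere and numeric TSVs are written at
  full precision, so identical configuration gives byte-identical outputs.

## The synthetic generator

The generator emulates the structural features the analysis relies on:
multiple records per (disease, miRNA) pair; disease classes whose members
draw from a shared class miRNA pool (`within_class_share`) with a common
reference direction per miRNA (`sign_concordance`); heavy-tailed per-disease
miRNA counts (1 + Geometric, matching the skew of real association counts);
and overlapping class pools, since real disease classes share pan-disease
miRNAs. Defaults — 3 classes × 20 diseases, 150 miRNAs, pool size 40, mean 8
miRNAs per disease, sharing and concordance 0.9, record multiplicity mean 1.5
(the ratio of records to unique pairs in large curated collections is about
1.5) — are the package's standard validation conditions.

What it does **not** emulate: real class-size imbalance (e.g. the dominance
of neoplasms in curated databases), literature bias correlated with disease
prominence, miRNA family structure, or any semantic relationship between
classes. Passing the planted-recovery tests therefore shows the pipeline
detects class-concordant miRNA sharing when present at these strengths; it
does not certify performance on the real database's much more uneven
marginals.

Two limiting configurations have exactly provable behaviour, used as tests:
with sharing and concordance both 1, all intra-class similarities are
nonnegative and every intra-class triangle is coherent; with sharing 0, the
expected shared support of two diseases is $k_x k_y / M$ (chance overlap)
and mean $|S|$ is near zero.

## Problem sizes

Validation runs use the 60-disease / 150-miRNA planted configuration with
200 shuffle replicates for the coherence null and 99 rewiring replicates for
enrichment; the oracle batteries run 200 random signed graphs (up to 12
nodes) for the triangle census and every 2×2 table with total ≤ 40 for the
Fisher test. These sizes give the property tests full coverage of the
combinatorial edge cases while the whole suite completes in well under a
minute.

## Known limitations

- The distance t-test inherits the non-independence of pairwise distances;
  its p-values are descriptive.
- The record-shuffle null conditions on record-count marginals only; other
  defensible nulls (independent label shuffles, direction shuffles) would
  condition differently and are not implemented.
- Similarity is computed densely; the documented TSV serialization is the
  only cache format. For curated datasets of a few hundred diseases this is
  far from limiting.
- Disease-name unification (ontology mapping) is taken as input: the package
  normalizes case and whitespace deterministically but does not attempt MeSH
  tree traversal.
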