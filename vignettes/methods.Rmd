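---
title: "Methods: host-microbial network inference and key-factor ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: host-microbial network inference and key-factor ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kfnet)
```

## The model

`kfnet` treats a paired study — an OTU count table and a gene-expression
table on the same samples — as a single set of nodes (microbes and genes)
whose pairwise monotone associations define an undirected covariance
network. The modelling assumptions are deliberately minimal:

* **Association = Spearman rank correlation.** Monotone but possibly
  nonlinear relations, unequal scales and heavy tails are all tolerated;
  only the ranks matter. No compositionality-aware estimator (SparCC-style)
  or partial correlation is used: plain pairwise Spearman is the estimand.
* **Edges are thresholded correlations.** A pair is connected iff
  `|rho| > 0.4` and `p < 0.05`, both strict. The p-value is the two-sided
  t approximation with `n - 2` degrees of freedom, the standard choice at
  the ~58-sample scale this package targets; an exact permutation p-value
  (`method = "permutation"` in `spearman()`) is available for very small n.
* **Regulation labels carry prior sign information.** A differentially
  expressed gene is up- or down-regulated; two same-direction DEGs should
  not be strongly negatively correlated, and an up/down pair should not be
  strongly positively correlated. Violations are treated as false-positive
  edges and removed. Microbes carry no regulation label, so the coherence
  rules only ever act on gene-gene edges.
* **Collapsed OTUs can hide edges.** When OTUs are merged because their
  representative sequences share a reference best hit, a gene may
  correlate strongly with every sub-OTU yet miss the threshold against the
  merged profile. If all sub-OTUs pass the thresholds with a common sign,
  the missing edge is added (`origin = "inferred"`).

## Key-factor ranking

For a source group S (microbes) and target group T (a functional DEG
group), the bi-partite betweenness centrality of node v is

$$g(v) = \sum_{s \in S,\, t \in T} \frac{\delta_{st}(v)}{\delta_{st}},$$

with $\delta_{st}$ the number of unweighted shortest s–t paths and
$\delta_{st}(v)$ those passing through v as an interior vertex.
Implementation decisions, each made where the definition leaves room:

* **Unweighted hop-count paths.** Correlation strength does not enter the
  path metric; a `1 - |rho|` weighted variant was considered and rejected
  as a default because the ranking should reflect topology, not estimator
  magnitude. (It is not currently exposed.)
* **Endpoints excluded.** $\delta_{st}(v)$ counts v strictly interior,
  consistent with standard betweenness.
* **Unordered pairs counted once.** Doubling would scale all scores by two
  and change no ranking.
* **No normalization by |S|·|T|** — the raw sum is reported; scores are
  therefore bounded by |S|·|T|.
* **Determinism.** Ties in the ranking are broken lexicographically by
  node id.

The production path is a Brandes-style single-source BFS accumulation with
the unit pair mass deposited only at target-group members. Its contract is
exact equality with the brute-force definition; the test suite enforces
this against an independent igraph path-enumeration oracle on 100+ random
graphs, and the acceptance script recomputes that agreement rate.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `rho_min` | 0.4 | strict lower bound on `abs(rho)` for an edge |
| `p_max` | 0.05 | strict upper bound on the (raw) p-value |
| `top_k` | 259 | OTUs kept, ranked by mean relative abundance |
| `evalue_max`, `pident_min` | 1e-5, 80 | strict BLAST-hit filters for the collapse map |
| `min_subnodes` | 2 | sub-OTUs a collapsed OTU must absorb before the false-negative rule applies |
| `bh_correction` | off | optional Benjamini–Hochberg adjustment of the pairwise p-values |
| `node_pairs` | `"all"` | `"microbe_gene"` restricts edges to cross-kind pairs |

Two of these deserve comment. *Abundance ranking* uses the mean per-sample
relative abundance: after normalization it is robust to unequal sequencing
depths, whereas total raw counts would let deep samples dominate and
prevalence would ignore magnitude. *No multiple-testing correction by
default*: the reference analysis applies the raw `p < 0.05` rule to all
C(n, 2) pairs; `bh_correction = TRUE` is exposed for users who prefer
FDR control, with the caveat that it changes which network is built.

Open choices resolved as package decisions: the best-hit rule for a query
with several surviving BLAST hits is lowest e-value, then highest percent
identity, then lexicographic subject id; collapsing happens on raw counts
*before* normalization (summing integer counts is exact and conserves
per-sample totals, which the tests assert); a query whose best hit is
shared by no other query keeps its own OTU id; merged OTUs are named
`collapsed:<subject>` for traceability. The inferred-edge attributes
(mean rho, max p) are this package's rule — the existence conditions
determine *that* an edge is added, not its attributes, and the
mean/maximum pair is the conservative summary of the sub-OTU evidence.
The network is built over *all* node pairs (microbe–microbe and gene–gene
included); `node_pairs = "microbe_gene"` gives the bipartite-only variant.

## The synthetic generator

`synthetic_spec()`/`generate_dataset()` emulate a paired study:

* a latent Gaussian copula over all nodes carries the planted pairwise
  Spearman correlations; the latent Pearson entry is
  $2\sin(\pi\rho_s/6)$, so the population Spearman equals the target
  exactly; a non-positive-semidefinite request errors before sampling;
* microbial counts: per-OTU base log-means drawn N(0, 1.5²) (heterogeneous
  community), per-sample intensities $\exp(\mu_i + z_{ij})$ converted to
  proportions and drawn as one multinomial per sample at a depth uniform
  on [10 000, 50 000] — unequal depths exercise normalization, and columns
  sum to their depth exactly;
* expression: the latent gene values plus independent N(0, 0.1²) noise —
  small, so the planted Spearman strength is attenuated well below the
  threshold resolution;
* labels: up/down drawn per `deg_fraction_up`, then planted gene-gene
  pairs forced sign-coherent so the false-positive rules never delete a
  true planted edge; groups drawn per `group_proportions`
  (default ¼ each);
* BLAST hits: each collapse group hits one shared subject passing the
  filters, plus a decoy failing them; ground truth ships with every
  dataset.

The same spec and seed give bit-identical outputs (the draw order is part
of the contract).

**What it does and does not emulate.** The generator reproduces the
statistical skeleton of a paired study — monotone associations of chosen
strength, compositional count observation, unequal depths, labelled DEGs,
collapsible OTUs — but not 16S sequencing artefacts (chimeras, error
profiles), taxonomic structure, or realistic zero-inflation patterns.
Passing tests demonstrate correctness of the pipeline's logic under
controlled truth, not performance on real amplicon data.

Two intrinsic features of the count layer matter when reading test
expectations. First, mapping latent normals through the multinomial read
draw attenuates microbe-side correlations by roughly 0.05–0.1 — per-sample
sampling noise does not average out with more samples — so planted
microbe-gene correlations are checked to a wider band than gene-gene ones.
Second, closure (proportions summing to one) induces weak spurious
negative correlations among OTUs, which is one reason the all-pairs
network at raw thresholds contains false microbe-microbe edges.

## Numerical choices

* Ranks use the average-tie convention (`rank()`'s default), the standard
  Spearman treatment.
* `rho` is computed as the Pearson correlation of centered rank vectors
  with explicit sums: ranks and their mean are exact multiples of ½, so
  the cross-products are exact in double precision and simple rational
  results (e.g. 8/10 on the five-point worked case) are correctly rounded.
* A constant vector (zero rank variance) yields the `NA` no-correlation
  sentinel, which can never form an edge; constant features are dropped
  from `correlate_all()` output.
* Parallel-edge resolution keeps the copy with the largest `|rho|`, then
  the smallest p-value.
* All thresholds are strict inequalities; records sitting exactly on
  `rho = 0.4` or `p = 0.05` never form an edge.
* Edge endpoints are stored and written in lexicographic order, and all
  rankings break ties lexicographically, so reruns are byte-identical.

## Problem sizes in the test suite

The suite checks the BpBC implementation against exhaustive enumeration on
100 random graphs of up to 12 nodes, the Spearman implementation against
the rank-then-Pearson oracle on 1 000 random vectors (ties included), and
the full pipeline on 50 seeded replicates of a 58-sample, 30-OTU, 50-gene
design with ten planted associations at Spearman 0.8 — sizes chosen so
the whole suite runs in well under a minute while every code path is
exercised at the study's sample scale.

## Known limitations

* **Precision at raw thresholds.** With ~3 000 candidate pairs, a handful
  of null pairs will exceed `|rho| > 0.4` at n = 58 by chance, and closure
  adds spurious microbe-microbe edges; the recovered network therefore
  contains false edges alongside the planted ones (the acceptance script
  reports the measured recall and precision). `bh_correction` and
  `node_pairs = "microbe_gene"` both reduce, but do not eliminate, this.
* Spearman is pairwise and marginal: indirect associations are not
  deconvolved, and compositional effects are not modelled.
* The false-negative rule only ever adds collapsed-OTU–gene edges; no
  other edge type can be inferred.
* BpBC significance is not assessed; the ranking is descriptive.
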