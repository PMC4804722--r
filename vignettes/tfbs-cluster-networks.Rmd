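---
title: "Stage-specific TFBS co-occurrence networks with Markov clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-specific TFBS co-occurrence networks with Markov clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfbsnet)
```

## The analysis in one paragraph

Developmental transitions — here, the differentiation of human stem cells
into cardiomyocytes over a 60-day time course — are driven by combinations
of transcription factors (TFs) acting on the promoters of stage-specific
genes. Single binding sites are weak evidence; *co-occurring* pairs of
TF binding sites (TFBSs) within one promoter, at biologically plausible
distances and orientations, are much stronger evidence of cooperating
factors. `tfbsnet` implements that idea as a pipeline: select the genes
uniquely differential in each developmental stage, extract their upstream
promoters, detect composite TFBS pairs with a PWM scanner under
distance/orientation constraints, summarize the pairs per stage as a
frequency-weighted undirected network, cluster each network with the
Markov clustering algorithm (MCL), and follow the hub-centered clusters
across stages: which partners a hub keeps, gains, and loses, whether the
underlying TF genes are actually expressed (FPKM at or above 10), and
whether the per-stage counts form the hourglass shape (high early and
late, minimal mid-course) reported for several developmental systems.

## Stages and differential genes

The time course has six timepoints (days 0, 3, 8, 13, 29, 60) bounding
five stages: mesoderm induction (0–3), early and late cardiac
specification (3–8, 8–13), early and late cardiac maturation (13–29,
29–60). A gene belongs to a stage's unique set when it passes `p <= 0.05`
and Benjamini–Hochberg `FDR <= 0.01` between that stage's two bounding
timepoints and in *no other* stage, is protein-coding, and is not itself a
TF gene. The full moderated linear-model machinery of microarray/RNA-seq
packages is deliberately out of scope; the differential test is pluggable
and defaults to a pooled-variance two-sample t-test on `log2(FPKM + 1)`
across replicates. Pooled variance matters with triplicates: Welch's
degrees of freedom collapse toward 2 and floor the attainable p-values
near the BH cutoff, whereas the pooled test (df = 4) behaves like the
moderated tests used in practice. The uniqueness comparison applies the
same thresholds symmetrically in the other stages, the simplest reading
of "unique".

## Promoters

Promoters are the 1 kb upstream of the annotated TSS (`[-1000, 0)` in
0-based, BED-style coordinates; the `[-500, 0)` and `[-500, +100)`
variants are exposed as configuration). Minus-strand genes mirror the
window and the sequence is reverse-complemented, so every promoter reads
5'→3' toward its TSS. Because one gene can carry several annotated TSSs,
overlapping promoter regions would overweight whatever sites they share;
any promoter overlapping another (same chromosome, strand-agnostic) is
dropped — both members of a pair. Internally the package uses 1-based
inclusive coordinates like the Bioconductor ranges infrastructure; all
files it writes are 0-based half-open.

## Scanning and composite pairs

A PWM is stored as an `L x 4` count matrix with a pseudocount and a
background distribution. Windows are scored on both strands with the
min–max-normalized log-probability ("MATCH-style") score
`(S - Smin) / (Smax - Smin)`, which maps the consensus to 1 and the
per-position-worst word to 0, making thresholds portable across matrices.
The default pseudocount is 1% of the mean per-position count total;
windows containing `N` never score. Information content is the
Kullback–Leibler divergence from background in bits, computed with the
same pseudocount — so printed IC values from count libraries are
reproduced only up to that convention.

A composite model pairs two PWMs with per-side thresholds, an
edge-to-edge gap window (nucleotides strictly between the two spans;
overlapping sites never pair), and an orientation constraint
(same/opposite/any strands). Pairs are unordered by default — either side
may lie upstream — matching their role as undirected network edges; an
`ordered` flag is available for genuinely directional models. Per stage,
the edge weight of a pair is the number of distinct promoters containing
it at least once (a total-occurrence mode exists; promoter counting is
the default because repeated hits within one promoter are usually the
same biological site family).

## The Markov clustering step

For each stage the pairs define an undirected network: nodes are TFBSs,
edge weights the pair frequencies `w(v_i, v_j)`. The adjacency matrix is
row-normalized into a transition matrix `M = Δ⁻¹·A` and clustered by
iterating **Expand** (`M ← M·M`) and **Inflate** (entrywise power `r`
followed by row renormalization) until the maximum entrywise change drops
below `1e-6` (default cap 200 iterations, warned on non-convergence).
The inflation parameter defaults to `r = 2`; larger values fragment the
network into finer clusters.

Numerical choices worth knowing:

* **Self-loops.** The bare `Δ⁻¹·A` normalization has no self-loops, and
  classic MCL convergence arguments need them. By default each node gets
  a self-loop equal to its maximum incident edge weight (1 for an
  isolated node); setting the weight to 0 recovers the literal formula.
* **Pruning.** Entries below `1e-9` are zeroed during inflation; the same
  epsilon defines attractor detection.
* **Cluster extraction.** Attractors are nodes with positive diagonal
  flow; attractors with direct mutual flow merge into one attractor
  system; every other node joins the attractor it sends maximal flow to,
  with ties resolved to the lexicographically smaller id (and a message).
  This yields a partition, which downstream stage tables require.
* **Singletons** are retained by `run_mcl` but removed by the
  reportable-cluster filter.

## Hubs, stage tables, and temporal categories

A cluster is *reportable* when its induced subgraph has at least three
edges — "at least three interactions", the size of the smallest hub
cluster worth reporting. The *hub* of a cluster is its node of maximal
within-cluster weighted degree (lexicographic tie-break); this formalizes
the informal notion of the binding site "in the center" of a cluster.
Tracking a hub across stages produces a presence table: one row per
partner ever adjacent to the hub inside its cluster, one +/- column per
stage. Rows fall into four temporal categories: `all_stages` (present
throughout), `interrupted` (any present–absent–present pattern),
`stage_specific` (exactly one stage), and `other` (plain early or late
blocks). The first two mirror the two headline categories of
developmental pair behaviour — constitutive versus switching — while
`other` keeps the classification total.

Expression annotation asks whether the TFs behind a pair could actually
meet: a side is "expressed" at a timepoint when the mean FPKM (replicates
averaged) of its best mapped TF gene is at least 10 (inclusive). A pair
whose sides share an expressed timepoint inside every stage where the
pair occurs is a `synergistic_candidate`; sides expressed in disjoint
windows within every present stage make an `antagonistic_candidate`
(e.g. one factor early, its partner late — the pair's sites persist while
the occupying factor switches); everything else is `indeterminate`. This
rule is a screening formalization of a qualitative argument, so the raw
expressed sets are always reported next to the label, and raising the
threshold can only demote a pair away from synergistic (expressed sets
shrink monotonically).

`hourglass_profile()` reduces a five-stage count vector to the position
of its minimum (first on ties) and whether that minimum is interior
(stages 2–4) — the signature of the hourglass: both the reported
per-stage pair counts (63, 82, 24, 52, 76) and DEG counts (429, 1233,
36, 205, 964) have their minimum at stage 3, late cardiac specification.

## The synthetic fixture

No public accession provides the underlying RNA-seq time course, and the
composite-pair library derived from curated TF-interaction data is
proprietary. The generator therefore emulates the *statistical shape* of
both, with ground truth recorded for every planted feature:

* **Genes and expression** (defaults): 300 genes, 6 timepoints, 3
  replicates, lognormal noise with sd 0.25 on the log2 scale. 40 unique
  DE genes per stage get a single step of |log2 FC| = 4 at their stage's
  closing timepoint; 6 decoys step up and back down, making them DE in
  two stages (they must never enter a unique set); background baselines
  straddle the FPKM-10 threshold; a few non-coding and
  overlapping-promoter decoys exercise the biotype and overlap filters.
  TF genes follow designed threshold-crossing patterns, including one
  always-expressed pair (the synergistic control) and one early/late
  disjoint pair (the antagonistic control).
* **Promoters and sites**: 1 kb promoters on alternating strands of one
  synthetic chromosome. Four hub TFBSs with 4–6 partners each; each
  present hub–partner pair is planted in 6 promoters per stage, weak
  cross-hub noise pairs in 1. The first three partners of every hub are
  present at all stages, so each per-stage hub cluster keeps at least
  three edges (the same shape as the largest reported cluster, whose six
  pairs include three constitutive ones). Remaining partners carry
  interrupted, stage-specific, and random patterns. Planted sites are
  sampled from the PWM distribution with a realized-score floor of 0.97,
  just above the default 0.95 scan threshold; consecutive plantings are
  spaced further apart than the maximal allowed gap so two plantings can
  never assemble into a spurious library pair.
* **Synthetic PWMs**: length 12, information content 16–20 bits, built
  from sharply peaked positions plus two "soft" two-letter positions
  (second letter nearly as probable as the first, the remaining two
  rare). Soft positions make planted sites vary while any mismatch
  outside the top two letters costs more log-probability than a 0.95
  threshold forgives — so background false sites, and hence false
  composites, are negligible and the planted pair counts are recovered
  exactly. Real curated matrices are broader (reported ICs around 12–14
  bits) and would carry a false-positive load; the generator trades that
  realism for exact oracles, which is the right trade for testing
  correctness but means measured false-positive rates here say little
  about genomic scans.
* **Background sequence** is i.i.d. with configurable GC; a Markov
  background would be more genomic but would only matter for
  false-positive statistics this fixture deliberately suppresses.

Every generator output is a deterministic function of the seed
(byte-identical files), and `ground_truth` carries planted occurrences,
per-stage pair weights, unique DEG sets, hub memberships and presence
patterns, and TF expressed sets.

What passing tests on this fixture show: the scanner, pair detector,
aggregator, network builder, MCL, hub tracker, and annotation rule are
correct and stable under realistic noise in expression space. What they
do not show: performance on real promoters (repeat structure, CpG
composition, soft matrices), nor anything about the biological claims of
any particular study.

One caveat is intrinsic rather than a bug: at `FDR <= 0.01` with ~260
true-null gene-stage tests per stage, Benjamini–Hochberg is *expected*
to admit a false discovery every few stages, so per-seed exact equality
of recovered and planted DEG sets is not a statistically attainable
contract. The suite asserts what the procedure does guarantee: ≥95%
recall of planted unique DEGs, and zero leakage of multi-stage DE genes
into any unique set.

## Problem sizes and runtime

The default fixture (300 genes, ~200 scanned promoters of 1 kb, ~26
PWMs, 5 stage networks of ~25 nodes) analyzes in a few seconds;
the replicate suites (20 seeds) run in a few minutes on one CPU. These
sizes were chosen so the hub-and-spoke structure is unambiguous at
`r = 2` while the whole study design, not a toy excerpt, is exercised.

## Known limitations

* The scanner's scoring is one defensible reading of "MATCH-style"; the
  original composite-detection tool's internal score is unpublished, so
  absolute thresholds are not transferable to it.
* The uniqueness rule uses symmetric thresholds across stages; a laxer
  counter-threshold would shrink the unique sets.
* MCL is the dense textbook formulation — adequate for TFBS networks of
  tens of nodes, not for genome-scale graphs.
* The synergistic/antagonistic labels are candidate screens over
  threshold-crossing patterns, not statements about physical interaction.
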