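---
title: "Methods: wiring and analyzing an integrated transcription-splicing regulatory network"
author: "crossregnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wiring and analyzing an integrated transcription-splicing regulatory network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossregnet)
```

## The model

`crossregnet` studies cross-regulation among the master regulators of gene
expression: splicing factors (SFs), transcription factors (TFs) and kinases.
The central object is a typed directed network whose nodes are regulator
genes and whose edges are predicted regulatory interactions of two kinds:

* **splicing edges** (SF → target): the target gene carries an
  alternative-splicing (AS) event — cassette exon, alternative 3′ or
  alternative 5′ splice site — and a conserved binding motif of the SF lies
  inside the event's search region;
* **transcription edges** (TF → target): a conserved binding motif of the
  TF lies inside the target's promoter.

Motif hits are *inputs*: the package does not score motifs or compute
conservation. Given gene models, AS events and hit tables, the wiring rules
are purely interval arithmetic, and everything downstream is statistics on
the resulting graph.

### Window rules

For a cassette exon, splicing motifs are searched in the last 100 nt of the
transcript-upstream intron, the entire event exon, and the first 100 nt of
the transcript-downstream intron. Alternative 3′ events search only the
upstream window and the exon; alternative 5′ events only the exon and the
downstream window. Windows truncate to the intron when it is shorter than
100 nt, and upstream/downstream are resolved in transcript orientation, so
the windows always abut the exon regardless of strand. The promoter is the
5,000 bases strictly upstream of the TSS; the TSS base itself is excluded.

Coordinates are 1-based closed intervals throughout (the Bioconductor
convention; BED input/output converts at the boundary via `rtracklayer`).
Overlap means nonempty intersection — a single shared base suffices, and a
hit spanning an exon/intron junction counts once. Self-loops
(autoregulation) are legitimate edges and are counted everywhere unless a
function's `selfLoops` argument says otherwise, because autoregulation of
splicing factors is a well-documented regulatory motif. A gene with several
AS events contributes one edge per regulator, not one per event.

### Layers

Nodes are classified by edge incidence: *source* (outedges only), *mixed*
(both), *sink* (inedges only), *isolated*. Kinases never emit edges — no
kinase→substrate map is wired — so they can only be sinks or isolated.

## Network statistics

**Clustering.** The global clustering coefficient (transitivity) is
3 × triangles / connected triples, computed on the undirected simple
projection of the network (directions, edge types and self-loops dropped),
via adjacency algebra: `trace(A³) / Σ k(k−1)`. Local coefficients are
defined as 0 for nodes of degree < 2. This matches the transitivity
convention of standard graph libraries (an igraph cross-check is part of
the test suite).

**Sparseness.** Edge count over a maximum-edge denominator. Because the
literature this analysis follows is ambiguous about the denominator (a
published formula reads E/E², which cannot stay in [0, 1]), three
conventions are exposed: `typed_bipartite` (default; E over the number of
wireable typed pairs, so a fully saturated planted network scores exactly
1), `simple_n2` (E/N²) and `paper_literal` (1/E, kept for comparison).
None is asserted to be "the" convention; the default is the one under
which sparseness is a calibrated fraction of realizable wiring.

**Null ensembles.** Two null models are exposed because "random networks
with a similar degree distribution" and "the same average number of
edges" describe different nulls:

* `degree_swap` (default): double-edge swaps within each edge type,
  10 × E attempted swaps per replicate, preserving every node's typed in-
  and out-degree exactly; swaps that would duplicate a typed edge are
  rejected, and self-loops may arise (degrees are still preserved).
* `density_matched`: uniform random typed edge sets with the observed
  per-type edge count and the same role constraints (splicing sources are
  SFs, transcription sources TFs).

Significance is summarized by the z-score against the null moments and by
the upper-tail empirical p-value `(r + 1)/(n + 1)`, which is never zero and
bottoms out at `1/(n + 1)`. When the null ensemble is degenerate (sd = 0)
the z-score is reported as `NA` while the empirical p remains valid.

## Group statistics

Per-group inedge densities are reported as mean ± sem (the ± convention of
the densities this package reproduces is consistent with a standard error,
not an sd, given the reported group sizes). Group contrasts use the
Mann–Whitney test: exact by full enumeration of pooled-label splits when
the number of splits is at most `maxEnum` (2 × 10⁵; this covers every
combined sample size the exactness tests require, while the 20-vs-90 and
90-vs-147 comparisons of the real group sizes use the tie-corrected normal
approximation with continuity correction, as any practitioner's tool
would). Two-sided is the default since no direction is pre-registered. The
Spearman correlation between a node's splicing and transcription inedge
counts is computed per target group with average ranks; it is `NA` for
constant count vectors.

The randomized-group control repartitions the pooled node labels, without
replacement, into pseudo-groups of the original sizes (20/90/147 at the
default composition) and summarizes each pseudo-group's mean inedge
densities over 100 iterations. A genuine group effect separates the true
group means from the pseudo-group spread; a size artifact does not.

## Combinatorial regulation

For every unordered factor pair, the number of shared targets is tested
against the upper-tail hypergeometric distribution with the full node set
as the universe (N = 257 at default composition; a restricted universe can
be passed explicitly, since the natural splicing universe — AS-event
bearing genes — is itself a modelling choice). SF–SF pairs compare
splicing target sets, TF–TF transcription target sets, and SF–TF pairs the
SF's splicing targets against the TF's transcription targets. The tail is
computed in log space (`phyper(..., log.p = TRUE)`), so the conventional
cutoff of 1e-16 — at the floor of double precision — remains a meaningful
threshold rather than a rounding artifact. Factors with no targets give
p = 1 by convention and all pairs are reported. Coverage is the fraction
of a group's genes that are targets of *both* members of at least one
significant pair.

## Tissue-specific subnetworks

A gene enters a tissue's subnetwork when its expression is strictly above
the tissue mean, the mean being taken over *all* atlas genes (network plus
array background) — ties are excluded because they have measure ~0 on real
arrays. The induced subgraph keeps exactly the edges with both endpoints
retained, and the group densities are recomputed on it. With the default
generator the heart tissue pins 14 SFs and 33 TFs above the mean and
smooth muscle 11 SFs and 40 TFs, the two tissues this analysis treats as
reference compositions.

## Sequence and term enrichment

The motif-validation procedure compares a "bound" set of 41-nt sequences
against a control set (default size 1,000, emulating random mid-intron
sequences): the hit fraction is the share of sequences with at least one
motif match (exact or IUPAC-degenerate), and enrichment is a one-tailed
Fisher exact test on the 2×2 hit table, with a Haldane-corrected odds
ratio when a cell is empty. Term enrichment over an annotation table is a
plain upper-tail hypergeometric per term with Benjamini–Hochberg
adjustment — deliberately the textbook test, not any tool-specific
modification, so exact reproduction of third-party GO-tool outputs is a
non-goal.

## Protein annotation summaries

Phosphorylation-site calls and per-residue disorder scores are inputs
(real analyses obtain them from dedicated predictors). Summaries report,
per group: the fraction of proteins with ≥ 1 site; among those, the
fraction whose site count exceeds 10% of protein length (strictly); the
mean site density; the mean fraction of residues with disorder score
≥ 0.75 (the cutoff is inclusive, flag-controlled, since the source
convention is unstated); and the fraction of proteins with at least one
run of ≥ 30 consecutive disordered residues. The random-proteome baseline
averages 10 draws of 250 pool proteins.

## The synthetic-data generator

The generator produces every input the pipeline consumes, with effect
sizes planted where the analysis expects them:

* **Gene features**: log-normal gene lengths, shifted negative-binomial
  exon counts and Poisson AS-event counts (per dataset tag A/B), all
  group-specific, chosen as the simplest two-parameter families that
  reproduce heavy-tailed gene-feature distributions. Defaults make kinase
  genes longest with the most exons and give SFs the most AS events per
  gene. Events sit on distinct internal exons and introns are ≥ 300 nt,
  so search regions of different events never touch.
* **Edges**: independent Bernoulli planting per (regulator, target) pair.
  A conserved hit is placed strictly inside an eligible window with
  probability `plantProb[type, group(target)]`. Defaults are calibrated
  from the reference group densities: splicing (4.0/20, 0.95/20, 1.0/20)
  and transcription (5.3/90, 8.3/90, 3.3/90) for (SF, TF, kinase) targets.
  Because a gene without an AS event in a dataset cannot receive splicing
  edges there, the analytic expected mean is
  `p × n_SF × fracWithEvent`, and the generator records exactly this in
  its ground truth. Non-conserved decoy hits (rate 0.05) exercise the
  conservation filter without affecting default wiring.
* **Atlas**: background genes are log-normal; network genes are pinned at
  known multiples of the *final* tissue mean (solved analytically), so
  planted above-mean sets are recovered exactly by the filter.
* **Annotations**: group-specific probabilities of carrying phospho sites
  (0.49/0.42/0.77 for SF/TF/kinase) and, among carriers, of high (>10%)
  coverage (0.88 for SFs; the TF and kinase values, 0.40 and 0.60, are
  qualitative choices where no reference number exists). Disorder scores
  follow a two-state Markov chain with group-specific stationary disorder
  probability and mean run length, making SFs/TFs more disordered with
  longer runs than kinases.
* **Sequences**: 41-nt sets with the motif planted at rate `qBound`
  (default 0.75) in bound and `qControl` (0.05) in control sequences;
  non-planted sequences are rejection-sampled motif-free so hit fractions
  estimate the planting rates exactly.

### What the generator does and does not emulate

Planting is independent across pairs. Real regulatory networks are not:
they exhibit triadic closure and coordinated binding. Consequently, on
default synthetic data the clustering z-score is near 0 and the pair scan
finds (correctly) no co-regulating pairs — those stages are validated
instead on hand-wired networks with planted triangles and planted shared
target sets, where their detection behavior is provable. Passing tests on
synthetic data therefore demonstrate correctness of the statistics, not
realism of any particular biological claim. Likewise no sequence-level
motif model, conservation process, probe effects or expression-length
coupling are simulated.

## Numerical and design choices

* Exact MW enumeration bounded by `maxEnum = 2e5` splits; beyond that the
  tie-corrected normal approximation is used and labelled as such.
* Hypergeometric and Fisher tails via `phyper`/`fisher.test`; pair tails
  in log space.
* Degree-swap attempts default to 10 × E per replicate; E < 2 edges of a
  type cannot be swapped and return copies with a warning.
* One master seed fans out to per-stage child seeds (`childSeeds`), so any
  stage can be re-run in isolation and the full pipeline is byte-identical
  across runs of the same configuration.
* Problem sizes used by the shipped checks: the full study composition
  (20/90/147) for end-to-end runs; 200 generator seeds for the
  planted-contrast power check and the no-effect false-positive check;
  100 seeds × 100 replicates for null-model calibration; 1,000
  degree-swap replicates for the headline clustering z-score; exhaustive
  graph enumeration to 5 nodes (1,099 graphs) plus sampled 6-node graphs
  for the clustering oracle.

## Worked example

```{r example}
cfg <- generatorConfig(seed = 11)
bundle <- generateBundle(cfg)
net <- buildNetwork(bundle, dataset = "A")
net

inedgeDensity(net, "splicing")[, c("group", "n", "mean", "sem")]

spl <- inedgeCounts(net, "splicing")
grp <- setNames(networkNodes(net)$group, networkNodes(net)$gene_id)
mannWhitney(spl[grp == "SF"], spl[grp == "TF"])$p
```

## Known limitations

* Motif hits, AS-event calls, expression values and predictor outputs are
  trusted inputs; no quality model is applied to them.
* The pair-scan universe defaults to all nodes for every pair class; a
  biologically restricted universe changes p-values and must be supplied
  by the caller.
* The exact MW path is bounded by enumeration size, not by the sample-size
  rule of thumb; borderline sample pairs silently use the normal
  approximation (the `method` field always says which was used).
* Tissue subnetworks filter nodes only by expression; they do not
  re-restrict AS events to tissue-derived event calls.
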