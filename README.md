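# crossregnet

Integrated transcription–splicing regulatory network analysis in R.

## The problem

Gene expression is steered by a small cadre of regulators — transcription
factors (TFs) that bind promoters, splicing factors (SFs) that bind
pre-mRNA near splice sites, and the kinases that modulate both. These
regulators also regulate *each other*, and a recurring organizing
principle is **cross-regulation**: a regulatory group tends to be wired by
the very modality it performs (SFs receive the densest alternative-splicing
regulation, TFs the densest transcriptional regulation), with weaker
**cross-talk** between modalities.

`crossregnet` is for computational biologists who want to build and
interrogate such an integrated network from standard evidence tables. The
nodes are SF, TF and kinase genes; the typed directed edges are wired by
two interval rules:

* **splicing edge** SFᵢ → gene j exists iff gene j has an
  alternative-splicing event (cassette exon, alt 3′ or alt 5′) and a
  conserved binding motif of SFᵢ overlaps the event's search region —
  the last 100 nt of the transcript-upstream intron, the event exon, and
  the first 100 nt of the downstream intron (sides dropped for alt 3′/5′);
* **transcription edge** TFᵢ → gene j exists iff a conserved motif of TFᵢ
  overlaps the 5 kb strictly upstream of gene j's TSS.

On the wired graph the package computes: the global clustering coefficient
*C* = 3·triangles/triples with z-scores against degree-preserving
(double-edge-swap) and density-matched null ensembles; network sparseness
under three denominator conventions; per-group inedge densities
(mean ± sem) with Mann–Whitney contrasts (exact by enumeration for small
samples, tie-corrected normal otherwise); Spearman correlations ρ between
a node's splicing and transcription inedges; a randomized-group control;
an upper-tail hypergeometric scan for factor pairs sharing more targets
than chance, P(X ≥ k | N, K, n), computed in log space so the 1e-16 cutoff
is meaningful; tissue subnetworks induced by an above-average expression
filter; Fisher-exact motif enrichment of bound vs control sequence sets;
generic hypergeometric term enrichment; and summaries of predicted
phosphorylation sites and intrinsic disorder (0.75 score cutoff, ≥30-residue
runs).

A first-class synthetic-data generator emulates every input — gene models,
AS events, motif-hit BED tables, a gene × tissue atlas, residue-level
annotations, labelled 41-nt sequence sets — with *plantable* effect sizes
and an analytic ground-truth record, so the whole pipeline is testable
end to end without any external downloads.

## Worked example

```r
library(crossregnet)

cfg <- generatorConfig(seed = 11)       # 20 SFs, 90 TFs, 147 kinases
bundle <- generateBundle(cfg)
net <- buildNetwork(bundle, dataset = "A")
net
#> RegulatoryNetwork: 257 nodes, 1570 typed edges (splicing: 240 ,
#>   transcription: 1330 ), dataset A
#> isolated    mixed     sink
#>        3      110      144

inedgeDensity(net, "splicing")[, c("group", "n", "mean", "sem")]
#>    group   n      mean        sem
#> 1     SF  20 3.7000000 0.44188591
#> 2     TF  90 0.5888889 0.09980561
#> 3 KINASE 147 0.7687075 0.08745143

spl <- inedgeCounts(net, "splicing")
grp <- setNames(networkNodes(net)$group, networkNodes(net)$gene_id)
mannWhitney(spl[grp == "SF"], spl[grp == "TF"])$p
#> [1] 8.427153e-10

nullZscore(net, nullModel = "degree_swap", nRandom = 200, seed = 1)
#> NullEnsembleResult [clustering, degree_swap null, n=200]
#>   observed = 0.1054, null = 0.1104 +/- 0.0027, z = -1.85,
#>   empirical p = 0.965
```

Reading: splicing regulation is an order of magnitude denser toward SFs
(3.7 inedges per SF vs 0.59 per TF; the planted cross-regulation effect),
the Mann–Whitney test resolves the contrast decisively, and — because the
generator plants edges independently — the clustering z-score against the
degree-preserving null is unremarkable, exactly as it should be for a
network without triadic structure.

`runPipeline(cfg, outDir = "run1")` executes every stage (build → null
ensembles → densities → correlations → control → pair scan → tissue
subnetworks → enrichment → annotation summaries) and writes per-stage TSVs
plus a JSON report; `inst/scripts/crossregnet.R` is a thin command-line
wrapper around it. Real data enter through the same TSV/BED/FASTA readers
the generator writes (`readGeneModels`, `readMotifHitsBed`, `readAtlas`,
`loadSupplementaryNetwork`, ...).

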