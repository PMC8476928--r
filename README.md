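# scBreg

Identification of regulatory B (Breg) cells and their B10 / non-B10
partition from paired single-cell gene expression and B-cell receptor
(BCR) sequencing across organs, for immunologists analysing multi-organ
B-cell atlases (mouse spleen, liver, mesenteric lymph node, peritoneal
cavity, bone marrow) and for methodologists who need a fully synthetic,
ground-truthed test bed for signature-score classifiers and repertoire
analytics.

Breg cells lack a unique surface marker, so the package defines them
operationally through a gene-signature module score. On the z-scored
expression matrix $z$, the score of cell $c$ for signature $S$ is

    score(c) = ln(1 + mean_{g in S} z_cg)

A cell is Breg when its Breg-signature score exceeds 0.16 (strictly);
Breg cells with a high B10-signature score form the B10 compartment, the
rest are non-B10 Breg. Around this core the package provides:

- **QC** with strict boundaries: cells kept with 300–8,000 unique genes,
  mitochondrial fraction ≤ 10%, complexity log10(genes)/log10(UMIs)
  ≥ 0.8; genes kept when expressed in ≥ 10 cells; removal of BCR
  multichain doublets (≥ 2 distinct heavy *and* ≥ 2 distinct light
  chains).
- **Per-organ differential expression** (Wilcoxon rank-sum with exact
  permutation p-values for small groups, Benjamini–Hochberg) and the
  cross-organ intersection yielding common Breg marker genes.
- **Repertoire analytics**: clonotype assignment from 10x-style contig
  annotations (V gene + CDR3 over all chains), pairwise organ sharing of
  clonotypes and cells, and entropy-based clonal indices (bits):
  expansion = 1 − H/log2 K, clone-size-weighted migration across tissues
  and transition between cluster pairs.
- **A seeded synthetic-data generator** planting Breg/B10 truth,
  expanded and organ-shared clones, and multichain doublets, so the
  whole pipeline is testable offline.

## Worked example

```r
library(scBreg)

cfg <- run_config(out_dir = "breg-out", sim = sim_config(seed = 1), seed = 1)
res <- run_pipeline(cfg)
summary(res)
#> Breg identification run
#>   cells (post-QC): 4771, genes: 1500
#>   Breg: 745 (15.6%), B10 among Breg: 59.5%
#>   common markers across 5 organs: 94
#>   recovery: Breg AUROC 0.989, doublets flagged 153/153
```

Reading the output: of 5,000 simulated B cells, 4,771 survive QC; 15.6%
are called Breg (the generator plants 14.4% on average, PC-enriched);
the calibrated B10 cut recovers 59.5% B10 among Breg against 60%
planted; 94 genes are upregulated in Breg cells in *every* organ (out of
134 planted signature genes); the Breg score separates planted truth
with AUROC 0.989, and all 153 planted multichain doublets are flagged,
with no false flags. Per-organ composition, DE tables, sharing matrices
and clonal indices are written as plain CSV/JSON under `breg-out/`,
together with the echoed configuration and a run log.

The same pipeline runs on real 10x exports via
`run_config(input_dir = ..., breg_signature = "breg.txt",
b10_signature = "b10.txt")`, where the signatures are plain-text gene
lists (one symbol per line). A thin command-line wrapper lives at
`inst/scripts/breg-pipeline.R` (`simulate` and `run` subcommands).

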