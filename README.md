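# graftflow

Detection and multi-omics analysis of **mobile mRNAs** (mb-mRNAs) in
grafted plants, for researchers studying long-distance RNA transport
between a rootstock (e.g. pumpkin) and a scion (e.g. watermelon).

When two species are grafted, some rootstock transcripts cross the graft
union and appear in scion tissues. They are detected from scion RNA-seq by
a two-stage classification:

1. align reads to the **scion** reference; a read is scion-mapped at
   identity ≥ 0.90 over ≥ 0.90 of its length;
2. rescue the remaining reads against the **rootstock** reference; reads
   with identity ≥ **0.95** (matches / alignment columns, over ≥ 0.80 of
   the read) are mb-mRNA candidates;
3. subtract false positives: any rootstock gene detected in a
   **homograft control** (same-species graft, where no foreign transcript
   exists) is excluded.

Downstream, candidates are quantified as FPKM; differential mb-mRNAs are
called at |log2FC| ≥ 1 and BH FDR ≤ 0.05 (exact binomial count test with a
library-size offset); tissue profiles are clustered by fuzzy c-means
(memberships u ∝ (1/d²)^{1/(m−1)}, default c = 5, m = 1.25); candidate
transcripts are folded (maximum base pairing and a constant-energy
partition function) to obtain base-pair probabilities, positional entropy
and a loop census; and transcripts, mb-mRNAs and metabolites are linked in
Spearman correlation networks (edges at |rho| ≥ 0.9, GraphML export).

A synthetic heterograft generator with planted ground truth (diverged
ortholog pairs, tissue-dependent mobility, sequencing errors, coupled
metabolites) makes every stage testable without any download.

## Worked example

```r
library(graftflow)

## a small simulated experiment: 30 ortholog pairs at 85% identity,
## 5 planted mobile genes, 2,000 reads per sample, 12 samples
cfg <- simulationConfig(nGenes = 30, geneLengthRange = c(200, 400),
                        nMobile = 5, readsPerSample = 2000, seed = 3)
sim <- simulateGraftExperiment(cfg)

se <- classifyExperiment(sim)          # trim, scion map, rootstock rescue
sh <- subtractHomograft(se)            # homograft false-positive filter

groundTruth(sim)$mobile_gene_ids
#> [1] "RSg0005" "RSg0020" "RSg0024" "RSg0027" "RSg0030"
sh$mobile_genes
#> [1] "RSg0005" "RSg0020" "RSg0024" "RSg0027" "RSg0030"
```

All five planted mobile genes are recovered, with no false positive. The
per-sample accounting shows the tissue distance effect — stem (near, YJ)
samples carry roughly five times the rootstock-read rate of pulp (far,
YG) samples, and homograft controls (XG/XJ) carry none:

```r
cd <- as.data.frame(SummarizedExperiment::colData(se))
cd[, c("sample_id", "clean_reads", "scion_mapped",
       "rootstock_mapped", "rootstock_overall_rate")]
#>      sample_id clean_reads scion_mapped rootstock_mapped rootstock_overall_rate
#> XG_1      XG_1        2000         2000                0                   0.00
#> XJ_1      XJ_1        2000         2000                0                   0.00
#> YG_1      YG_1        2000         1994                6                   0.30
#> YJ_1      YJ_1        2000         1965               35                   1.75
#> ...
```

`rootstock_overall_rate` is the percentage of clean reads accepted as
rootstock candidates (e.g. `mappedRate(35, 2000)` = 1.75). Folding a
candidate transcript and decomposing its loops:

```r
rna <- as.character(rootstockReference(sim)[["RSg0005"]])
fold <- nussinovFold(rna)
decomposeLoops(fold)
#> LoopCensus: hairpin 14 | internal 4 | bulge 34 | multibranch 12 | stacks 80 | external 1
prof <- pairProbabilities(rna)   # base-pair probabilities + entropy (nats)
```

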