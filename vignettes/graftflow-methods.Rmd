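---
title: "Detecting mobile mRNAs in grafted plants with graftflow"
author: "graftflow authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mobile mRNAs in grafted plants with graftflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graftflow)
library(SummarizedExperiment)
```

## The problem

When a scion (e.g. watermelon) is grafted onto a rootstock of another
species (e.g. pumpkin), some rootstock transcripts travel across the graft
union — typically via the phloem — and can be detected in scion tissues.
These graft-transmissible transcripts (mobile mRNAs, mb-mRNAs) are
identified from RNA-seq of scion tissues: reads are first aligned to the
scion genome; the reads that fail are rescued against the rootstock
reference, and those with high sequence identity to the rootstock are
candidate mobile transcripts. Because the two genomes are related, some
scion reads cross-map to the rootstock; a homograft control (scion grafted
on its own species, where no foreign transcript can exist) identifies
these homology-driven false positives, which are subtracted gene-wise.

graftflow implements this pipeline end to end, together with the
downstream layers usually reported alongside it: FPKM quantification and
differential calling of mobile transcripts between grafting conditions,
fuzzy c-means clustering of tissue expression profiles, secondary-structure
analysis of candidate transcripts (mobility has been linked to loop
content), and Spearman correlation networks integrating transcripts,
mobile transcripts and metabolites.

## The synthetic heterograft generator

Real mobile-mRNA datasets need two genomes and hundreds of millions of
reads. To make every stage testable, the package ships a generator
(`simulateGraftExperiment()`) with known ground truth. Its default
configuration is the study design the package targets, at desk scale:

* **200 ortholog pairs**, lengths 300–1500 nt. Each ancestor gene is drawn
  i.i.d. uniform over ACGT (GC 50%) and diverged into a scion and a
  rootstock copy by point substitutions only. The substitution count is
  fixed at `round((1 - identity) * L)` with positions sampled without
  replacement, so the realized per-site identity equals the 0.85 target up
  to rounding — substitution-only divergence keeps identity arithmetic
  exact and the aligner's test surface clean. 0.85 mimics cucurbit
  ortholog homology: close enough to cause cross-mapping pressure, far
  enough that a 95% identity rule separates the genomes.
* **20 planted mobile genes**. In heterograft samples a read is of
  rootstock origin with probability equal to the tissue's *mobility
  factor*: 0.02 in stem (near the graft union) and 0.004 in pulp (far).
  The distance dependence of RNA mobility is encoded as these two scalars
  because only the qualitative ordering (stem > pulp) is established;
  published stem rates of roughly 1.5–3% versus pulp rates of roughly
  0.4% motivate the defaults.
* **12 samples**: homograft/heterograft × pulp/stem × 3 replicates,
  labelled XG/XJ/YG/YJ (X = homograft, Y = heterograft, G = pulp,
  J = stem). Homografts draw from scion transcripts only.
* **50,000 single-end 100-nt reads per sample** with per-base substitution
  probability 0.005 and Sanger Phred+33 qualities consistent with that
  rate. Paired-end simulation is available (`paired = TRUE`).

Read names carry a provenance suffix (`|og=<gene>|gn=<genome>`) used only
by tests and oracles; a dedicated test permutes these tags and checks that
classification output is unchanged, so the classifier provably never reads
them.

What the generator does *not* emulate: splicing and isoforms, expression
dispersion beyond multinomial sampling, positional quality degradation,
adapter contamination, and indels (an option deliberately left out of the
defaults). Passing tests therefore demonstrate the pipeline's correctness
and its operating characteristics under clean homology structure, not its
robustness to spliced genomes or degraded libraries.

## Read classification

`classifySample()` follows the published two-stage rule:

1. **Trimming** (`trimReads()`): sliding window of 4 bases, cut before the
   first window with mean Phred quality < 15, discard reads shorter than
   75 nt — the common Trimmomatic `SLIDINGWINDOW:4:15 MINLEN:75` setting.
   The window semantics (cut before the window's first base) are pinned by
   an exhaustive window-scan oracle in the tests.
2. **Scion stage**: a read is scion-mapped when its best scion hit reaches
   identity ≥ 0.90 over ≥ 0.90 of the read. The published pipeline used a
   spliced aligner with default thresholds here; since the criterion is
   unstated we chose these round numbers and made them configurable.
3. **Rescue stage**: reads failing the scion stage are aligned to the
   rootstock reference and counted as mobile-mRNA candidates when identity
   ≥ 0.95 (the mobile-mRNA identity rule) over ≥ 0.80 of the read. The
   denominator of "95% identity" is matching columns over alignment
   columns (BLAST-like), computed on a fitting alignment (global in the
   read, free end-gaps in the reference window).
4. **Homograft subtraction** (`subtractHomograft()`): any rootstock gene
   with ≥ 1 candidate read in any homograft sample is excluded — the
   strictest reading of "detected in controls"; the threshold is
   configurable.

The aligner is built in: k-mer seeding (k = 15) on both strands, the modal
diagonal per reference, then banded global alignment (band 3) over the
seeded window, in C++. The published pipeline delegated these roles to
HISAT2 and BLASTN against whole genomes; at desk scale, with intron-free
synthetic references, a deterministic seed-and-extend aligner is
sufficient and keeps every alignment reproducible bit for bit. Ties are
broken by score, then lexicographically smallest gene id, then + strand.
The banded scores are verified against `Biostrings::pairwiseAlignment`
(global and global-local modes) in the tests. Paired mates are classified
independently and each fragment counts once, to the mate with the stronger
rootstock hit (ties to mate 1).

`mappedRate()` reproduces accounting-table arithmetic: 100 × mapped/clean
rounded half away from zero to 2 decimals. Note one subtlety: in published
accounting tables the rootstock-stage "clean reads" are the reads left
unmapped by the scion; the same convention is used here
(`rootstock_mapped_rate`). In the clean simulation almost every
scion-origin read maps to the scion, so that denominator is nearly all
rootstock-origin reads and the rate saturates; the accounting therefore
also reports `rootstock_overall_rate` (candidates over all clean reads),
which is the statistic that exhibits the distance effect.

## Quantification and differential calling

FPKM is `counts * 1e9 / (length * library size)`. Differential mobile
transcripts between two conditions are flagged at |log2FC| ≥ 1 and
BH-adjusted FDR ≤ 0.05. The fold change uses a +1 pseudocount on mean FPKM
for stability at the low abundances typical of mobile transcripts. The
p-value comes from an exact binomial test of a gene's pooled count in
group A out of the pooled A+B total against the library-size-expected
proportion. The published analysis named only the thresholds, not the
engine (likely a negative-binomial package); the exact binomial test was
chosen as a deterministic, dependency-free test whose null behaviour can
be verified exactly — a documented divergence. Consequences worth knowing:
the test is exact, hence slightly conservative at low counts (its size
approaches the nominal level as counts grow — the operating-characteristic
tests use genes with mean pooled counts in the thousands so discreteness
is negligible), and it does not model biological overdispersion across
replicates. BH adjustment is applied within each pairwise comparison.

`fuzzyCMeans()` clusters standardized log2(FPKM + 1) profiles
(`standardizeProfiles()`; constant rows are excluded since they carry no
shape). Defaults: c = 5 clusters (the usual choice for graft
tissue-course profiles), fuzzifier m = 1.25 (soft but decisive, in the
customary Mfuzz range for standardized profiles), tolerance 1e-6 on the
center shift, k-means++-style initialization from a seeded RNG so a fixed
seed reproduces the clustering exactly. A gene exactly on a center takes
membership 1 there (the degenerate-distance rule). The objective
trajectory is stored and tested to be non-increasing, and memberships are
cross-checked against `e1071::cmeans` on a fixture. Clustering operates on
whichever profile matrix is supplied; condition means are recommended for
tissue-course interpretation, replicate-level profiles for diagnostics.

Term enrichment (`hypergeometricEnrichment()`) is a one-sided
hypergeometric test against user-supplied gene-to-term annotations; the
background is the quantified gene universe of the comparison, not a whole
genome. `deltaDeltaCt()` provides the 2^−ΔΔCt relative-expression
arithmetic used for qPCR validation tables.

## Secondary structure

`nussinovFold()` maximizes the number of allowed pairs (AU/GC/GU, minimum
hairpin 3) by dynamic programming with a deterministic traceback (prefer
unpaired, then the smallest partner). `pairProbabilities()` computes the
partition function over all pseudoknot-free structures with a **constant
energy per pair** (E = −1, kT = 1) and inside/outside recursions, giving
base-pair probabilities, unpaired probabilities (which sum to 1 per
position, tested to 1e-9) and positional entropy in nats (base e, so
profiles are comparable across runs). Lengths beyond 2,000 nt are rejected
before the partition function can overflow.

This is deliberately *not* the Turner nearest-neighbour model used by
RNAfold: structural counts published for a specific transcript (e.g.
hundreds of internal loops in a full-length mRNA) are not reproduction
targets here. What the module does reproduce exactly is the machinery —
the loop taxonomy (`decomposeLoops()`: hairpin, stack, bulge, internal,
multibranch, external), the ensemble/MFE/centroid mountain profiles
(`mountainProfile()`, height at k = pairs (i, j) with i ≤ k < j, centroid
pairs at P > 0.5), and the positional-entropy profile — all verified
against exhaustive structure enumeration for short sequences. As kT → 0
the ensemble provably concentrates on the maximum-pairing structure, which
the tests confirm.

## Correlation networks

`spearmanRho()` is Pearson on average ranks (ties get mean ranks);
`buildNetwork()` computes all pairwise correlations across typed nodes
(rna / mobile_rna / metabolite), retains |rho| ≥ 0.9 by default, and
exports edge lists or GraphML for igraph/Cytoscape.
`pathwaySubnetwork()` filters edges to nodes sharing requested pathway
tags. Two granularities are possible: replicate-level profiles (up to 12
points in the default design — the package default, for statistical
sanity) or condition means (4 points, the mode used when only XG/XJ/YG/YJ
summaries exist). With 4 tie-free points Spearman can only attain
±1, ±0.8, ±0.6, ±0.4, ±0.2, 0 — the tests enumerate this set — so no
p-value filter is offered at that granularity; the threshold on |rho| is
the only filter, and 0.9 was chosen as the default since an unstated
threshold must have been high for the published networks to stay sparse.
The metabolite simulator couples a metabolite to a transcript profile by a
signed standardized transform plus Gaussian noise; `noiseForTargetRho()`
calibrates the noise so the expected correlation matches a target
magnitude, and with zero noise the realized Spearman is exactly ±1.

## Numerical and design choices

* Coordinates are 1-based closed in R structures; the C++ aligner works
  0-based half-open internally.
* All randomness flows from user-supplied integer seeds through R's RNG
  (including the C++ read mutator), so simulations are byte-identical
  under a fixed seed.
* Alignment scores: match +1, mismatch −1, gap −2 (linear). With
  substitution-only reads gaps are never favourable, but the band (±3)
  leaves room for small indels in real data.
* The identity example "3 substitutions in a 100-nt read → identity 0.97"
  holds exactly because the fitting alignment counts 100 columns.
* `validObject()` enforces the documented invariants on every S4 class
  (balanced structures, canonical pairs, membership row sums, probability
  conservation, sample-sheet uniqueness).

## Problem sizes used in the shipped checks

The test suite runs the full default design (200 genes, 12 samples,
50,000 reads each) for 10 seeds in the end-to-end recovery check, 50
count-level seeds for the null-size check and 20 for power, exhaustive
structure enumeration up to length 12, and 1,000 random p-vectors for the
BH oracle; unit tests use a 30-gene / 2,000-read miniature of the same
design. The acceptance script repeats the end-to-end run at 3 seeds.
These sizes were chosen so the whole suite completes in minutes on a
laptop while every statistical check retains enough resolution to fail
loudly if an operating characteristic regresses.

## Known limitations

* The aligner is unspliced and transcript-level; genome-level input with
  introns requires ingesting external alignments instead.
* The DE test ignores replicate-level overdispersion; with strongly
  dispersed real data an NB-based engine will be better calibrated.
* The folding model's energies are uniform; use it for loop taxonomy and
  entropy structure, not for thermodynamic accuracy.
* Homograft subtraction is gene-level and binary; partial (per-tissue)
  subtraction is not implemented.
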