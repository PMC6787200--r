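# tadgc

Sequence-composition analysis of chromatin architecture: GC-gradient
classification of TADs and loops, isochore families, interchromosomal
contact probability (ICP), nuclear-hub composition statistics, and
intra-TAD functional-element distributions — with a synthetic-genome
generator that makes every step testable against known ground truth.

## Who this is for

Computational (epi)genomicists who have TAD/loop calls (BED), a genome
(FASTA), and optionally binned contact data, hub annotations, feature
tracks and expression tables, and who want to ask: *how does DNA base
composition structure these domains and their nuclear behaviour?*

## The core statistics

**Gradient classes.** Each TAD/loop is divided into 100 equal bins; GC%
is computed per bin. For the two halves (bins 1–50, 51–100) the Pearson
correlation *r* between bin GC% and bin index is taken, and the sign
pattern of (r₁, r₂) against a flat threshold (|r| < 0.4 ⇒ flat) assigns
one of six classes:

- **A** — monotone GC increase/decrease: both halves same sign
- **B** — bell/peak: (+, −)
- **C** — valley: (−, +)
- **B⁻** — half bell (one ramping half, high plateau): (+, 0) / (0, −)
- **C⁻** — half valley: (−, 0) / (0, +)
- **D** — flat or uncorrelated: (0, 0)

Reversing a profile maps (r₁, r₂) → (−r₂, −r₁), so classes are invariant
to 5′/3′ orientation by construction. Classes are tabulated by isochore
family (L1 < 37% GC, L2 37–41, H1 41–46, H2 46–53, H3 ≥ 53, from the TAD
mean), verified by PCA of the N×100 GC matrix (F1 tracks mean GC%; F2/F3
separate bell-like from valley-like shapes), and probed for stability by
re-classification after ±50 kb boundary shifts.

**ICP.** For genomic bin *i* of a symmetric binned contact matrix,

    ICP_i = Σ_{j : chrom(j) ≠ chrom(i)} C_ij / Σ_j C_ij ∈ [0, 1],

the propensity of a region to form interchromosomal contacts; it is
correlated with windowed GC%, and GC% is compared between
nucleolar-hub and speckle-hub bins (Student's t-test).

**Tau.** Gene tissue-specificity on x = log2(TPM+1) over N tissues:
Tau = Σᵢ (1 − xᵢ/max x) / (N − 1); Tau < 0.3 ⇒ housekeeping, Tau > 0.8 ⇒
tissue-specific. Feature positions inside TADs use a 0–1 relative index
(midpoint, full containment required), with reflected-boundary kernel
density estimates.

## Worked example

```r
library(tadgc)

demo <- demo_pipeline(seed = 7, outdir = "demo_out")
demo$recovery
#  class_recovery        f1_gc_r   hub_gc_shift       icp_gc_r
#       0.9833333      0.9999988      5.0476153      0.5883258
```

This synthesizes a 120-TAD genome (four chromosomes, known gradient
classes, hub shift 5 GC points, GC–contact coupling 0.6), writes it to
FASTA/BED/TSV, re-reads the files, and runs the whole analysis. The
numbers mean: 98.3% of TADs were assigned their generating gradient
class; the first principal component of the profile matrix correlates
with mean GC% at |r| ≈ 1.0; the recovered speckle-minus-nucleolar GC
difference is 5.05 points (generator target 5); and the measured ICP–GC
Pearson r is 0.59 (generator target 0.6). `demo_out/results/` contains
the per-TAD class table, stratified class frequencies, PCA scores,
GC/ICP bedGraphs, relative-position records, gene Tau classes, and
per-family density tables.

The same pieces compose directly on real inputs:

```r
genome <- read_genome_fasta("hg19.fa")
tads   <- read_bed("tads.bed")
prof   <- tad_profiles(genome, tads)            # N x 100 GC matrix + families
cls    <- classify_all(prof)                    # six-class labels + frequencies
pca    <- fit_pca(prof, k = 3)
f1_gc_correlation(pca, prof$meta$mean_gc)

cm  <- read_contacts("contacts.tsv", 1e6, setNames(Biostrings::width(genome), names(genome)))
icp <- compute_icp(cm)
icp_gc_correlation(icp, windowed_gc(genome, 1e6))
```

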