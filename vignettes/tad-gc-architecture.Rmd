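---
title: "Sequence composition and chromatin architecture: methods and design"
author: "tadgc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence composition and chromatin architecture: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadgc)
```

## The scientific question

Topologically associating domains (TADs) and chromatin loops are
self-interacting genomic regions, and their nuclear behaviour — which
interchromosomal hubs they join, how densely they loop internally, which
functional elements they carry — co-varies with DNA base composition.
`tadgc` provides a tested pipeline for quantifying that co-variation from
sequence and standard genomic tracks:

1. **Composition**: windowed GC% tracks, 100-bin GC profiles of TADs, and
   isochore-family assignment of each TAD from its mean GC% (L1 < 37%,
   L2 37–41%, H1 41–46%, H2 46–53%, H3 ≥ 53%, half-open cut-points with
   clamping at the extremes).
2. **Gradient classification**: each TAD profile is split into halves
   (bins 1–50 and 51–100) and the Pearson correlation between bin GC% and
   within-half bin index is computed for each half. The sign pattern of
   `(r1, r2)` against a flat threshold (default 0.4) yields six classes:
   `A` monotone, `B` bell/peak, `C` valley, `Bminus` half-bell, `Cminus`
   half-valley, `D` flat/uncorrelated.
3. **Unsupervised verification**: PCA of the N×100 profile matrix; the
   first component tracks mean GC%, the second and third separate
   bell-like from valley-like shapes.
4. **Hubs and contacts**: the interchromosomal contact probability
   `ICP_i = (inter-chromosomal contacts of bin i) / (all contacts of bin i)`
   from a binned contact matrix, its correlation with GC%, and GC%
   comparisons between nucleolar and speckle hub bins.
5. **Functional elements**: relative positions (0–1) of genes,
   super-enhancers and CTCF sites inside TADs, per-100-kb densities by
   isochore family, and gene stratification by the tissue-specificity
   index Tau.

Everything is validated end-to-end on a synthetic genome whose ground
truth is known by construction.

## Reading "slope of the correlation coefficient"

The gradient of each TAD half is quantified by the Pearson correlation
coefficient `r` between bin GC% and bin index, sign-interpreted as the
gradient direction. We deliberately use the correlation itself rather than
a bp-scaled regression slope: the flat band is defined as `−0.4 < r < 0.4`,
a cut that is only meaningful on the correlation scale. The ±0.4 cut is
stated in the source analysis only for the flat class; we apply it as the
universal flat/non-flat threshold for all six classes because a single
threshold makes the `(sign(r1), sign(r2))` table an exhaustive, mutually
exclusive partition:

| (s1, s2) | class |
|---|---|
| (0, 0) | D |
| (+, +) or (−, −) | A |
| (+, −) | B |
| (−, +) | C |
| (+, 0) or (0, −) | Bminus (plateau-high interior) |
| (−, 0) or (0, +) | Cminus (plateau-low interior) |

Reversing a profile maps `(r1, r2) → (−r2, −r1)`, so every class is
invariant to 5′/3′ orientation *by construction*; this is property-tested
over random profiles. A zero-variance half is defined as `r = 0` (the
definitional flat case), which also makes noiseless half-bell profiles
classify deterministically. Masked bins (assembly gaps, high-N windows)
are dropped pairwise within their half; a half with fewer than 3 unmasked
bins makes the TAD unclassifiable, and such TADs are excluded and
reported rather than guessed.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `n_bins` | 100 | bins/TAD | fixed by the profile convention; configurable for short loops |
| `flat_threshold` | 0.4 | \|r\| | the stated flat band; universal cut (see above) |
| isochore cut-points | 37/41/46/53 | GC% | the five-family scheme; half-open, clamped below 37 and above 53 |
| perturbation `delta` | 50,000 | bp | boundary-uncertainty probe, applied to both ends |
| Tau thresholds | 0.3 / 0.8 | — | housekeeping below 0.3, tissue-specific above 0.8, strict inequalities |
| track `resolution` | 1,000,000 | bp | hub and ICP analyses are defined at 1 Mb |
| `mask_threshold` | 0.5 | fraction | windows/bins with more non-ACGT than this are masked |

Bins within a TAD are near-equal: the integer remainder is distributed to
the leftmost bins. Any fixed rule works; this one is simple and testable,
and orientation equivalence is handled in the classifier, not the binning.

## PCA choices

PCA is fit on the raw profile matrix with column centering and **no**
unit-variance scaling (`fit_pca(center = TRUE, scale = FALSE)`). Scaling
bin columns would flatten the between-TAD GC-level signal and destroy the
near-perfect correlation between the first component and mean GC% that
motivates using F2/F3 for shape clustering. Both choices are exposed as
flags. Component signs are fixed by orienting each loading vector so its
largest-magnitude element is positive, and the F1–meanGC correlation is
reported as an absolute value, so results do not depend on the sign
convention. Masked bins are mean-imputed per row; fully masked rows must
be excluded upstream. A documented directional property: removing row
means before PCA promotes the former F2 (shape) to F1, which is why the
raw matrix is the right input here.

Cluster separation of {B, Bminus} vs {C, Cminus} in the (F2, F3) plane is
quantified two ways, because "visually separate clusters" is not a test:
the silhouette coefficient of the two super-groups and the accuracy of a
nearest-centroid rule.

## ICP conventions

`ICP` is a per-bin ratio in [0, 1]; bins with zero total contacts are
undefined rather than zero. The diagonal (self-bin) count is included in
the intra-chromosomal denominator — the literal reading of "inter plus
intra" — with `include_diagonal = FALSE` available. Contact matrices are
symmetrized at read time (both triangle entries summed); `compute_icp`
refuses asymmetric input rather than silently fixing it. No matrix
balancing (ICE/KR) is applied: ICP is a per-bin ratio and the definition
assumes raw counts.

Both directions of the GC–contact linear model are reported separately
(`icp ~ gc` and `gc ~ icp`); ordinary least squares is asymmetric, so the
reverse slope is not the reciprocal of the forward slope unless |r| = 1,
and conflating the two is a classic error the interface prevents.

## The synthetic generator: what it emulates, and what it does not

The generator (`synthetic_config()`, `synthesize_genome()`,
`synthesize_contacts()`, `synthesize_features_and_expression()`) produces
a genome in which every quantity the pipeline estimates has a known
generating value:

- **Gradient shapes**: per-TAD target profiles (ramp, triangle,
  half-plateau, flat) with a controllable amplitude, plus per-bin Gaussian
  noise (`bin_noise_sd`).
- **Isochore spread**: per-TAD mean GC uniform on `mean_gc_range`
  (default 33–59%, the span of the five families).
- **Hub GC shift**: bins at `hub_resolution` are labelled
  speckle/nucleolar by a greedy swap from a random balanced split until
  the group mean difference hits `hub_gc_shift`; at shift 0 the split
  stays random, which is the null used for p-value calibration.
- **GC–contact coupling**: per-bin interchromosomal propensity
  `logistic(alpha + beta·gc + noise)`, with `beta` calibrated by bisection
  against the *realized* ICP–GC Pearson r (candidate matrices are rebuilt
  from a fixed internal sub-seed so the bisection target is a
  deterministic function of beta). Counts are Poisson; matrices symmetric
  sparse integers.
- **Positional biases**: gene and CTCF midpoints are Beta(0.5, 0.5)
  (border-heavy) in valley-class TADs; super-enhancers Beta(4, 4)
  (centre-heavy) in bell-class TADs; uniform otherwise. Symmetric Betas
  are the simplest family matching the observed density shapes.
- **Tau structure**: housekeeping genes get a common level with small
  log-normal tissue scatter (Tau < 0.3 by construction), tissue-specific
  genes one dominant tissue (Tau > 0.8), intermediates graded expression;
  27 tissues by default. Housekeeping genes are placed at a higher rate
  in bell-class than valley-class TADs.
- **Family density gradient**: per-100-kb gene/SE/CTCF rates rise
  several-fold from L1 to H3, mirroring the strong inter-family gradients
  seen in real data and keeping the monotonicity property testable
  against Poisson counting noise.

Two deliberate departures from naive sequence simulation:

1. **Exact per-bin GC counts.** The per-bin GC fraction is drawn as
   `target + Normal(0, bin_noise_sd)` and the bin sequence contains
   *exactly* that count of G/C bases in random order. Independent
   per-base Bernoulli sampling would add `100·sqrt(p(1−p)/L)` ≈ 2–3 GC
   points of binomial noise at the bin lengths used here (a few hundred
   bp), which would swamp a 1-point noise dial and make gradient recovery
   at amplitude 5 impossible at any sample size — the noise would no
   longer be controllable. Since the entire analysis consumes only
   windowed GC%, higher-order sequence realism (dinucleotides, repeats,
   centromeres) adds nothing testable and is not modelled.
2. **TAD lengths are multiples of `n_bins`** so bins are equal length.
   With unequal bins, integer rounding of GC counts produces a tiny step
   function correlated with bin index — enough to destabilize the
   classification of *noiseless* flat halves, which must be exactly flat.

The standard validation suite (`standard_suite_config()`) fixes the
conditions used throughout the tests: 600 TADs, 100 per class, mean GC
uniform on 33–59%, amplitude 5, noise sd 1, seed 7, TAD lengths 10–30 kb
over 6 chromosomes (~13 Mb). TAD lengths are not dictated by the
biological scale (real TADs are ~100 kb–1 Mb) because every statistic in
the pipeline depends on the *binned profile*, not the physical length;
desk-scale lengths keep the full suite under two minutes. The boundary
perturbation analysis, which does depend on physical length (±50 kb),
is validated on a separate configuration with 150–250 kb TADs.

What passing these tests does **not** show: that real TAD calls in real
assemblies yield the published class frequencies (45% B in H2–H3, 32% C
in L1, ~70% in C/B⁻/C⁻), hub correlations (r = 0.82), or ICP–GC
correlation (r = 0.62) — those require the original Hi-C/SPRITE/TCC
datasets and are out of scope here. The operations that would compute
them on such data are the ones validated synthetically.

## Numerical conventions and degenerate inputs

- GC% excludes N and IUPAC ambiguity codes from the denominator; a
  window/bin is masked when its non-ACGT fraction exceeds 0.5. A trailing
  window shorter than 10% of the resolution is masked. Soft-masked
  (lowercase) bases count as their base identity — no masking rule is
  imposed beyond N-content, which maximizes data use.
- Empty sequences, all-zero expression rows, zero-contact bins, constant
  vectors in correlations, and single-member groups in tests all return
  explicit `NA`/flags or errors; nothing silently coerces to 0.
- KDEs of relative positions use Gaussian kernels with Silverman
  bandwidth and reflection at 0 and 1, so the estimate integrates to ~1
  on the unit interval and border peaks are not artificially halved.
- One generator self-check worth flagging: the realized-profile vs
  target-profile correlation is tested at amplitude 8× the noise sd. At
  exactly 4× the population correlation for ramp shapes is ~0.76, so a
  universal 0.8 bound there would be noise, not signal.
- Overlapping/nested TAD calls: a contained feature is assigned to the
  smallest containing TAD (leftmost on ties) — a deterministic rule for
  inputs the analysis itself assumes to be non-overlapping.

## Known limitations

- Isochore families are fixed GC cut-points applied to TAD means, not a
  de novo isochore segmentation.
- Chromatin sub-compartment labels (A1/A2/B1–B4) are accepted only as
  optional precomputed annotations; the package does not call them.
- The synthetic genome has no repeat structure, no centromeres, and no
  nested sub-TAD hierarchy beyond an optional sub-structure track; hub
  behaviour of satellite DNA is therefore outside the model.
- All coordinates are 0-based half-open internally (BED convention);
  1-based inputs must be declared at the reader boundary
  (`read_bed(..., one_based = TRUE)`). All inputs are assumed to share
  one assembly; no liftOver is performed.

## A compact run

```{r demo, eval = FALSE}
demo <- demo_pipeline(seed = 7)
demo$recovery
#  class_recovery        f1_gc_r   hub_gc_shift       icp_gc_r
#       0.9833333      0.9999988      5.0476153      0.5883258
```

`demo_pipeline()` synthesizes a 120-TAD data set, writes it to standard
formats (FASTA/BED/TSV), re-reads the files, runs every stage, and
reports how well the analysis recovers the generator's ground truth. The
full standard suite is exercised by the test suite and by
`scripts/acceptance.R`.
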