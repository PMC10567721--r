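---
title: "Clustering-based annotation-free glioma WSI classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering-based annotation-free glioma WSI classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliopatch)
```

## The problem

Integrated diagnosis of adult-type diffuse gliomas under the 2021 WHO
classification assigns a patient to one of six categories — astrocytoma,
IDH-mutant, grades 2–4 (A2, A3, A4); oligodendroglioma, IDH-mutant and
1p/19q-codeleted, grades 2–3 (O2, O3); glioblastoma, IDH-wildtype, grade 4
(GBM) — by combining histology with molecular markers. `gliopatch`
implements a weakly supervised pipeline that predicts this category from a
single H&E whole-slide image (WSI) per patient, without any region-level
annotation: the only supervision is the patient-level category, inherited
by every patch of the slide.

The central difficulty of this weak-label setting is that a gigapixel
slide contains many tissue morphologies, most of which carry no diagnostic
signal; a classifier trained on all patches spends its capacity on
uninformative regions and its patch-level predictions are noisy. The
pipeline addresses this with four steps:

1. **Patch clustering.** Tissue patches are embedded in a feature space and
   partitioned with K-means into K morphology clusters; K is selected by
   the silhouette coefficient over a scanned range (default 2–12), with the
   Calinski–Harabasz index as a cross-check.
2. **Patch selection.** One patch-level classifier is trained per cluster,
   and an *all-patch classifier* (trained on every patch) serves as the
   performance benchmark. Clusters whose validation accuracy is *strictly
   greater* than the benchmark's are selected: these are the morphologies
   that actually carry category signal.
3. **Patch-level classification.** A final classifier is trained from
   scratch on the union of the selected clusters.
4. **Patient-level classification.** Each of a patient's patches lying in
   a selected cluster votes its argmax category; the modal category is the
   patient-level prediction.

## Tissue segmentation and tiling

Slides are downsampled by block averaging (default factor 4, i.e. a 5×
view of a 20×, 0.5 µm/pixel scan), converted from sRGB to CIE L\*a\*b\*
under the D65 white point, and thresholded on the **chroma magnitude**
$\sqrt{a^{*2}+b^{*2}}$ with Otsu's method on a 256-bin histogram over
[0, 128]. The choice of channel is a design decision: H&E-stained tissue
is chromatic while slide background is near-achromatic white, so chroma
separates them robustly across illumination levels, whereas an L\*
threshold would confound pale tissue with background. Otsu ties are broken
toward the smallest threshold for determinism; a degenerate histogram
(e.g. an entirely blank slide) yields an empty mask with a warning rather
than an arbitrary split.

Tiling lays a non-overlapping grid of `patch_size` × `patch_size` patches
(default 1024 px = 512 µm) anchored at the level-0 origin, with 0-based,
half-open pixel coordinates. A patch is retained iff its tissue fraction
under the mask is at least `min_tissue_fraction` (default 0.5 — no
canonical value exists; 0.5 keeps patches that are mostly tissue while
tolerating tissue edges, and it is configurable). Only full patches are
considered, so an image narrower than one patch yields none.

## Features

Clustering operates in a feature domain, not on raw pixels. The extractor
is a pluggable contract — any pure function from a 256 × 256 patch to a
fixed-length vector; a 2048-d average-pooling embedding of a trained
50-layer residual network is one admissible implementation. The package
ships a deterministic hand-crafted baseline (D = 48: per-channel mean and
root-variance, 8-bin per-channel histograms, and gradient-magnitude
statistics over a fixed 4 × 4 grid) so the clustering and selection logic
is exercisable without GPU training. Dispersion is reported as the *root*
of the variance so that every feature lives on the 0–255 intensity scale;
with raw variances the squared units dominate all distances and the
extractor's geometry degenerates. Features are not standardized before
K-means by default (configurable), since the baseline features share a
scale by construction.

## Clustering and model selection

K-means uses Lloyd's algorithm with k-means++ seeding, the best of 10
restarts by inertia, fully determined by a seed. An emptied cluster is
re-seeded from the point farthest from its centroid. The silhouette is
computed exactly (vectorized O(n²)) with the singleton-cluster convention
s(i) = 0; beyond 20 000 points a seeded subsample caps the quadratic cost.
`choose_k` takes the silhouette argmax, breaking ties by higher
Calinski–Harabasz and then smaller K, and warns when the two indices
disagree — in well-separated data they peak together, as they do on the
synthetic benchmark (both peak at the planted K = 9). Cluster assignment
of new patches is nearest-centroid with ties to the lowest id.

## Classifiers, selection and voting

The reference desk-scale learner is a seeded multinomial logistic
regression (fit via `nnet::multinom`, mild L2 decay so separable problems
stay finite); predictions are computed from the stored coefficient matrix,
which makes trained bundles round-trip through plain-text files and
inference exactly reproducible. An iterative learner (e.g. a deep network)
plugs into the same contract and should follow `early_stop_rule`: train at
least 50 epochs, track the 10-epoch moving average of validation loss,
keep the model at the end of the best window, stop once the best window
has not improved for 20 epochs, or at 150 epochs. Two points were left
open by the setting and resolved here as package choices: the selected
model is the *last* epoch of the best window, and "minimum confirmed" is
operationalized by the patience rule.

Cluster selection is **global**: one selected set per trained model,
computed from validation-cohort accuracies, with strict inequality against
the benchmark. If no cluster qualifies, the single best cluster is
selected with a warning (an empty selection would leave nothing to vote).
Patient voting breaks ties by the higher mean predicted probability among
the tied categories, then by category order; a patient with no patch in a
selected cluster falls back to all-patch voting, with a message.

## Evaluation statistics

`ovr_report` evaluates each category one-vs-rest: AUC by the rank
(Mann–Whitney) statistic with ties counted ½; accuracy, sensitivity,
specificity and F1 from argmax assignments (the operating point matching
majority-vote labels); ROC and precision–recall curves; and the
unweighted macro-average AUC, which also drives `select_best_fold` in
cross-validation. Correlated AUCs are compared with the DeLong test from
the structural components of the Mann–Whitney statistic; with zero
variance the p-value is 1 when the AUCs agree and 0 (with a warning)
otherwise. `make_folds` stratifies patients by category (optionally
further variables), dealing each stratum round-robin from a rotating
offset so per-fold class counts deviate from proportionality by at most 1;
five folds give the 4:1 train:validation ratio.

## The WHO 2021 rule engine

`integrate_diagnosis` encodes the adult-type diffuse-glioma scheme:
IDH-mutant + 1p/19q codeletion → oligodendroglioma (grade = histologic
grade); IDH-mutant without codeletion → astrocytoma, elevated to grade 4
by microvascular proliferation, necrosis, or CDKN2A/B homozygous deletion
in any combination; IDH-wildtype → glioblastoma when the histologic
high-grade picture or a molecular criterion (TERT promoter mutation,
high-level EGFR amplification, +7/−10) holds, regardless of a grade-2/3
histologic appearance. Whether the IDH-wildtype histologic qualification
requires MVP *and* necrosis or either one is genuinely ambiguous in
practice; the engine defaults to *either* (the classical criterion) behind
the `histology_rule` switch. Unknown markers on a decisive path produce an
`unresolved` outcome naming the missing marker — never a silent default —
while positive qualifiers fire monotonically even when other qualifiers
are unknown. An IDH-wildtype tumor with no qualifying feature is
`indeterminate` (outside this scheme), not an error.

## The synthetic benchmark

Because the clinical WSI cohorts are restricted, every stage is validated
on a two-tier generator with planted ground truth.

**Feature tier.** Each slide of a category emits patches from a
category-specific mixture over P = 9 pattern archetypes, of which 3 are
informative. Pattern centroids sit on orthogonal axes scaled so that every
pairwise centroid distance equals `separation` (default 8) in units of the
within-pattern standard deviation; informative patterns additionally shift
their mean by `class_shift` (default 2) along a category-specific
orthogonal direction, so the category is decodable *within* an informative
cluster but invisible in uninformative ones. The default mixture puts 0.4
of each category's mass on one informative pattern — shared between a
"hard pair" with similar histology (A2/A3, O2/O3, A4/GBM) — and 0.1 on
each of the six uninformative patterns. Defaults of 6 categories × 20
slides × 64 patches, feature_dim 32, were chosen once as a desk-scale
cohort in which the selection signal (per-cluster accuracy ≈ 0.95+ for
informative clusters vs a benchmark ≈ 0.45) matches the qualitative regime
the method targets.

**Image tier.** A white canvas carries a contiguous rectangle of textured
blocks, one pattern per block: oriented sinusoid gratings (odd patterns)
and blob fields (even patterns), with category-coded frequency/density
shifts for informative patterns. Colors stay in a constrained H&E-pink
family whose red channel is always ≥ 30 above green and whose dynamic
range leaves headroom for the ±45 lightness modulation, so every tissue
pixel is reliably chromatic and background is exactly white — giving
segmentation an exact ground truth.

What the generator does *not* emulate: stain variability and scanner color
shifts, nuclei-scale morphology, tissue tears and pen marks, label noise,
and class imbalance of clinical cohorts. Tests passing on this benchmark
therefore validate the *algorithmic* behavior (clustering, selection,
voting, statistics), not clinical performance.

## Numerical choices and limitations

* Problem sizes in the test suite and acceptance script — up to ~7 700
  patches for K scans, 10-seed selection replicates, n = 500 silhouette
  oracle — were chosen as desk-scale settings where every oracle is
  computable exactly.
* All randomness flows from a single seed fanned out to per-stage seeds by
  fixed offsets; two runs with the same configuration are bit-identical,
  including persisted bundles.
* The silhouette subsample cap (20 000) introduces the only sanctioned
  approximation; below the cap the statistic is exact.
* Probabilities from a cluster classifier assign exactly 0 to categories
  absent from that cluster's training data; the patient-level tie-break
  therefore never resurrects a category no selected cluster has seen.
* JPEG input is not supported (PNG/TIFF readers only), and multi-slide
  patients are out of scope (one patient, one WSI).
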