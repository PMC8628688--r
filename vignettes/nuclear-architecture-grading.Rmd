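---
title: "Nuclear-architecture features and clinical-imaging fusion for tumor grading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nuclear-architecture features and clinical-imaging fusion for tumor grading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(nucleograde)
library(dplyr)
```

## The problem

Nottingham grade stratifies breast tumors by tubule formation, nuclear
pleomorphism and mitotic activity; high-grade (G3) disease drives urgent
treatment decisions, but manual grading is slow and shows substantial
interobserver variability. `nucleograde` implements a computational grading
pipeline that works from two modest inputs per patient: the centroids of
malignant nuclei on each core-needle-biopsy (CNB) section of a digitized
slide, and four routine clinicopathologic variables (age, ER%, PR%, HER2
status). The task throughout is binary: G3 versus the pooled low/intermediate
grades (G1,2).

The package deliberately excludes the deep-learning stages that would
produce these inputs in a production system (tumor-bed localization and
nucleus instance segmentation). Their *outputs* — centroid tables, tumor-bed
areas, per-tile tumor-bed probabilities — are first-class pipeline inputs,
and their *evaluation metrics* (AJI, mAP, matched precision/recall/F1) are
implemented so segmentation quality can be audited when masks are available.

## The spatial feature set

Each section contributes exactly 52 features computed from its nuclear
centroids:

* **Graph features (24).** The Voronoi tessellation contributes per-cell
  area, perimeter and maximum vertex distance (12 statistics); the Delaunay
  triangulation contributes unique edge lengths and triangle areas (8); the
  Euclidean minimum spanning tree contributes branch lengths (4). Each
  per-object list is collapsed into four statistics: mean, population
  standard deviation, min/max ratio, and the disorder statistic
  $\sigma/(\mu+\sigma)$ — an algebraic form of $1 - 1/(1+\sigma/\mu)$ that
  stays defined at $\mu = 0$ and is set to 0 when $\sigma = 0$.
* **Density features (27).** For radii $d_1 < \dots < d_4$ the per-nucleus
  neighbour counts $n_d(i)$ (16 statistics); for neighbour counts
  $k_1 < k_2$ the k-th-nearest-neighbour distances $r_k(i)$ (8); and the
  min/median/max of the local density estimate
  $\rho_i = k_\rho / (\pi r_{k_\rho}(i)^2)$ (3). A nucleus is never its own
  neighbour.
* **Nuclear count (1).**

Numerical choices worth knowing: unbounded Voronoi cells (cells of
convex-hull points) are excluded rather than clipped to an arbitrary box;
Delaunay edges are counted once, not once per incident triangle; the MST is
built on the Delaunay edge set (the Euclidean MST is always a subgraph of
it), with a complete-graph fallback for degenerate inputs; duplicate
centroids are merged before tessellation; and sections with fewer than 10
nuclei are excluded with an explicit report, because the tessellation
statistics are not meaningful below that. All distances are in pixels — no
micron calibration is assumed.

The neighbourhood scales are tunable through `density_config()`. The
defaults — radii 25/50/75/100 px, $k \in \{3, 5\}$, $k_\rho = 5$ — are
plausible nuclear neighbourhood scales at 40\(\times\) magnification and
were fixed once as package defaults; they are a design choice, not an
empirical estimate, and together with the four summary statistics they
produce the canonical 24 + 27 + 1 = 52 registry asserted by the tests.

```{r features}
set.seed(1)
pts <- tibble::tibble(x = runif(120, 0, 750), y = runif(120, 0, 750))
fv <- extract_spatial_features(pts)
length(fv)
fv[c("voronoi.max_dist.disorder", "mst.branches.min_max_ratio",
     "density.rho.median", "nuclei_count")]
```

## The machine-learning stage

The modeling protocol is leakage-safe by construction:

1. **Collinearity pruning.** For every continuous feature pair with Pearson
   $r^2 \ge 0.7$, the member with the lower absolute point-biserial
   correlation against the grade label is dropped (point-biserial is
   computed as Pearson correlation with the 0/1 label, which is identical).
2. **Patient-level stratified split.** 70/30 with per-class test counts
   $\lceil 0.3 \, n_\text{class} \rceil$; all sections of a patient stay on
   one side. On the 80 G3 / 58 G1,2 mix this yields a 42-patient test set
   with 57.14% G3 prevalence.
3. **Standardization.** Z-scores with training means and standard
   deviations retained and re-applied verbatim to the test set.
4. **Oversampling.** The minority class is raised to the majority count by
   SMOTE (clinical channel) or borderline-SMOTE (spatial channel), inside
   training folds only. Borderline seeds are the "danger" minority points —
   at least half, but not all, of their nearest neighbours in the full
   training set belong to the majority class — and the variant falls back
   to plain SMOTE with a warning when no such point exists.
5. **Feature selection.** Sequential forward selection, repeated (100
   iterations by default) with fresh 10-fold CV assignments, maximizing
   mean held-out AUC, capped at 10 features (the 10:1 rule). The reported
   subset is the *modal* exact subset across iterations; ties break by
   higher mean AUC, then lexicographic name order. For section-level rows
   the CV folds are grouped by patient, which is the strict reading of a
   patient-level protocol. A floating (add/remove) variant is available
   behind `floating = TRUE`.
6. **Hyperparameters.** Randomized search (100 draws by default) over
   conventional per-model spaces (`default_search_space()`), scored by the
   same CV AUC. Logistic regression has no tunable hyperparameter and an
   empty space.
7. **Models.** K-NN, logistic regression, Naive Bayes, SVM, random forest
   and XGBoost, all exposed through one probability interface. Naive Bayes
   is rejected for clinical feature sets, whose mix of continuous and
   ordinal inputs violates its assumptions.
8. **Evaluation.** The extended diagnostic panel (AUC by the rank method,
   accuracy, sensitivity, specificity, prevalence, FNR, FPR, PPV, NPV, FDR,
   FOR, LR+, LR−, DOR, F1) computed from the confusion table at a fixed 0.5
   probability threshold. The panel identities (Sn + FNR = 100,
   LR+ = Sn/(100−Sp), DOR = LR+/LR−, ...) hold to numerical precision and
   are tested on random tables.

## Section-to-patient aggregation and fusion

Spatial models predict per section; patients are scored by the
tumor-bed-ratio weighted average $p = \sum_s \mathrm{TBR}_s\, p_s$, where a
section's TBR is its tumor-bed pixel area divided by the patient's summed
tumor-bed areas. The clinical and spatial channels are then fused linearly,
$p = (1-w)\,p_\text{clin} + w\,p_\text{spat}$, with $w$ scanned over
$0, 0.01, \dots, 1$ (101 weights). At each weight the mean 10-fold CV AUC of
the fused training probabilities is computed; the maximizing weight is
selected (ties toward the smaller, more clinical weight) and only then
evaluated on the untouched test set. The endpoints of the scan reproduce the
single-channel CV AUCs exactly, which the tests assert to 1e-12. When
several candidate models exist per channel, `scan_weight_pairings()`
selects the pairing by training-CV AUC — never by test performance — which
is the leakage-safe reading of "best combination".

Two design choices here were genuinely open and are fixed as follows: the
fusion scan consumes precomputed patient-level spatial probabilities (it
does not re-aggregate sections inside folds), and missing TBRs fall back to
uniform section weights with a message.

## The synthetic cohort generator

Real CNB cohorts with grade labels are not shippable, so `generate_cohort()`
produces seeded cohorts with the statistical structure the analysis assumes:

* **Clinical marginals.** Age approximately normal (51.6 ± 10.8 vs
  50.3 ± 9.2 years by group); ER and PR as zero-inflated percentages — a
  point mass at 0 for receptor-negative patients plus a Beta-distributed
  component on (0, 100] — because the G3 group's median ER of 0 cannot be
  produced by any plain continuous model; HER2 near-balanced Bernoulli
  (0.448 vs 0.488). Positivity rates default to the published group rates
  (ER 74.1% vs 42.5%, PR 60.3% vs 37.5%), so the G1,2 ER median lands high
  (≥ 50) and the G3 median at 0.
* **Spatial structure.** G3 sections default to a Thomas cluster process
  with a higher expected count (more, more clustered nuclei); G1,2 sections
  to hard-core sequential inhibition (sparser, more regular). This encodes
  the observed direction of the grade effect without claiming a specific
  generative process for real tissue. Expected counts default to 400 vs 250
  nuclei on a 750 × 750 px section — deliberately desk-scale values chosen
  once so that the full pipeline runs on one CPU; no per-section count
  table exists to calibrate against.
* **Determinism.** One master seed; each patient draws from a
  counter-derived substream, so extending a cohort never reshuffles
  existing patients, and identical specs serialize byte-identically.

What the generator does *not* emulate: H&E texture (mask fixtures are flat
disks), segmentation noise in centroid positions, within-patient grade
heterogeneity, and any correlation between clinical and spatial channels
beyond the shared grade label. Passing tests therefore demonstrate that the
pipeline recovers structure it is pointed at and stays at chance when none
exists — not that the published effect sizes transfer to real slides.

```{r cohort}
coh <- generate_cohort(cohort_spec(n_patients = 10, seed = 7))
coh
count(coh$clinical, grade)
```

## Problem sizes used by the tests and the acceptance script

The shipped checks run the complete pipeline at reduced-but-honest sizes,
chosen once as the package's own verification conditions: a 200-patient
signal cohort (grade affects the expected nuclear count, 250 vs 400, and
the ER/PR marginals) analysed with 20 SFFS iterations × 5-fold CV and
logistic models in both channels, and a 400-patient null cohort (identical
distributions in both groups) with 10 iterations. On the signal cohort the
modal subsets recover `nuclei_count` and `er` and the fused test AUC
exceeds 0.8; on the null cohort the fused test AUC stays near 0.5. The
full 100 × 10 protocol is the package default and is what a real analysis
should run.

## Segmentation metrics

`aji()` implements the Aggregated Jaccard Index with greedy per-ground-truth
pairing in stable ascending-id order (ties broken by larger intersection) and
unused predicted pixels added to the denominator. `match_instances()` does
one-to-one matching in descending-IoU order at a threshold, and
`average_precision()` uses the *unscored* AP convention
$\mathrm{AP}(t) = \mathrm{TP}/(\mathrm{TP}+\mathrm{FP}+\mathrm{FN})$
averaged over IoU 0.50–0.95: predictions here carry no confidence scores, so
score-ranked COCO AP is not applicable; this divergence is deliberate and
documented.

## Pre-processing helpers

`tissue_mask()` (Otsu threshold on the grayscale render, binary closing,
small-object removal), `tile_image()` (origin-anchored non-overlapping
750-px grid, tiles retained when background ≤ 10%), and
`stain_normalize()` (Macenko-style: stain vectors from the extreme angles of
the optical-density cloud in its top-2-eigenvector plane, concentrations by
least squares, rescaled to a shipped reference). Near-white tiles skip
normalization with a `no_stain` flag. Tumor-bed probability per tile is an
injected interface — a vector or callable — replacing the out-of-scope CNN;
`assign_tumor_bed()` integrates it into the per-section tumor-bed area that
feeds the TBR.

## Known limitations

* Synthetic cohorts validate machinery, not clinical effect sizes; the
  published cohort is private and its AUCs are not reproducible here.
* The density-feature scales and the hyperparameter search spaces are
  conventional defaults, not published values.
* Grouped CV folds for section-level data are stricter than a protocol
  that randomizes sections independently; reported CV AUCs are accordingly
  conservative.
* The unscored AP convention is not comparable to score-ranked COCO mAP.
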