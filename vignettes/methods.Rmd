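---
title: "Methods: multi-lesion radiomics and ensemble response modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-lesion radiomics and ensemble response modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`radresp` predicts the volumetric response of multi-site ovarian cancer to
neoadjuvant chemotherapy from baseline data. The endpoint is the log ratio
of total disease volume after versus before treatment,
$\mathrm{Response} = \ln\!\big(\sum_i v_i^{1} / \sum_i v_i^{0}\big)$, with
per-lesion volumes in cm³. Natural logarithm is used; any other base would
only rescale the endpoint uniformly. A complete response (zero residual
volume) is floored at $\varepsilon = 0.01$ cm³ — roughly the smallest
measurable lesion on 5 mm slices — so the endpoint stays finite; the
record is flagged and $\varepsilon$ is configurable. Binary responder
classes use volume-reduction thresholds of 30 % (RECIST-equivalent), 50 %
(WHO), 65 % (spherical: a sphere whose diameter shrinks 30 % loses
$1 - 0.7^3 = 65.7\,\%$ of its volume) and 30 % (ellipsoidal).

The pipeline assumes contrast-enhanced CT with a multi-label lesion
segmentation on the same grid (one integer label per anatomic site, a
sidecar YAML mapping labels to the 15 standard sites), voxel spacing in
millimetres from the NIfTI header, and slices along the third array axis.

# Lesion extraction and radiomics

**Connected components.** Each label is decomposed independently into
26-connected components (voxels connected through faces, edges or
corners). There is no minimum component size: single-voxel lesions are
kept and counts are logged, since dropping them would silently alter total
disease volume.

**HU floor.** Voxels below −100 HU (strictly below; −100 itself is
retained) are excluded from all intensity-based calculations, removing fat
and air from intensity statistics. If a lesion is emptied by the floor its
intensity features are missing, not zero.

**Shape (6 features).** Volume is voxel count × voxel volume (exact).
Surface area uses a normal-weighted boundary-face estimator: every exposed
voxel face contributes its physical area times $|n \cdot e|$, where $e$ is
the face axis and $n$ the local unit normal estimated from the gradient of
a 3×3×3 box-smoothed copy of the mask. For a digitized plane the weighted
projected areas telescope to the true area, so the estimator is exact on
axis-aligned faces and accurate on curved surfaces (a radius-20 digital
ball measures within 0.2 % of $4\pi r^2$, giving sphericity ≈ 1 where
plain face counting would give 0.67); the cost is a slight bevelling of
sharp edges on small objects (a 10³-voxel cube measures ≈ 9 % under its
nominal 6 cm²), which the unit tests assert at that stated tolerance.
Sphericity is $\pi^{1/3}(6V)^{2/3}/A$; the maximum 3-D diameter is the
largest voxel-centre distance plus one voxel diagonal (so a single voxel
has its diagonal as diameter); elongation is
$\sqrt{\lambda_2/\lambda_1}$ of the voxel-cloud principal moments.

**First order (16) and IVH (4).** Histogram statistics use population
moments; skewness and excess kurtosis of constant data are defined as 0;
entropy uses 256 bins over the observed range with base-2 logarithm (0 for
constant data). Intensity-volume-histogram features are absolute volumes
of voxels strictly above 50, 100, 150 and 200 HU, non-increasing in the
threshold by construction.

**Texture (18).** Grey-level co-occurrence matrices use 100 equal-width
levels on the fixed range −100…1000 HU with clipping; fixed binning keeps
levels comparable across lesions and scanners. Symmetric matrices at
offset 1 are accumulated over all axial slices for each of the four
in-plane directions, each direction is normalized, and the *matrices* (not
the statistics) are averaged over directions with at least one pair — the
exhaustive pair-enumeration oracle in the test suite pins this convention.
Logarithms are base 2; correlation and the information measures are
defined as 0 for degenerate (zero-variance or zero-entropy) matrices so a
constant lesion has the signature energy 1, contrast 0, entropy 0.

**Rim and peripheral ratios (2 × 38).** The lesion contour is eroded and
dilated by a physical 4 mm margin, strictly in 2-D per axial slice (slice
thickness, typically 5 mm, exceeds the margin, so through-slice morphology
would mix tissue layers). The structuring element is a rasterized disc:
a pixel offset belongs to it iff its centre lies within the physical
radius, computed per axis so non-square pixels still honour the margin in
both directions (an elliptical element in index space). Ratios are
`f(eroded)/f(standard)` (rim, intra-lesion heterogeneity) and
`f(dilated)/f(standard)` (peripheral, lesion context) for the 38 non-shape
features; shape features are excluded. IVH features are included among the
38: they are non-shape intensity features, and their ratios carry the
core-to-whole volume concentration of bright tissue. Denominators with
$|f| < 10^{-12}$ yield missing values, never infinities; an erosion that
empties every slice makes all rim ratios missing.

**Density flags.** Hyper-/hypodense sub-segmentation is a configurable
threshold proxy: a flag raises when ≥ 1 % of lesion voxels exceed +160 HU
(calcification) or fall below +20 HU (cystic/fatty), evaluated on raw
voxels without the HU floor since fat is exactly what the hypodense flag
must see. The thresholds are configuration, not learned.

**Aggregation.** Patient profiles are unweighted means over lesions,
skipping missing lesion values (zero is a meaningful feature value, so
missingness is never zero-filled); a feature is missing at patient level
only when missing for every lesion, and contributing-lesion counts are
recorded.

# Feature table

The per-patient imaging block has exactly 164 columns: 15 per-site volumes,
15 per-site lesion counts, mean/max/total volume, lesion counts above
0/1/10/100 cm³, four density flags (omentum/pelvis × hyper/hypo), ascites,
pleural effusion and pleural thickening, plus the 44 patient-averaged
intensity radiomics and the 38 + 38 ratio features. Ascites and pleural
effusion enter as the radiologist's 0–3 semiquantitative scores used
ordinally (binarization is exposed to the caller but not the default).
Clinical features are age, the ordinal FIGO stage (1A→1 … 4B→10) and nine
treatment features: three agent indicators, three schedule-combination
indicators (weekly paclitaxel + 3-weekly carboplatin, both weekly, both
3-weekly), carboplatin monotherapy, an irregular-schedule flag, and the
number of chemotherapy sessions before the second scan. A regimen is
weekly when the mean inter-dose gap is 6–10 days inclusive and 3-weekly at
18–24 days; single doses are irregular. The nested model inputs are
clinical (11), +CA-125 (12), +imaging (176) and +ctDNA (179: TP53 MAF,
t-MAD, TP53 mutation detected).

# Ensemble model

Each of the three pipelines (elastic net, RBF-kernel SVR, random forest)
shares the same preprocessing, fitted strictly inside its training rows:
mean imputation, removal of constant columns, collinearity reduction,
z-scoring, and univariable selection. Collinearity reduction builds a
graph on feature pairs with $|r| > 0.95$ (absolute value, so
anti-correlated duplicates are also pruned) and keeps, per connected
component, the feature most correlated with the response — a
component-survivor rule rather than sequential greedy pruning, because it
is deterministic and independent of column order except for explicit
first-column tie-breaks. Univariable selection keeps the top *k* features
by regression F statistic (the squared t statistic).

Hyperparameters are tuned by randomized search (default 60 draws per
algorithm per seed) under 5-fold cross-validated MSE, with
$k \in \{5, 10, 20, 40, \text{all}\}$ searched jointly with the algorithm
ranges: elastic-net penalty $10^{[-3,2]}$ and mixing $[0.05, 1]$; SVR cost
$10^{[-2,3]}$, $\gamma \in 10^{[-4,1]}$, $\varepsilon \in [0.01, 1]$;
forest with 100–500 trees, depth 2–10 or unlimited, node size 1–10. All
ranges are configuration so published grids can be dropped in. The winner
is chosen by the one-standard-error parsimony rule: among configurations
within one standard error of the best cross-validated MSE, the smallest
selection size wins (then draw order). This is the same convention as
`lambda.1se` in penalized regression and keeps near-tied searches from
drifting to larger, noisier feature sets.

The search repeats over five seeds; each seed's best configuration per
algorithm is refit on the full training set, giving 15 members whose
unweighted mean is the prediction (equivalently, the mean over seeds of
per-seed pipeline means — equal weights make the two readings identical).
Refits under the same seeds are bit-identical. At prediction time, columns
are matched by name and anything absent — whole columns (e.g. ctDNA in an
external cohort) or individual cells — is imputed with training-set means.

**Feature reports.** Selection frequency counts the members (0–15) in
which a feature survived collinearity reduction and selection. Importances
exist for the elastic net (absolute coefficients) and random forest
(impurity importance) only; each member's importances are normalized to
sum 1 and averaged over those ten members. Reported rows are restricted to
features selected in at least three of the five seeds (selected by any of
a seed's three pipelines), for robustness.

# Evaluation statistics

MSE quantifies calibration; Pearson and Spearman correlations (two-sided)
quantify discrimination. AUCs use the rank (Mann–Whitney) formulation with
mid-rank ties; predicted scores are negated first so that larger =
more responder-like, since more negative predicted response means more
shrinkage. RECIST-group ranking is reported both ways the three groups can
reasonably be scored: point-biserial tests (Pearson on the indicator, t
transform, two-tailed) for responder-vs-rest and progression-vs-rest, plus
the Spearman correlation against the 0/1/2 ordinal. Group comparisons use
the two-sided Mann–Whitney U test, exact when both groups have ≤ 8
observations without ties (enumeration is cheap below that) and the
tie-corrected normal approximation otherwise. Multiple testing uses
Benjamini–Hochberg step-up adjustment.

# Imaging-feature clusters

Imaging features are clustered by their Spearman-correlation profiles
against clinical/biological features: average linkage on Euclidean
distances between profile rows (linkage is configurable; average linkage
is the default for correlation-profile data because single linkage chains
and complete linkage splinters small blocks). For each candidate k the
cluster-association metric takes, per cluster, the median |r| over members
for each clinical feature, maximizes over clinical features, and averages
over clusters; a max-over-members variant is emitted alongside since
either reading of "cluster-to-clinical correlation" is defensible. The
chosen k is the smallest whose metric is within 2 % of the maximum over
the candidate range — a plateau rule that formalizes "the curve flattens"
without eyeballing. The NMF cross-check shifts profiles by
$x \mapsto (x+1)/2$ (Spearman lies in $[-1,1]$), factorizes with seeded
multiplicative updates minimizing Frobenius error, assigns each feature to
its largest factor loading, and reports the adjusted Rand index against
the hierarchical assignment.

# Synthetic data: what it does and does not show

`make_phantom` rasterizes ellipsoidal lesions with three analytically
tractable textures (constant, Gaussian noise, two-level checker), optional
concentric core offsets and hyper-/hypodense inclusions, and returns exact
ground truth (voxel counts, volumes, mean HU) so feature tests assert
against construction rather than re-derivation. `make_cohort` draws
standard-normal features with optional planted linear signal, collinear
duplicates at a target correlation and missingness, producing responses on
the endpoint scale clipped to $[-9.2, 1]$ and threshold-derived
RECIST-like labels. `make_paired_scans` applies per-site shrinkage factors
to baseline volume tables. All generators are pure functions of spec +
seed.

These generators validate the machinery — feature definitions, selection,
leakage-freedom, recovery of planted structure — under conditions chosen
to resemble the clinical setting (5 mm slices, sub-millimetre in-plane
spacing, soft-tissue HU ranges, response scale). They do not emulate CT
noise spectra, beam hardening, partial-volume effects, scanner
heterogeneity, anatomically realistic lesion shapes, or the correlation
structure of real radiomics features; passing tests therefore demonstrate
correctness of the computations and honest generalization behaviour, not
clinical performance.

The test and verification runs use deliberately moderate problem sizes —
a planted-recovery cohort of n = 300 with 20 features, 200 null-cohort
repetitions at n = 100 for the p-value uniformity check, 100 seeded 8×8×2
texture phantoms and 50 morphology cases up to 64×64 — chosen as the
smallest scales at which the checked properties are stable.

# Known limitations

Density flags are a threshold proxy for proper tissue sub-segmentation.
Morphology is 2-D by design and would under-serve isotropic
high-resolution volumes. The surface estimator bevels sharp edges of
objects a few voxels across. DICOM series assembly, automatic
segmentation, inter-timepoint registration, scanner harmonization and
survival endpoints are out of scope.
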