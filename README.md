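# radresp

Multi-lesion CT radiomics and ensemble prediction of volumetric response to
neoadjuvant chemotherapy.

High-grade serous ovarian carcinoma typically presents as multi-site
metastatic disease, and response to neoadjuvant chemotherapy (NACT) is
highly variable between patients and between anatomic sites within a
patient. `radresp` is an R toolkit for building and validating integrative
response models from data available at diagnosis: contrast-enhanced CT with
multi-label lesion segmentations, clinical and chemotherapy records, CA-125,
and circulating tumour DNA summaries. It is aimed at imaging scientists and
biostatisticians working on radiomics-based treatment-response biomarkers.

## What it computes

**Endpoint.** Models predict the relative volumetric response

```
Response = ln( Σᵢ vᵢ¹ / Σᵢ vᵢ⁰ )
```

where `vᵢ⁰` and `vᵢ¹` are per-lesion volumes at baseline and after NACT.
Complete responses are floored at 0.01 cm³ and flagged. Binary responder
classes are derived at volume-reduction thresholds matching RECIST 1.1
(30 %), WHO (50 %), spherical-volume (65 %) and ellipsoidal (30 %) criteria.

**Radiomics.** Every 26-connected lesion component yields a 120-feature
vector: 6 shape, 16 first-order, 4 intensity-volume-histogram ("HU > x"
volumes) and 18 Haralick texture features (grey-level co-occurrence
matrices, 100 levels on −100…1000 HU, four in-plane directions averaged),
plus *rim* ratios `f(eroded)/f(standard)` and *peripheral* ratios
`f(dilated)/f(standard)` of the 38 non-shape features, computed with a
physical 4 mm (0.4 cm) in-plane margin. Voxels below −100 HU are excluded
throughout. Patient profiles are unweighted means over lesions, and the
full per-patient imaging block has 164 features (per-site volumes/counts,
global volume statistics, density flags and semantic scores + the averaged
radiomics and ratio families).

**Model.** An ensemble regressor: three pipelines (elastic net, RBF-kernel
SVR, random forest), each preceded by collinearity reduction (|Pearson| >
0.95, keep the member most correlated with the response), z-scoring, and
top-k univariable F-statistic selection. Hyperparameters (including k) are
tuned by randomized search under 5-fold cross-validation, the whole
procedure repeated with 5 seeds; the prediction is the unweighted mean of
the 15 members. Validation reports MSE, Pearson/Spearman correlations,
criterion-wise AUCs and RECIST-group ranking; feature-selection frequency
(0–15) and normalized elastic-net/random-forest importances summarize what
the models use. Imaging features can additionally be clustered by their
Spearman-correlation profiles against clinical/biological features, with a
plateau rule for the cluster number and an NMF cross-check.

Everything is testable without patient data through synthetic phantom scans
(`make_phantom`) and simulated cohorts with planted signal (`make_cohort`).

## Worked example

```r
library(radresp)

## a synthetic two-lesion phantom with known ground truth
ph <- make_phantom(phantom_spec(
  shape = c(48, 48, 10), spacing = c(1, 1, 5), background_hu = -20,
  lesions = list(
    list(site = "omentum", label = 1L, center = c(15, 15, 5),
         radii_mm = c(12, 12, 12), base_hu = 50,
         texture = list(type = "gaussian", sigma = 15)),
    list(site = "ovaries_pelvis", label = 2L, center = c(35, 35, 5),
         radii_mm = c(8, 8, 10), base_hu = 35, hyper_fraction = 0.05)),
  seed = 3))
lesions <- split_lesions(ph$mask, ph$image$spacing)
fv <- lesion_features(lesions[[1]], ph$image)
round(fv[c("shape.volume_cm3", "shape.sphericity", "fo.mean",
           "glcm.entropy", "rim_ratio.fo.std", "peripheral_ratio.fo.mean")], 3)
#>         shape.volume_cm3         shape.sphericity                  fo.mean
#>                    7.305                    0.947                   49.873
#>             glcm.entropy         rim_ratio.fo.std peripheral_ratio.fo.mean
#>                    5.025                    0.987                    0.342
```

The omental lesion is a 7.3 cm³ near-sphere (sphericity 0.95) whose mean
intensity matches the generated 50 HU; its rim ratio near 1 says the core
is as heterogeneous as the whole lesion, while the peripheral mean ratio of
0.34 reflects the darker (−20 HU) surroundings entering the dilated mask.

```r
## a simulated cohort with two informative features, fit and validate
ch <- make_cohort(cohort_spec(200, 20, beta = c(x1 = 1, x2 = -0.6),
                              noise_sd = 0.3, seed = 7))
model <- fit_ensemble(ch$features[1:150, ], ch$response[1:150],
                      pipeline_spec(search_iterations = 10), base_seed = 0)
scores <- predict(model, ch$features[151:200, ])
validation_metrics(scores, ch$response[151:200], ch$labels[151:200])
#> <validation_report> n=50  MSE=0.1426  Spearman r=0.951 (p=3.28e-26)
#>   AUC: recist30 0.966, who50 0.965, sphere65 0.967, ellipsoid30 0.966
head(importance_report(model), 3)
#>  feature selection_count n_seeds_selected importance
#>       x1              15                5 0.53029466
#>       x2              15                5 0.33308068
#>      x10              15                5 0.04128376
```

The two planted features are selected by all 15 ensemble members and carry
most of the normalized importance; held-out scores rank patients almost
perfectly (Spearman 0.95) and separate volumetric responders with AUC ≈
0.97 under every criterion.

A thin command-line interface over the same functions lives at
`inst/cli/radresp.R` (subcommands `simulate`, `extract`, `train`,
`predict`, `evaluate`, `cluster`).

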