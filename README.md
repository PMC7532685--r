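# phenocount

Automated identification, localization and enumeration of fluorescent
cell phenotypes in multi-channel microscopy, with an image-forensics
layer and the statistics used to benchmark rare-cell counts.

Rare-cell liquid-biopsy assays (circulating tumor cells, circulating
hybrid cells) are scored from fields of view with one nucleus channel
(DAPI) and up to three cytoplasm marker channels. A *phenotype* is a
±-pattern over the markers with the nucleus always positive — e.g. an
epithelial CTC is DAPI+/CD45−/E-cadherin+/vimentin−. `phenocount`
implements a hybrid rule-based + machine-learning pipeline:

1. **Binarization** — bilateral denoising, CLAHE, then a global threshold
   `T = c · T_raw`, where `T_raw` comes from one of sixteen classical
   histogram methods (Triangle by default) and the correction factor `c`
   is predicted by a random forest from a 166-dimensional image
   descriptor (7 whole-image histogram statistics + 63 block statistics +
   96 Gabor-bank moments). Touching nuclei are split by watershed.
2. **Rule-based phenotyping** — objects outside 200–2000 px or with
   eccentricity > 0.8 are purged; the cytoplasmic mask of a pattern is
   the product of the binary marker masks (inverted for "−" entries);
   applied to the nucleus mask, a region-growing area-ratio filter
   removes objects with masked/filtered area ratio < 0.6; surviving
   blobs are cells, exported as counts, positions, overlays and 120×120
   thumbnails.
3. **Forensics** — robust PCA (k = 1, α = 0.70) on the same features
   flags bad-leverage points as anomalous inputs; a random forest flags
   tampered images and a cubic SVM synthetic ones; flagged tampering is
   localized by hierarchically clustering PCA-estimated block noise
   levels (64×64 coarse / 32×32 fine, gap statistic and silhouette,
   least-pixel class = tampered).
4. **Evaluation statistics** — percentage count error, pooled detection
   sensitivity/specificity with bootstrap CIs, Passing–Bablok regression
   (with Kendall τ and cusum linearity pre-tests), Bland–Altman limits of
   agreement, Gwet's AC1, Poisson/NB/ZIP/ZINB count-model comparison by
   AIC with incidence-rate ratios, optimism-adjusted AUC, Youden cutoffs
   and 2×2 diagnostics with LOOCV.

A SIMCEP/SimuCell-style synthetic image generator with exact ground truth
(elliptical nuclei and cytoplasm, Perlin-textured markers, CCD noise,
clustered placement, splice forgeries, mirror augmentation, anomaly
images) makes every layer trainable and testable without any external
data. See the vignette in `vignettes/phenocount-methods.Rmd` for the
models, formulas and design decisions.

## Worked example

Generate a synthetic phenotype set, train the threshold-correction model
on generator fixtures, and enumerate one field of view:

```r
library(phenocount)

## fixtures: channel images + exact binary truth masks
train <- generate_phenotype_set(n_fov_per_group = 4, seed = 99,
                                width = 192, height = 192, mean_count = 4)
imgs <- list(); msks <- list()
for (e in train) {
  imgs[[length(imgs) + 1]] <- e$fov$nucleus
  msks[[length(msks) + 1]] <- e$truth$masks$nucleus
  for (i in seq_along(e$fov$markers)) {
    if (sum(e$truth$masks$markers[[i]]) == 0) next
    imgs[[length(imgs) + 1]] <- e$fov$markers[[i]]
    msks[[length(msks) + 1]] <- e$truth$masks$markers[[i]]
  }
}
model <- train_correction_model(imgs, msks, seed = 1,
                                config = pheno_config())
model
#> Threshold-correction model (random_forest, n = 64)
#>   test RMSE = 0.456, MAE = 0.359 (always-1 baseline MAE = 1.215)

s <- generate_phenotype_set(n_fov_per_group = 1, seed = 7,
                            width = 348, height = 260, mean_count = 5)
e <- s[[1]]
res <- enumerate_fov(e$fov, e$phenotypes,
                     pheno_config(correction_model = model))
res$counts          # enumerated
#>  P1  P4  P6 P10 P13
#>   4   2   2   4   2
e$truth$counts      # ground truth
#>  P1  P4  P6 P10 P13
#>   4   3   3   4   4
head(res$records[, c("x", "y", "area", "eccentricity",
                     "equivalent_diameter", "phenotype")], 4)
#>           x        y area eccentricity equivalent_diameter phenotype
#> 1  49.04043 115.1362  470    0.5395798            24.46268        P1
#> 2 257.04348 201.2292  506    0.5105607            25.38226        P1
#> 3 291.26080 176.5847  602    0.5050479            27.68556        P1
#> 4 326.55589 231.6752  662    0.5396614            29.03247        P1
```

The per-record fields are the cell centroid (pixels), area, eccentricity
and equivalent diameter `2*sqrt(area/pi)*pixel_size`. A single dense
small FOV undercounts a little (cells lost to overlap and the
conservative area-ratio filter); pooled over a full density-matched image
set, `enumeration_experiment()` reaches ~0.91–0.93 detection sensitivity
and ~0.99 specificity (see below).

Diagnostic 2×2 analysis of a count biomarker at a ≥ 1 cutoff:

```r
diagnostics_2x2(tp = 10, fp = 2, tn = 9, fn = 3, B = 0)
#> Diagnostic 2x2 analysis
#>   counts: tp=10 fp=2 tn=9 fn=3
#>   sensitivity 0.769, specificity 0.818, PPV 0.833, NPV 0.750, accuracy 0.792
```

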