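# radbatch

Reproducible radiomic biomarkers from heterogeneously acquired images.

Radiomic features are numbers computed from voxel arrays, so they inherit
every acquisition choice baked into those arrays: pixel spacing, slice
thickness, reconstruction kernel, contrast enhancement, scanner. A
prognostic model built on raw features can score c = 0.65 in one
acquisition stratum and 0.54 in another — at which point the "biomarker"
is measuring the scanner, not the tumor. `radbatch` is a pipeline for
*mitigating* that heterogeneity and *quantifying* whether mitigation made
prognostic performance comparable across acquisition strata:

1. **Extraction at a physical scale** — 3D feature extraction (intensity,
   histogram, volumetric, morphology, GLRLM, NGTDM, GLSZM families; 53
   features by default) from NIfTI image/mask pairs, with neighborhood
   offsets specified in millimetres and optional anisotropic resampling of
   every image to the dataset-minimum voxel spacing.
2. **Nested ComBat harmonization** — parametric empirical-Bayes
   location/scale batch correction (numerically identical to the reference
   genomics implementation), applied sequentially over several batch
   variables. The application order is selected by minimizing the number
   of features still flagged by the k-sample Anderson–Darling test, and
   features the procedure cannot harmonize are discarded. Clinical
   covariates are protected; outcomes never enter the design.
3. **Phenotype discovery** — Ward/Euclidean hierarchical clustering with
   consensus-based selection of the cluster number (area under the CDF of
   the consensus matrix) gated by SigClust significance of each dendrogram
   split: the cluster index CI = within-SS / total-SS is tested against a
   Gaussian null fit to the data (principal-axis spectrum, exactly
   conditioned — see the vignette).
4. **Prognostic evaluation by batch group** — per-stratum Cox models
   (phenotype indicator + clinical covariates), apparent and
   cross-validated Harrell's C, NMI between scenario phenotypes, and
   chi-square phenotype–covariate associations, assembled over the eight
   mitigation scenarios (`scenario_table()`: original, 3/5 mm offsets ×
   {spacing, acquisition, both} harmonization, and resample-then-harmonize).

A synthetic-cohort generator (`simulate_feature_table()`,
`simulate_images()`, `simulate_survival()`) plants batch effects under the
ComBat generative model, image-level acquisition effects (spacing, kernel
blur, contrast offset), a texture-encoded latent phenotype, and
exponential survival — so the entire pipeline is testable with no data
download.

## Worked example

```r
library(radbatch)
dir <- tempfile()
make_fixtures("feature-only-small", seed = 7, dir = dir)   # 150 x 60 cohort
features <- read_feature_table(file.path(dir, "features.csv"))
cohort   <- read.csv(file.path(dir, "cohort.csv"))

harm <- nested_combat(features,
                      data.frame(contrast = factor(cohort$contrast),
                                 kernel   = factor(cohort$kernel)),
                      covariates = as.matrix(cohort$covar1))
harm
#> nested ComBat harmonization
#>   chosen order: contrast > kernel
#>   AD-significant features: before = 42 / 60 , after = 0
#>   discarded: 0 feature(s)

phen <- consensus_cluster(harm$features, seed = 7)
phen
#> consensus clustering over k = 2, 3, 4, 5, 6
#>   CDF areas: 2: 0.502, 3: 0.616, 4: 0.712, 5: 0.774, 6: 0.814
#>   chosen k = 2
phen$split_p$p[1]                      # top dendrogram split: p = 0.005
nmi(phen$labels, cohort$phenotype)     # 1: the planted phenotype, exactly

fit <- fit_cox(data.frame(phenotype = as.integer(phen$labels == 2),
                          covar1 = cohort$covar1),
               cohort$time, cohort$event)
c_statistic(fit$risk, cohort$time, cohort$event)
#> [1] 0.691
```

Reading: 42 of 60 raw features carried detectable batch effects; after
nested harmonization none did and nothing had to be discarded. Consensus
clustering picks exactly two phenotypes (the consensus-area candidate is
gated back to k = 2 by split significance), the top dendrogram split is
significant (p = 0.005), the recovered labels match the planted phenotype
perfectly (NMI = 1), and the phenotype + covariate Cox model reaches an
apparent c-statistic of 0.69.

The full scenario battery runs through a JSON config:

```r
cfg <- run_config(features_csv = file.path(dir, "features.csv"),
                  cohort_csv   = file.path(dir, "cohort.csv"),
                  scenarios    = c("original", "3"),
                  spacing_vars = "spacing_group",
                  acquisition_vars = c("contrast", "kernel"),
                  covariate_cols = "covar1",
                  output_dir = "out")
res <- run_all(cfg)   # writes cscores.csv, nmi.csv, split_p.csv, manifest
```

or from the shell via `inst/exec/radbatch` (`simulate`, `run-all`,
`scenarios`, `defaults`; exit codes 0/2/3).

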