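Package: radbatch
Title: Mitigation of Image-Parameter Heterogeneity in Radiomics
Version: 0.1.0
Authors@R: person("radbatch", "maintainers", email = "radbatch@example.org",
    role = c("aut", "cre"))
Description: Tools for building reproducible radiomic biomarkers from 3D
    images acquired under heterogeneous protocols. Implements anisotropic
    voxel resampling with physical-unit (mm) neighborhood offsets, extraction
    of intensity, histogram, volumetric, morphologic, gray-level run length
    (GLRLM), neighboring gray tone difference (NGTDM) and gray-level size
    zone (GLSZM) feature families, parametric empirical-Bayes ComBat
    batch-effect harmonization extended to multiple batch variables by
    sequential (nested) application with k-sample Anderson-Darling order
    selection, radiomic phenotype discovery via Ward hierarchical clustering
    with consensus-based cluster-number selection and SigClust significance
    testing, and batch-group-wise prognostic evaluation with Cox models and
    Harrell's concordance statistic. A synthetic-cohort generator with
    planted batch effects, phenotypes and survival outcomes makes the whole
    pipeline testable without any imaging download.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    survival,
    igraph,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
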