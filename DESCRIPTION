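Package: phase4d
Title: Respiratory-Phase Selection and Stability Assessment for 4D-CT Radiomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for using four-dimensional computed tomography (4D-CT)
    respiratory-phase information in radiomic survival modelling of lung
    tumours. Implements per-patient selection of the most stable respiratory
    phase by cyclic neighbour-phase feature differences, four single-feature-set
    construction methods (mean, median, 50% phase, personalised), ICC(A,1)
    feature-stability classification over ten or three neighbour phases,
    peritumoural band geometry with high-density correction, an IBSI-style
    93-feature extraction pipeline (first order, GLCM, GLRLM, GLSZM, NGTDM,
    GLDM on original and Laplacian-of-Gaussian images), unsupervised volume and
    redundancy filters, three supervised selectors (univariable Cox,
    likelihood-ratio over a clinical base model, minimum-redundancy
    maximum-relevance) inside repeated event-matched stratified
    cross-validation, and clinical-radiomics Cox model comparison by bootstrap
    concordance index and fraction of new information. Includes synthetic
    cohort and 4D phantom generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    data.table
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
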