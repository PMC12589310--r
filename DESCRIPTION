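Package: habitatPET
Title: Metabolic Habitat Radiomics for PET/CT Prediction of PD-L1 Status
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Segments FDG-PET/CT tumour volumes into four metabolic habitat
    subregions by intersecting Otsu thresholds on the PET (SUV) and CT (HU)
    channels, quantifies per-habitat metabolic parameters (SUVmax, SUVmean,
    MTV, TLG) and spatial characteristics, extracts an IBSI-style inventory
    of 1015 radiomic features per region, selects features through a
    Mann-Whitney / Spearman / LASSO cascade, fits and evaluates Extra Trees
    and clinical logistic classifiers of PD-L1 positivity (ROC, exact
    binomial CIs, calibration, decision curves), relates habitat spatial
    characteristics to PD-L1 status by univariate logistic regression, and
    runs a companion glycolysis-gene expression arm (empirical-Bayes
    location-scale batch adjustment, moderated-t differential expression
    with Benjamini-Hochberg FDR, gene-list intersection and Spearman
    correlation). A seeded synthetic phantom module generates PET/CT
    cohorts and expression matrices with known ground truth so the whole
    pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    ranger,
    RNifti,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    sva
Config/testthat/edition: 3
RoxygenNote: 7.3.3
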