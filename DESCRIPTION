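Package: rectomics
Title: MRI Radiomics Pipeline for Predicting Rectal Cancer Treatment Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable radiomics pipeline for predicting pathological response
    of locally advanced rectal cancer to neoadjuvant chemoradiotherapy from
    multiparametric MRI (T2-weighted volumes and apparent diffusion coefficient
    maps). Implements region-of-interest re-segmentation and fixed-bin-count
    discretization, a 157-feature texture catalogue (GLCM, GLRLM, GLSZM, NGTDM
    and GLDM families with 2.5D slice-averaged aggregation), three feature
    selection strategies (stability-resampled AUC ranking with correlation
    pruning, affinity propagation, and minimum-redundancy maximum-relevance),
    four classifier families with cross-validated hyperparameter optimisation,
    external and hybrid validation with mask-provenance comparison, and a
    synthetic multicentre cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    e1071,
    randomForest,
    rpart,
    glmnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
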