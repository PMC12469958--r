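Package: msiclass
Title: Outcome Classification from MALDI Mass Spectrometry Imaging Peptide Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting chemoradiotherapy outcome from MALDI mass
    spectrometry imaging (MSI) of tryptic peptides in tumor tissue. Implements
    spectrum preprocessing (morphological top-hat baseline removal, total ion
    count normalization, peak detection and alignment into a feature matrix),
    univariate ROC-AUC screening of m/z features with rank-sum testing and
    multiplicity correction, L1-penalized logistic regression with
    patient-grouped stratified cross-validation and spectra- and patient-level
    evaluation, cross-cohort model transfer, and peptide/protein annotation of
    discriminative m/z features against a bottom-up LC-MS/MS peptide library.
    A synthetic two-cohort MSI generator with known ground truth (planted
    outcome-associated features, intratumoral subclones, per-slide batch
    effects) makes every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
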