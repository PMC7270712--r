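Package: rodentmri
Title: Small-Animal Brain MRI Preprocessing on Synthetic and Real NIfTI Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for preprocessing small-animal
    (rodent and other small-mammal) brain MRI: polynomial bias-field
    correction, histogram-based brain extraction with a quantitative
    mask-quality report, intensity-based rigid, affine and free-form
    nonlinear registration driven by normalised mutual information,
    iterative group-wise template construction, per-slice EPI
    distortion-correcting coregistration, FAIR arterial-spin-labelling
    T1 fitting with cerebral blood flow quantification, and Dice-based
    overlap evaluation. A deterministic head-phantom generator provides
    ground-truth data (known deformations, bias fields, motion and
    perfusion parameters) so that every stage can be exercised and
    validated end-to-end without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    minpack.lm,
    optparse,
    yaml
Config/testthat/edition: 3
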