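Package: tensorcardio
Title: Tensor Cardiography: ECG Decomposition into Gaussian CDF Differences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models each ECG heartbeat as differences of Gaussian cumulative
    distribution functions representing the collective depolarization and
    repolarization transitions of anodic (endocardial-side) and cathodic
    (epicardial-side) myocardium. Fits the model per beat and per lead by
    bounded nonlinear least squares (RT-separate, RT-bulk and extended modes),
    assembles the fitted parameters into a fourth-order beat x lead x
    component x metric tensor, applies fixed-threshold flagging of
    repolarization spread, and scores beat-to-beat abnormality with the
    Mahalanobis distance against a reference beat window. A forward-model
    synthetic-ECG generator, beat segmentation, and WFDB/CSV input/output
    make the full pipeline reproducible without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
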