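Package: roldsis
Title: Regression on Low-Dimension Spanned Input Space for ERP Analysis
Version: 0.1.0
Authors@R: person("RoLDSIS", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Exact, parameter-free linear regression for high-dimension,
    low-sample-size (HDLSS) data, obtained by restricting the solution to
    the subspace spanned by the observations.  Built around it is a complete
    event-related potential (ERP) analysis toolkit: discrete wavelet
    transform feature extraction with a length-8 least-asymmetric
    (symlet) filter, psychometric curve fitting for stimulus calibration,
    neurophysiological-axis geometry with bootstrap reliability
    (hyperspherical coordinates, PCA-LDA separability), cross-validated
    benchmarking against ridge, lasso and sparse partial least squares,
    and a synthetic ERP experiment generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
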