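Package: powerprop
Title: Power-Proportion Correction of Regional Brain Volumes for Head Size
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Corrects regional brain volumes for intracranial volume (ICV)
    using the power-proportion method: the allometric model
    VOI = alpha * ICV^beta + e is fitted by nonlinear least squares and each
    volume of interest (VOI) is normalized as VOI / ICV^b, where b is the
    fitted scaling exponent. Includes the classical alternatives (the
    VOI/ICV proportion, linear and quadratic ANCOVA residuals, and the
    log-log residual method), leave-one-out cross-validated model
    comparison, corrected-volume-versus-ICV diagnostics, readers for
    CSV/TSV volume tables and FreeSurfer stats files, a calibrated
    synthetic-data generator for simulation studies, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
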