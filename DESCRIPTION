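Package: optomask
Title: Widefield Calcium Imaging and Psychophysics Pipeline for
    Optogenetic Masking Experiments
Version: 0.1.0
Authors@R:
    person("Open", "Neuroimaging", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analyzing trial-based widefield GCaMP imaging
    experiments in which a visual detection task is combined with direct
    optogenetic stimulation of cortex. Provides preprocessing of per-trial
    image stacks (motion-regression stabilization, heartbeat-artifact
    removal via a heart-rate polynomial model, dF/F normalization, linear
    detrending, blank-trial z-scoring), quantification of sublinear
    visual-by-optostim interactions (Naka-Rushton contrast-response fits
    and a proportional-reduction statistic with bootstrap inference), and
    joint signal-detection psychometric fitting of detection behavior.
    A synthetic-session generator with full ground-truth sidecars makes
    every stage verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
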