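Package: aasroi
Title: Subcortical ROI Analysis of Reward Anticipation and Subsequent
    Memory in Event-Related fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A desk-scale, fully synthetic-data-testable pipeline for
    region-of-interest analysis of small subcortical nuclei in
    event-related BOLD fMRI of a monetary incentive delay task with a
    delayed recognition-memory test. Provides a synthetic study
    generator with known ground-truth effects, a monetary incentive
    delay task engine with adaptive response-deadline titration and
    signal-detection scoring of recognition memory, semi-automated
    intensity-sigmoid segmentation of the locus coeruleus anchored to a
    probabilistic prior, probability-weighted ROI timeseries extraction
    with percent-signal-change conversion, event-related GLMs with a
    rigorous confound model (motion, FD, DVARS, discrete-cosine drift,
    RETROICOR physiological regressors, fourth-ventricle signal),
    psychophysiological-interaction regressors, and group-level linear
    mixed-effects inference with Benjamini-Hochberg FDR control and
    BIC-approximate Bayes-factor model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
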