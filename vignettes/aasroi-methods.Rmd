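---
title: "Methods: subcortical ROI analysis of reward anticipation and subsequent memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subcortical ROI analysis of reward anticipation and subsequent memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aasroi)
```

## The scientific problem

Small subcortical neuromodulatory nuclei of the ascending arousal system
(AAS) — locus coeruleus (LC), basal forebrain (BF), medial and dorsal raphe
(MRN, DRN), substantia nigra (SN), and ventral tegmental area (VTA) — are
candidates for modulating both reward anticipation and memory encoding, but
they are tiny, lie next to CSF compartments and large vessels, and carry
weak BOLD signal. `aasroi` implements a desk-scale analysis pipeline for
this setting: an event-related monetary incentive delay (MID) task with a
next-day recognition test, probability-weighted ROI timeseries extraction
from unsmoothed data, GLMs with a rigorous physiological confound model,
and group-level mixed-effects inference. Because raw 7T data of this kind
are rarely shareable, the package's first-class citizen is a synthetic
study generator with known ground truth, so every stage is testable end to
end.

## The task model

A MID session consists of runs of trials with equal numbers of reward and
neutral trials in randomized order. Each trial is: fixation (2–11 s,
truncated shifted-exponential with mean 5 s), item picture (2 s, with an
item classification response), a second identical fixation, a target number
from {1, 4, 6, 9} (0.1 s, speeded higher/lower-than-5 classification), a
1 s blank, and a 0.5 s outcome. Reward trials pay +2 points when both
classifications are correct *and* the number response beats a deadline;
otherwise −1. Neutral trials always pay 0.

Two numerical choices deserve note:

* **ITI calibration.** Truncating an exponential changes its mean, so the
  raw rate is solved numerically (closed-form truncated mean, root-found
  with `uniroot`) such that the *truncated* mean equals the nominal 5 s.
  At the default bounds the calibrated rate is 0.23879 s⁻¹.
* **Deadline titration.** The design goal is that ~70% of reward trials
  end positively for a typical participant. The update rule implemented is
  the 70th percentile (linear interpolation) of all previous
  number-classification RTs in the run: an agent with stationary,
  continuous RTs beats its own 70th percentile 70% of the time, so the
  long-run positive-outcome rate converges to 70% without any assumption
  about the RT distribution's shape. The deadline before any history
  defaults to 0.6 s (configurable); a practice-based initial calibration
  is out of scope. A percentile rule is one of several updates compatible
  with the stated goal; it is documented here as the package's choice and
  validated by its convergence property, not by provenance.

The delayed recognition test mixes all old items with half as many lures;
responses are old/new plus a 0–100 confidence slider. Scoring follows
signal detection theory (hits, misses, false alarms, correct rejections;
recognition = hit rate − false-alarm rate), with two filters used by the
behavioral analyses: a high-confidence filter keeping confidence strictly
greater than 66, and exclusion of old items whose encoding item
classification was wrong. Participant outliers are flagged at strictly
more than 3 SD from the condition mean (a value at exactly 3 SD is kept;
per-condition SD is used when conditions are compared). Runs in which more
than half the items were misclassified are dropped entirely.

## The synthetic study generator

The generator is the pipeline's measurement standard, not a fixture. Its
defaults describe the study conditions all acceptance properties are
evaluated under:

* grid 40 × 40 × 30 voxels at 1.5 mm isotropic; TR 1.38 s; 2 runs × 120
  volumes; 8 participants; 10 MID trials per run (the most that fit a
  165.6 s run under the task's ITI distribution with headroom for the
  hemodynamic tail). Behavioral-only simulations keep the full 4 × 64
  design.
* eleven spherical ROIs (the 10 analysis ROIs plus the fourth ventricle)
  with Gaussian-falloff probabilistic weights (σ = radius/2, truncated at
  the radius). LC and fourth ventricle are placed close enough that their
  supports overlap, so the overlap-resolution step always has work to do.
* a 3D MT-weighted-like anatomical volume: flat background, LC raised by
  +30, CSF by +120, Gaussian noise SD 3 — the CSF compartment is brighter
  than the LC so the μ + 3σ cutoff of the segmentation is exercised.
* quasi-periodic cardiac (65 bpm) and respiratory (0.25 Hz) traces with
  5% cycle-length jitter; raised-cosine cycles guarantee exactly one
  detectable peak per cycle.
* 4D BOLD per run via the forward model
  `y_v(t) = B (1 + [Σ_k w_v β_k x_k(t) + drift(t) + physio(t)]/100) + ε_v(t)`
  with baseline B = 1000, HRF-convolved task regressors `x_k` in
  percent-signal-change (PSC) units, drift a random combination of the
  first 3 DCT components, physio a scaled resampling of the generated
  traces, and white voxel noise.

**Effect sizes.** No magnitudes for AAS BOLD responses were available to
calibrate against, so the injected effects are free parameters chosen once
for realism at desk scale: voxel noise SD 1.0 PSC, a reward-vs-neutral
condition effect of 0.4 PSC in the six AAS nuclei plus striatum, CA1 and
DG, and a remembered-vs-forgotten memory effect of 0.4 PSC in CA1 and CA3
only, drift amplitude 1.0 PSC and physiological amplitude 0.5 PSC. These
are larger than typical single-trial subcortical effects because the
synthetic study is much smaller than a real one (8 participants × 2 runs
× 10 trials versus 32 × 4 × 64); the choice keeps the contrast-to-noise
of the *group* test in a realistic regime rather than the per-trial
amplitude.

**What the generator does not emulate.** No head-motion geometry (motion
parameters are generated as a random walk and used by the confound model,
but the images do not actually move), no susceptibility distortion, no
slice-timing offsets, no spatially correlated noise, no vascular
artifacts. Passing tests therefore demonstrate correctness of the
estimators and the logic connecting them — not robustness to every noise
process in real 7T data.

**A property worth knowing.** The forward model injects voxel signal
`w_v·β·x(t)` and extraction computes the `w`-weighted mean, so an
ROI-level fitted beta equals `β · Σw²/Σw` (≈ 0.45 for the default
Gaussian masks) — a partial-volume-like attenuation that leaves every
significance pattern intact but shrinks recovered magnitudes. With
weight-1 (binary or single-voxel) masks the two operations compose to the
identity, which is how the exact-recovery tests are built. Similarly,
converting to PSC by the *empirical* temporal mean introduces a
multiplicative bias of about `mean(signal)/100` (&lt; 0.1% here);
exact-recovery tests therefore normalize by the true baseline.

## LC segmentation

The LC is segmented semi-automatically from the MT-like image anchored to
a published-prior-style probabilistic mask (in synthetic mode: the true LC
weight map shifted by one voxel and renormalized, emulating imperfect
registration; it is labelled synthetic everywhere it appears):

1. weighted mean μ and SD σ of image intensity under the prior;
2. a lower-cutoff logistic sigmoid centered at μ with slope σ;
3. a CSF sigmoid centered at μ + 3σ with the same slope;
4. grey-scale dilation (spherical element, physical mm) of the prior and
   of the CSF sigmoid by 0.5 mm — the lower sigmoid is never dilated;
5. the mask is `sqrt(dilated prior × lower sigmoid × (1 − dilated CSF
   sigmoid))`.

Design choices where the procedure was underdetermined: the S-curve is the
logistic (only center and slope anchors are specified by the procedure);
"slope" is the σ scale parameter of that logistic; the CSF term uses the
dilated CSF map; a zero weighted SD (constant image) is guarded by an
epsilon-scaled slope with a warning; at 1.5 mm synthetic resolution the
0.5 mm dilation is sub-voxel and reduces to the identity, which is the
correct physical behavior of a radius smaller than the voxel. The whole
procedure is invariant to affine intensity rescaling `a·I + b` (a > 0),
which the tests assert.

LC/fourth-ventricle overlap is resolved per voxel by keeping the higher
probability in its own mask and zeroing the other; ties are kept in the
first-listed (LC) mask — a deterministic, documented tie-break.

## GLMs

ROI timeseries are probability-weighted means over unsmoothed voxels,
converted to PSC (`100·s/mean(s) − 100`). The canonical double-gamma HRF
(peak 6 s, undershoot 16 s, dispersions 1, ratio 1/6, 32 s, unit peak) is
convolved with event boxcars on a 0.05 s oversampled grid — fine enough to
represent the 0.001 s number/outcome events as stated rather than as true
deltas — and sampled at frame times `v·TR + TR/2` (the middle of each
acquisition, matching slice-time referencing to half the TR).

* **GLM 1** models items with four regressors (condition × subsequent
  memory), number and outcome onsets, and a 2 s misclassified-item
  nuisance regressor when such trials exist.
* **GLM 2** adds the memory-test confidence as a parametric modulator,
  z-scored within participant (the within-participant choice removes
  between-participant scale differences in slider use).
* **GLM 3** adds an RT-duration regressor: boxcars whose durations are the
  per-trial item-classification RTs.

The confound block is 6 motion parameters + framewise displacement (50 mm
sphere convention) + DVARS + 12 DCT drift components + 18 RETROICOR
columns (cardiac orders 3, respiratory 4, interaction 1; cardiac phase by
linear interpolation between detected peaks, respiratory phase by
amplitude-histogram equalization signed by the derivative) + 1
mean-centered fourth-ventricle timeseries = 39 columns. The enumerated
composition sums to 39, and that is the count implemented and exposed;
when physiological recordings are absent, the RETROICOR block may be
replaced by any same-width matrix of data-driven noise components, which
conserves the count.

PPI regressors multiply the demeaned hippocampal seed (probability-weighted
union of CA1, CA3, DG) with mean-centered condition and memory indicator
columns; centering the indicators reduces collinearity with the seed main
effect, which is always included. Runs in which the two indicators are
collinear (possible when a short run lacks two of the four item cells) are
skipped for PPI with a message, since the contrast is unidentifiable
there.

Fitting is ordinary least squares via QR; rank-deficient designs produce a
warning and a flagged minimum-norm solution rather than an error. No
prewhitening is applied, matching the ROI-level estimation strategy the
pipeline implements.

## Group statistics

Per ROI, item betas are modeled as
`beta ~ condition + memory + (1 | participant)` by REML. The package
reports the standardized statistic (estimate/SE) but computes two-sided
p-values from the t distribution with Satterthwaite degrees of freedom
rather than the plain normal approximation: measured on truly-null memory
effects across 20 default synthetic studies, the normal approximation was
anticonservative at this sample size (empirical SD of the null statistic
1.06; the nominal 1.5% tail realized at 2.5%), which is the familiar
z-versus-t discrepancy at ~50 effective degrees of freedom, and it
produced occasional spurious subcortical memory effects. Satterthwaite
p-values restore calibration without touching any threshold. A singular
fit falls back to pooled OLS (t-based as well) and is flagged. P-values are Benjamini–Hochberg
FDR-corrected across the 10-ROI family, separately per effect. RT-regressor
betas (GLM 3) are averaged within participant and tested against zero with
one-sample t-tests, FDR-corrected the same way. Model comparison fits
intercept-only, condition-only, memory-only, and condition+memory mixed
models by maximum likelihood and reports BIC-approximate Bayes factors
`BF = exp((BIC_0 − BIC_m)/2)` — a deterministic unit-information-prior
approximation chosen over MCMC for desk scale; it preserves model ranking
for clear effects but is not a posterior-calibrated Bayes factor, and
exact reproduction of sampler-based Bayes factors is out of scope.
Voxelwise tests within a single ROI fit the same design per voxel and
FDR-correct across that ROI's voxels only.

## Problem sizes and determinism

All stochastic components flow from one master seed through named integer
substreams (participant, run, stage), so any bundle or pipeline result is
a pure function of (config, seed). Default problem sizes used throughout
the test suite and examples: the generator defaults above for end-to-end
properties (each full pipeline run takes ~15–20 s), a 16 × 16 × 12 grid
for unit-level forward-model checks, 6 000 simulated trials for the
titration convergence property, and 10⁵ draws for the ITI mean.

## Known limitations

* The attenuation and PSC-bias properties above mean recovered magnitudes
  are interpretable relative to the forward model only after accounting
  for `Σw²/Σw`; significance patterns are unaffected.
* Mixed-model inference treats run-level betas as homoscedastic,
  ignoring that cells with few trials produce noisier first-level
  estimates, and ignores within-run covariance between the four cell
  betas — both inherent to the two-stage summary-statistics approach
  implemented here.
* The BIC Bayes factors are approximations; they should not be compared
  numerically against sampler-based values.
* Real-data mode expects preprocessed, co-registered inputs (NIfTI volumes
  and masks on one grid, BIDS-style events, motion parameters,
  physiological traces); registration, distortion correction and
  segmentation of non-LC structures are upstream of this package.
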