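---
title: "Linking sensory-training-related connectivity change to neurobehavioral recovery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking sensory-training-related connectivity change to neurobehavioral recovery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connrecov)
```

## The analysis problem

Severe traumatic brain injury can leave patients in disordered states of
consciousness (vegetative or minimally conscious). Small randomized trials of
passive sensory stimulation in this population compare an intervention arm
(familiar auditory sensory training, FAST: autobiographical stories read by
familiar voices) with a placebo arm, and ask whether treatment-related
changes in brain network connectivity relate to neurobehavioral recovery.
The data are as hostile as the question is interesting: four imaging
subjects per arm, two imaging timepoints (baseline BL, endpoint EP),
heterogeneous lesions that leave at least one region or tract indiscernible
in every subject, behavioral instruments with ordinal item scores and
multiple raters, and head motion that must be scrubbed before any
connectivity estimate is trustworthy.

`connrecov` implements the complete analysis chain for this design as
reusable, tested components, together with a synthetic cohort generator
that reproduces the statistical structure each stage assumes, so the whole
pipeline can be exercised and validated with no access to patient data.

## Pipeline stages and their models

### Motion scrubbing

Acquisitions of 205 volumes at TR = 3 s lose their first 3 volumes to
signal stabilization (202 remain). Signals are linearly detrended and
bandpass filtered to 0.01–0.08 Hz with an FFT brick-wall filter (components
outside the passband, including DC, are zeroed — out-of-band attenuation is
therefore complete rather than the ≥ 20 dB a recursive filter would give).
Framewise displacement is the Power-style sum of absolute backward
differences of the six realignment parameters, with rotations converted to
millimetres on a 50 mm sphere. DVARS is the root-mean-square volume-to-volume
signal change after rescaling the series to a global median of 1000, which
makes the conventional threshold of 50 equal to 5% of the signal. A volume
is retained iff FD < 0.5 mm **and** DVARS ≤ 50; the FD boundary is censored
and the DVARS boundary retained, following the printed directions of the
two inequalities. Retained volumes are used as-is (non-contiguous allowed),
and every subject is truncated to the earliest common number of surviving
volumes so all correlation estimates share one sample size. BL–EP motion
differences are tested per arm with an exact paired Wilcoxon signed-rank
test (zeros dropped; the 2^n sign assignments enumerated for n ≤ 15, so the
all-zero case returns p = 1 rather than failing).

DVARS is computed on the unfiltered (post-discard) series; the filtered
series is what enters connectivity estimation. Computing DVARS after a
0.01–0.08 Hz bandpass would smear single-volume spikes across neighbours
and weaken exactly the criterion it implements.

### Two connectivity metrics, deliberately different

Within-network strength preserves *correlation* structure: the mean Fisher
z over all unordered ROI pairs inside a network, anticorrelations included,
computed from the 26 × 26 ROI–ROI Pearson matrix. Between-network strength
preserves *signal* structure: each network is collapsed to the plain
average of its member time series (no per-ROI standardization), and the
4 × 4 correlation matrix of these mask series is Fisher transformed. The
two choices are not interchangeable — amplifying one node rescales nothing
in the within-network metric (correlations are scale-free) but can
dominate the mask average; the test suite asserts exactly this contrast.
Missing ROIs propagate: a pair touching a missing ROI is missing, a
network mean is taken over remaining pairs, and only a network with fewer
than two usable ROIs becomes a missing metric handed to imputation.

ROI-to-network membership is configuration, not code. The default
assignment covers 26 ROIs: default mode (6), language (6), salience (7)
and attention (7). Published region lists for these networks are ambiguous
about one bilateral pairing in the attention network; the right
temporo-parietal junction is kept in the default-mode list only, which is
the assignment that reconciles the listed regions with a 26-ROI total.

### Tract FA and the length-standardized verification

Tract-mean fractional anisotropy is extracted within a common-voxel mask —
voxels with FA ≥ 0.2 at *both* timepoints (0.2 inclusive, keeping
partial-volume edges) — intersected with each hand-drawn tract mask. The
verification adjustment standardizes the amount of substrate: the shortest
anterior–posterior tract extent in the cohort defines a fixed length, each
subject's length is that minimum scaled by their skull length relative to
the template skull length (rounded half away from zero), and the adjusted
mask keeps the voxels within that length of the tract's *posterior pole*.
Conventions that the data formats do not pin down are fixed here: the
anterior–posterior axis is the second grid axis by default (configurable),
anterior sits at the low index, extents are inclusive voxel counts times
the voxel size, and the "skull length" is measured on the supplied
brain/head mask.

The adjustment can only shrink a tract, so it under- rather than
over-states an FA–behavior correlation; a positive correlation that
survives it is labelled robust by sign alone (significance is not
required). The generator can confine a planted FA change to the posterior
or anterior segment, which the tests use to show sign preservation in the
shared segment and attenuation outside it.

### Rasch person measurement

Item-level scores are converted to interval measures before any linear
modelling. The partial-credit model gives every item its own category
thresholds; the many-facet extension adds an additive rater severity to
the linear predictor (ability − step − severity), with severities summing
to zero and item difficulties centered at zero. Estimation is joint
maximum likelihood with alternating Newton blocks: person abilities are
profiled out with an inner Newton loop, item step parameters take a full
within-item multivariate Newton step (the steps of one item are strongly
coupled through the category probabilities — updating them one at a time
oscillates), and severities follow. Convergence requires the largest
parameter change in a sweep to fall below 1e-4 logits, with adaptive
under-relaxation (the step factor halves whenever the sweep change stops
decreasing) to break the small limit cycles undamped alternating Newton
can enter near the optimum.

Floor-heavy response data — the norm in disorders of consciousness —
creates two degeneracies with documented remedies. Categories never
observed among non-extreme persons have no finite step estimate, so each
item's scale is collapsed to its observed categories before estimation
(the mapping is kept in the fit); a ±12-logit cap on step parameters
remains as a safety net. Persons with zero or perfect total scores have no
finite maximum-likelihood measure and are assigned one by solving for the
ability whose expected raw score equals the observed score adjusted inward
by 0.3 score points. The conditional standard error of measurement is the
inverse square root of the test information at the person's measure, and
the conditional minimal detectable change is
`z_(1+c)/2 * sqrt(sem_BL^2 + sem_EP^2)` at 95% confidence, with a gain
counted as meaningful only if it strictly exceeds it.

A practical identification note: rater severities are only estimable in a
linked design. Since person-timepoints are treated as separate measurement
occasions, a design where each occasion is scored by a single rater
confounds that rater's severity with the mean ability of their occasions;
the generator therefore has every rater score every occasion
(double/triple scoring), and the fitting function rejects disconnected
rater networks by name.

### Mixed-model change indices

Each measure — 10 network metrics, 19 tract FA values, 3 behavioral
measures — is modelled as
`value = beta1_g + beta2_g * time + b0_i + b1_i * time + eps`, by maximum
likelihood (not REML, for cross-model comparability), with group-specific
fixed effects and subject random intercepts and slopes. Subject-level
indices derive from the model: BL is the subject's intercept, EP the
prediction at the endpoint time, and change their difference, which equals
`(beta2_g + b1_i) * t_EP` exactly.

With six (DOCS-like weekly) or twelve (CNC-like) occasions the model is
well identified and fit with `lme4::lmer`. With the two imaging timepoints
it is not: the marginal covariance of (BL, EP) has three free moments but
the model has four variance parameters, so the profiled likelihood is flat
along a ridge and any point on it — each with *different* shrinkage of the
subject effects — is an ML solution. Rather than let an optimizer pick an
arbitrary ridge point, the two-timepoint fit uses the deterministic
boundary representative with residual variance zero: fixed effects are the
group means of level and change rate, subject effects reproduce the
observed values exactly, and the random-effect covariance is the
ML (divide-by-n) covariance of those effects. This is also the regime in
which the model-derived indices show the near-zero mean absolute error
(MAE) and mean absolute relative error (MARE) that the verification step
expects, and it keeps the between-subject change variance intact for the
discovery correlations. Hard failures of the well-identified fits fall
back to a random-intercept-only model and are flagged.

A subject missing a measure entirely is imputed from the group fixed
effects — the average of the other subjects nested in the same arm, with
no subject-specific effect available — flagged, and used downstream
exactly like observed values. Imputation is validated by masking observed
subjects, re-imputing them, and testing the discrepancy: each held-out
subject contributes a Mahalanobis-type term `e' Cov^-1 e`, where `Cov` is
the marginal covariance of a new subject's observations (random-effect
covariance at the observation times + residual variance + fixed-effect
estimation covariance — the last two alone would misstate the variance of
a held-out subject's deviation, which is why the random-effect part is
included), with degenerate zero-variance directions projected out. The sum
is referred to a chi-square with one degree of freedom per retained
direction; under the correct model these p-values are uniform, which the
test suite checks by simulation.

### Exact permutation inference and FDR filtering

All small-sample significance uses exact enumeration. Within-arm change
tests flip the signs of the n paired changes (2^n assignments); between-arm
BL/EP tests exchange group labels (`choose(nA + nB, nA)` relabelings, 70
for 4 + 4). The *ordered p* is the count of permuted statistics strictly
greater than the observed one, divided by the number of permutations —
faithfully to that counting rule it can be exactly zero, and a
`(k+1)/(N+1)` estimator is available behind a switch. The standalone test
functions default to one-sided counting on the observed direction (the
convention the worked example 3/16 = 0.19 implies). The pipeline's summary
tables and baseline screen, however, use the two-sided count
(`|permuted| > |observed|`): one-sided observed-direction p-values are
bounded by 0.5 and anti-conservative under the null (uniform on (0, 0.5)),
whereas the tabulated values this analysis style reports include ordered
p above 0.5 — only the two-sided count produces those, and only it keeps
the FDR filter calibrated. Families are
FDR-filtered with the Benjamini–Hochberg step-up rule at q = 0.20: the 10
network tests per contrast, the 19 tract tests per contrast, and the
discovery correlations.

Baseline screening runs the group-exchange test on every feature's BL
values and excludes FDR-flagged features from discovery (a raw-p variant is
available), recording the reason — the analog of dropping a tract whose
arms already differed before treatment.

### Discovery and verification

Connectivity change is correlated with behavioral change per arm (n = 4
per correlation; pooling is off by default and config-exposed), for every
screened feature × outcome pair. Significance uses the t transform
`t = r sqrt((n-2)/(1-r^2))` two-sided; the FDR flag applies BH at q = 0.20
over the whole discovery family of one run (groups × features × outcomes
in a single family — the most conservative of the defensible family
choices for the "no spurious resting-state finding" behaviour, and both
raw and FDR flags are always reported side by side). Positive,
raw-significant FA findings in the intervention arm are then re-derived
end to end with adjusted tracts — adjusted masks, re-extracted FA, re-fit
mixed models, re-computed correlation — and labelled robust iff the
verified correlation stays positive.

## The synthetic cohort generator

The generator is the package's stand-in for the trial: every default is a
study condition, not a tuning knob.

* **BOLD**: 205 volumes at TR = 3 s over 26 ROIs with block-structured
  correlations (configured within- and between-network levels validated
  for positive semi-definiteness, offending block named on failure), unit
  structure scaled to mean 1000 / SD 20 so DVARS thresholds mean what they
  say, linear drift at 2% of the marginal SD, and single-volume spikes
  that displace the realignment parameters and the signal *together*, so
  FD and DVARS censoring fire on the same volumes — deliberately
  exercising the AND of the two criteria.
* **FA**: 19 axis-aligned box tracts with an explicit posterior pole on a
  1 mm grid (a scaled-down synthetic geometry whose template skull length
  is 60 mm), voxel FA = tract mean + spatial noise, endpoint mean shifted
  by a per-arm effect. The coupled tract's per-subject length is drawn
  from 14–24 voxels with the cohort minimum forced to 14. Intervention-arm
  FA changes in the default configuration rise in the left inferior
  longitudinal fasciculus and right-hemisphere language-homolog tracts;
  placebo-arm changes fall in callosal and right arcuate tracts.
* **Behavior**: polytomous responses drawn from the partial-credit /
  facets model itself, 6 weekly DOCS-like occasions (25 items) and 12
  CNC-like occasions (11 items with item-specific scales), raters with
  fixed severities scoring every occasion.
* **Coupling**: one latent recovery factor per subject drives the
  between-subject spread of both behavioral slopes and (in the
  intervention arm only) the coupled tract's FA change. Resting-state
  metrics are never coupled to behavior. Setting the FA coupling to zero
  gives the null-coupling condition.
* **Missingness**: each region/tract is independently indiscernible per
  subject (default rate 0.06), every imaging subject is guaranteed at
  least one missing region, and sampled patterns are repaired so every
  (arm, region) keeps at least two observed subjects — group-nested
  imputation is undefined otherwise, and a pattern that removes a whole
  network or tract for a whole arm is rejected outright.
* **Determinism**: one master seed; per-subject substreams derive from a
  stable hash of the subject id, so single subjects are reproducible in
  isolation and cohorts are bit-identical across runs.

What the generator does *not* emulate matters for interpreting green
tests: no hemodynamics or autocorrelated BOLD noise, no scanner artifacts
beyond the coupled spikes, no lesions (missingness is random rather than
anatomically structured), FA values are drawn directly rather than fit
from diffusion gradients, and ability trajectories are linear. Passing
tests certify the *statistical machinery* — estimator definitions,
invariances, calibration, recovery of planted effects — not fidelity to
real pathophysiology.

## Simulation study sizes and the planted-effect check

The package's validation suites use these sizes, chosen to give stable
Monte-Carlo margins: population-fidelity checks at 10,000 volumes
(tolerance 0.02), BH-FDR calibration on 10,000 simulated families of 10
p-values (5 uniform nulls, 5 Beta(0.1, 1) alternatives), fixed-effect
recovery over 500 simulated longitudinal cohorts, Rasch difficulty
recovery at 200 persons (correlation ≥ 0.95), imputation calibration over
150 refits, and the end-to-end study at 20 planted-effect plus 12
null-coupling cohorts.

The end-to-end check plants its effect at generous sizes, and the
generosity is mostly *measurement* generosity: with four subjects per arm
the sampling noise of a Pearson correlation is brutal (the Fisher-z
standard error is 1), so detecting the planted coupling in ≥ 80% of
replicates requires the latent-factor signal to dominate measurement
error. The planted configuration therefore widens the instrument (7
response categories, difficulty range ±8 logits, an 8-item
auditory-language subscale spread across the difficulty ladder), has three
raters score every occasion, sets the behavioral slope spread to 0.7
logits/week and the FA coupling to 0.05 FA units, and exempts the coupled
tract from the missingness process so the check isolates discovery
behaviour from imputation (which has its own calibration suite). Success
is defined as the planted tract × auditory-language × intervention-arm
correlation being positive, raw-significant and verified robust; the
null-coupling condition requires the FDR-filtered discovery list to
contain no resting-state–behavior finding.

## Known limitations

JMLE is consistent in the long-test limit but biased at fixed test length;
the recovery suites work at the scale where that bias is visible but small
(difficulty correlations ≥ 0.95, severities within 0.1 logits). The
two-timepoint boundary fit deliberately does not shrink — with two
observations per subject there is no data-driven way to choose a shrinkage
level, and reproducing observed values is the transparent choice, at the
cost of noisier change indices than a longer design would give. Exact
enumeration limits (n ≤ 20 sign-flip, combined n ≤ 16 exchange) cover the
intended cohort sizes; larger samples would need the Monte-Carlo mode the
error messages point to. The chi-square imputation validation treats
variance components as known at their estimates, so its calibration is
approximate in very small cohorts.
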