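---
title: "Quantifying presynaptic endocytosis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying presynaptic endocytosis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endokin)
```

endokin quantifies synaptic vesicle (SV) recycling from three kinds of data:
time-lapse fluorescence videos of pH-sensitive reporters (pHluorin,
CypHer5E), multicolor gSTED images of synapses, and electron-microscopy
morphometry tables. This vignette explains the models behind each stage, the
parameters that matter, what the synthetic-data generators do and do not
emulate, and the design decisions taken where more than one reasonable
implementation exists.

## The kinetic model behind the trace analysis

pHluorin fused to the luminal domain of an SV protein is quenched in the
acidic vesicle and fluoresces once exposed at the neutral cell surface, so a
train of action potentials (APs) produces a fluorescence rise (exocytosis)
followed by a decay as reporter is re-internalised and re-acidified. Under
train stimulation at physiological temperature, endocytosis is the
rate-limiting step of that decay, so the post-stimulus decay constant tau is
the kinetic readout of endocytosis. CypHer5E has inverted polarity (bright in
the acidic lumen), giving a downward deflection with the same kinetics.

The simulator implements the simplest model whose decay constant equals the
quantity the pipeline estimates. The surface reporter fraction S(t) obeys

$$\frac{dS}{dt} = E(t) - \frac{S}{\tau_{endo}},$$

where exocytosis E(t) injects `exo_fraction` of the pool uniformly over the
stimulus window and retrieval is first order with time constant `tau_endo`.
Reacidification is folded into tau (it is fast relative to retrieval under
these conditions). The measured signal is

* pHluorin: amplitude x (S + resting fraction),
* CypHer: amplitude x (1 − S − resting fraction),

multiplied by a mono-exponential photobleaching factor exp(−t/`tau_bleach`),
offset by the camera background, plus Gaussian read noise with SD
`noise_sd_fraction` x amplitude (an EM-CCD-regime approximation chosen so
fits can be tested at controlled SNR; Poisson noise is used for the photon-
limited STED images instead). The solution for S(t) is piecewise analytic,
so generated traces carry no integration error.

Assumptions worth keeping in mind: a single well-mixed vesicle pool, no
ultrafast (<1 s) endocytosis component, no calcium dynamics, and bleaching
acting multiplicatively on the whole signal.

## Trace quantification

The analysis follows the standard reporter-assay conventions:

* **F0** is the mean of the first 5 frames (pHluorin) or first 10 frames
  (CypHer) of the background-corrected trace — always that fixed window.
* **Surface normalization** F/F0 yields the fold increase max(F)/F0
  (pHluorin) or the exocytic amplitude F0 − min(F) (CypHer) as measures of
  exocytosis.
* **Peak normalization** subtracts F0, flips the sign for CypHer so both
  indicators are positive-going, and divides by the peak deflection dFmax,
  giving norm. dF with maximum exactly 1 at the peak frame.
* **Decay fitting** uses the constrained mono-exponential
  y0 + A exp(−t'/tau) with y0 = 1 and offset 0, which reduces to
  exp(−t'/tau) with t' measured from the peak frame. tau is the only free
  parameter; it is found by golden-section least squares over all frames
  from the peak to the end of the recording, within
  (frame interval/10, 10 x recording length). A fit landing on a bound is
  flagged, not silently reported. An independent 10,000-point grid search
  (`grid_search_tau()`) is provided as a cross-check and agrees with the
  fitter to well under 0.5% on noisy traces.

**Fit origin.** The constrained model must equal 1 at t' = 0, so the only
consistent origin is the peak frame itself. The peak is searched within the
stimulus window plus a two-frame lag when the protocol is known: the
physiological extremum sits at the end of the train, and an unrestricted
argmax would latch onto bleach-induced late drift in uncorrected CypHer
traces or onto late noise excursions.

**Averaging and normalization unit.** The ROI analysis averages the
background-corrected fluorescence of all (>= 20) responding boutons of a
video at each time point, and normalization operates on that per-video
trace; per-video norm. dF traces are then averaged across videos and the
average is fitted. Normalizing each bouton separately before averaging is
available (`normalize_unit = "bouton"`), but it divides each trace by its
own noisy maximum, which at realistic SNR biases the fitted tau downward by
several percent; the per-video default avoids this because the maximum is
taken on a 20-30-fold less noisy trace.

## Photobleaching correction (CypHer)

CypHer recordings bleach appreciably. The bleaching curve
B(t) = b0 exp(−t/tau_bleach) is fitted to the first 10 (pre-stimulation)
frames — with the amplitude profiled out analytically, leaving a
one-dimensional search in tau_bleach — and the correction adds the
cumulative loss: F_corr(t) = F(t) + (B(0) − B(t)). Among the additive
readings of "adding the value of the photobleaching curve", only the
cumulative-loss form leaves a signal-free exponential baseline stationary
(the package tests enforce a post-correction slope below 1e-6 x b0 per
second); the literal variant that adds B(t) itself is available via
`mode = "literal"` for comparison. A fitted tau_bleach above `tau_cap`
(default 1e4 s) is treated as negligible bleaching and the correction is
the identity.

One property of this correction deserves emphasis. When bleaching is truly
multiplicative — as in the generator — the additive add-back restores the
baseline exactly but leaves a residual exp(−t/tau_bleach) factor on the
stimulus deflection, so the fitted constant on corrected traces is
analytically tau x tau_b / (tau + tau_b) rather than tau: about 9% low at
tau = 15 s, tau_b = 150 s. The unit tests assert exactly this composite
value, and the correction is still indispensable — without it the deflection
never decays back and the fit runs away to its upper bound. An exact
correction would divide by the normalized bleach curve instead of adding
the loss back; the additive form is retained as the default because it is
the established convention for this assay, and the residual compresses
both conditions of a comparison by the same factor, leaving percent-level
differences and orderings intact.

## Responding-bouton detection

Published automated bouton-detection tools for this assay do not document a
reference algorithm, so the package implements an explicit, testable
contract: a difference image (mean of the frames spanning the stimulus
minus the mean baseline frame; sign flipped for CypHer), Gaussian smoothing
(sigma 2 px), Otsu thresholding, connected-component labelling with area
bounds, and a per-component response criterion peak dF/F0 >= 0.05. Otsu
always splits a histogram somewhere, so the threshold must additionally
clear a robust noise floor (median + 5 x MAD of the smoothed difference
image); without this, a response-free video would yield dozens of noise
components. Videos with fewer than 20 responding boutons are flagged
excluded — the per-video analysis floor — rather than silently analysed.

The background region for trace measurement defaults to the dimmest decile
of pixels outside all ROIs, selected on the mean over *all* frames:
selecting on a subset of frames would correlate the region with those
frames' noise and bias every baseline (this bias was directly visible in
early tests as a spurious downward drift of averaged traces).

## STED line profiles

Synapse orientation is quantified on line profiles perpendicular to the
synaptic cleft: 1.0 um long, averaged over 0.4 um width, sampled every
18.9 nm (the pixel size), i.e. floor(1000/18.9) + 1 = 53 samples, with
bilinear interpolation for off-grid sampling. Profiles are aligned so the
raw maximum of the presynaptic reference channel (Bassoon) sits at 0 nm,
ties broken toward the profile centre.

**Axis sign.** Which side is positive is a pure convention; the package
orients every profile so the postsynaptic marker's intensity-weighted
centroid lies at negative positions. The asymmetric presynaptic
integration window, −37.8 to +151.4 nm, then points away from the
postsynapse — the only direction in which it makes sense. On the 18.9 nm
grid these bounds are −2 and +8.01 pixels, so the window is read as the
closed set of 11 grid samples from −37.8 to +151.2 nm. Presynaptic levels
are the plain sum of the raw (non-normalized) protein-of-interest samples
in that window; any constant-factor convention cancels in the
percent-of-control normalization (control mean set to 100).

For localization analysis each channel of each synapse is normalized to its
own maximum (set to 1) and averaged pointwise across synapses on the common
position grid (the intersection of the aligned grids, keyed on positions
rounded to 0.1 pm to avoid floating-point grid fragmentation).

The knock-in intensity measurement blurs both confocal channels (Gaussian,
sigma 2 px), binarizes each with Otsu's method, intersects the masks,
labels connected components and reports the mean STED intensity per
component; an empty intersection returns an explicitly flagged empty table.

## Morphometry and statistics

EM morphometry records are per-synaptic-profile counts of SVs,
endosome-like vacuoles, non-coated invaginations, coated pits and coated
vesicles together with the bouton profile area; densities are count/area
with mean +- SEM per group. The generator samples areas from a lognormal
(default mean 0.35 um^2, CV 0.5 — typical for cultured hippocampal bouton
profiles) and counts from Poisson(density x area). The default SV density,
92.2/um^2, matches a control condition of the kind of culture this
pipeline targets; the rarer structures default to low single-figure
densities.

The statistical engine encodes a normality-gated decision rule: when total
n exceeds 100 or the number of independent experiments N exceeds 5, each
group is tested with the D'Agostino-Pearson K2 omnibus test (implemented
from the published skewness and kurtosis transformations; no installed R
package provides it), and any group with p < 0.05 routes the comparison to
the nonparametric branch. Concrete tests by design: unpaired two-tailed
Student's t / Mann-Whitney (two groups), one-sample t / one-sample Wilcoxon
against the normalization reference (100 or 1), one-way ANOVA + Tukey HSD /
Kruskal-Wallis + Dunn (three or more groups). Decisions the rule leaves
open were fixed as: alpha = 0.05 for the gate; any-group-fails routes
nonparametric; Dunn's pairwise z-tests use the joint-rank formula with tie
correction and Bonferroni adjustment (the most common "Dunn's multiple
comparison" convention, configurable). Mann-Whitney p-values are exact
when the product of group sizes is at most 400 and no ties are present,
and use the normal approximation with tie correction otherwise; an
exhaustive-enumeration oracle (`mannwhitney_exact_oracle()`, capped at 12
observations) validates the exact branch in the tests.

## What the generators emulate — and what they do not

The generators reproduce the statistical and kinetic *structure* the
analysis assumes: first-order retrieval kinetics with uniform exocytic
injection, per-bouton amplitude heterogeneity (lognormal, CV 0.3),
multiplicative bleaching, Gaussian read noise on videos and Poisson photon
noise on STED images, Gaussian marker clusters convolved with Gaussian
PSFs, and Poisson count statistics over lognormal bouton areas. They do
not emulate: focal drift or lateral motion, spatially correlated noise,
vesicle-pool subcompartments, ultrafast endocytosis, asymmetric or
multi-modal marker clusters, chromatic offsets, or detector saturation.
Passing tests therefore demonstrate that the pipeline recovers planted
truth under the stated model, not that real recordings satisfy that model;
on real data the drift/registration and cluster-shape caveats matter most.

Noise levels and amplitude distributions are calibration choices, not
facts from any particular dataset: trace tests use 5% amplitude noise
(video detection tests use 2%, which puts the centroid response at SNR of
about 13, matching the "SNR >= 10" regime the detector is specified for),
and STED tests use a photon scale of 50 counts at unit intensity.

## Numerical choices

* 1-D least squares (decay tau, bleach tau_bleach) uses `stats::optimize`
  with absolute tolerances of 1e-9 x and 1e-12 x the upper bound
  respectively; amplitudes are profiled out in closed form.
* Peak ties resolve to the earliest frame; reference-maximum ties resolve
  toward the profile centre.
* Degenerate inputs fail loudly: flat traces are non-responders, flat
  reference channels cannot be aligned, zero-variance groups are rejected
  by rank tests, all-identical ANOVA groups are undefined, zero-area
  morphometry records are rejected with a report.
* All randomness is seeded through the configs; every generator is
  bit-for-bit reproducible, and the end-to-end driver derives per-video
  seeds from the experiment seed so a report is reproducible from its
  config alone (hash recorded in the report).

## Problem sizes used by the test-suite

The suite checks tau recovery at tau in {10, 30, 60} s (noiseless, within
1%) and tau = 30 s with 5% noise, 30 boutons/video, 8 videos, 10 seeds
(within 10%); bleach correction at tau = 15 s, tau_bleach = 150 s;
detection on ten 128 x 128 videos with 25 responders + 5 silent boutons;
offset recovery at {−150, 0, +40, +150} nm with 100 synapses per offset
and a 2x level difference with 100 synapses per condition; type-I error of
the gate+test procedure on 2,000 Gaussian null replicates at n = 60/group
(99% binomial band around 0.05); and the directional tau-ordering check on
100 replicates of the full video pipeline at 96 x 96 px with 25
responders/video — sizes chosen so each property is measured at tight
Monte-Carlo error while the whole suite stays desk-scale.

## Known limitations

* The additive bleach correction under truly multiplicative bleaching
  compresses tau by the factor tau_b/(tau + tau_b), as analysed above.
* No hierarchical modelling of the bouton-within-video-within-culture
  nesting; videos are treated as the independent unit, as is conventional
  for this assay.
* Line placement on real STED images is manual (line endpoints supplied);
  automatic cleft finding is out of scope, as are deconvolution, chromatic
  correction and 3-D profiles.
* Two-phase or stretched-exponential decays are out of scope; the single
  constrained exponential is the model of record for this assay.
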