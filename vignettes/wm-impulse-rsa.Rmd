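---
title: "Decoding veridical and transformed working-memory content from impulse responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding veridical and transformed working-memory content from impulse responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmrsa)
```

## The scientific problem

When an item held in working memory is mentally transformed — here, an
orientation grating rotated by an instructed angle — does the brain keep the
original, now task-irrelevant representation alongside the rotation product,
or overwrite it? The experimental handle is *impulse perturbation*: a
task-irrelevant visual stimulus flashed during the maintenance period evokes
an EEG response that partially reflects the hidden state of the memory
network, so multivariate pattern analysis of that response can read out
memory content even when ongoing delay activity has returned to baseline.

This package implements the full multivariate analysis chain for such
designs, together with a generative simulator of population codes that makes
every inferential step testable end to end:

1. a balanced factorial trial design (6 cued x 6 uncued orientations x
   2 cue sides x 5 rotations);
2. spatiotemporal feature extraction from epoched EEG;
3. cross-validated squared-Mahalanobis representational dissimilarity
   matrices (the linear discriminant contrast, LDC) and hypothesis-model
   regression, including residualised and split-half controls;
4. trial-wise Mahalanobis orientation decoding with a half-cosine basis
   set, decoding-strength summaries, and their across-item correlation;
5. cross-temporal generalisation of coding schemes;
6. permutation and cluster-based group inference, and trial-wise
   neural-to-behaviour regressions.

## The design and its bookkeeping

`generate_design()` builds the trial table. Orientations live on the axial
half-circle (a grating at $\theta$ equals one at $\theta + 180$), so all
angular bookkeeping uses `wrap180()` and the axial distance
$d(a,b) = \min(|a-b|,\, 180-|a-b|) \in [0, 90]$. The rotation product is
`rotated_ori = wrap180(cued_ori + rotation)`.

One modelling choice deserves a note: the cued and uncued orientation of a
trial may coincide. Balancing is experiment-wide, which is exactly what
yields the 72 unique (cued, uncued, side) conditions at the first impulse —
a 72 x 72 RDM — and 60 (cued, rotation, side) conditions at the second. If
equal orientations were excluded within a trial, those cardinalities would
be impossible.

Probes match the task-relevant item on half the trials of every design
cell; non-matching probes are drawn uniformly from the five other
orientations (with four trials per cell, an exact within-cell balance of
probe identity across five alternatives is impossible; uniform sampling is
used). Session and block indices are assigned sequentially after shuffling;
they carry no analysis role.

## The LDC core

For a condition pair $(A, B)$, the cross-validated squared Mahalanobis
distance is the bilinear form

$$\mathrm{MD}^2 = (P_A - P_B)_{\mathrm{train}}\; \hat\Sigma^{+}\;
  (P_A - P_B)^\top_{\mathrm{test}},$$

with condition-mean patterns $P$ estimated separately in the training folds
and the held-out test fold. Because the two factors are independent, the
estimator is unbiased: under the null its expectation is zero and negative
values are legitimate. `compute_rdm()` repeats the 8-fold construction with
fresh random folds and fresh random subsampling (per-condition trial counts
are equalised within the training set and within the test fold separately)
and averages, which stabilises the estimate.

The noise covariance $\hat\Sigma$ is a Ledoit–Wolf shrinkage estimate
computed from the condition-mean-centred training trials: the sample
covariance is blended with a scaled identity target using the analytic
intensity of the well-conditioned estimator. Its pseudoinverse is taken by
eigendecomposition, zeroing eigenvalues below
$\lambda_{\max} \cdot p \cdot \epsilon_{\mathrm{machine}}$. These two
choices keep the metric defined even when features outnumber the trials of
a fold.

Numerical notes: z-scoring operates on the unique off-diagonal cells only
(the diagonal is identically zero); a constant vector z-scores to zeros
rather than erroring, so degenerate inputs propagate as "no evidence"
instead of failures; multiple regression keeps an intercept even though the
vectors are standardised.

The fold-wise kernels are compiled (RcppArmadillo) because the permutation
null re-runs the whole RDM construction hundreds of times per subject. A
pure-R reference implementation of the identical algorithm ships alongside
(`engine = "r"`) and the test suite proves the two agree to numerical
precision on shared folds, as well as against an independently coded
brute-force cross-validated Euclidean RDM when the covariance is forced to
identity.

## Hypothesis models and residualised fits

`model_rdm()` builds the design matrices: cue-side (0/1), parametric
circular coding of an item (axial distance between the item's orientations
in the two conditions), generalisation between two items (symmetrised cross
distance), and per-level rotation-instruction models. The rotation models
code *same versus different* instruction — cells whose two conditions share
the level are marked similar, all others dissimilar — with one model per
level and no assumed relationship between levels; their betas are averaged.
Location-specific model variants replace the unwanted half of the cells
(across-side or within-side) with the pre-replacement matrix mean, which
z-scores to zero — effectively down-weighting them.

After the rotation instruction the cued-item and rotated-item models are
structurally related (the rotated orientation is a deterministic function
of the cued one and the instruction, and 0-rotation trials make them
identical), so `fit_impulse2_models()` fits each on the residual of the
other: the cued model on the residual left by the rotated model; the
rotated model on the residual left by the cued model *and* the rotation
models (to which it is marginally related); the generalisation model on the
residual left by both items. When 0-rotation trials are excluded (48
conditions) the dependency disappears and direct fits are appropriate
(`residualise = FALSE`).

`split_half_regress_out()` is the sharper control for the same problem: the
contribution of one item model is *estimated on an independent half of the
trials* (4-fold CV within each half), scaled out of the other half's
z-scored RDM vector, and both models are then fit to the residual. If the
two items genuinely carry separate pattern information, removing the
estimated cued contribution leaves the rotated fit intact while the cued
residual fit averages to zero — and vice versa. The scaling used when
subtracting is beta times the z-scored model vector, the natural
regression-based choice. The test suite runs this control at 50 iterations
per subject; iteration counts beyond that changed group-level signs in no
run we observed, and the full-fidelity setting (1000) remains available.

## Trial-wise decoding and the strength correlation

`decode_item()` is an 8-fold Mahalanobis classifier over the six
orientations. Training class means are convolved with a half-cosine basis
raised to the 5th power, $w(\delta) = \cos(\delta)^5$ on the axial scale —
1 at zero offset, 0 at 90 degrees — pooling information across similar
orientations. The six distances of a test trial are summarised by the
sign-flipped, mean-centred cosine-weighted average

$$s = -\tfrac{1}{6}\sum_k \cos\!\big(2(\theta - c_k)\big)\,(d_k - \bar d),$$

so that positive $s$ means class means near the true orientation are
closer. The mean-centring makes $s$ invariant to any common shift of the
six distances (trial-wise noise level); non-squared distances are used, so
a noisy trial compresses the informative profile and lowers $|s|$ — this is
what makes the across-item strength correlation diagnostic: if both items
are coded in every trial, shared noise induces a *positive* correlation of
their strengths; if only one item is coded per trial, the correlation is
*negative*.

`cross_generalise()` trains on one impulse's patterns and tests on the
other's, with folds defined on shared trial ids so no trial is in training
and test simultaneously, run within each cue side and pooled. The spec-level
ambiguity of how folds straddle the two impulses is resolved exactly this
way and documented here.

## Inference

Group inference is permutation-based throughout. For model betas, the null
re-runs the analysis with shuffled per-trial condition labels: the RDM is
rebuilt per permutation (at a reduced repetition count, `null_reps = 1` by
default, purely for cost; the observed analysis keeps its own `n_reps`) and
the full residual workflow re-applied, giving per-subject null betas that
are converted to a null t distribution across subjects. p-values include
the observed statistic in the null count, so $p \ge 1/(n_{\mathrm{perm}}+1)$
and a zero-variance, all-zero statistic yields $p = 1$ by convention.

Time-courses use a cluster-based permutation test: mass-univariate t per
window centre, clusters formed at two-sided $p < 0.05$ under the t
distribution, scored by summed t, and compared against the permutation
distribution of the maximum absolute cluster score under per-subject sign
flips (the group-level exchangeability scheme for one-sample tests; the
sign of every subject's whole time-course is flipped jointly, preserving
autocorrelation). Gaussian smoothing of time-courses (SD 16 ms) truncates
and renormalises its kernel at the series edges, so constants pass through
unchanged.

`behaviour_regression()` residualises the two strength series on each other
per subject, then predicts accuracy (logistic) and log RT (linear) from
both residual series; group tests are one-sided in the direction of
facilitation (positive for accuracy, negative for log RT), with nulls from
trial shuffling. Subjects with degenerate logistic fits (separation or
constant accuracy) are excluded from the accuracy aggregate and reported.

## The generative simulator

`simulate_subject()` emulates a subject's impulse-2 feature patterns in a
20-dimensional feature space. A coding scheme is a pair of random
standard-normal patterns weighted by $\sin 2\theta$ and $\cos 2\theta$. The
angle doubling maps the axial orientation space onto the full circle: without
it, $\theta$ and $\theta + 180$ would be distinct, which is physically
meaningless for gratings, and the parametric circular-distance models would
not apply.

Six maintenance scenarios are implemented: only the rotation product coded;
a single half-rotated item; both items in one shared scheme (always, or one
per trial); both items in unique independent schemes (always, or one per
trial). "One per trial" uses an independent fair coin, the mixing proportion
being otherwise unspecified. Trial-wise noise is a fresh standard-normal
20-vector scaled by a scalar drawn from Normal(10, 3) each trial — the
scalar is used as drawn, without truncation — so trials differ in their
overall noise level, which is the mechanism probed by the strength
correlation. The item signal amplitude defaults to 1 (the natural scale of
the unit-normal schemes); it is exposed as a tunable because no other value
is dictated by the scenarios themselves. An optional rotation-condition
signal adds one unique random pattern per rotation level; the design has
five levels, so five patterns are used.

`run_scenario_battery()` analyses each simulated cohort exactly like real
post-rotation data — RDM, residualised model fits, strength correlation —
with one deliberate simplification: simulated patterns carry no cue-side
code ("cue-specific effects are not simulated"), so conditions collapse
over side (30 instead of 60). The battery's default settings (30 subjects,
10 RDM repetitions, 200 permutations, 10 decoding repetitions) are the
reduced-cost testing configuration; they reproduce the qualitative scenario
discrimination — full replacement, partial rotation / shared-scheme
equivalence, unique schemes with positive or negative strength correlation —
in a few minutes of CPU time, while the full-fidelity settings (100
repetitions, 1000+ permutations) remain plain arguments.

What the simulator does *not* emulate is worth stating: volume conduction
and channel covariance structure, temporal dynamics within the impulse
window, eye-movement or muscle artefacts, behavioural responses coupled to
the neural state, and cue-side-specific coding. Passing the battery
therefore shows that the *analysis chain* discriminates the maintenance
scenarios it was designed to discriminate — not that real EEG satisfies the
scenarios' assumptions.

`embed_in_epochs()` closes the loop for the feature-extraction stage: it
lays simulated patterns onto a channels-by-time carrier with per-trial
offsets and a drift ramp that plateaus over the extraction window, and the
test suite verifies that `extract_spatiotemporal()` recovers the pattern
exactly up to the per-channel window-mean projection.

## Feature extraction choices

The relative, within-window baseline (removing each trial's and channel's
mean over the analysis window) is what makes the first and second impulse
directly comparable: a pre-trial baseline would be temporally closer to one
than the other, so unremoved drift would penalise the later impulse.
Windows are half-open $[\mathrm{start}, \mathrm{end})$ on the output grid,
so 100–400 ms at 100 Hz gives exactly 30 time points and 17 channels
x 30 points = 510 features; sliding 100 ms windows give 170 features per
centre. Downsampling from the recording rate uses an anti-alias FIR filter
(zero-phase, with odd-reflection padding to keep transients out of the
window) followed by decimation; the residual window mean after filtering is
removed again so the zero-mean invariant holds exactly. Searchlight
neighbourhoods are each electrode plus its two nearest neighbours by
Euclidean distance in whatever montage coordinates are supplied, with
distance ties broken by channel label; an idealised flat layout of the 17
posterior channels is bundled for examples, and real analyses should pass
digitised positions.

## Problem sizes used in the shipped checks

The package's own validation (test suite and `scripts/acceptance.R`) runs
the battery at 30 subjects per scenario with the reduced-cost settings
above; the split-half control at 12 subjects x 50 iterations; the type-I
calibrations at 500 null simulations with 199 permutations each; and the
behaviour-effect recovery at 100 subjects x 576 rotation trials with a
planted log-RT slope of -1 per unit decoding strength (strengths simulated
at the empirically typical scale, mean 0.04, SD 0.05, log-RT noise SD
0.25). These sizes were chosen as the smallest at which the qualitative
contrasts of interest are unambiguous; all of them are function arguments,
not constants.

## Known limitations

* The orientation decoder is a 6-class read-out with basis smoothing, not a
  continuous tuning-curve inversion; `strength_from_distances` is its only
  summary.
* Bayes factors reported alongside p-values in some analyses of this
  paradigm are out of scope; inference here is permutation-based only.
* Raw EEG preprocessing (referencing, filtering, artifact rejection) is
  assumed done upstream; `epochs()` expects clean epoched data.
* The split-half control's subtraction scale (beta times the z-scored
  model) is one defensible reading of "regressing out" an independently
  estimated fit; alternatives (e.g. unstandardised scaling) would change
  betas by a constant factor but not their zero/non-zero pattern.
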