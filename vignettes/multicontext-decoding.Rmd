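---
title: "Conjunctional cross-context decoding for multi-context visuomotor adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conjunctional cross-context decoding for multi-context visuomotor adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmadapt)
```

`vmadapt` implements, end to end, the analysis of a multi-context
visuomotor-adaptation fMRI experiment: a carryover-balanced erasing task
performed under three cursor transformations, first-level beta-series
estimation, conjunctional cross-context searchlight decoding of visual,
movement and task-context representations, TFCE permutation inference, and
the correlation between context-decoding accuracy and behavioral
performance. Because the interesting statistical machinery is the decoding
and inference layer, the package also contains a synthetic-data generator
that emulates the study design closely enough that every stage can be
exercised, calibrated and validated without scanner data. This vignette is
the package's own account of the model and of the design decisions that
were genuinely open.

## The task

Each session has 15 blocks: three adaptation contexts (rotation by -90
degrees, rotation by +90 degrees, and a horizontal mirror reversal), each
repeated five times in a randomized order. In screen coordinates with x
rightward and y downward (a left-handed frame, so "up" is (0, -1)), the
hand-to-cursor transformation matrices are

$$
T_{rot-90} = \begin{pmatrix} 0 & 1 \\ -1 & 0 \end{pmatrix},\quad
T_{rot+90} = \begin{pmatrix} 0 & -1 \\ 1 & 0 \end{pmatrix},\quad
T_{mirror} = \begin{pmatrix} -1 & 0 \\ 0 & 1 \end{pmatrix}.
$$

Only this coordinate convention reproduces the task's stated
correspondences (under the -90 degree rotation, an upward line requires a
rightward hand movement; under +90, a leftward one; the mirror leaves
vertical motion untouched), and the package fixes it once in
`direction_labels()` and `context_transforms()`. `required_movement()` is
the inverse map, `visual_of_movement()` the forward one, and a round-trip
identity over all twelve context-direction combinations is asserted in the
tests.

A block contains 17 erasing trials over four line directions, ordered as a
type 1 index 1 continuous-carryover sequence: among the 16 transitions,
every ordered pair of directions — self-pairs included — occurs exactly
once, so each direction precedes and follows every direction equally often
and first-order carryover effects cancel out of the decoding features. For
four conditions the generator permutes the labels of the task's fixed
17-element order template (`carryover_template()`); for
other condition counts it draws a random Eulerian circuit of the complete
digraph with self-loops, which has the same balance property
(`generate_carryover_sequence()`).

Timing defaults (`timing_params()`): 3.5 s trial window, 6 s ITI, 8 s
preparation stimulus, 4 s score display, TR 2.3 s. The preparation period
is placed strictly before the first trial — whether it overlaps the first
ITI is not specified by the design, and this is the simpler reading. A
short termination instruction (1.5 s) closes each block; its duration is
not specified either and is exposed as a parameter.

## Behavioral simulation and the performance metric

Trials erase a line of seven 16-px dots (112 px) with a 12-px circular
cursor. A dot disappears when the cursor center is strictly inside its
square and all earlier dots are gone. Dot centers are placed collinearly
at 16-px spacing starting 16 px from the cursor start — the dot size and
count are given, the spacing is not, and a contiguous line is the only
arrangement consistent with a "line" whose one-and-a-half length equals
the 168-px outlier threshold. Performance is the erasing speed, dots
erased per trial duration. For completed trials the duration is the time
of the last erasure; for incomplete ones it is the full 3.5-s window. The
formula leaves "trial duration" ambiguous for completed trials; this
choice makes fast completions score above 2 dots/s, which is what the
metric needs to work as a proficiency measure. A trial whose cursor path
exceeds 168 px (strictly, reading "further than" as strict) is flagged as
an outlier; outliers are excluded from GLM task regressors and modeled as
separate columns, but are kept in behavioral summaries by default
(exclusion there is flag-controlled, since the design does not say).

The mover policy progresses along the required direction at a constant
rate with a sinusoidal perpendicular wiggle of amplitude under half a dot
(so no dot is missed); exploratory trials (probability 0.04) use a large,
fast wiggle that doubles or triples the path length without changing
progress, which is how the generator produces outlier trials whose speed
distribution matches ordinary ones. Per-trial progress rates are lognormal
around a subject-level target; the deterministic map from progress rate to
erasing speed is tabulated and inverted so that a subject's expected
erasing speed equals the target. Cohort defaults are targets of 1.7 dots/s
(rotation contexts) and 2.4 dots/s (mirror) with 0.22 dots/s
between-subject spread — the group means the task is known to produce,
with a spread chosen so that the implied absolute rotation-mirror gap
(the behavioral confound) is realistic (about 0.7 dots/s). For large
cohort replicates, `simulate_subject_behavior_fast()` draws the same
outcome distribution from the speed map directly, skipping the trial
mechanics; the full simulator remains the reference and the two are
compared in the tests.

## Synthetic neural data

The generator works on a common 3-mm grid (default 24 x 24 x 18 with an
ellipsoidal mask, about 5400 voxels) chosen so that a whole-"brain"
searchlight with group permutation inference runs on a desk machine; the
grid is configuration, not a constant. Four disjoint cubic regions carry,
respectively, visual-direction patterns, movement-direction patterns,
task-context patterns, and nothing (the null region used for chance-level
checks). Per subject, each direction or context has a Gaussian voxel
pattern; a beta volume for block $b$ and direction $d$ in context $c$ is

$$
\beta_{b,d} = a_v P^{vis}_d \cdot 1_{vis} + a_m P^{mov}_{m(c,d)} \cdot
1_{mov} + a_c P^{ctx}_c \cdot 1_{ctx} + \varepsilon,\qquad
\varepsilon \sim N(0, \sigma^2),
$$

with $m(c,d)$ the required movement. Preparation betas carry a separate
per-context pattern in the context region.

Context-representation commonality is the correlation $\rho$ between
context patterns, constructed by Gaussian mixing
($P_2 = \rho P_1 + \sqrt{1-\rho^2}\,W$), which achieves the population
correlation exactly. The two rotation patterns are correlated at
$\rho_{rot} = \mathrm{link}(\text{rotation performance})$; the mirror
pattern is correlated with the normalized rotation-family mean at
$\rho_{mir} = \mathrm{link}(\text{mirror performance})$. The default link
is affine and clipped, $\rho = \mathrm{clip}(-0.98 + 0.9\,s, 0, 0.95)$ —
increasing, so better performers have more similar context patterns, the
hypothesis under study; transparent, so the planted correlation between
performance and $\rho$ is recoverable by construction. Over the default
performance spread this maps subjects to roughly $\rho \in [0.3, 0.9]$.

Amplitudes default to 0.35 with unit voxel noise. This is a calibration,
made once: with 9-mm spheres (123 voxels) it puts single-subject decoding
accuracy in the informative mid-range — own-level analyses around 70-80%
rather than at ceiling — so that accuracy still varies with $\rho$ across
the plausible range and the accuracy-performance slope is detectable in
cohorts of about a dozen subjects (`slope_recovery_experiment()` measures
exactly this). At ceiling the slope would vanish; much lower, nothing
would be detectable at desk-scale cohorts.

Betas can be generated directly (the fast path used by most experiments)
or by simulating a full BOLD series — the first-level design matrix
applied to the planted betas plus AR(1) noise, random-walk motion
parameters and optional FD or global-signal spikes — and refitting the
GLM. Both paths must agree: the noiseless round trip is exact to solver
tolerance and noisy recovery is unbiased, which the acceptance suite
asserts.

## First-level GLM

Two design-matrix variants (`build_design_matrix()`). The mass-univariate
variant has one HRF-convolved box-car per context over its non-outlier
trials. The MVPA variant has, per block, one regressor per erasing
direction (trials 2-17, non-outlier), a null regressor for the first trial
(whose preceding context differs from everything else in the block), and
per-block preparation, score and termination regressors; the beta series
of the direction regressors is the decoding feature store, and the
preparation betas feed the preparation-period analyses. Both variants add
one regressor per outlier trial (if the first trial is an outlier it is
modeled once, as an outlier), six motion parameters with their
backward-difference gradients, one spike regressor per flagged scan, a
discrete-cosine drift basis up to 1/128 Hz, and an intercept. The HRF is
the canonical double-gamma (peak 6 s, undershoot 16 s, ratio 6, length
32 s) — the conventional default, since only "the hemodynamic response
function" is specified — with parameters exposed. High-pass filtering is
implemented as DCT regressors inside the GLM rather than pre-filtering;
under OLS the two are equivalent and the regressor form is directly
testable. No pre-whitening is applied; with AR(1) noise the OLS betas
remain unbiased (variance estimates are mildly optimistic, which matters
for single-subject inference but not for the group permutation tests used
here). Outlier scans are those with framewise displacement above 0.9 mm —
the sum of absolute backward differences of the six realignment
parameters, rotations converted on a 50-mm sphere, the common convention
where the source toolbox gives none — or global-signal excursions beyond
5 SD.

## Conjunctional decoding

Cross-classification restricts generalization to one representation
level. For visual (or movement) decoding, the classifier trains on one
direction axis in one context and tests on the same axis in another
context, so the paired other-level directions differ per label and the
contexts differ; there are 6 such unordered context-axis combinations.
For context decoding, training cells are matched on one level and test
cells on the other: for each of the 4 visual-matched training sets exactly
2 movement-matched test sets share no condition cell, giving 8 set pairs
for the rotation pair and 16 for the two rotation-mirror pairings.

The published totals count these differently — 12 for the direction-level
analyses but 8 and 16 for the context analyses — and no single
ordered/unordered convention yields all three. The resolution implemented
here: every unordered pair is evaluated in both train/test directions and
the two accuracies averaged (any training set can serve as a test set);
the direction-level totals count the 12 ordered units while the context
totals count the 8/16 unordered pairs. Arithmetically the two conventions
give identical averaged accuracies for the direction-level analyses, so
the choice affects bookkeeping, not results; `enumerate_pairs()` exposes a
`dedup` flag so either convention can be produced and audited.

Context analyses subdivide each pair with leave-two-block-out
cross-validation: fold $k$ tests on the $k$-th repetition block of each
class and trains on the rest, guarding against within-block temporal
similarity. The correlation-analysis variant skips this subdivision
(`use_folds = FALSE`) to maximize between-subject accuracy variance.
Preparation-period decoding uses the five preparation betas per context
with the analogous leave-two-out scheme: 5 folds for the rotation pair, 10
(two schemes of five) for rotation versus mirror.

The classifier is a soft-margin linear SVM with C = 1 on per-sphere
train-mean-centered features. It is implemented as dual coordinate
descent in Gram form (deterministic fixed sweep order, tolerance 1e-3,
at most 200 passes), which makes the roughly million single-sphere fits
of a cohort run in seconds; the hyperplane agrees with the libsvm
reference implementation to high cosine similarity, and test predictions
agree exactly on separated data — asserted in the tests, where libsvm is
the independent oracle. Whether the original toolbox scaled features is
unknown; centering without scaling is the default and both are
configuration. Searchlight spheres take all in-mask voxels within 9 mm of
the center voxel (center-to-center, inclusive; 123 voxels in the
interior at 3-mm voxels). Betas are smoothed at 2 mm before decoding and
accuracy maps at 8 mm before group statistics, matching the two-kernel
preprocessing scheme. Per sphere, accuracies are averaged over pairs and
folds and 50% chance is subtracted, giving accuracy-minus-chance maps
in [-50, +50] percentage points.

One structural property deserves emphasis: a *confound* direction-level
signal does not push the other direction-level analysis above chance, but
it can push it below. Between the two rotations, a visual axis maps to
the same movement axis with opposite polarity, so a classifier that
learned movement patterns anti-generalizes (accuracy near 0%) on those
pairs while rotation-mirror pairs sit at chance. This is intrinsic to
cross-classification between two opposite rotations, not a generator
artifact. The one-sided group inference used throughout is blind to
below-chance values, so conjunctional specificity — no spurious
*detection* — holds exactly; `specificity_experiment()` measures both the
below-chance dip in the planted region and the absence of above-chance
detections anywhere.

## Group inference

Group maps are tested voxelwise with OLS GLMs: a one-sample (intercept)
test for accuracy above chance, with the absolute rotation-mirror
performance gap as an *uncentered* confound where the analysis calls for
it (the intercept is then the confound-adjusted group mean at confound
zero, which is the construction the confounded one-sample test uses); or
a covariate test for the accuracy-performance slope, one-sided in the
negative direction. TFCE integrates cluster support over thresholds,
$\mathrm{tfce}(v) = \sum_h e_v(h)^{E} h^{H}\, dh$ with the published
defaults E = 0.5, H = 2, 26-connectivity, and dh = (observed max)/100.
The step height is fixed from the observed map and shared by every
permutation — letting each permuted map choose its own step breaks
comparability of the enhanced values and measurably inflates the FWE,
which the calibration experiment exposed. Family-wise error is controlled
by the maximum-statistic permutation distribution, 5000 permutations at
study scale: sign-flipping of reduced-model residuals for intercept
tests, Freedman-Lane residual permutation for covariate tests (the
scheme for covariate tests is not specified at the source; Freedman-Lane
is the standard choice with nuisance regressors), with
$p_{FWE}(v) = (1 + \#\{\max_j \ge \mathrm{obs}(v)\})/(1 + n_{perm})$.
Weak control uses Benjamini-Hochberg over voxelwise parametric one-sided
t p-values (the engine retains only the max-statistic null). ROI tests
average each subject's map over the mask and run the same GLM with a
parametric one-sided p. Mass-univariate group maps reuse this permutation
machinery; analytic random-field-theory correction is a deliberate
substitution and out of scope.

## Validation experiments and problem sizes

Three experiment drivers double as the acceptance surface.
`specificity_experiment()` (8 subjects, 24 x 24 x 18 grid, 500
permutations, about three minutes) plants one level at a time and checks
the detection diagonal. `slope_recovery_experiment()` (12-subject
cohorts on a 16 x 16 x 12 grid, ROI decoding of the context region
without folds, permutation slope test with 199 shuffles) runs 20
increasing-link replicates for sign recovery and 200 flat-link replicates
for type-I calibration. `fwe_calibration_experiment()` (150 exchangeable
null replicates, 10 subjects, 12 x 12 x 10 grid, 500 permutations)
estimates the attained FWE. These sizes are the package's chosen
desk-scale study conditions; the full-scale constants (22 subjects, 5000
permutations) remain the defaults where they are cheap (pair counts,
folds, thresholds) and configuration elsewhere.

What passing shows — and what it does not: the synthetic cohorts have
Gaussian, spatially unstructured noise, box-shaped regions, exact
pattern reuse across blocks, and a noiseless link between behavior and
commonality apart from sampling error. Real data add spatial noise
correlation, anatomy, session drift in representations, and registration
error; passing here validates the pipeline's logic, bookkeeping and
statistical calibration, not the empirical effect sizes of any real
cohort.

## Known limitations

Only linear decoding is implemented (nonlinear classifiers are explicitly
out of scope); the behavioral model has no within-session learning
dynamics (performance level is a cohort parameter); the BOLD model's
noise is AR(1) plus spikes, without physiological structure; and the
voxelwise FDR is parametric rather than permutation-based, since the
permutation engine keeps only the max-statistic null.
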