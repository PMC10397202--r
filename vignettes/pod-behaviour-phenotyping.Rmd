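---
title: "Multi-scale phenotyping of delirium-like behaviour: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale phenotyping of delirium-like behaviour: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(podspace)
```

Postoperative delirium (POD) in mouse models is behaviourally heterogeneous:
animals that underwent the same anaesthesia and surgery split into affected
and unaffected subsets, and the affected ones into hyperactive and
hypoactive psychomotor subtypes. Classical single-number read-outs (centre
time, a recognition index) blur these distinctions. This package analyses
behaviour at three time scales instead — pose (frame-level kinematics),
behaviour (fractions of 40 discrete movement modules) and action sequence
(object-investigation bouts) — and builds its diagnosis in a low-dimensional
"delirium-like behaviour space". This vignette records the models, the
tunable parameters, and the reasoning behind the choices that were genuinely
open.

## Inputs and their assumptions

The package consumes 3-D skeleton trajectories (`T x 16 x 3` mm coordinates
at 30 frames/s, 16 canonical keypoints from nose to tail tip) and per-frame
movement labels over a 40-class vocabulary. Both come from upstream tools
(markerless tracking + movement segmentation) that are out of scope here.
Two assumptions follow:

* **No imputation.** Validation rejects non-finite coordinates rather than
  filling them; dropped-tracking policy belongs upstream, and silent
  interpolation would bias the speed features.
* **Units are mm and frames.** Speeds are reported per frame
  (mm/frame); `per_second()` converts for reporting. All geometric
  thresholds below are in mm.

## Pose features and their summaries

Thirteen per-frame features are computed (`compute_pose_features()`). The
enumerated descriptor list yields eleven names once "height" is split into
neck and back height; the full configuration adds whole-body centroid speed
(`body_speed`) as the thirteenth. The feature list is a configuration
option (`pose_feature_set()`): the full set gives a
13 x 7 = 91-dimensional summary vector, the reduced 11-feature set
(single height, no centroid speed) gives 77. Both dimensionalities are used
in practice — fraction-of-variance arguments do not favour one, so the
package exposes both rather than guessing.

Each feature series is histogrammed into a 50-bin PMF spanning its observed
range (a constant series gets a symmetrically widened range so exactly one
bin is occupied — degenerate input, not an error). Seven descriptor
statistics per curve, in fixed order (mean, median, SD, q25, q75, min,
max), form the summary ("eigenvalue") vector.

Two readings of "statistics of the PMF curve" exist, and the package
implements both (`summarize_pmf(on =)`):

* `"probabilities"` (default): the statistics of the 50 probabilities
  treated as a discrete signal. Note the mean is then 1/50 by construction
  and the minimum is almost always 0; these columns carry no information.
* `"values"`: the same statistics of the underlying feature distribution
  (bin midpoints weighted by probability).

The probability-level reading is retained as the default summary, but the
**subtype workflow uses `on = "values"`**: because each animal's PMF spans
its own min–max range, the probability vector is nearly invariant to the
location and scale of the distribution — and location/scale (faster nose,
higher back) is precisely the signal separating hyperactive from hypoactive
animals. Simulations with a 2x speed-scale contrast confirm the
distribution-level summaries separate the subtypes cleanly while the
probability-level ones need not.

## The resampling KS test

Group PMF curves are compared by drawing `n_resample = 500` values from
each curve's implied distribution (inverse-CDF sampling, uniform placement
within a bin — this also makes ties measure-zero) and taking the maximum
absolute difference of the two empirical distribution functions over the
pooled sample. The seed convention is deliberate: a scalar seed seeds both
draws identically, so a curve compared against itself gives exactly D = 0;
a length-2 seed gives independent draws for calibration and power studies.

The rejection threshold is the standard two-sample asymptotic critical
value `c(alpha) * sqrt((n1+n2)/(n1*n2))` with
`c(alpha) = sqrt(-log(alpha/2)/2)`. A one-sample table lookup at the pooled
sample size is available as `critical = "pooled-table"` for compatibility
with analyses that used that convention; it is anticonservative for the
two-sample problem, which is why it is not the default.

## Investigation bouts and the DSP

A frame is investigating if either geometric rule holds: **approach**
(2-D nose-to-object-centre distance < 60 mm and the neck-to-nose direction
within an acute angle of the neck-to-object direction) or **climb**
(nose < 30 mm and back z above the object's top — no orientation
condition). The acute-angle threshold is exposed (`max_angle`) because a
stricter cone is a defensible alternative reading; the literal acute angle
is the default. Distance is measured to the object centre; the footprint
radius is available on the object spec for a surface-distance correction.

Frames define the rules; bouts are a package construct: investigating runs
separated by fewer than 5 frames (~167 ms at 30 fps) merge, which stops
tracking flicker from inflating bout counts. A bout is **deep** when
climb-triggered or when any of its frames carries a movement label from the
configured deep-interaction classes (sniff/touch/crab); otherwise shallow.
The preference statistic `DSP = asin((T_deep − T_shallow)/(T_deep +
T_shallow))` lives in [−π/2, π/2]; its arcsine form stretches resolution
near exclusive preference.

## Behaviour-level statistics

Movement selection runs a Welch two-sample t test per movement with Sidak
adjustment over the whole 40-class family (`1 − (1 − p)^40`). This
reproduces the post-hoc contrasts of the conventional two-way ANOVA + Sidak
analysis for a single comparison, without re-implementing the omnibus step
that contributes nothing to selection. Centre time uses the back keypoint
as the animal's reference point (the most stable torso point). Its zone
radius defaults to 50 mm for open-field behaviour and 100 mm when feeding
the composite Z — both conventions are in active use, so each entry point
defaults to its own. The recognition index is the difference-over-sum form;
the novel-time share is provided separately (`novel_ratio()`) since both
conventions circulate. The composite Z is the literal sum of the three
control-standardised scores; no sign flip is applied to centre time because
the direction of a "delirium-like" change there is not settled.

## Diagnosis, embedding and the severity axis

`diagnose_pod()` z-scores each movement across all model + control samples,
cuts a Ward (Euclidean) dendrogram into two clusters, and calls the cluster
holding more control animals the non-delirium side. A plain 2-cut, however,
always splits — a model cohort statistically identical to controls would be
divided arbitrarily and half of it labelled POD. POD labels are therefore
only issued when cluster membership is associated with group membership
(Fisher exact test, alpha 0.05). Under the null the gate almost always
holds everything at nonPOD; under a real effect the association is
overwhelming and the gate is invisible.

The discriminative fractions are embedded in 3-D by an exact t-SNE written
for this package's sample sizes (tens of animals): full pairwise
affinities, per-point precisions calibrated to the target perplexity by
binary search, KL gradient descent with early exaggeration. The
"neighbourhood parameter 6" maps onto perplexity, the closest faithful
reading for a t-SNE. Two determinism measures are worth noting:

* rows are optimised in a canonical (lexicographic) order and restored
  afterwards, making the embedding an exactly permutation-equivariant
  function of the data;
* initialisation is the first three principal components (signs anchored on
  the feature-space loadings) scaled to SD 1e-4, so a given matrix always
  embeds identically — no random restarts;
* the final coordinates are rotated to their own principal axes with
  third-moment sign anchors, since the KL objective is rotation-invariant
  and the raw optimiser orientation is arbitrary.

A linear SVM (unit cost, no rescaling) separates POD from nonPOD in the
embedded space; `project_onto_boundary()` reports the signed Euclidean
distance from the plane, oriented POD-positive, and also exposes the raw
decision values for analyses that used unnormalised scores. Treated animals
are placed into the fitted space post hoc by affinity-weighted nearest
neighbours in the fraction space (`predict.pod_space()`), because t-SNE has
no parametric out-of-sample map; a joint refit including the treated
animals is the alternative and can be had by calling `pod_space()` on the
pooled data.

## Subtypes and treatment evaluation

`cluster_subtypes()` standardises the summary matrix (zero-variance columns
dropped — the probability-level mean and min columns are constants),
embeds to 3-D with the same machinery, and runs seeded k-means (20
restarts). Hyper/Hypo naming depends only on the speed-feature block means,
never on cluster indices, so relabelling cannot flip the semantics.

`train_classifier()` is ridge-penalised logistic regression; "30
iterations" of the original toolbox workflow is interpreted as 30 candidate
regularisation strengths (log-spaced over 10^1..10^-5) evaluated by
stratified 5-fold CV, with the best-so-far error sequence kept as the
minimum-classification-error curve. Ridge rather than an unpenalised fit
because separable 14-dimensional fraction data at n of tens otherwise gives
divergent coefficients; the lambda grid's upper end behaves like a
majority-class baseline, so a permuted-label control lands at chance error
as it should.

## The synthetic generator: what it emulates, what it does not

The generator exists so that every stage has ground truth. Its defaults are
the study conditions of the analyses:

| parameter | default | rationale |
|---|---|---|
| session length | 18,000 frames | 10 min at 30 fps |
| baseline class fraction | 1/40 | uninformative baseline over the vocabulary |
| mean bout length | 9 frames | sub-second movement modules (~0.3 s) |
| between-animal fraction SD | 0.004 | keeps all 40 fractions positive after a 3-SD shift |
| POD effect | 3 SD on 14 designated classes | 8 classes up, 6 down, mass-balanced |
| Hyper / Hypo speed scale | 4 / 2 mm/frame | 2x contrast, ~120 vs 60 mm/s |
| Hyper / Hypo height scale | 28 / 22 mm | elevated vs hunched carriage |
| turn rate | 0.15 rad/frame | bounded angular velocity; caps nose swing at a 55 mm lever arm |
| keypoint noise | 1 mm isotropic | tracking jitter |

Labels come from a semi-Markov scheme (bout classes drawn from the expected
fractions, geometric durations): it reproduces fraction structure and
bout-level autocorrelation but **not** real transition dynamics between
specific movements, which the analyses here never consume. The skeleton is
a rigid body plan rotated by a smoothed heading around an
Ornstein–Uhlenbeck centroid walk reflected at the walls: realistic in
speed/height distributions, deliberately unrealistic as gait (no limb
phases, no grooming posture changes). Scheduled investigation sessions are
geometric constructions — during a bout the nose is placed in the approach
zone facing the object (deep bouts get climbing frames), outside bouts the
animal faces away whenever it strays near an object, so detection recovers
the schedule exactly. Passing tests therefore demonstrate that the
*analysis code* implements its definitions and recovers planted structure
at realistic noise levels; they do not validate the upstream segmentation,
nor calibrate thresholds against real mice.

Problem sizes used by the test-suite simulations: diagnosis recovery runs
100 cohorts of 20 + 20 animals; subtype recovery 50 cohorts of 10 + 10
animals at 2,500 frames each (pose PMFs are stable well before that);
KS calibration 1,000 null repetitions; treatment evaluation a 50-animal
half-POD mixture. These sizes were chosen as the smallest at which the
binomial/clustering error bounds quoted in the tests are meaningful.

## Numerical choices and degenerate inputs

* PMF of a constant series: widened range, single occupied bin (no error).
* `dsp()` and `recognition_index()` are undefined at 0/0 and error rather
  than return 0: "never investigated" is not "no preference".
* KS draws: `n_resample >= 2` enforced; within-bin uniform placement makes
  the brute-force EDF oracle and the implementation agree exactly despite
  the discrete curve.
* Embedding requires `n - 1 > perplexity` and at least 4 samples.
* `diagnose_pod()` errors on an all-identical sample matrix (no clustering
  is meaningful); zero-variance movement columns are dropped before
  z-scoring.
* All generators and fits are pure functions of (parameters, seed); the
  pipeline (`run_pipeline()`) derives every stage seed from one master
  seed, so a rerun reproduces labels, projections and incidence exactly.

## Known limitations

* The synthetic kinematics cannot probe features that depend on limb
  coordination (the claw speeds inherit the body plan's rigid motion), so
  between-feature correlations are more rigid than in real animals.
* The Fisher gate in `diagnose_pod()` trades a small loss of sensitivity at
  marginal effect sizes for stability under the null; cohorts with a
  genuine but tiny affected subset (< ~3 animals) may come out all nonPOD.
* Out-of-sample placement in the behaviour space is a nearest-neighbour
  approximation; treated animals far outside the training cloud project
  unreliably (their incidence labelling runs on the logistic classifier,
  not on the embedding, for exactly this reason).
* The per-movement Sidak correction assumes independent contrasts;
  fractions are compositional (they sum to 1), so the correction is mildly
  conservative.
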