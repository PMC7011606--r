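---
title: "Methods: multi-view action classification and the interaction MDP"
author: "crilearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-view action classification and the interaction MDP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crilearn)
```

# The setting

`crilearn` implements the computational core of a smart rehabilitation
environment in which very young children with mobility challenges play with
small socially assistive robots while a rig of five synchronized cameras
(15 fps) observes the scene. Two problems are addressed:

1. **What is the child doing?** Classify a trimmed action instance —
   simultaneously observed by up to five cameras — into one of four
   gross-motor classes: crawling, sitting, standing, walking.
2. **What should the robot do?** Choose robot maneuvers (approach, hold,
   retreat) that keep the child engaged and moving, learned per child from
   very few observed interactions.

Real recordings of children cannot be redistributed, so the package ships
seeded synthetic generators (a multi-view scene renderer, a feature-space
bag sampler, and a ground-truth child simulator) that make every stage
testable end to end. This vignette documents the models, the parameters
that matter, the numerical choices, and what the synthetic experiments do
and do not establish about real data.

# Video representation

## Dense trajectories

`extract_trajectories()` tracks densely seeded points for `L = 15`
consecutive frames — one second at 15 fps. Points are (re-)seeded each
frame on a 5-pixel grid wherever no active track is nearby, but only where
the local gradient structure tensor has minimum eigenvalue at least
`min_eigen = 0.05`: homogeneous areas cannot be tracked and would otherwise
inherit motion from the median filter. Points are advected by iterative
(three-step Newton-refined) Lucas–Kanade flow estimated in a 9×9 window,
then median-filtered component-wise over all tracked points within twice
the seeding stride, which suppresses isolated bad matches. Tracks whose
total displacement over the window is below `min_displacement = 1` pixel
are static and discarded; a perfectly static clip therefore yields no
trajectories at all, by design. Camera-motion compensation is omitted: the
camera rig is static, so all image motion is scene motion.

## Descriptors

`compute_descriptors()` attaches a 220-dimensional vector to each
trajectory:

* **shape** (28 dims): the 14 frame-to-frame displacements, L1-normalized
  by the total displacement magnitude. A blob translating 1 px/frame
  rightward gives exactly `(1/14, 0)` repeated 14 times — this closed form
  is a test oracle.
* **motion** (96 dims): magnitude-weighted orientation histograms (8 bins)
  of dense one-shot Lucas–Kanade flow over a spatio-temporal tube that
  follows the trajectory: a 12×12-pixel cross-section split into 2×2
  spatial cells and 3 temporal segments.
* **appearance** (96 dims): gradient-orientation histograms over the same
  tube. Gradients are invariant to additive brightness shifts, and a
  zero-contrast tube yields an exactly zero appearance block.

Tube patches extending past the image are clamped to the border rather than
erroring. The motion and appearance blocks are each L1-normalized.

## Fisher-vector encoding

`fit_codebook()` fits the "dictionary": descriptors from *training videos
only* are PCA-projected to half their dimension and modeled by a
diagonal-covariance Gaussian mixture with `K = 64` components by default
(EM via mclust, model `VVI`, hierarchical initialization on a seeded subset
of at most 2000 descriptors; a k-means-derived mixture is the fallback for
degenerate samples on which EM fails). Variances are floored at `1e-6`.
`encode_fisher()` then embeds a video's descriptor set as the concatenated
first- and second-order deviations from the mixture, soft-assigned by
posterior responsibility and **averaged** over descriptors — which makes
the embedding invariant to duplicating the set — followed by signed square
root and L2 normalization. The embedding length is `2 K d'`. An empty
descriptor set (a fully occluded or fully static view) encodes to a zero
vector flagged `empty`; downstream classification tolerates such views
rather than failing, because an uninformative camera is an expected
condition, not an error.

# Classifying a five-view action instance

Each action instance is a *bag* of per-view embeddings with a single label.
Both classifiers share the same base learner: a linear C-SVM (`C = 1`,
libsvm via e1071, no feature scaling) trained one-vs-rest, reduced to an
explicit weight vector per class, with the decision-score sign calibrated
on the training data.

**SVM-MV (majority voting).** Training transfers the bag's label to every
one of its views and fits the SVM on the unrolled views. Label transfer is
deliberately noisy — an occluded view is trained with a label its pixels
never showed. At prediction, each view votes and the modal label wins; vote
ties (possible with 5 votes over 4 classes) break by the larger summed
decision score among the tied classes, then by the fixed class order
`crawling < sitting < standing < walking`.

**MI-SVM (multiple-instance).** One-vs-rest witness alternation per class:
initialization is exactly label transfer (all views of positive bags
positive); each round selects, per positive bag, the view with the highest
current decision score (the *witness*) and refits on witnesses versus all
views of negative bags, stopping when the witness assignment is stable or
after `max_alternations = 20` rounds (then the model is returned flagged
non-converged). The regularized hinge objective over (witnesses, negatives)
is recorded per round and is non-increasing from the first witness
selection on; round 0 trains on a different instance set (all positive
views) and is not comparable. Prediction takes the maximum view score per
class and the argmax class — no voting; a single clear view suffices,
which is why the approach is robust to occluded views.

**Evaluation protocol.** `make_splits()` draws stratified random splits
with a per-class *ceiling* at `train_frac = 0.8`: ceiling is the rounding
under which class counts of 166/228/406/248 instances produce exactly
840 training and 208 testing instances per split (4200/1040 videos at five
views each), which is how the package's defaults reproduce the reference
protocol's totals. `evaluate()` reports per-split accuracy (percent of
correctly classified instances), the mean over splits, and row-normalized
confusion matrices whose rows sum to 100.

Two open protocol details were resolved as follows: the codebook is refit
per split on training descriptors only (leakage-safe), and no class-balance
weighting is applied to the SVMs.

# The interaction MDP

Child–robot interaction during a chasing game is a four-state,
three-action MDP. States are the child's engagement modes — `NL` (not
looking), `L` (looking, not following), `TA` (touching the robot or
aroused/excited), `M` (moving/following) — and actions are the robot's
maneuvers `f` (approach), `s` (stay/turn in place), `b` (retreat facing the
child). Reaching `TA` or `M` is success, so the default state utilities are
`u = (0, 0, 1, 2)`.

## Learning transitions from sparse data

The sufficient statistic is the count tensor `N[s, a, s']`, updated online
one observed child response at a time (`update_counts()`,
`count_episode()`). Two estimators:

* **Maximum likelihood**: `P[s,a,·] = N[s,a,·] / Σ N[s,a,·]`. Rows with no
  observations are *undefined* (`NA`), deliberately distinct from uniform,
  and observed rows give exact zeros to unobserved next states. Planning on
  an ML estimate with undefined rows is refused with a pointer to
  smoothing: an event not yet observed is not necessarily impossible, and
  the package forces that choice to be explicit rather than silent.
* **Additive smoothing**: `P[s,a,k] = (N[s,a,k] + λ) / (Σ N[s,a,·] + 4λ)`
  with `λ = 1` by default. Add-λ was chosen among smoothing schemes for its
  transparency and closed form; `λ` is configurable to study the
  sparse-data regime, and the estimate converges to ML as `λ → 0`.

## Planning and scoring

`value_iteration()` solves the discounted problem with reward `u(s')`
collected on entering a state (utilities attach to states, so the reward is
earned when the child arrives in one), default `γ = 0.95`, sup-norm
tolerance `1e-8`. Because the space is tiny (3⁴ = 81 deterministic
stationary policies), `enumerate_policies()` evaluates every policy exactly
by solving `(I − γ P_π) V = P_π u` and serves as a brute-force optimality
oracle in the tests.

The baseline **regular policy** encodes the human operator's heuristic:
approach a child that is not engaging (`NL, L → f`), hold when the child is
touching/aroused (`TA → s`), retreat when the child gives chase (`M → b`).
The state-action table is an interpretation of that narrative strategy —
no published mapping exists — and is flagged as such in the documentation.

Sessions are scored by `accumulate_utility()`: the summed utility of
recorded state entries divided by the session duration (utility per
second). `policy_change_score()` is the absolute difference of this rate
between a child's first and last sessions — the quantity used to ask
whether switching the robot from the regular to the computed optimal policy
changed outcomes more than re-measurement under an unchanged policy.
Whether "accumulated utility" should count every annotated time step or
only state changes is a logging convention; here an episode record *is* a
state entry, and the convention is documented in the episode CSV schema.

# Synthetic generators: what they emulate, and what they do not

**Scene renderer** (`render_session()`). 2-D orthographic grayscale frames
(64×48 default) with per-view horizontal parallax; no 3-D camera model,
because the feature pipeline only needs per-view appearance and motion.
The child agent is a textured soft-edged blob whose kinematics encode the
four archetypes: crawling = low/wide with ±10 px horizontal oscillation;
walking = tall with ±12 px oscillation plus a 1.5 px gait bounce; sitting =
low/wide, near-static (1.2 px rock); standing = tall/narrow, near-static
(1.2 px sway and 0.8 px bob). Sitting and standing deliberately differ
mainly in geometry, not motion, so motion-based features struggle exactly
where they struggle on real children. The idle amplitudes are set just
above the 1 px static-rejection threshold so that near-static postures
still produce trackable texture motion. Occlusion hides the child behind a
static panel per (view, segment) draw; distractor agents reuse the
archetype motions so scene-level features are genuinely confounded.

**Feature-space bags** (`make_feature_bags()`). For fast classifier
experiments, bags are drawn directly in feature space: class means are
orthogonal directions at separation 2.5 (in unit-noise units), and with
probability 0.4 (default) a view is replaced by a draw from the shared
zero-mean background — an occluded camera — and marked uninformative in
the metadata, which is what lets tests audit MI-SVM witness recovery
against ground truth.

**Child simulator** (`simulate_episode()`). Responses are sampled from a
ground-truth tensor `P*`; inter-transition times are exponential with mean
dwell 2 s — only time-normalized totals matter downstream, so the timing
model is the simplest one consistent with that. Two fixture profiles ship
with the package, both *synthetic and calibrated to no real subject*: a
"responsive" child (retreat sustains a chase; holding draws a looking child
into touching; approaching a looking child tends to startle) and a
"distractible" child (heavy leak back to `NL`). Under the responsive
profile the operator heuristic is noticeably suboptimal, which gives the
regular-versus-optimal comparison a true signal. Recovery experiments
explore actions uniformly to guarantee row coverage;
`compare_policies()` pairs the two arms on common random numbers.

Passing the synthetic suite shows the *machinery* is correct — the
estimators converge, the planner is exactly optimal, the MIL witness logic
recovers planted structure, occlusion hurts voting more than max-scoring.
It does not certify accuracy levels on real video: real children are
articulated, appearance varies, occlusions are structured rather than
Bernoulli, and the archetype kinematics are caricatures. Directional
claims (e.g. MI-SVM ≥ SVM-MV under occlusion) transfer as hypotheses, not
as measurements.

# Numerical choices and degenerate inputs

* Score and vote ties break deterministically: summed decision scores
  first, then fixed class order.
* Flow solves guard the structure-tensor determinant (`< 1e-6` ⇒ zero
  flow); mixture variances are floored at `1e-6`; Fisher normalization
  guards the zero vector.
* Clips shorter than `L` warn and return no trajectories (not an error);
  empty descriptor sets encode to flagged zero vectors; bags with missing
  views simply omit them from voting/max-scoring rather than imputing.
* All stochastic functions take explicit seeds and restore the caller's
  RNG state; libsvm and EM fits are deterministic given their inputs.

# Problem sizes used by the shipped tests

The test suite keeps simulations small enough for routine runs while still
exercising every claim: the classifier benchmark uses the reference class
proportions at half scale (83/114/203/124 bags, 16-dim features, five
splits); the end-to-end rendering check uses 12 instances per class of
25-frame clips at five views with `K = 8`; estimator-recovery uses 10,000
transitions (consistency) and 30 transitions × 100 seeds (sparse regime);
policy comparisons use 100 paired 3-minute episodes. The acceptance script
(`scripts/acceptance.R`) recomputes the same quantities from scratch at the
same sizes.

# Known limitations

* The trajectory extractor is a simplified dense-trajectory scheme: no
  camera-motion compensation, no multi-scale pyramid, no warped-flow
  descriptors. Fine for a static rig and synthetic scenes; published
  large-scale video benchmarks would need the full machinery.
* Linear SVMs use standard hinge loss (libsvm); squared-hinge variants
  would require a solver not available to the package.
* The MDP has no partial observability: the child's state is assumed
  annotated or classified upstream. Temporal segmentation of untrimmed
  video is likewise out of scope — instances arrive trimmed.
* Fixture child profiles are invented; nothing in the package estimates a
  real child's tensor beyond the generic estimators.
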