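---
title: "Discriminative fiber filtering: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminative fiber filtering: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Deep brain stimulation (DBS) cohorts targeting different structures — the
anterior limb of the internal capsule (ALIC), the subthalamic nucleus (STN),
the nucleus accumbens — may modulate one shared white-matter pathway. To ask
whether stimulation of one tract explains clinical improvement across
targets, fiberfilter implements discriminative fiber filtering: every
streamline of a normative tractogram is scored by how well connectivity to
it separates good from poor responders, and the resulting per-fiber weights
form a predictive model that can be carried to new cohorts.

The pipeline consumes three inputs: a tractogram in world millimetre (RAS)
coordinates, one binary stimulation volume (VTA — volume of tissue
activated) per active electrode with its stimulation amplitude, and a cohort
table with the clinical outcome. The outcome is percent Y-BOCS improvement,
$100\,(\mathrm{baseline}-\mathrm{postop})/\mathrm{baseline}$, signed and
unclamped: a worsening patient must pull fiber scores down, not be clipped
away.

## Connectivity

A fiber and a stimulation are *connected* when at least one vertex of the
fiber, after resampling, falls inside a support voxel of any of the
stimulation's masks. Three choices pin this down:

* **Resampling.** Each segment is subdivided into equal parts no longer than
  `max_step`; the default is half the smallest voxel edge of any mask, which
  guarantees no voxel can be skipped between consecutive vertices. Original
  vertices are preserved, so the geometric path and arc length are unchanged.
* **Voxel membership.** A vertex belongs to the voxel nearest to its
  inverse-affine image (0-based indices; voxel $(i,j,k)$ maps to world
  coordinates through the affine). This matches the semantics of a binary
  mask as a set of voxel-center samples, and is simple enough that an
  independent implementation can reproduce it point for point — the test
  suite exploits exactly that, re-deriving incidence analytically for
  voxelized spheres at a 0.05 mm sampling density and requiring exact
  agreement when the pipeline runs at the same density. At coarser default
  steps the sampled-vertex rule is deliberately resolution-dependent for
  chords shorter than the step; the monotonicity and translation-equivariance
  properties are tested at the default.
* **Multiple masks.** Volumes of one stimulation record (bilateral or
  multi-electrode settings) are OR-combined: the record is one clinical
  observation, and a fiber touching either hemisphere's volume is connected
  to it. Connectivity is strictly binary — no path-length or E-field
  weighting.

## The fiber score model

For fiber $f$ with connected-group improvements $y_C$ and unconnected-group
improvements $y_U$, the weight is the two-sample t-statistic

$$ t_f \;=\; \frac{\bar y_C - \bar y_U}{s_p\sqrt{1/n_C + 1/n_U}}, $$

with the pooled standard deviation $s_p$ by default (the classical
two-sample form; Welch is available via `var_equal = FALSE`). The connected
mean comes first, so fibers connected to good responders score positive.
Implementation notes that matter numerically: improvements are centered
before the moment sums are formed (the statistic is shift-invariant, and
centering avoids catastrophic cancellation in $\sum y^2 - n\bar y^2$), and
within-group sums of squares are clamped at zero against roundoff.

A fiber is *valid* only when both groups contain at least `min_per_group`
stimulations (default 2, the smallest count with an estimable variance).
Invalid fibers keep a weight of exactly 0 and a flag — they are never
dropped, so fiber indexing is stable across cohorts and a model fitted on
one cohort applies positionally to another. Zero pooled variance with
unequal means is flagged invalid rather than scored $\pm\infty$.

No per-fiber p-values are computed and no multiple-testing correction is
applied: across millions of mass-univariate tests the t-values are not
significance claims but predictive weights.

## Aggregation, correlation, permutation inference

The aggregate score of a stimulation is the sum of t-values of all valid
connected fibers — positive and negative alike — divided by the stimulation
amplitude. The division counteracts larger stimulation fields mechanically
collecting more fibers; for multi-electrode records the OR-combined
incidence sums across targets before the one division by the record's total
amplitude (amplitudes of simultaneously active electrodes are added, the
total-charge reading of "the stimulation amplitude"). The top-`fraction`
fiber selection (`top_fraction()`, ties broken by ascending fiber ID) is a
display/export device only; aggregation always uses every valid fiber.

Aggregate scores are correlated with improvements (Pearson by default, the
plain R of a scatterplot with a linear fit; Spearman by flag), and the
p-value comes from Monte-Carlo permutation of the improvement vector:
geometry stays fixed, outcomes are exchangeable under the null. With
$r_{\mathrm{obs}}$ and permuted values $r_1,\dots,r_B$,

$$ p \;=\; \frac{1 + \#\{\,|r_b| \ge |r_{\mathrm{obs}}|\,\}}{B + 1}, $$

the add-one estimator: $p$ is never exactly zero and its resolution is
$1/(B+1)$ ($B = 1000$ by default). Two-sided by default; one-sided
alternatives are available since score-improvement associations are
directional hypotheses in some analyses. The seed is recorded in the result,
and every draw in the package goes through a save/restore wrapper
(`with_seed()`), so results are bit-reproducible and never perturb the
caller's RNG.

Cross-cohort prediction (`cross_predict()`) fits the model on the training
incidence and outcomes only, then evaluates scores and permutation p on the
test cohort; the firewall is structural (the fit never sees test data) and
asserted by a test that mutates test outcomes and checks the fitted weights
are bit-identical.

The low/high subgroup contrast (`low_high_comparison()`) compares
improvements of stimulations scoring below a cutoff against the rest with a
classical pooled t-test (low minus high, so a negative t means high-scoring
stimulations improved more) — this is the one analysis that keeps a
parametric p. Whether such a cutoff should apply to raw sums or
amplitude-normalized scores is genuinely ambiguous in the field; the
function applies it to whichever vector the caller passes and the
documentation says so.

## Literature targets

`builtin_targets()` embeds the eleven published OCD-DBS target coordinates
(MNI, $x$ as a $\pm$ pair) with reported mean percent Y-BOCS improvements
where available; amGPi, NAcc and BNST report none and are excluded from
correlations while still being scored. The published weighting scheme
behind "overlap between a stereotactic site and a tract" is not reproduced
here; the package's declared proxy is a bilateral pair of 3 mm spheres at
the printed coordinates, scored by the same aggregate-fiber-score machinery
with amplitude 1. The radius is a parameter; overlap is monotone
non-decreasing in it for nonnegative-weight models, so a sensitivity sweep
is one loop. Only the printed MNI column is used — no AC/PC conversion is
attempted. Three thalamic rows (MD, VA, iml) share one reported improvement
and are kept as three points, as printed.

## The synthetic generator

Patient VTAs, outcomes and the normative connectome behind the original
analyses are not redistributable, so the package ships a generator that
emulates their statistical structure:

* **Planted bundle** (`make_bundle()`): a smooth centerline through
  waypoints; each fiber adds a Gaussian radial offset (sd `radial_sd`,
  default 2 mm — a plausible compact-bundle cross-section) drawn at four
  knots and interpolated smoothly along the arc. Default 200 fibers, 1 mm
  vertex spacing, ~62 mm length.
* **Background** (`make_background()`): momentum-smoothed random walks
  (smoothness 0.85, lengths 40–80 mm) reflected at the walls of an
  80 mm box — incoherent clutter standing in for the non-predictive bulk of
  a whole-brain connectome. Default 2000 fibers, i.e. a planted fraction of
  ~9%.
* **Cohorts** (`make_cohort()`): stimulation centers drawn from a Gaussian
  around a point offset 3.5 mm from the bundle midline (dorsal for cohort A,
  lateral for cohort B — two surgical approaches to one tract), spread
  (8, 3, 3) mm so centers slide along the bundle more than across it;
  amplitudes uniform on 2–5 V with sphere radius $1.5 + 0.6a$ mm
  (2.7–4.5 mm, the scale of clinical VTA models); outcome
  $\mathrm{improvement} = \beta\,o + \varepsilon$, where $o$ is the fraction
  of planted fibers the sphere intersects, $\beta = 60$ improvement points
  per unit overlap and $\varepsilon \sim N(0, 10^2)$. With the geometry
  above, $o$ spans roughly 0–0.8 with a spread near 0.2, so the signal-to-
  noise ratio $\beta\,\mathrm{sd}(o)/\sigma$ sits near 1 and in-sample
  correlations land in the 0.6–0.8 range reported for real cohorts — by
  construction, not by tuning.
* **Determinism**: all draws derive from per-fiber / per-stimulation
  substreams of one seed (a counter-based multiplicative scheme), so
  sub-draws are reproducible regardless of draw order, and every cohort
  carries a ground-truth sidecar (centers, radii, overlaps, noise) from
  which the outcome formula can be re-evaluated exactly.

What the generator does *not* emulate: realistic white-matter geometry and
crossing-fiber anatomy, FEM-based E-field volumes (spheres stand in),
electrode trajectories, registration error, and patient-level covariates.
Passing recovery tests therefore demonstrates that the estimator chain is
correct under its own assumptions — not that those assumptions hold in any
clinical dataset.

## Test problem sizes

The recovery experiments used in the test suite run at 200 planted + 2000
background fibers, 20 stimulations per cohort, 1000 permutations, 20
cross-prediction replicates, and 500 calibration repetitions at 500
permutations — sizes chosen so the full suite exercises every claim in a
couple of minutes on a laptop while keeping Monte-Carlo intervals tight
enough to be meaningful (e.g. the binomial 99% band around a 5% rejection
rate at 500 repetitions is [0.030, 0.072]).

## Known limitations

* TRK/TCK floats are 32-bit; coordinates round-trip to ~1e-4 mm at brain
  scale, not bit-exactly. Per-fiber scalars stored in TRK track properties
  share that precision (the TCK sidecar table is full-precision text).
* The vertex-sampling connectivity rule is resolution-dependent by design;
  at the default half-voxel step, chords shorter than the step can be
  missed. Tighten `max_step` when masks are much smaller than fibers'
  curvature scale.
* Incidence is kept as a sparse logical matrix; at
  fibers $\times$ stimulations far beyond $10^7$ connected pairs, memory —
  not time — becomes the binding constraint.
* `low_high_comparison()` inherits the cutoff-scale ambiguity described
  above; report which score vector the cutoff was applied to.
* Permutation p-values have resolution $1/(B+1)$; with $B = 1000$ the
  smallest reportable value is ~0.001.
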