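---
title: "Dynamic-stability gait analysis for vestibulopathy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic-stability gait analysis for vestibulopathy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vestgait)
```

## The problem

Patients with bilateral (BV) or unilateral (UV) vestibulopathy suffer from
chronic imbalance that is hard to quantify in the clinic: many walk
normally on flat ground and decompensate only when vision or proprioception
cannot substitute for the missing vestibular input (eyes closed, narrow
base, turning). `vestgait` implements an instrumented analysis of walking
trials that computes a battery of twenty dynamic-stability, spatial,
temporal and kinematic parameters from 3-D marker trajectories, evaluates
which task/parameter combinations separate patient groups from controls
(discriminant validity), which track self-reported handicap (convergent
validity against the Dizziness Handicap Inventory, DHI), and which a
clinician could realistically assess (clinical applicability) — and
synthesises the three into a short-form functional gait battery.

Because raw laboratory recordings are bulky and subject-identifying, the
package ships a kinematic synthetic walker that generates full marker-set
cohorts with ground-truth sidecars, so every stage of the pipeline is
testable end to end.

## Pipeline

1. **Ingest** (`read_c3d`, `read_fixture`, `load_cohort`): trials become
   `trial_record`s (metres, seconds, lab frame X = progression,
   Y = medio-lateral, Z = vertical); cohort metadata carries group,
   affected side, DHI and FGA item scores.
2. **Preprocess** (`fill_gaps`, `lowpass`, `add_virtual_markers`,
   `detect_gait_events`): gap filling, 4th-order 6 Hz zero-phase
   Butterworth low-pass, regression-based joint centres, coordinate-based
   gait-event detection.
3. **Parameters** (`compute_trial_parameters`): the battery below, with
   per-cycle values reduced to the per-trial median.
4. **Statistics** (`run_pipeline`): Kruskal-Wallis across the three groups
   per task and parameter, Dunn post-hoc with Holm correction when
   significant, Pearson correlations with the DHI inside each patient
   group, category thresholds, and the relevance synthesis feeding the
   short-form report.

## Models and formulas

**Centre of mass.** The whole-body CoM is a mass-fraction-weighted sum of
segment CoMs from a reduced 9-segment model (head+trunk, pelvis, thighs,
shanks, feet, lumped arms) driven by 13 markers/joint centres. Segment
mass fractions, CoM ratios and gyration radii are adult averages from the
standard published inertia tables, renormalised to sum to one, and
overridable via `read_body_model()`.

**Extrapolated CoM and margin of stability.** Under the inverted-pendulum
model, the extrapolated CoM is
`xCoM = CoM_horizontal + v_horizontal / omega0`, `omega0 = sqrt(g / l)`,
with `l` the mean vertical CoM height. The margin of stability at each
leading-foot strike is `MoS = BoS - xCoM`, with the base of support
reduced to the lateral malleolar marker of the leading foot. Signs:
medio-lateral MoS is positive when the xCoM lies medial to the malleolus
(mechanically stable); antero-posterior MoS is positive when the xCoM is
behind the malleolus. Note that `xCoM`'s velocity term grows as
`sqrt(l)`: taller pendula extrapolate further.

**Whole-body angular momentum (WBAM).** Sum over a 13-segment model of
`L_i = m_i (r_i - r_com) x (v_i - v_com) + R_i I_i R_i' w_i`, with
segment orientations from marker triads and angular velocities from the
triad derivatives (`w = 0.5 * sum_k e_k x de_k/dt`). The result is made
dimensionless by body mass x height x mean horizontal CoM speed (the
normaliser is configurable and echoed into the run metadata). Components
are reported about walking-direction-aligned axes as sagittal / coronal /
transverse; the clinical literature sometimes says "frontal" for the
coronal plane, and the run metadata records that mapping. The reference
CoM for the transfer terms is the 9-segment CoM throughout.

**Zone scores.** Four nested medio-lateral zones are defined about the
walkway midline (least-squares line through the floor-plane path; one
midline per straight leg on turn trials). Default half-widths are the
6/10/15-inch deviation bands of level-surface gait scoring (0.1524,
0.254, 0.381 m) with weights 0, 1, 2, 3 — both configurable, since the
clinical source specifies neither. The CoM score adds the entered zone's
weight at every outward boundary crossing (a between-frame jump across
several zones scores the zone it lands in); the foot score instead
integrates the fraction of trial time during which *both* heels lie in
zone >= z, weighted per zone. The asymmetry — counting crossings for the
CoM, integrating time for the feet — mirrors the two scores' clinical
definitions and is preserved deliberately.

**Spatio-temporal measures.** Step width is the ML distance between the
leading heel at strike and the contralateral heel at its own previous
strike; the ML step distance is the maximum ML offset difference between
consecutive ipsilateral placements (sensitive to lateral catch-up steps);
double support is the summed stance overlap per gait cycle; walking speed
is CoM path length between first and last strike over elapsed time. The
tandem step count follows the heel-to-toe rule: consecutive placements
within 0.05 m of the tandem line before the first off-line placement.
The taped tandem line is treated as a lab fixture (default: the lab X
axis through the origin) rather than estimated from the data.

**Head anchoring index.** `AI = (sd_rel - sd_abs) / (sd_rel + sd_abs)`
per plane (yaw/pitch/roll), where `sd_abs` is the SD of the head
orientation in space and `sd_rel` its SD relative to the trunk. +1 means
the head is stabilised in space, -1 that head and trunk move "in block".
The SDs are taken over orientation angles (not angular velocities); a
variance-based variant would change magnitudes but not signs.

**Angular-velocity RMS and GaitSD.** Head/trunk angular-velocity
magnitude is expressed per percent of gait cycle (deg/%cycle) so cadence
differences cancel; alternatives (none, per walking speed) are selectable.
GaitSD is the square root of the mean across-cycle variance of nine
time-normalised (101-point) lower-body kinematic curves (pelvis
tilt/obliquity/rotation, hip flexion/abduction/rotation, knee flexion,
ankle dorsiflexion, foot progression).

**Laterality.** Side-dependent parameters use the left side for BV
patients and controls and the pathological side for UV patients
(`analysis_side()`, overridable).

## Statistical framework

Group comparisons are nonparametric throughout (three groups of ten;
Shapiro-Wilk screening is reported but never switches the pipeline to
parametric tests). Each task x parameter cell gets a tie-corrected
Kruskal-Wallis H with a chi-square (df = 2) p-value; cells significant at
the primary alpha (0.05) get two-sided Dunn z-tests with Holm step-down
adjustment over the three pairwise comparisons, and every cell carries a
strict flag at the 0.01 threshold. Convergent validity is the Pearson
correlation with the DHI within BV and within UV separately; subjects
with missing DHI are excluded pairwise and a correlation is reported only
with at least three complete pairs.

Categories: discriminant — excellent p <= 0.001, good <= 0.01, moderate
<= 0.05, fair < 0.1, poor >= 0.1; convergent on |r| — excellent > 0.8,
good > 0.6, moderate > 0.4, fair > 0.2, poor otherwise. A cell is
**relevant** when discriminant and convergent validity are both at least
moderate and clinical applicability is excellent; **interesting** when
both validities are at least moderate but applicability falls short. The
applicability ratings are inherently subjective expert judgements, so
they live in an editable table (`default_applicability()`).

Descriptive statistics use quantile type 7 (linear interpolation at
`(n - 1) q`); this convention reproduces the published cohort's printed
medians and first quartiles, and is configurable.

The power helper draws normal groups with given means/SDs and counts
Kruskal-Wallis rejections — a parametric-draw, nonparametric-test design
recorded in the output. For the comfortable-gait walking-speed contrast
(1.09 +/- 0.22, 1.05 +/- 0.17, 1.29 +/- 0.09 m/s; n = 10 per group;
alpha = 0.05) it yields a power of about 0.91 at 20,000 replicates.

## The synthetic walker

`generate_trial()` is a *kinematic* walker: every marker position is an
analytic function of gait phase plus noise. That is sufficient because
every parameter in the battery is positional/kinematic; no forces are
ever needed. It emulates:

- alternating step placements with programmed width, length and cadence
  plus Gaussian placement and timing noise;
- sinusoidal vertical and medio-lateral CoM oscillation, slow lateral
  path wander, and Poisson-timed lateral catch-up steps that drag the
  body sideways for a moment;
- trunk yaw/pitch/roll oscillations, and head motion mixed as
  `coupling x trunk + (1 - coupling) x independently stabilised motion`;
- task modifiers: speed/cadence scaling (slow, fast, dual task), width
  and sway gains with eyes closed, added head oscillation for head-turn
  tasks, a 180-degree path bend for turn-pivot, on-line heel-to-toe
  placements with a per-step off-line hazard for tandem.

Walking trials are trimmed to the steady-state window (third placement to
half a step past the second-to-last), emulating mid-walkway capture;
gait initiation and termination transients are generated but not emitted,
and ground-truth events cover the steady state. Tandem trials keep their
standing start because the step count begins at the first placement.

Subject draws couple every feature to a latent severity in [0, 1], and
the DHI is generated from the same severity (`DHI = 5 + 55 x severity +
noise`, clipped to [0, 100]); this is what makes convergent-validity
correlations recoverable by design. Group presets anchor comfortable
walking speed to the published group summaries (BV 1.09 +/- 0.22,
UV 1.05 +/- 0.17, HS 1.29 +/- 0.09 m/s), with the severity slope and
residual SD chosen so the *total* SD matches the printed value while
severity explains enough variance for speed-DHI correlations around
-0.5 to -0.6. All other preset values (width, sway, coupling, catch-up
rates, kinematic noise, wander) are synthetic choices that reproduce the
qualitative patient contrasts — wider steps, larger sway, stiffer
head-trunk coupling, noisier kinematics — and are documented as such,
not as estimates.

What the walker does **not** emulate: ground-reaction forces and true
dynamics, physiological vestibular control loops, marker soft-tissue
artefact, occlusion patterns of real optical capture, fatigue or
learning across trials, and the heterogeneous compensation strategies of
real patients. Passing tests therefore demonstrate that the pipeline
measures what the generator programs — correctness of the measurement
chain — not that the synthetic cohort is biomechanically faithful.

## Numerical choices

- **Filtering** is forward-backward (zero-phase) with the 4th-order 6 Hz
  Butterworth design applied in each pass; zero phase is the gait-lab norm
  and keeps event timing unshifted. Columns are level-shifted before the
  recursion so start-up transients vanish; ends are mirror-padded
  (50 samples).
- **Gap filling**: gaps <= 10 frames use cubic splines; longer gaps use
  iterated rank-15 principal-component reconstruction over the full
  marker matrix (30 iterations or 1e-6 m convergence), initialised by the
  spline. Rank 15 sits near the effective rank of a full-body gait marker
  matrix; much higher ranks start reproducing the spline initialisation
  instead of the shared motion. Gaps longer than `max_gap` are reported,
  never silently filled.
- **Event detection** is coordinate-based: strikes at maxima of the
  (heel - mid-PSIS) progression coordinate, offs at minima of the
  (toe - mid-PSIS) coordinate, along the locally estimated walking
  direction, with a pelvis-speed mask (>= 30% of the 80th-percentile
  speed) that removes noise extrema during standing phases and a
  same-side minimum event separation (0.6 s; 1.2 s for tandem's slow
  strides). On synthetic trials the detector lands within ~10 ms of
  ground truth.
- **Walking direction**: first principal component of the floor-plane
  path, sign-aligned with net displacement; per-frame headings from
  low-passed pelvis velocity on turning tasks; trials displacing less
  than 0.5 m fall back to the lab X axis with a warning.
- **Degenerate inputs**: collinear pelvis markers, zero-length segments
  and empty groups raise explicit errors; all-identical statistical
  groups return H = 0, p = 1; a zero Dunn standard error yields z = 0.
- **Parameter count.** The battery enumerates twenty named parameters
  (six stability, five spatial, three temporal, six kinematic). Clinical
  summaries that treat the coronal and frontal angular-momentum planes as
  one quantity count nineteen; the package reports all twenty columns.
- **Restricted tasks.** Tandem, backwards and stairs trials are hard to
  label reliably, so a single parameter is computed: the tandem step
  count for tandem, and task time for backwards and stairs — task time
  being the only battery member that needs no marker labelling quality.

## Problem sizes used by the test-suite

The packaged checks run on deliberately desk-scale cohorts: recovery
checks use 30 subjects x 1 task; the null calibration uses 26 seeds of
24-subject cohorts over four walking tasks on a 4 m walkway (about 2,000
task x parameter cells); the power simulation uses 20,000 Monte-Carlo
cohorts. Null cohorts are built exactly as "all three presets identical"
(the control preset for every group), which also leaves the DHI undefined
for all subjects — convergent validity is then unreportable and the
short-form report is empty by construction, as it should be when nothing
distinguishes the groups.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
cohort <- generate_cohort(n_per_group = 10,
                          tasks = c("comfortable", "eyes_closed", "tandem"),
                          seed = 42)
res <- run_pipeline(cohort$trials, cohort$cohort)
subset(res$relevance, tier == "relevant")
res$report
write_outputs(res, "vestgait-run")
```

## Known limitations

- The C3D support is a minimal Intel/floating-point subset (no analog
  channels, no integer-scaled data); the plain-text fixture format is the
  primary serialisation.
- The anchoring-index and angular-velocity normalisation conventions vary
  across the clinical literature; both are configurable and echoed into
  the run metadata, but cross-study numerical comparability is limited.
- Anthropometric tables are adult population averages; no subject-specific
  inertia scaling beyond mass and height is attempted.
- The relevance synthesis inherits the subjectivity of the clinical
  applicability ratings; changing that table changes the short-form set,
  which is why it is an explicit, editable input.
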