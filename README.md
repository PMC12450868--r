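# vestgait

Dynamic-stability gait analysis for vestibulopathy cohorts.

Patients with bilateral (BV) or unilateral (UV) vestibulopathy often walk
normally on flat ground and decompensate only when vision or
proprioception cannot substitute for the missing vestibular input —
walking with eyes closed, on a narrow base, or while turning. `vestgait`
turns 3-D motion-capture walking trials into a battery of twenty
dynamic-stability, spatial, temporal and kinematic parameters, tests which
task/parameter combinations discriminate patient groups from controls and
track self-reported handicap, and synthesises the result into a short-form
functional gait battery a clinician can actually run.

## What it computes

**Dynamic stability** — medio-lateral CoM range of motion; margin of
stability `MoS = BoS − xCoM` with the extrapolated centre of mass
`xCoM = CoM + v/ω₀`, `ω₀ = √(g/l)` (Hof's inverted pendulum), evaluated
at leading-foot strikes against the lateral malleolus; whole-body angular
momentum `L = Σᵢ mᵢ(rᵢ−r꜀)×(vᵢ−v꜀) + RᵢIᵢRᵢᵀωᵢ` over a 13-segment model,
reported as per-plane ranges, normalised by mass × height × speed.

**Spatial** — zone-based CoM and foot deviation scores over four nested
medio-lateral floor zones; step width; maximum medio-lateral distance
between ipsilateral steps (catch-up steps); tandem step count.

**Temporal** — walking speed, double-support time, task time.

**Kinematic** — head anchoring indices `AI = (σᵣ−σₐ)/(σᵣ+σₐ)` per plane
(+1 head stabilised in space, −1 head/trunk "in block"); normalised head
and trunk angular-velocity RMS; GaitSD (root mean across-cycle variance of
nine lower-body kinematic curves).

**Statistics** — Kruskal–Wallis across BV/UV/HS per task × parameter,
Dunn post-hoc with Holm correction, Pearson correlations with the
Dizziness Handicap Inventory, published category thresholds, and the
relevance rule (discriminant ≥ moderate AND convergent ≥ moderate AND
excellent clinical applicability) that yields the short-form report.

A kinematic synthetic-walker module generates full marker-set cohorts at
100 Hz with ground-truth sidecars (events, placements, programmed gait
features, severity-coupled DHI scores), so the entire pipeline is testable
without laboratory data.

## Worked example

```r
library(vestgait)

cohort <- generate_cohort(n_per_group = 10,
                          tasks = c("comfortable", "eyes_closed", "tandem"),
                          seed = 42)
res <- run_pipeline(cohort$trials, cohort$cohort)

subset(res$relevance, tier == "relevant")
#>         task     parameter discriminant convergent applicability     tier
#>  comfortable    ML_CoM_rom    excellent  excellent     excellent relevant
#>  eyes_closed    ML_CoM_rom    excellent       good     excellent relevant
#>  comfortable       ML_step         good  excellent     excellent relevant
#>  eyes_closed       ML_step    excellent  excellent     excellent relevant
#>  eyes_closed    Step_width    excellent       good     excellent relevant
#>  comfortable     Task_time         good  excellent     excellent relevant
#>  eyes_closed     Task_time         good  excellent     excellent relevant
#>  comfortable Walking_speed         good  excellent     excellent relevant
#>  eyes_closed Walking_speed         good  excellent     excellent relevant

head(res$report, 3)
#>         task  parameter           direction strict
#>  comfortable ML_CoM_rom higher for patients   TRUE
#>  eyes_closed ML_CoM_rom higher for patients   TRUE
#>  comfortable    ML_step higher for patients   TRUE
```

`res$parameters` is the long-form table (subject, group, task, parameter,
value); `res$grid` holds the Kruskal–Wallis/Dunn cells; `res$correlations`
the per-group DHI correlations. `write_outputs(res, dir)` exports
everything as CSV plus a relevance heatmap and a metadata echo of every
methods choice (filter, zones, normalisations, thresholds).

The per-trial entry point is `compute_trial_parameters(trial, side)`,
which runs gap filling, 6 Hz zero-phase filtering, joint-centre
construction and coordinate-based gait-event detection before computing
the battery. Trials can be read from C3D (`read_c3d`) or the plain-text
fixture format (`read_fixture`/`write_fixture`); cohort metadata loads
from CSV (`load_cohort`), including the packaged 30-subject clinical
table (`cohort_table_path()`).

The exact conventions (zone widths, anchoring-index variant, angular
momentum normalisation, quantile type, event-detector settings) are
documented in the methods vignette (`vignettes/vestgait-methods.Rmd`).

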