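# toolplast

Kinematic analysis of tool-use-induced body-representation plasticity
across pubertal development.

## The problem

After a few minutes of using a long mechanical grabber, adults reach for
objects with their bare hand as if their arm were longer: wrist
acceleration, velocity and deceleration peaks come later and are smaller.
These kinematic after-effects are the standard motor signature of *tool
incorporation* into the body schema. Whether — and when — children and
adolescents show the same plasticity is an open developmental question,
complicated by the growth spurt: a body whose metrics change quickly may be
harder to keep represented accurately.

`toolplast` implements the full analysis chain for studies of this kind,
for motor-control and developmental researchers:

1. **Extraction** of the nine trial-level kinematic parameters from 3D
   marker trajectories (wrist, thumb, index at 200 Hz): latencies and
   amplitudes of the wrist acceleration, velocity and deceleration peaks,
   maximum grip aperture (MGA) and its latency, and movement time. Onset is
   the first sample with tangential velocity ≥ 10 mm/s after switch
   release; filtering is zero-phase Butterworth (4th order, 10 Hz).
2. **Mixed modelling** of each parameter on individual trials,

   `parameter ~ session + poly(puberty, 2) + session:poly(puberty, 2) + (1 | subject)`

   with the session factor (PRE/POST, or FIRST/LAST tool block) coded
   ±1/2, Type III Wald χ² tests, and a likelihood-ratio choice between
   linear and quadratic puberty trends (ML refits, 2 df).
3. **A meta-parameter**: the score on the first principal component of the
   correlation matrix of the nine parameters, used as a single multivariate
   outcome in the same mixed model.
4. **Crossing point and interval of equivalence**: the fitted PRE and POST
   curves are compared point-by-point along a fine puberty grid; the
   crossing point is where the two condition curves intersect (the
   developmental reversal of the after-effect), and the interval of
   equivalence is the contiguous range of puberty scores where the PRE–POST
   difference is not significant at the 5% level.
5. **A synthetic-data generator** (cohorts, trial parameters, and full
   minimum-jerk marker trajectories with embedded ground truth) that
   reproduces the statistical structure of such a study — 90 subjects with
   puberty scores 5–20, 18 free-hand trials per session, 4 tool blocks of
   12 trials, subject random intercepts, and a session×puberty interaction
   whose reversal sits at a configurable crossing point — so every stage is
   testable without access to recorded data.

The same machinery drives the two control analyses: the tool-use session
itself (FIRST vs LAST block, linear puberty covariate) and the arm-length
estimation task (estimates analysed in percent of the veridical forearm
length).

## Worked example

Simulate a study-sized cohort with the reversal embedded at puberty score
16 and run the free-hand analysis end to end:

```r
library(toolplast)
cohort <- generate_cohort(90, seed = 1)
trials <- generate_trial_parameters(cohort, n_trials = 18, seed = 2)
report <- run_freehand_analysis(trials)
print(report)
```

```
<analysis_report> variant: freehand
  trend selection: quadratic (LRT chi2(2) = 6.49, p = 0.039)
  meta-parameter: first PC explains 65.7% of variance
         term        chi2 df         p
1   condition 3867.428838  1 0.0000000
2   covariate    2.555795  2 0.2786225
3 interaction 5043.153739  2 0.0000000
<crossing_result> meta: crossing 15.85, interval of equivalence [15; 17] (alpha = 0.05)
  crossing table:
        parameter crossing_point interval_lo interval_hi
1     acc_latency          15.84          15          17
...
12 Meta-parameter          15.85          15          17
```

Reading the output: the puberty trend is quadratic (LRT); the first
principal component summarises 65.7% of the variance of the nine
parameters; there is no main puberty effect on the PRE kinematics
(covariate p = 0.28) but a strong session×puberty interaction — the
after-effect of tool use reverses with development — and the fitted PRE and
POST curves cross at puberty score 15.85 (truth: 16), with no significant
PRE–POST difference inside [15; 17].

Trajectory-level work looks the same with `generate_trajectories()` +
`extract_trials()` in front, and `run_tooluse_analysis()`,
`run_armlength_analysis()` and `run_imitation_analysis()` cover the other
tasks. A thin command-line front-end wraps these drivers:

```sh
Rscript exec/toolplast simulate --seed 1 --out simdir
Rscript exec/toolplast freehand --in simdir/freehand.csv --out report.json
```

`reproduce_study()` points the pipeline at a local copy of a study's
long-format trial exports (the reference archive is distributed via the
Open Science Framework, accession `osf.io/3g9mz`) and emits a comparison
table against the published values at documented tolerances; file names and
column mappings are configurable.

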