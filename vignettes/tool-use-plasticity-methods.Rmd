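---
title: "Methods: kinematic markers of tool incorporation across puberty"
author: "toolplast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinematic markers of tool incorporation across puberty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toolplast)
```

## The scientific question

Using a hand-held grabber for a few minutes changes how adults subsequently
reach for objects with their bare hand: latencies of the wrist acceleration,
velocity and deceleration peaks lengthen and their amplitudes shrink, as if
the arm were represented as longer. This package implements the analysis
chain used to ask *when this plasticity of the body representation emerges
during development*: reach-to-grasp movements are recorded before (PRE) and
after (POST) a tool-use session in participants spanning the whole pubertal
range, and the PRE/POST contrast is modelled as a smooth function of a
puberty score (PS, 5--20, the sum of five self-rated pubertal development
items). The signature finding this pipeline is built to detect and localise
is a *reversal*: below some puberty score the after-effect of tool use goes
one way (shorter latencies, larger peaks), above it the adult pattern
appears, and at the crossing point there is no effect at all.

## Trial-level kinematic parameters

Each trial yields nine parameters. The reaching component is described by
the latencies (ms from movement onset) and amplitudes of the wrist
acceleration peak (mm/s^2), the wrist velocity peak (mm/s) and the wrist
deceleration peak (mm/s^2, reported as a positive magnitude). The grasping
component is described by the maximum grip aperture (MGA, the largest
Euclidean thumb--index distance, mm) and its latency. Movement time runs
from onset to the stabilised grasp.

Operational definitions, all configurable:

* **Onset**: first sample at or after switch release where the wrist
  tangential velocity reaches 10 mm/s.
* **Grasp end**: first time after the aperture maximum at which the grip
  aperture rate stays below 5 mm/s for at least 50 ms while the wrist moves
  slower than 20 mm/s. The end rule is our operationalisation of
  "stabilised grasp"; its thresholds are assumptions and are echoed in every
  report.
* **Search windows**: the acceleration peak is sought between onset and the
  velocity peak, the deceleration peak between the velocity peak and grasp
  end; this enforces the physiological ordering of a single-peaked reach.
  Ties take the earliest sample.
* **Latencies** are measured from detected onset (not from switch release);
  this matches the definition of movement time and is configurable.

Marker positions are low-pass filtered before differentiation with a
zero-phase 4th-order Butterworth filter (10 Hz cutoff at 200 Hz sampling) --
the standard choice for reach kinematics; zero-phase (forward--backward)
filtering introduces no latency bias. Because `signal::filtfilt` starts from
zero initial conditions, series are padded with odd reflections of their
endpoints so no edge transient leaks into the recording. The tangential
speed (norm of the differentiated positions) is filtered a second time
before peak finding and before the acceleration is taken: the norm
re-injects high-frequency noise, and the velocity peak of a bell-shaped
speed profile is flat enough that an unsmoothed argmax is ill-conditioned.
Filtering can be bypassed entirely (`filter = list(bypass = TRUE)`).

For left-handed participants the paradigm mirrors the object placement;
since all extracted quantities are norms (speed, aperture) no axis
mirroring is needed in the extraction itself.

## The mixed model

For every parameter (and for the meta-parameter below) we fit the
random-intercept model

$$y_{ist} = \beta_0 + b_i + \beta_1 s + f(p_i) + g(p_i)\, s +
\varepsilon_{ist},$$

where $s$ is the condition contrast coded $-\tfrac12$ (PRE / FIRST block)
vs $+\tfrac12$ (POST / LAST block), $p_i$ the puberty score, $f$ and $g$
polynomials of degree 1 or 2 on an *orthogonal* polynomial basis,
$b_i \sim N(0, \sigma_b^2)$ a subject random intercept and homoscedastic
Gaussian trial noise. Fitting uses lme4. Three design choices matter:

* **Sum-to-zero condition coding** ($\pm\tfrac12$) makes $\beta_1$ the
  POST$-$PRE shift at the basis origin and is the only coding under which
  Type III tests are invariant; Type III Wald chi-squares are computed
  per term block as $\hat\beta' V^{-1} \hat\beta$ (df = block size) and
  cross-checked against `car::Anova` in the test suite.
* **Orthogonal polynomial basis** (`stats::poly`, with stored recurrence
  coefficients for exact out-of-sample evaluation on the crossing grid).
  Fitted values and Type III p-values are identical under raw centred
  powers -- a property the suite asserts -- so the basis is a numerical
  convenience, not a modelling assumption.
* **REML for reporting, ML for comparison**: coefficients, covariances and
  Wald tests come from REML fits; the linear-vs-quadratic decision refits
  both models by ML on identical rows and uses
  $\chi^2 = 2(\ell_{quad} - \ell_{lin})$ with 2 df (quadratic main +
  quadratic interaction), selecting the quadratic iff $p < 0.05$. The
  degree decision is made once, on the meta-parameter, and then applied to
  all parameters of that task. At small sizes (a few hundred observations)
  this ML likelihood-ratio test runs slightly above its nominal level
  (about 7% at 20--30 subjects in our calibration runs); by roughly 60
  subjects $\times$ 10 trials it is within binomial noise of 5%. The
  calibration checks therefore run at the latter size.

No multiplicity correction is applied across the nine parameters (raw
p-values are reported, as is conventional for this design); a Holm
correction can be applied downstream by users who want it.

## The meta-parameter

With nine correlated outcomes per task, a single multivariate summary is
useful. The meta-parameter is the score on the first principal component of
the *correlation* matrix of the nine parameters (correlation, not
covariance, so the component is unit-free). Scores are standardised
parameters projected on the first eigenvector, with the sign fixed so the
velocity-amplitude loading is positive. The loadings are estimated once on
all trials of a task (PRE and POST pooled) and then frozen for scoring --
one score per trial enters the same mixed model as any parameter.
Trial-level rows are the default (subject means are available via
configuration); pooling PRE and POST is the default and is flagged in
reports. Component-wise meta-parameters (reaching: the six wrist
parameters; grasping: MGA and its latency) provide the per-component
"global p-values". The explained-variance fraction $\lambda_1/9$ is
reported with every PCA; above 50% the single score is considered a good
summary.

## Crossing point and interval of equivalence

From a fitted model, the PRE and POST curves are evaluated on a fine
puberty grid (5 to 20, step 0.01 -- far finer than the integer scale, so
interpolation error is negligible). The pointwise difference
$d(p)$ has standard error $\sqrt{c' V c}$ with $c$ the difference of the
two design rows; a two-sided z-test is computed at every grid point, with
no multiplicity correction (the equivalence notion is pointwise at the 5%
level by definition).

* The **crossing point** is a sign change of $d$, located by linear
  interpolation between grid points. Multiple sign changes are all
  returned; the primary one is the root inside the widest non-significant
  run (logged).
* The **interval of equivalence** is the maximal contiguous run of
  non-significant grid points containing the crossing. When the interval
  reaches the scale boundary, it is reported as such (this maximal-run rule
  is our formalisation). When the curves never cross, no crossing is
  reported, the minimum-|z| point is given as a diagnostic, and the result
  is flagged "no reversal" rather than failing -- user data need not show
  the phenomenon.
* In publication-style tables, interval endpoints are rounded outward to
  integer puberty scores and the crossing to 0.01; exact values are kept in
  the machine-readable columns.

Per-parameter crossings are aggregated as mean and median, but the
meta-parameter's crossing is the primary estimate: only a single fitted
curve has a global interval of equivalence.

## The synthetic cohort and trajectory generator

The generator is first-class code: it defines the conditions under which
every statistical guarantee of this package is tested.

* **Cohort**: 90 subjects by default, puberty scores drawn with the
  per-score sample sizes of the reference cohort profile; heights and
  forearm lengths follow the per-score means with Gaussian jitter (7 cm /
  1.5 cm), with the within-score jitter correlation solved analytically so
  the pooled height--forearm Pearson correlation is 0.89 in population.
  Tool length is assigned from height (25 cm $\le$ 122 cm; 32 cm for
  123--146 cm; 40 cm from 147 cm).
* **Trial parameters**: the generative model mirrors the analysis model
  exactly; the generator's `target_crossing` adjusts the interaction
  intercept so the population POST$-$PRE difference is exactly zero at the
  requested puberty value (16 by default for kinematics, 7.5 for the
  arm-length task). Defaults place the interaction slope at one third of
  the residual SD per puberty unit. The reference study reports no variance
  components, so the residual and between-subject SDs (e.g. 70 mm/s for
  the velocity peak, 6 mm for MGA) are stated assumptions chosen to give
  realistic trial-to-trial scatter. A latent per-trial and per-subject
  "vigour" factor carrying 35% of the noise variance (positive loadings on
  amplitudes, negative on latencies and movement time) reproduces the
  cross-parameter correlation of real data; together with the shared
  session-by-puberty structure this puts the first-PC explained variance
  near 65%, in the range observed empirically.
* **Trajectories**: the wrist follows a minimum-jerk path whose distance
  and duration realise the row's peak velocity and movement time (peak
  velocity $= 1.875\,D/T$; a 35 cm reach in 1 s gives 656.25 mm/s); the
  grip aperture is a single-peaked raised cosine from 30 mm through the
  row's MGA down to the 25 mm object grip. Measurement noise defaults to
  0.01 mm, a typical motion-capture resolution. The stored ground truth
  applies the extractor's own operational definitions to the continuous
  profiles (closed forms where available, a dense 10 kHz evaluation for
  the end rule), so round-trip checks are meaningful.

What the generator does **not** emulate: marker dropout and occlusion,
skin-motion artefacts, non-Gaussian or heteroscedastic trial noise,
movement corrections / double-peaked profiles, learning within a session,
and any biomechanical arm model. Passing tests therefore certify the
statistical machinery and the extraction pipeline under clean single-peaked
kinematics, not robustness to messy recordings.

## Numerical tolerances used by the test suite

* Amplitudes round-trip within 2%; latencies within 15 ms (one 5 ms sample
  of onset quantisation, extremum discretisation, and the smoothing-induced
  argmax shift of flat extrema).
* Movement time round-trips within one sample plus the 50 ms stabilisation
  dwell of the end rule: smoothing the aperture shifts the detected
  stabilisation time by up to a few tens of ms.
* Wald type-I calibration (null interaction) runs 500 cohorts of 30
  subjects $\times$ 6 trials; likelihood-ratio size runs 500 cohorts of 60
  $\times$ 10; power runs 200 cohorts of 30 $\times$ 6 with a strong
  quadratic interaction; crossing recovery runs 100 replicates at the full
  study scale (90 subjects $\times$ 18 trials per session). These sizes
  were chosen as the smallest at which the asymptotic approximations hold.

## Known limitations

* Wald chi-squares with no degrees-of-freedom correction
  (Satterthwaite/Kenward--Roger) are reported by design; at very small
  subject counts they are mildly anticonservative.
* Random intercepts only: no random slopes or crossed random effects.
* The crossing point has no bootstrap or credible interval; uncertainty is
  carried by the interval of equivalence.
* The end-of-grasp rule and the onset threshold are operational choices;
  results on real data should be checked for sensitivity to them (both are
  single config values).

## A minimal run

```{r example, eval = FALSE}
cohort <- generate_cohort(90, seed = 1)
trials <- generate_trial_parameters(cohort, n_trials = 18, seed = 2)
report <- run_freehand_analysis(trials)
report$crossing_table
```
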