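---
title: "Motor-cortex mapping and multivariate mixed models: methods and design choices"
author: "tmsmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motor-cortex mapping and multivariate mixed models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmsmap)
```

## What this package computes

`tmsmap` implements the analysis chain of a case-control study of primary
motor cortex (M1) organization in low back pain (LBP): transcranial magnetic
stimulation (TMS) mapping of four trunk muscles, a spiral-tracking motor
test, a quantitative sensory testing (QST) battery, and multivariate
two-level mixed models for group differences and brain-behaviour
associations. Because participant-level data of such studies are not
public, the package ships a synthetic-cohort generator with known ground
truth; every stage of the pipeline is validated by recovering what the
generator planted.

## MEP extraction

EMG recorded during TMS mapping is high-pass filtered at 30 Hz and cut
into 500 ms post-stimulus epochs. A motor evoked potential (MEP) is an
epoch whose peak-to-peak amplitude exceeds 50 uV; within each muscle's
session, accepted MEPs below 25% of that session's peak response are then
discarded.

Design choices where the procedure leaves room:

* **Filter realization.** "High-pass at 30 Hz" is implemented as a
  4th-order Butterworth applied forward and backward
  (`signal::filtfilt`), i.e. zero-phase. The signal is demeaned first;
  this removes the DC component exactly and avoids the slow edge
  transient a forward-backward IIR filter otherwise leaves on offset
  signals.
* **Boundaries are strict as printed**: an epoch at exactly 50.0 uV is
  rejected (`> 50`), a response at exactly 25% of the peak is retained
  ("less than 25%" removed). The package treats these as contracts and
  tests them at the boundary.
* **Scope of the 25% rule**: the peak response is the maximum accepted
  peak-to-peak within one muscle x session. Applying the rule a second
  time changes nothing (the peak survives by construction), which is
  asserted as an idempotence property.
* **Epoching** starts at the stimulus with no pre-stimulus window; an
  optional artefact-blanking interval at the start of the epoch is
  available (`blank`), defaulting to 0 since no blanking is part of the
  procedure.

## Map features: CoG and area

The centre of gravity is the amplitude-weighted centroid of the
MEP-positive stimulation sites,

$$\mathrm{CoG} = \left( \frac{\sum_i V_i X_i}{\sum_i V_i},\;
\frac{\sum_i V_i Y_i}{\sum_i V_i},\;
\frac{\sum_i V_i Z_i}{\sum_i V_i} \right),$$

with $V_i$ the MEP amplitude at site $i$ in template-space millimetres
(X medio-lateral, Y posterior-anterior, Z vertical). It is invariant to
uniform amplitude scaling, equivariant under rigid translation, and always
lies inside the convex hull of the sites; all three are tested, and the
implementation is checked against a brute-force weighted mean.

**Cortical map area** is defined here as the planar area of the alpha
shape (default `alpha = 15` mm) of the MEP-positive sites after projection
onto their best-fit plane (principal axes of the 3-D cloud); the convex
hull is available as a documented alternative. The rationale: an alpha
shape respects non-convex map outlines, tends to the convex hull as
`alpha` grows (a tested monotonicity), and has an exact geometric oracle
(empty-circumcircle checks and known rectangle areas). Equivalence with
surface-mesh-based area algorithms used elsewhere is *not* claimed; only
the contract above is. Since no alpha-shape routine is available in the
supporting libraries used here, the 2-D Delaunay triangulation
(Bowyer-Watson) and the alpha complex are implemented in the package, with
a deterministic micro-jitter that disambiguates exactly cocircular
configurations (regular grids) without changing the coordinates that enter
the area.

Degenerate maps (fewer than 3 sites, or collinear sites) report area 0
with a flag rather than an error, because their CoG is still defined. A
session with no accepted MEPs at all yields a missing outcome that
propagates to the models as a dropped record.

**Hemisphere pooling.** Stimulation targets the hemisphere contralateral
to the most painful side, so cohorts mix left- and right-hemisphere maps
(the study structure is roughly 9:16 left:right). Before group analysis,
left-hemisphere X coordinates are mirrored (X to -X) so "more lateral"
keeps a single sign. The published convention is not stated; mirroring is
this package's choice and is applied symmetrically in the generator and
the analysis, so it cancels in recovery tests.

## Spiral tracking

The target moves anticlockwise along an Archimedean spiral
$r(\theta) = R_{max}\,\theta/\theta_{max}$ at constant angular rate,
with $R_{max} = 6.25$ degrees; duration (120 s) and number of turns (4)
are package choices where only extent, direction and approximate duration
are given. Three outcomes are computed from the per-sample Euclidean
error $e_t = \sqrt{(x^{tgt}_t - x_t)^2 + (y^{tgt}_t - y_t)^2}$:

* `angular_near`: mean of the smallest $\lceil q/100 \cdot n \rceil$
  errors (default $q = 90$);
* `time_near`: percentage of samples with $e_t < r$ (default
  $r = 0.9$ degrees, strict);
* `path`: the sum of all per-sample errors.

`path` as defined grows with the sampling rate; the outcomes table
records the rate so models can hold it fixed, and a time-integral variant
(`normalize = TRUE`) plus the distinct "total distance travelled"
quantity (`path_travelled()`) are provided for comparability, since both
definitions circulate under the same name. The first trial of the task is
a practice trial and is excluded from analysis by default.

## QST battery

Scoring follows the standard battery arithmetic: vibration threshold and
pressure pain threshold (PPT) as means of three trials; temporal
summation as mean rating after a 10-stimulus pinprick train minus mean
rating after single stimuli (5 repetitions each); graphaesthesia as
incorrect figures / 20; two-point discrimination (TPD) as the mean of six
per-location thresholds from an ascending 20 mm + 5 mm staircase.

Two conventions had to be fixed:

* **CPM sign.** Conditioned pain modulation is `during - before` on the
  PPT (absolute, N) and `100 * (during - before) / before` (relative, %):
  positive = the threshold rose under the conditioning stimulus =
  efficient inhibition. A `flip_sign` switch produces the opposite
  convention. Both effects always share sign.
* **TPD ceiling.** A participant who never reports "two" yields a
  missing threshold with a ceiling flag by default; a numeric ceiling is
  configurable. NPRS ratings of the conditioning hand are carried in the
  raw schema but enter no score.

## The multivariate two-level mixed model

Tests with correlated outcomes within a participant are analyzed jointly:
for a family of tests $t$ (the four muscles for each map feature; the QST
pain tests; the sensory-accuracy tests; the three tracking outcomes), the
model is

$$y_{it} = \mu_t + \beta_t x_i + u_i + \varepsilon_{it}, \qquad
u_i \sim N(0, \sigma_u^2), \quad
\varepsilon_{it} \sim N(0, \sigma_{e}^2 \text{ or } \sigma_{e,t}^2),$$

fitted by REML, where $x_i$ is the group indicator (group differences,
$\beta_t$ = LBP minus control per test) or a subject-level clinical score
(associations, $\beta_t$ = per-muscle slope). Wald standard errors with
normal critical values give $\beta_t \pm 1.96\,SE$ intervals and p-values,
matching the symmetric intervals the design targets; no degrees-of-freedom
correction is applied (a documented deviation risk versus software that
uses Satterthwaite or residual df). No multiple-testing adjustment is
applied beyond what the joint model itself provides — by design.

Choices worth flagging:

* **One model per CoG axis** (three models), muscles as the Test
  variable, rather than one joint axis x muscle model: axes carry
  incommensurable directions and the per-axis layout reproduces the
  reported table structure.
* **Residual structure.** `mvmm()` defaults to one residual variance per
  family (lme4). For the clinical families, which stack tests with
  wildly different units (a 0-10 rating next to Newtons and percentages),
  the pipeline fits per-test residual variances (`var_by_test = TRUE`,
  `nlme::varIdent`); with homogeneous variances the pooled residual
  mis-scales every per-test SE. Estimates of $\beta_t$ are essentially
  unaffected on balanced data (tested), only the SEs differ. The
  heterogeneous optimizer tries `nlminb` strictly, falls back to
  `optim`, and as a last resort returns a flagged non-strict fit.
* **Degenerate noiseless data** (zero within-cell variance, factor
  predictor) bypasses the optimizer entirely: the exact per-cell solution
  is returned with SE 0 and a singular flag.
* **Missing outcomes** are dropped, not imputed; the likelihood analyzes
  all available rows. Stratified (within-group) association refits run
  only for associations significant in the pooled model — the pipeline
  enforces that gate — and require at least 3 subjects per stratum.

## The synthetic cohort: what it emulates, and what it does not

`sim_config()` fixes the study conditions: 25 subjects per group, four
trunk muscles, 100 stimulations per session drawn uniformly over a
60 x 60 mm scalp patch (the spatial distribution of "pseudorandom"
stimulation is not specified; uniform is assumed), a 6.5%
completely-at-random missing rate for muscle outcomes (realized as
sessions in which no epoch crosses 50 uV), two 120 s tracking trials, and
the full QST battery.

* **MEP amplitudes** follow an isotropic Gaussian response surface,
  $V(d) = V_{peak} e^{-d^2 / 2 s^2}$ ($V_{peak} = 400$ uV, $s = 10$ mm),
  plus amplitude noise (SD 20 uV) — the simplest surface with a
  well-defined centroid for recovery tests. Each stimulation yields a raw
  EMG epoch containing one biphasic wavelet whose peak-to-peak equals the
  surface value exactly; the wavelet frequency is locked to one twentieth
  of the sampling rate so the extremes fall on samples. The generator
  makes no attempt at realistic EMG spectral content beyond what the
  30 Hz filter and peak-to-peak detection need, so passing tests say
  nothing about artefact rejection on real EMG.
* **Planted effects.** Group effects on the clinical tests and CoG axes
  default to the published case-control coefficients, and the noise
  scales are back-solved from the published standard errors
  ($\sigma_{tot} = SE \sqrt{n/2}$ at $n = 25$), with one third of each
  test's variance allotted to the subject level (capped within each
  family by its smallest-variance test, so a single additive intercept
  is consistent). Subject-level map position varies per axis (SDs 8.4,
  10.0, 4.9 mm, same back-solving), and map extent varies between
  subjects via a lognormal multiplier of the surface width (CV 0.3).
  These values were fixed once as the generator's definition of a
  realistic cohort.
* **Physical consistency over independence.** The raw QST records encode
  the planted outcome values through replicate trials that score back
  exactly (means of identical replicates), but CPM-relative is *derived*
  from CPM-absolute and baseline PPT rather than planted independently,
  graphaesthesia counts are rounded to the 20-figure grid, and values are
  clamped to their physical scales (ratings 0-10, fork scale 0-8, PPT
  floors). Likewise, group differences in map *area* are not planted in
  the raw route (planting through the surface width is ill-conditioned).
  Statistical validation of the models therefore uses the outcome-level
  generator `simulate_outcome_table()`, which plants every test
  independently; the raw route validates the plumbing end to end.
* **Reproducibility.** All randomness derives from one root seed via
  stable hashing of (seed, entity, purpose), so identical configurations
  are byte-identical and adding subjects never reshuffles existing ones.

## Numerical choices and problem sizes

Delaunay robustness uses a deterministic jitter of $10^{-9}$ times the
point-cloud diameter (topology only). The best-fit plane uses principal
axes with a collinearity guard at a $10^{-9}$ relative singular-value
ratio. The closest-$q$% count uses the ceiling and a stable sort, so ties
at the cut keep rank order.

The validation suites run at sizes chosen to exercise the estimators
honestly while staying desk-sized: mixed-model calibration uses 200
replicate cohorts at 25 subjects per group (bias, 95% CI coverage and
type-I error pooled over the four planted tests), CoG recovery uses full
100-stimulation sessions, and end-to-end determinism uses a reduced smoke
cohort (4 per group, 20-25 stimulations). The acceptance script rebuilds
a full-scale cohort (25 + 25, 4 muscles, 100 stimulations at 2 kHz EMG)
from scratch.

## Known limitations

* Coordinates are consumed already warped to template space; warping,
  segmentation and neuronavigation are upstream and out of scope, as are
  map volume and between-muscle map overlap.
* The area definition is a planar alpha shape, not a cortical-surface
  mesh area; absolute areas are comparable within this package only.
* Wald/normal inference is slightly anticonservative at $n = 50$
  subjects (expected coverage just below nominal, which the calibration
  suite shows); software using t critical values will report slightly
  wider intervals.
* The generator's group labels, not a pain model, drive the planted
  effects; nothing here speaks to mechanisms of LBP.
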