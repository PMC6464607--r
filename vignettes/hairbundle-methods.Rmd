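---
title: "Models and methods behind hairbundle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hairbundle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hairbundle)
```

This vignette explains the models the package implements, the conventions and
fixtures behind its defaults, the numerical choices that matter, and what the
test suite does and does not establish. Everything quantitative shown here is
computed by the package at build time.

## 1. The physical chain

### Fluid-jet force calibration

A fluid jet applies a distributed drag to the hair bundle. Three ingredients
convert a voltage command into an effective point force at the bundle's tip:

* **Effective hydrodynamic radius.** The bundle is approximated by a prolate
  ellipsoid of short axis $h$ (height) and long axis $W$ (width) in a flow
  perpendicular to its symmetry axis. With $\phi = W/h$,
  $$R_{HB} = \frac{4h}{3\left[\frac{\phi}{\phi^2-1} +
  \frac{(2\phi^2-3)\ln(\phi+\sqrt{\phi^2-1})}{(\phi^2-1)^{3/2}}\right]}.$$
  The formula is exact only for an ellipsoid in unbounded fluid; the bundle
  stands on the cell's apical surface, so this is an approximation carried by
  the whole calibration. At $\phi = 1$ the bracket equals $8/3$ and
  $R_{HB} = h/2$, the Stokes radius of a sphere of diameter $h$.
* **Velocity-profile averaging.** Bead tracers show the jet's lateral profile
  follows $v_X(y) = V_{max}/(1+(y/A)^2)^2$ with lateral extension $A$.
  Averaging over a probe of half-width ratio $w$ gives
  $\beta(w) = \left[\tfrac{w}{1+w^2}+\arctan w\right]/(2w)$, a closed form of
  the profile integral. The cone width at target distance $x$ is
  $L = 2x\tan\alpha + D_{FJ}$ and $A \approx L/2$, so the bundle uses
  $\beta(W/L)$ and the calibration fiber, which spans the cone, uses
  $\beta(1)$.
* **Fiber calibration and geometry factor.** The force on a fiber of
  stiffness $k_F$ is $k_F\,\Delta X$; its regression against the command
  voltage gives the calibration constant $C$ (pN/V). The geometry factor
  $G = \beta_{HB}R_{HB}/(\beta_F R_F)$, with
  $R_F = 2L/[3(\ln(L/D_F)+0.84)]$ for a cylindrical fiber, transfers the
  calibration to the bundle. Modeling the bundle as a stiff pivot with a
  linear vertical fluid-velocity profile puts the drag centroid at $2h/3$,
  so the tip-equivalent force is $F = \tfrac{2}{3} G C V_C$ regardless of
  $h$.

The fiber only samples fluid out to $y = \pm L/2$, where the profile still
carries 25% of the peak speed; the package checks (but, matching the
calibration convention, does not apply) the correction from integrating out
to $y = L$, which changes $G$ by about +4%.

### Mechanics, tip links, tension

Stiffness is the slope of effective force against displacement, the
displacement being the mean position over a window 5-10 ms after step onset
minus the pre-step baseline (a window average rather than a point sample, to
suppress noise without engaging the slower creep). The decomposition
$K_{HB} = K_{GS} + K_{SP}$ uses the amplitude ratio before/after tip-link
disruption, $r = 1 - a_i/a_d$; per-element values are
$\kappa = K_{SP}h^2/N_{SP}$ and $k_{GS} = K_{GS}/(\gamma^2 N_{TL})$. In the
package's display units (mN/m, um, nm, pN) these formulas need no conversion
factors: pN/nm = mN/m and mN/m x um^2 = fN m/rad numerically.

Tip-link counts divide the saturating transduction current by the
single-stereocilium current: $I_1 = 35.4$ pA for inner hair cells
(one link per stereocilium, $I_1/i = 2.36$ channels per link with
$i = 15$ pA), and $2.36\,i(CF)$ for outer hair cells with $i$ interpolated
linearly in fractional tonotopic distance between (4 kHz, 8.3 pA) and
(14 kHz, 12.1 pA). Interpolating in distance rather than log-frequency is a
package decision (the map position, not the frequency, is the physical
variable); the distance map itself is piecewise-linear in $\log_2$ CF
through the four anchor locations (1, 2, 4, 15 kHz at 5, 10, 20, 50% from
the apex), octave spacing being the natural scale of the tonotopic map.
$N_{TL}$ is kept real-valued everywhere downstream; rounding is for display
only.

Tension follows from statics: the steady offset after disruption releases
the resting tension, $T_R = K_{SP}\Delta X_R$ and
$t_R = T_R/(\gamma N_{TL})$ per link; the negative excursion upon calcium
chelation adds $\Delta T = -K_{SP}\Delta X_{Ca}$, giving
$t_{max} = t_R + \Delta T/(\gamma N_{TL})$. All tensions are reported along
the bundle's axis of bilateral symmetry; no tip-link-axis angular
correction is applied.

## 2. Statistics

Derived group values are products/quotients of group means, so their SEMs
propagate as
$$\sigma_P = \left|\prod_i \bar X_i\right|\sqrt{\sum_i (\sigma_i/\bar X_i)^2},
\qquad
\nu_{eff} = \frac{\left(\sigma_P/\prod_i \bar X_i\right)^4}
{\sum_i \frac{1}{n_i-1}(\sigma_i/\bar X_i)^4},$$
the Welch-Satterthwaite effective degrees of freedom. Group comparisons use
two-tailed Welch t-tests (consuming either raw samples or
mean/SEM/$\nu_{eff}$ summaries) and one-way ANOVA across locations.
Tonotopic gradients are weighted linear regressions with weights
$1/\mathrm{SEM}^2$.

**Slope comparison.** Two gradients are compared by
$t = (b_1-b_2)/\sqrt{se_1^2+se_2^2}$. The degrees of freedom default to the
pooled residual degrees of freedom of the two fits. A Welch-Satterthwaite
combination is available (`df_method = "welch"`), but with 3-4 group means
per gradient each fit has only 1-2 residual df and the Welch df collapses
toward 1, making the test so conservative that a 23-sigma slope difference
fails at the 5% level; the pooled convention is the one under which the
study-scale gradient contrasts behave sensibly, so it is the default.

## 3. The synthetic-data generator

The generator's defaults *are* the study conditions: seven cohort groups
(outer hair cells at 1, 2, 4 kHz; inner at 1, 2, 4, 15 kHz) with the
published group sizes and group means for bundle stiffness, disruption
offset, negative excursion, creep and their SEMs. Per-cell scatter is set to
$\mathrm{SEM}\times\sqrt{n}$ so a cohort at the published $n$ attains the
published SEM. Parameters are drawn from truncated normals whose location is
moment-matched so that the *truncated* mean equals the prior mean (naive
truncation at zero would, for example, inflate a gating fraction of 0.22
with SD 0.17 to about 0.25). Each cell draws from its own stream derived
from the master seed, so cohorts are reproducible under partial re-runs.
`rnorm_trunc(..., stratified = TRUE)` additionally offers Latin-hypercube
stratification of the CDF - identical marginals, near-zero Monte Carlo error
on the ensemble mean - used where an ensemble statistic rather than
realization scatter is the quantity of interest (the acceptance script's
parameter-recovery runs).

Quantities the study reports only as grand means (gating fraction 22 +/- 2%
over 71 cells, negative excursion -26 +/- 2 nm over 83 cells) have separate
ensemble priors in `default_ensemble_priors()`.

**Fixtures.** Per-location morphology ($h$, $W$, $N_{SP}$), projection
factors $\gamma$, tip-link counts $N_{TL}$, and the per-location gating
fractions are *internally consistent fixtures*, not published facts: they
were solved, once, so that the deterministic chain
$K_{SP} = (1-r)K_{HB}$, $\kappa = K_{SP}h^2/N_{SP}$,
$k_{GS} = rK_{HB}/(\gamma^2 N_{TL})$, $T_R = K_{SP}\Delta X_R$,
$t_R = T_R/(\gamma N_{TL})$ reproduces the published group-mean stiffnesses
and tensions, and so that the geometry factors fall inside the calibrated
ranges (1.27-1.65 for inner, 1.12-1.47 for outer hair cells). Four
consequences are worth knowing:

* The per-location gating fraction is not constant: the published products
  imply $r \approx 0.20$ for 1-kHz and $\approx 0.36$ for 4-kHz outer hair
  cells, with the ensemble mean at 22%.
* The fixture $\gamma$ values do not follow the idealized
  $\gamma \propto 1/h$ scaling exactly (that scaling is what
  `projection_factor()` implements for generated series); they absorb the
  per-location constraints instead.
* The published group means are themselves mutually inconsistent at the
  ~1 SEM level, because each quantity was averaged over a different cell
  sample. For example, resting and maximal single-link tension at the
  inner-hair-cell 4-kHz location cannot both sit at their published centers
  for any pivot stiffness once the offset and excursion are fixed, since
  $t_{max} - t_R = t_R\,|\Delta X_{Ca}|/\Delta X_R$. The fixtures therefore
  sit within two published SEMs of every main-text value rather than
  exactly on all of them.
* The inner-hair-cell rotational stiffness is fixed per location at
  (0.4, 0.4, 0.6, 0.7) fN m/rad - the study reports a doubling between the
  2- and 4-kHz locations with an ensemble mean of 0.5 - because a uniform
  0.5 would force basal bundles too small to keep the geometry factor in
  its calibrated range.

**Trace conventions** (the study prints none of these time constants; all
are package conventions):

| Parameter | Default | Why |
|---|---|---|
| creep time constant | 20 ms | creep completes within the 100-ms step |
| creep onset delay | 10 ms | the slow phase starts just past the 5-10 ms stiffness window, so the early window isolates the elastic response and the end-of-step deflection exceeds it by exactly the creep fraction |
| position / current noise SD | 2 nm / 10 pA | published SEMs attainable at published n |
| iontophoresis dip and relaxation time constants | 50 / 100 ms | dip and recovery resolved at 2.5-25 kHz sampling |
| dwell at the negative extremum | 20 ms | the extremum survives 5-ms smoothing exactly |
| channel activation | Boltzmann, midpoint 0, slope 20 nm | resting open probability 1/2 |
| disrupted-state creep | 2% of intact | creep collapses upon tip-link disruption |

The generator is phenomenological: no myosin/Ca kinetics, no gating
compliance (force-displacement relations are generated, and measured,
linear), no photodiode nonlinearity (a warning flags excursions beyond the
+/-150 nm monitor range). Passing tests therefore show that the estimators
invert the stated generative model at realistic noise - not that they are
robust to every artifact of real recordings (drift, seal instability,
nonstationary noise).

## 4. Numerical choices

* **Ellipsoid radius near the sphere.** For $|\phi - 1| < 10^{-4}$ the
  bracket is evaluated by its series
  $8/3 - \tfrac{16}{15}(\phi-1) + \tfrac{52}{105}(\phi-1)^2$, avoiding the
  $0/0$ cancellation; the closed form and the series agree to well below
  the formula's own slope across the switch. Axes passed in the wrong order
  are swapped with a warning.
* **$\beta(w)$** returns its limit 1 below $w = 10^{-8}$ and matches
  adaptive quadrature of the profile integral to $10^{-9}$ relative error
  over $w \in [10^{-3}, 50]$.
* **Velocity-profile fitting** uses Levenberg-Marquardt (`minpack.lm`) with
  initial values from the sample maximum and the quarter-height distance
  ($v(A) = V_{max}/4$).
* **Calibration regression** fits an intercept (expected ~0) rather than
  forcing the line through the origin, exposing un-nulled steady-state flow.
* **Saturating current** is the difference between the all-open and
  all-closed plateaus of the 2-ms-smoothed current, each the mean of
  samples within 2% of the respective extreme; the stimulus is declared
  non-saturating if widening the band to 10% moves the estimate by more
  than 3% (a peaked, non-dwelling response fails this flatness check).
  A flat zero trace returns 0 with a disrupted-links flag.
* **Iontophoresis features**: 5-ms moving-average smoothing; the negative
  extremum is the mean of the smoothed trace within +/-5 ms of its minimum
  between step onset and the polarity reversal (annotated, else the
  smoothed-derivative zero crossing after the minimum); the steady offset
  is the mean over the final 20% of the record minus the pre-step baseline
  (at least 200 ms). Both features are invariant to constant baseline
  shifts; baseline drift beyond 5 nm sets a quality flag. Disruption is
  inferred from the companion current channel (transduction abolished).
* **Degenerate inputs**: sub-noise early deflections make the creep ratio
  undefined (error rather than a wild value); a disrupted response smaller
  than the intact one clamps $r$ to 0 with a warning; zero-variance groups
  short-circuit the ANOVA and Welch test to their exact null answers.

## 5. Testing strategy and problem sizes

Unit tests freeze independent oracle values (20-digit symbolic evaluations
of the ellipsoid radius, hand-evaluated propagation examples, quadrature of
the profile integral) and check estimator round-trips on noiseless traces
exactly. Property tests loop over randomized inputs under fixed seeds:
stiffness conservation ($K_{GS}+K_{SP}=K_{HB}$ and the per-element
recomposition), tension ordering ($t_{max} \ge t_R$), the
Welch-Satterthwaite bound ($\nu_{eff} \le \sum(n_i-1)$), monotonicity of the
tonotopic map, and nominal type-I error (5%) of the tests on null
simulations at 2,000 replicates.

Cohort-level recovery runs simulate at the published group sizes
(129 cells across 7 groups; well under a minute per cohort). Because the
per-cell scatter is $\mathrm{SEM}\sqrt n$ by design, a single cohort's group
mean jitters with SD of about one SEM; recovery tests therefore average
three replicate cohorts (distinct sub-seeds) and require the published
value within two published SEMs - testing the estimators' central tendency
rather than one realization. The full suite runs in well under a minute on
one CPU.

## 6. Known limitations

* The ellipsoid and cylinder drag formulas assume unbounded fluid; wall
  effects at the apical surface are not modeled (they bias the calibration,
  not the package's inversion of it).
* Tensions and stiffnesses are reported along the bundle's symmetry axis;
  if tip links run at an angle to it, per-link values underestimate the
  true ones, more so for the V-shaped outer-hair-cell bundles.
* The unitary-current interpolation for outer hair cells extrapolates below
  the 4-kHz anchor (with a warning); apical unitary currents are not
  directly measured.
* Whether the displacement in the 5-10 ms window should be a point sample
  or a window mean is unspecified in the source conventions; the package
  uses the mean, which is unbiased under the generator's creep-onset
  convention but would slightly mix in creep if the slow phase started
  earlier.
* The generator emulates statistical structure, not biophysics: conclusions
  about real recordings require the real artifacts (drift, nonstationary
  noise, gating compliance) that it deliberately omits.
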