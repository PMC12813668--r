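---
title: "Models and methods behind flightscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind flightscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flightscope)
library(dplyr)
```

flightscope studies the flight performance of large waterbirds — the worked
default is the great cormorant (*Phalacrocorax carbo sinensis*) — from
ornithodolite observations: time-stamped laser range, azimuth and elevation
of a flying bird, together with a mast anemometer and balloon wind
soundings. This vignette explains the models the package implements, the
choices made where the design was genuinely open, and what the synthetic
validation world does and does not establish.

## The mechanical power curve and its characteristic speeds

Power required for level flapping flight is modelled with the classic
fixed-wing decomposition

$$P(V) = \underbrace{\frac{2k(mg)^2}{\pi b^2 \rho V}}_{\text{induced}} +
\underbrace{\tfrac12 \rho V^3 S_b C_{Db}}_{\text{parasite}} +
P_{\text{pro}},$$

with $m$ body mass (kg), $b$ wingspan (m), $\rho$ air density
(1.225 kg m$^{-3}$ by default — sea level, appropriate for coastal work),
$k$ the induced drag factor (1.2 for flapping flight), $S_b = 0.00813\,
m^{0.666}$ m$^2$ the allometric body frontal area, and $C_{Db}$ the body
drag coefficient. The two fundamental optima follow in closed form:
the minimum power speed $V_{mp}$ (argmin of $P$) and the maximum range
speed $V_{mr}$ (argmin of $P/V$, i.e. minimum energy per distance). For
the two-term curve $V_{mr} = 3^{1/4} V_{mp} \approx 1.32\,V_{mp}$ exactly,
and

$$V_{mp} = 0.807\,\frac{k^{1/4} m^{1/2} g^{1/2}}
{\rho^{1/2} b^{1/2} S_b^{1/4} C_{Db}^{1/4}}.$$

$C_{Db}$ is the contentious parameter; the package tabulates 0.1, 0.2 and
0.27, the values in current use for large birds:

```{r}
predict_speeds(cormorant_morphology())
```

**Profile power.** $V_{mr}$ is reported for the "ultimate maximum
lift-to-drag" case — profile power excluded — which is what makes the
$3^{1/4}$ ratio exact. Where a full curve is needed (the muscle-power
analysis below), profile power is included with the simplest published
closure: constant with speed, $P_{\text{pro}} = (C_{pro}/AR)\,P_{am}$ with
$C_{pro} = 8.4$, $AR = b^2/S$ the aspect ratio, and $P_{am}$ the absolute
minimum power of the two-term curve. This is a deliberate,
documented approximation: published feasibility tables for cormorants use
an unstated profile treatment, so the package asserts the *pattern* of
feasibility (monotone in muscle fraction and specific power), not exact
maximum-speed values. Under this closure a few marginal cells sit on the
other side of the feasibility boundary than tables computed with other
closures — e.g. the 17% muscle fraction at $C_{Db} = 0.27$ and
100 W kg$^{-1}$ misses feasibility by about 3% of the required power.

**Muscle-power limit.** Power available is
`specific power × muscle fraction × mass`; the maximum level airspeed is
the upper root of $P(V) = P_{av}$, found by bracketed root search from
$V_{mp}$ up to a 60 m s$^{-1}$ ceiling at $10^{-6}$ m s$^{-1}$ tolerance.
Infeasibility ($P_{av}$ below the curve minimum) is a typed result
(`feasible = FALSE`), never an exception; an un-bracketable search (power
line above the curve at the ceiling) is a distinct error.

**Best glide.** The glide polar adds a wing profile drag area
$S\,C_{Dpro}$ to the body term; with $C_{Dpro} = 0$ the best-glide speed
reduces exactly to the profile-free $V_{mr}$. Published cormorant
best-glide values depend on an unstated $C_{Dpro}$, so the coefficient is
left configurable rather than pinned.

## Wind model

Anemometer readings $V_{an}$ at mast height $h_{an}$ (5 m in the default
setup) are corrected for surface friction with the logarithmic wind
profile: friction speed $V_{fr} = \kappa V_{an}/\ln(h_{an}/h_0)$ and
$V(h) = (V_{fr}/\kappa)\ln(h/h_0)$, with von Karman's constant
$\kappa = 0.42$ and roughness height $h_0 = 0.05$ m. The profile is zero
at $h_0$ and passes exactly through $V_{an}$ at mast height — both
properties are tested to $10^{-12}$. Above a 15-m blend height balloon
soundings take over: linear interpolation in speed, shortest-arc
interpolation in direction, constant extrapolation above the top level.
Requesting wind above the blend height without a balloon profile is an
explicit error; the surface law is never silently extrapolated upward.

Two conventions are enforced package-wide: wind *inputs* are
meteorological FROM-directions, all internal vectors are motion-TOWARD
(one tested conversion function), and all compass directions are degrees
clockwise from north.

Open choices, decided once: the wind for a run is the vector mean of all
1-Hz anemometer samples within the run's time span plus 30 s padding
(matching the instrument's 1-s cadence); balloon profiles are chosen
nearest in release time with no temporal blending (soundings are hourly
or more frequent, so blending would fabricate smoothness).

## Track processing

Fixes are converted to a flat-earth local frame centred on the instrument
(ranges are below ~2.5 km, so curvature and refraction are negligible;
the round trip is tested to $10^{-9}$ m). The per-run ground vector is the
endpoint displacement over elapsed time: the unit of observation is one
run's mean velocity, and endpoint displacement gives exactly that
regardless of how many fixes the run contains. Airspeed follows from the wind triangle
$\vec V_a = \vec V_g - \vec V_w$ in the horizontal plane; vertical speed
is carried separately. Tail components are signed (positive assists);
side components are positive toward the bird's right, and the statistical
stage consumes their absolute value. Runs that fail any step are reported
with an error message, never silently dropped.

## Circular statistics and wind drift

Mean direction and resultant length $r$ come from the unit-vector sum;
the Rayleigh test uses $Z = nr^2$ with the standard series p-value
(its type-I error is verified at $0.05 \pm 0.01$ over $10^4$ uniform
samples), and mean directions are compared with the Watson–Williams
F-test including the $1 + 3/(8\hat\kappa)$ concentration correction,
with a non-fatal validity warning when the pooled $r < 0.45$.

Drift is quantified by splitting tracks into wind-from-left and
wind-from-right groups relative to the overall mean track (exact head or
tail winds are excluded and counted) and computing

$$b_{\text{track}} = \frac{T_1 - T_2}{\alpha_1 - \alpha_2},
\qquad \alpha_i = T_i - H_i,$$

with all differences on the signed shortest arc. This is the unique
linear form with the two anchor properties: identical tracks give
$b = 0$ (full compensation), identical headings give $b = 1$ (full
drift). Values below 0.1 are classified as complete compensation.

## The airspeed model

Airspeed is modelled by ordinary least squares with behaviour
(spring migration, autumn migration, local movement) as a fixed category
and vertical speed, tail-wind component, absolute side-wind component and
log flock size each *nested within behaviour*: a separate slope per
behaviour level with no shared main-effect slope. Backward elimination
removes whole nested blocks — never single slopes — by block F-test,
least significant first, refitting each step, while the block p exceeds
$\alpha = 0.05$; ties in p are broken by removing the smaller F. The
behaviour category itself is never a candidate for removal: it is the
design's organising factor, and the least-squares means per behaviour are
a required output regardless of significance. Rank deficiency (e.g. a
zero-variance covariate) is an explicit error naming the collinear terms.

Behaviour contrasts are Tukey-HSD-adjusted pairwise differences of the
least-squares means (via emmeans). One-sample comparisons of observed
mean airspeeds against predicted characteristic speeds are one-sided
t-tests in the direction asserted. The altitude analysis regresses
altitude on the tail-wind component, overall and per behaviour. All of
this feeds a six-prediction scorecard (seasonal speed ordering, wind
response of airspeed, drift compensation, climb-rate trade-off, flock
size, altitude–wind response), each verdict carrying the statistic and
p-value it was decided on, with explicit gaps when an upstream stage is
missing.

## The synthetic world, and what passing it shows

Because no raw tracks are publicly deposited, validation runs on
synthetic sessions with known truth. The generator emulates the study's
structure with these defaults, chosen once: goal track 197°; winds mostly
from WSW (mean 247.5°, sd 40°; 6 ± 2 m s$^{-1}$ at the 5-m mast);
per-behaviour true airspeeds of 18.85 ± 2.82, 16.87 ± 1.74 and
17.95 ± 1.81 m s$^{-1}$ with sample sizes 13/63/64; log-uniform flock
sizes 1–100; log-normal altitudes clamped to 2–150 m; vertical speeds
N(0, 0.15) m s$^{-1}$ (most birds fly nearly level over water);
instrument noise of 2 m in range and 0.1° in the angles, applied in
instrument coordinates; 3–8 fixes per run at 3-s cadence. Birds fly
straight at constant velocity within a run — runs span seconds, and the
two-fix minimum makes any richer kinematics unidentifiable. The heading
rule interpolates between full compensation (track equals goal) and full
drift (heading equals goal) via the drift parameter $\beta$; when the
crosswind exceeds the airspeed, compensation falls back to the maximum
90° crab and is flagged. The truth wind field is exactly the structure
the pipeline assumes: log law below 15 m, constant free stream above,
reported by a per-run balloon profile pinned continuously at the blend
height.

What the passing tests establish: exact recovery of every kinematic
quantity at zero noise; per-behaviour mean airspeed recovery within
±0.2 m s$^{-1}$ at default noise with 200 runs; monotone recovery of the
planted $\beta$ with endpoint accuracy ±0.05 at 400 tracks per side; and
nominal type-I behaviour of the elimination procedure when covariates are
independent noise at the analysis-table level.

What they do not establish: real sessions have wind fields that change
within runs, non-straight flight, misclassified behaviours and
autocorrelated fix errors, none of which the generator emulates. One
subtlety the synthetic world *does* reproduce deliberately: measurement
errors are geometrically correlated (range noise acts along the line of
sight, angle noise across it), so airspeed errors and wind-component
errors share structure within a run. In fully synthetic end-to-end
sessions this — together with the genuine altitude–wind coupling induced
by the wind gradient, and the small spring sample (n = 13) — can produce
covariate slopes that pass the 5% threshold even though no behavioural
response is planted. That is a property of the measurement geometry real
ornithodolite data share, which is why type-I calibration is asserted at
the table level, and why scorecard verdicts on synthetic data should be
read against the planted truth, not as calibration claims.

## Numerical choices

* Root finding: bracketed `uniroot` from $V_{mp}$ to 60 m s$^{-1}$,
  tolerance $10^{-6}$ m s$^{-1}$.
* Angle wrapping: signed shortest arc in $(-180°, 180°]$ everywhere a
  difference is taken; directions reported in $[0°, 360°)$.
* A vanishing air vector leaves the heading undefined and flagged rather
  than arbitrary; a vanishing circular resultant flags the mean the same
  way; coincident crab angles leave $b_{\text{track}}$ undefined and
  flagged.
* Degenerate inputs (non-positive masses or speeds, zero-variance
  regressors, too-few observations) raise typed errors
  (`flightscope_domain_error`, `flightscope_rank_deficient`,
  `flightscope_no_profile`, `flightscope_unbounded_error`).
* Test problem sizes are chosen to make each statistical check decisive
  at desk scale: $10^4$ replicates for the Rayleigh calibration, 400
  tracks per side for drift recovery, 200 runs for end-to-end airspeed
  recovery, 200 replicate fits for elimination calibration.

## Known limitations

* The flapping-wing aerodynamic alternative to the fixed-wing model is
  out of scope; published numbers derived from it (and feasibility cells
  depending on its profile treatment) are not reproduced.
* Metabolic power, basal overheads and fuel-load dynamics are not
  modelled; all speeds are mechanical.
* The surface layer is neutral: no stability correction, gusts or
  turbulence spectra.
* Balloon winds are not interpolated in time; the nearest sounding wins.
* The printed 95% CIs in some published summary tables are slightly wider
  than mean ± t·se; the package reports the standard t-based interval.
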