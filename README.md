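# flightscope

Flight-performance analysis for ornithodolite bird tracks, built around
the question of whether large waterbirds — the worked default is the
great cormorant (*Phalacrocorax carbo sinensis*, ~2.55 kg) — have enough
flight-muscle power to fly at ecologically appropriate speeds, or whether
the flight-for-diving muscle trade-off pins them near their minimum power
speed.

The package implements, as composable data-frame-in/tibble-out functions:

* **Flight mechanics** — the U-shaped mechanical power curve
  `P(V) = 2k(mg)²/(πb²ρV) + ½ρV³S_bC_Db [+ P_pro]` with body frontal area
  `S_b = 0.00813 m^0.666`; its characteristic speeds, the minimum power
  speed

  `V_mp = 0.807 k^¼ m^½ g^½ / (ρ^½ b^½ S_b^¼ C_Db^¼)`

  and the maximum range speed `V_mr = 3^¼ V_mp` (profile power excluded);
  best glide speed; and the muscle-power-limited maximum level airspeed
  with a typed infeasibility result.
* **Wind model** — logarithmic surface-layer correction of anemometer
  readings (`V_fr = κV_an/ln(h_an/h₀)`, zero at the roughness height,
  exact at mast height) blended at 15 m with balloon-sounded upper-air
  profiles.
* **Track processing** — ornithodolite fixes → local positions → per-run
  ground vectors → wind-triangle airspeed and heading
  (`V_a = V_g − V_w`), with tail/side wind components on both heading and
  track.
* **Circular statistics** — mean direction and resultant length r,
  Rayleigh and Watson–Williams tests, and the wind-drift index
  `b_track = (T₁−T₂)/(α₁−α₂)` (0 = full compensation, 1 = full drift).
* **Statistical pipeline** — nested linear model of airspeed (per-behaviour
  slopes, block-wise backward elimination), Tukey HSD behaviour
  contrasts, one-sample speed tests, altitude–wind regression, CV table,
  and a six-prediction scorecard of adaptive flight behaviour.
* **Synthetic data** — a seeded ornithodolite session generator with
  known ground truth (drift parameter, per-behaviour airspeeds, wind
  field, instrument noise) so every stage is testable end to end.

Fitted airspeed models support broom-style `tidy()`/`glance()` and
`autoplot()`; result tibbles chain with the pipe.

## Worked example

```r
library(flightscope)

# 1. model predictions for the default cormorant (2.55 kg, b = 1.35 m)
predict_speeds(cormorant_morphology())
#>   body_drag_coeff vmp_mps vmr_mps
#> 1            0.1     16.6    21.9
#> 2            0.2     14.0    18.4
#> 3            0.27    13.0    17.1

# 2. a synthetic field season with known truth, processed end to end
sim    <- simulate_session(scenario(seed = 1))
wf     <- wind_field(sim$anemometer, sim$balloons)
tracks <- process_session(sim$session, sim$runs, wf)
behaviour_speed_summary(tracks)
#>   behaviour            n mean_airspeed    sd    se ci_low ci_high
#> 1 autumn_migration    63          17.1  1.68 0.211   16.6    17.5
#> 2 local_movement      64          17.9  1.42 0.178   17.5    18.3
#> 3 spring_migration    13          19.5  2.30 0.637   18.1    20.9

# 3. drift analysis: the generator's drift_beta = 0 should come back as
#    near-complete compensation
estimate_drift(tracks)[, c("T1", "H1", "T2", "H2", "b_track", "classification")]
#>     T1    H1    T2    H2 b_track classification
#> 1 197.  190.  197.  212.  0.0140 complete compensation

# 4. the nested airspeed model and the prediction scorecard
model     <- fit_airspeed_model(tracks)
contrasts <- pairwise_behaviour_contrasts(model)
altitude  <- altitude_wind_regression(tracks)
evaluate_predictions(model, estimate_drift(tracks), contrasts, altitude)
#>   prediction supported evidence
#> 1          1 TRUE      spring-autumn |t|=5.67 p=2.65e-07; local-autumn |t|=2.71 p=0.0208
#> 2          2 TRUE      tail slope -0.325 (p=0.00678) in spring_migration; ...
#> 3          3 TRUE      b_track = 0.014 (complete compensation)
#> 4          4 FALSE     vz eliminated
#> 5          5 TRUE      logN slope 1.12 (p=0.000876) in spring_migration
#> 6          6 FALSE     slope -2.28 m per m/s (p=0.00677) in group 'local_movement'
```

Reading the scorecard against the planted truth: predictions 1 and 3 are
genuine — the generator plants faster spring/local airspeeds and full
drift compensation, and both are recovered. No airspeed–wind,
climb-rate, or flock-size response is planted, so verdicts 2 and 5 here
are chance findings in the small spring sample (n = 13) amplified by the
geometrically correlated measurement errors the generator deliberately
reproduces, and the negative altitude–wind slope in 6 is the mechanical
imprint of the wind gradient (higher birds meet stronger headwinds), not
a behavioural choice. The methods vignette
(`vignettes/flightscope-methods.Rmd`) discusses this in detail.

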