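# Default synthetic ornithodolite scenario: coastal autumn conditions,
# goal track 197 deg, WSW winds, 5-m anemometer mast.
seed: 1
goal_deg: 197
drift_beta: 0
behaviours:
  - {behaviour: spring_migration, n_runs: 13, mean_airspeed: 18.85, sd_airspeed: 2.82}
  - {behaviour: autumn_migration, n_runs: 63, mean_airspeed: 16.87, sd_airspeed: 1.74}
  - {behaviour: local_movement,   n_runs: 64, mean_airspeed: 17.95, sd_airspeed: 1.81}
wind_speed_mean: 6
wind_speed_sd: 2
wind_dir_mean: 247.5
wind_dir_sd: 40
sigma_range: 2
sigma_azimuth: 0.1
sigma_elevation: 0.1
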