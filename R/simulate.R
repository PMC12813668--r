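# Synthetic ornithodolite sessions with known ground truth. Each simulated
# run is a bird (or flock) flying straight at constant velocity: a true
# airspeed drawn per behaviour, a heading set by the drift parameter beta
# (0 = full compensation so the track equals the goal direction, 1 = full
# drift so the heading equals the goal), and the wind triangle determines
# the ground vector. Fixes are observed from the instrument origin and
# noise is applied in instrument coordinates (range, azimuth, elevation),
# as the real instrument errs. The same wind structure the pipeline
# assumes generates the data: a log-law surface layer below the blend
# height, constant free-stream wind above it, reported via a balloon
# profile per run.

#' Simulation scenario
#'
#' Collects every knob of the synthetic world. Defaults echo the coastal
#' cormorant study conditions: goal direction 197 deg, winds mostly from
#' WSW, per-behaviour true airspeed distributions
#' (spring 18.85 +/- 2.82, autumn 16.87 +/- 1.74, local 17.95 +/- 1.81
#' m s^-1) with the study's sample sizes (13/63/64), altitudes of a few
#' to ~150 m, a 5-m anemometer mast, and instrument noise of 2 m in range
#' and 0.1 deg in the angles.
#'
#' @param seed RNG seed; the whole session is reproducible from it.
#' @param goal_deg Goal (intended track) direction, compass degrees.
#' @param drift_beta Drift parameter in \[0, 1\]: 0 full compensation,
#'   1 full drift.
#' @param behaviours Tibble with columns `behaviour`, `n_runs`,
#'   `mean_airspeed`, `sd_airspeed`.
#' @param wind_speed_mean,wind_speed_sd Per-run anemometer wind speed
#'   distribution (m s^-1, truncated at 0.1).
#' @param wind_dir_mean,wind_dir_sd Per-run wind FROM-direction
#'   distribution (deg).
#' @param altitude_meanlog,altitude_sdlog,altitude_range Log-normal
#'   altitude distribution, clamped to the range (m).
#' @param vz_sd Vertical speed sd (m s^-1), mean zero.
#' @param flock_max Flock sizes are log-uniform on 1..`flock_max`.
#' @param sigma_range,sigma_azimuth,sigma_elevation Instrument noise
#'   (m, deg, deg).
#' @param fix_interval_s Time between fixes in a run (s).
#' @param n_fixes_range Inclusive range of fixes per run (minimum 2).
#' @param run_spacing_s Time between run starts (s).
#' @param anemometer_height_m,instrument_height_m Mast and instrument
#'   heights above the surface (m).
#' @param start_distance_range Range of initial bird distances from the
#'   instrument (m).
#' @param surface A [surface_params()].
#' @return An object of class `flight_scenario`.
#' @export
scenario <- function(seed = 1L,
                     goal_deg = 197,
                     drift_beta = 0,
                     behaviours = tibble::tribble(
                       ~behaviour,          ~n_runs, ~mean_airspeed, ~sd_airspeed,
                       "spring_migration",  13L,     18.85,          2.82,
                       "autumn_migration",  63L,     16.87,          1.74,
                       "local_movement",    64L,     17.95,          1.81
                     ),
                     wind_speed_mean = 6, wind_speed_sd = 2,
                     wind_dir_mean = 247.5, wind_dir_sd = 40,
                     altitude_meanlog = log(20), altitude_sdlog = 0.9,
                     altitude_range = c(2, 150),
                     vz_sd = 0.15,
                     flock_max = 100,
                     sigma_range = 2, sigma_azimuth = 0.1,
                     sigma_elevation = 0.1,
                     fix_interval_s = 3,
                     n_fixes_range = c(3, 8),
                     run_spacing_s = 120,
                     anemometer_height_m = 5,
                     instrument_height_m = 2,
                     start_distance_range = c(300, 800),
                     surface = surface_params()) {
  stopifnot(drift_beta >= 0, drift_beta <= 1,
            sigma_range >= 0, sigma_azimuth >= 0, sigma_elevation >= 0,
            all(behaviours$sd_airspeed >= 0), n_fixes_range[1] >= 2)
  structure(as.list(environment()), class = "flight_scenario")
}

#' Heading and ground vector under a drift strategy
#'
#' Implements the wind triangle for a bird aiming at `goal_deg` with true
#' airspeed `airspeed` in wind (`wind_east`, `wind_north`). With
#' `beta = 0` the heading is crabbed into the wind so the resulting track
#' equals the goal (full compensation); with `beta = 1` the heading equals
#' the goal and the wind displaces the track (full drift); intermediate
#' values rotate the heading by `(1 - beta)` times the full-compensation
#' crab angle. When the crosswind exceeds the airspeed full compensation
#' is impossible; the bird falls back to the maximum 90-degree crab and
#' the result is flagged.
#'
#' @param airspeed True airspeed (m s^-1), positive.
#' @param wind_east,wind_north Wind vector (motion toward, m s^-1).
#' @param beta Drift parameter in \[0, 1\].
#' @param goal_deg Goal direction (deg).
#' @return A one-row tibble with `heading_deg`, `track_deg`,
#'   `ground_east`, `ground_north`, `ground_speed`, `crab_deg`,
#'   `infeasible_compensation`.
#' @examples
#' make_bird_motion(10, wind_east = -5, wind_north = 0, beta = 0,
#'                  goal_deg = 180)
#' @export
make_bird_motion <- function(airspeed, wind_east, wind_north, beta,
                             goal_deg) {
  if (!is.finite(airspeed) || airspeed <= 0)
    abort("`airspeed` must be strictly positive.",
          class = "flightscope_domain_error")
  stopifnot(beta >= 0, beta <= 1)
  # crosswind component, positive toward the bird's right of the goal
  cross <- wind_components(wind_east, wind_north, goal_deg)$side_mps
  infeasible <- abs(cross) > airspeed
  crab_full <- if (infeasible) -sign(cross) * 90 else
    -rad2deg(asin(cross / airspeed))
  heading <- wrap_deg(goal_deg + (1 - beta) * crab_full)
  u <- dir_to_unit(heading)
  ge <- as.numeric(airspeed * u[, "east"] + wind_east)
  gn <- as.numeric(airspeed * u[, "north"] + wind_north)
  tibble(
    heading_deg = heading,
    track_deg = vec_to_dir(ge, gn),
    ground_east = ge, ground_north = gn,
    ground_speed = sqrt(ge^2 + gn^2),
    crab_deg = (1 - beta) * crab_full,
    infeasible_compensation = infeasible
  )
}

# log-law surface value, or constant free stream above the blend height;
# the truth uses exactly the structure the pipeline assumes
true_wind_speed_at <- function(h, v_an, scn) {
  blend <- scn$surface$blend_height
  wind_speed_at_height(pmin(h, blend), v_an, scn$anemometer_height_m,
                       scn$surface)
}

#' Simulate a full ornithodolite session
#'
#' Draws per-run truth (behaviour, true airspeed, altitude, vertical
#' speed, flock size, wind), flies each bird in a straight line through
#' the wind field, observes noisy fixes from the instrument, and emits the
#' four tables the processing pipeline consumes plus the truth record.
#' Bit-identical output for identical seeds.
#'
#' @param scn A [scenario()].
#' @return A list of tibbles: `session` (fixes), `runs` (metadata),
#'   `anemometer`, `balloons`, `truth`.
#' @examples
#' sim <- simulate_session(scenario(seed = 7))
#' names(sim)
#' @export
simulate_session <- function(scn) {
  stopifnot(inherits(scn, "flight_scenario"))
  withr::local_seed(scn$seed)

  beh <- scn$behaviours
  runs_truth <- purrr::pmap(beh, function(behaviour, n_runs, mean_airspeed,
                                          sd_airspeed) {
    tibble(behaviour = behaviour,
           airspeed_true = stats::rnorm(n_runs, mean_airspeed, sd_airspeed))
  }) |> dplyr::bind_rows()
  n <- nrow(runs_truth)
  runs_truth <- runs_truth |>
    mutate(
      run_id = row_number(),
      airspeed_true = pmax(.data$airspeed_true, 1),
      altitude_true = pmin(pmax(
        stats::rlnorm(n, scn$altitude_meanlog, scn$altitude_sdlog),
        scn$altitude_range[1]), scn$altitude_range[2]),
      vz_true = stats::rnorm(n, 0, scn$vz_sd),
      flock_size = pmax(1L, as.integer(round(
        exp(stats::runif(n, 0, log(scn$flock_max)))))),
      v_an = pmax(0.1, stats::rnorm(n, scn$wind_speed_mean,
                                    scn$wind_speed_sd)),
      wind_from_surface = wrap_deg(stats::rnorm(n, scn$wind_dir_mean,
                                                scn$wind_dir_sd)),
      t_start = (row_number() - 1) * scn$run_spacing_s,
      n_fixes = {
        choices <- seq(scn$n_fixes_range[1], scn$n_fixes_range[2])
        if (length(choices) == 1) rep(choices, n) else
          sample(choices, n, replace = TRUE)
      },
      start_dist = stats::runif(n, scn$start_distance_range[1],
                                scn$start_distance_range[2]),
      start_bearing = stats::runif(n, 0, 360)
    )

  # wind at the bird's altitude and the resulting motion
  wind_alt <- purrr::pmap(
    list(runs_truth$altitude_true, runs_truth$v_an,
         runs_truth$wind_from_surface),
    function(h, v_an, dirf) {
      sp <- true_wind_speed_at(h, v_an, scn)
      wind_from_to_vector(sp, dirf)
    }) |> dplyr::bind_rows()
  motion <- purrr::pmap(
    list(runs_truth$airspeed_true, wind_alt$east, wind_alt$north),
    function(va, we, wn) make_bird_motion(va, we, wn, scn$drift_beta,
                                          scn$goal_deg)
  ) |> dplyr::bind_rows()

  truth <- dplyr::bind_cols(
    runs_truth |> select("run_id", "behaviour", "airspeed_true",
                         "altitude_true", "vz_true", "flock_size",
                         "v_an", "wind_from_surface", "t_start"),
    wind_alt |> rename(wind_east = "east", wind_north = "north"),
    motion |> rename(heading_true = "heading_deg",
                     track_true = "track_deg",
                     ground_speed_true = "ground_speed")
  ) |> mutate(beta = scn$drift_beta)

  # noisy fixes in instrument coordinates
  session <- purrr::pmap(
    list(truth$run_id, runs_truth$t_start, runs_truth$n_fixes,
         runs_truth$start_dist, runs_truth$start_bearing,
         truth$ground_east, truth$ground_north,
         truth$altitude_true, truth$vz_true),
    function(id, t0, nf, dist, bear, ge, gn, alt, vz) {
      u <- dir_to_unit(bear)
      tt <- t0 + (seq_len(nf) - 1) * scn$fix_interval_s
      rel <- (seq_len(nf) - 1) * scn$fix_interval_s
      east <- dist * u[, "east"] + ge * rel
      north <- dist * u[, "north"] + gn * rel
      height <- alt + vz * (rel - rel[length(rel)] / 2)
      fx <- position_to_fix(east, north, height, scn$instrument_height_m)
      tibble(
        run_id = id, time = tt,
        range_m = pmax(1, fx$range_m +
                         stats::rnorm(nf, 0, scn$sigma_range)),
        azimuth_deg = wrap_deg(fx$azimuth_deg +
                                 stats::rnorm(nf, 0, scn$sigma_azimuth)),
        elevation_deg = pmin(90, pmax(-90, fx$elevation_deg +
                                        stats::rnorm(nf, 0, scn$sigma_elevation)))
      )
    }) |> dplyr::bind_rows()

  runs <- truth |>
    mutate(species = "Phalacrocorax carbo", site = "A",
           instrument_height_m = scn$instrument_height_m) |>
    select("run_id", "species", "behaviour", "flock_size", "site",
           "instrument_height_m")

  # 1-Hz anemometer rows around each run with that run's surface wind
  anemometer <- purrr::pmap(
    list(runs_truth$t_start, runs_truth$n_fixes, runs_truth$v_an,
         runs_truth$wind_from_surface),
    function(t0, nf, v_an, dirf) {
      t1 <- t0 + (nf - 1) * scn$fix_interval_s
      tibble(time = seq(t0 - 40, t1 + 40),
             speed_mps = v_an, dir_from_deg = dirf,
             height_m = scn$anemometer_height_m)
    }) |> dplyr::bind_rows()

  # one balloon profile per run, released mid-run, reporting the constant
  # free-stream wind above the blend height (levels pinned so the profile
  # is continuous with the surface law at the blend height)
  blend <- scn$surface$blend_height
  balloons <- purrr::pmap(
    list(runs_truth$t_start, runs_truth$n_fixes, runs_truth$v_an,
         runs_truth$wind_from_surface),
    function(t0, nf, v_an, dirf) {
      sp <- true_wind_speed_at(blend, v_an, scn)
      tibble(release_time = t0 + (nf - 1) * scn$fix_interval_s / 2,
             height_m = c(blend, 50, 150, 300),
             speed_mps = sp, dir_from_deg = dirf)
    }) |> dplyr::bind_rows()

  list(session = session, runs = runs, anemometer = anemometer,
       balloons = balloons, truth = truth)
}

#' Write a simulated session to CSV files
#'
#' Writes `session.csv`, `runs.csv`, `anemometer.csv`, `balloons.csv` and
#' `truth.csv` into a directory.
#'
#' @param sim Output of [simulate_session()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(sim))
    readr::write_csv(sim[[nm]], file.path(dir, paste0(nm, ".csv")))
  invisible(dir)
}

#' Read a scenario from a YAML configuration
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [scenario()]; `behaviours` may be a list of records.
#' @return A `flight_scenario`.
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$behaviours))
    cfg$behaviours <- purrr::map(cfg$behaviours, as_tibble) |>
      dplyr::bind_rows() |>
      mutate(n_runs = as.integer(.data$n_runs))
  do.call(scenario, cfg)
}
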