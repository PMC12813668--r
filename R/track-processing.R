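# Ornithodolite track processing. Each fix is a time-stamped laser range,
# azimuth and elevation from the instrument; a run is >= 2 fixes on the
# same bird or flock. Positions are reconstructed in a flat-earth local
# frame centred on the instrument (ranges below ~2.5 km make earth
# curvature and refraction negligible), the per-run ground vector comes
# from the endpoint displacement over elapsed time, and the wind triangle
# V_a = V_g - V_w yields airspeed and heading.

#' Convert an ornithodolite fix to a local position
#'
#' @param range_m Laser range (m), positive; vectorised with the angles.
#' @param azimuth_deg Compass azimuth (deg).
#' @param elevation_deg Elevation above horizontal (deg), in \[-90, 90\].
#' @param instrument_height_m Instrument height above the surface (m).
#' @return A tibble with `east_m`, `north_m`, `height_m` (height above the
#'   surface).
#' @examples
#' fix_to_position(100, 90, 0, instrument_height_m = 3)
#' @export
fix_to_position <- function(range_m, azimuth_deg, elevation_deg,
                            instrument_height_m = 0) {
  if (any(!is.finite(range_m)) || any(range_m <= 0))
    abort("`range_m` must be strictly positive.",
          class = "flightscope_domain_error")
  if (any(elevation_deg < -90) || any(elevation_deg > 90))
    abort("`elevation_deg` must lie in [-90, 90].",
          class = "flightscope_domain_error")
  el <- deg2rad(elevation_deg)
  az <- deg2rad(azimuth_deg)
  tibble(
    east_m = range_m * cos(el) * sin(az),
    north_m = range_m * cos(el) * cos(az),
    height_m = range_m * sin(el) + instrument_height_m
  )
}

#' @rdname fix_to_position
#' @param east_m,north_m,height_m Local coordinates to convert back to
#'   instrument-frame range/azimuth/elevation.
#' @export
position_to_fix <- function(east_m, north_m, height_m,
                            instrument_height_m = 0) {
  dz <- height_m - instrument_height_m
  r <- sqrt(east_m^2 + north_m^2 + dz^2)
  tibble(
    range_m = r,
    azimuth_deg = vec_to_dir(east_m, north_m),
    elevation_deg = rad2deg(asin(pmin(1, pmax(-1, dz / r))))
  )
}

#' Per-run ground velocity
#'
#' The run's mean ground vector is the endpoint displacement divided by the
#' elapsed time; vertical speed likewise from the height change; altitude
#' is the time-weighted (trapezoidal) mean of fix heights.
#'
#' @param fixes A tibble of fixes in time order with columns `time`,
#'   `range_m`, `azimuth_deg`, `elevation_deg` (at least 2 rows).
#' @param instrument_height_m Instrument height above the surface (m).
#' @return A one-row tibble with `ground_east`, `ground_north`,
#'   `ground_speed`, `track_deg`, `vertical_speed`, `altitude_m`,
#'   `duration_s`, `n_fixes`, `time_mid`.
#' @export
run_velocity <- function(fixes, instrument_height_m = 0) {
  fixes <- as_tibble(fixes)
  if (nrow(fixes) < 2)
    abort("A run needs at least two fixes.", class = "flightscope_domain_error")
  if (any(diff(fixes$time) <= 0))
    abort("Fix times must be strictly increasing.",
          class = "flightscope_domain_error")
  pos <- fix_to_position(fixes$range_m, fixes$azimuth_deg,
                         fixes$elevation_deg, instrument_height_m)
  dt <- fixes$time[nrow(fixes)] - fixes$time[1]
  de <- pos$east_m[nrow(pos)] - pos$east_m[1]
  dn <- pos$north_m[nrow(pos)] - pos$north_m[1]
  dh <- pos$height_m[nrow(pos)] - pos$height_m[1]
  # trapezoidal time-weighted mean height
  tt <- fixes$time
  alt <- sum(diff(tt) * (utils::head(pos$height_m, -1) +
                           utils::tail(pos$height_m, -1)) / 2) / dt
  tibble(
    ground_east = de / dt, ground_north = dn / dt,
    ground_speed = sqrt(de^2 + dn^2) / dt,
    track_deg = vec_to_dir(de, dn),
    vertical_speed = dh / dt,
    altitude_m = alt,
    duration_s = dt, n_fixes = nrow(fixes),
    time_mid = (tt[1] + tt[length(tt)]) / 2
  )
}

#' Wind-triangle air vector
#'
#' Subtracts the wind vector from the ground vector in the horizontal
#' plane: \eqn{V_a = V_g - V_w}. A zero air vector leaves the heading
#' undefined (`NA`, flagged).
#'
#' @param ground_east,ground_north Ground-vector components (m s^-1).
#' @param wind_east,wind_north Wind-vector components (motion toward,
#'   m s^-1).
#' @return A one-row tibble with `airspeed`, `heading_deg`, `air_east`,
#'   `air_north`, `heading_defined`.
#' @examples
#' air_vector(0, -15, 0, -5)   # pure tailwind on a southbound bird
#' @export
air_vector <- function(ground_east, ground_north, wind_east, wind_north) {
  ae <- ground_east - wind_east
  an <- ground_north - wind_north
  spd <- sqrt(ae^2 + an^2)
  defined <- spd > 0
  tibble(
    airspeed = spd,
    heading_deg = ifelse(defined, vec_to_dir(ae, an), NA_real_),
    air_east = ae, air_north = an,
    heading_defined = defined
  )
}

#' Tail and side wind components
#'
#' Projects a wind vector onto a reference direction (a bird's heading or
#' track). The tail component is positive when the wind assists; the side
#' component is positive when the wind blows toward the bird's right.
#'
#' @param wind_east,wind_north Wind components (motion toward, m s^-1).
#' @param reference_deg Reference compass direction (deg).
#' @return A tibble with `tail_mps` and `side_mps`.
#' @examples
#' wind_components(0, -5, 180)  # wind moving south, bird heading south
#' @export
wind_components <- function(wind_east, wind_north, reference_deg) {
  u <- dir_to_unit(reference_deg)
  r <- dir_to_unit(reference_deg + 90)  # unit vector to the bird's right
  tibble(
    tail_mps = as.numeric(wind_east * u[, "east"] + wind_north * u[, "north"]),
    side_mps = as.numeric(wind_east * r[, "east"] + wind_north * r[, "north"])
  )
}

#' Process one tracked run through the wind triangle
#'
#' Composes [run_velocity()], [wind_at()] (anemometer samples averaged over
#' the run's time span plus padding), [air_vector()] and
#' [wind_components()] on both heading and track, recording where the wind
#' estimate came from.
#'
#' @param fixes Tibble of the run's fixes (see [run_velocity()]).
#' @param wf A [wind_field()].
#' @param instrument_height_m Instrument height above the surface (m).
#' @param wind_pad Extra half-window (s) around the run's time span for
#'   anemometer averaging.
#' @return A one-row tibble: ground vector, airspeed, heading, vertical
#'   speed, altitude, wind vector and provenance, and tail/side components
#'   on both heading and track.
#' @export
process_run <- function(fixes, wf, instrument_height_m = 0, wind_pad = 30) {
  rv <- run_velocity(fixes, instrument_height_m)
  h <- max(rv$altitude_m, wf$surface$roughness_height)
  pad <- rv$duration_s / 2 + wind_pad
  w <- wind_at(wf, h, rv$time_mid, pad = pad)
  av <- air_vector(rv$ground_east, rv$ground_north, w$east, w$north)
  ch <- wind_components(w$east, w$north, av$heading_deg)
  ct <- wind_components(w$east, w$north, rv$track_deg)
  dplyr::bind_cols(
    rv,
    tibble(airspeed = av$airspeed, heading_deg = av$heading_deg,
           heading_defined = av$heading_defined,
           wind_east = w$east, wind_north = w$north,
           wind_speed_mps = w$speed_mps, wind_from_deg = w$dir_from_deg,
           wind_provenance = w$provenance,
           tailwind_heading = ch$tail_mps, sidewind_heading = ch$side_mps,
           tailwind_track = ct$tail_mps, sidewind_track = ct$side_mps)
  )
}

#' Process a whole ornithodolite session
#'
#' Applies [process_run()] to every run in a session table and joins the
#' run metadata, producing the per-run analysis table (one row per
#' observation). Runs that fail a processing step are reported with an
#' `error` message in the output rather than dropped silently.
#'
#' @param session Tibble of fixes with columns `run_id`, `time`, `range_m`,
#'   `azimuth_deg`, `elevation_deg`.
#' @param runs Tibble of run metadata with columns `run_id`, `species`,
#'   `behaviour`, `flock_size`, `site`, `instrument_height_m`.
#' @param wf A [wind_field()].
#' @param wind_pad Anemometer averaging padding (s), see [process_run()].
#' @return A tibble with one row per run: metadata, kinematics, wind and
#'   components, `log_flock_size`, and an `error` column (`NA` on success).
#' @export
process_session <- function(session, runs, wf, wind_pad = 30) {
  session <- as_tibble(session); runs <- as_tibble(runs)
  out <- purrr::map(runs$run_id, function(id) {
    meta <- runs |> filter(.data$run_id == id)
    fx <- session |> filter(.data$run_id == id) |> arrange(.data$time)
    res <- tryCatch(
      process_run(fx, wf, meta$instrument_height_m[1], wind_pad),
      error = function(e) tibble(error = conditionMessage(e))
    )
    if (!"error" %in% names(res)) res$error <- NA_character_
    dplyr::bind_cols(meta, res)
  })
  dplyr::bind_rows(out) |>
    mutate(log_flock_size = log(.data$flock_size))
}

#' Read ornithodolite session files
#'
#' `read_session_csv()` reads the per-fix file (`run_id`, `time`,
#' `range_m`, `azimuth_deg`, `elevation_deg`); `read_runs_csv()` reads the
#' run-metadata sidecar (`run_id`, `species`, `behaviour`, `flock_size`,
#' `site`, `instrument_height_m`).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_session_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, comment = "#")
}

#' @rdname read_session_csv
#' @export
read_runs_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, comment = "#")
}
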