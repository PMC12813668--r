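# Surface-layer wind model. Anemometer readings at a known mast height are
# corrected for surface friction with the logarithmic wind profile:
#   V_fr = kappa * V_an / ln(h_an / h0)          (friction speed)
#   V(h)  = (V_fr / kappa) * ln(h / h0)          (speed at height h)
# so the profile is zero at the roughness height h0, passes exactly through
# the anemometer reading at h_an, and grows logarithmically above. Above a
# blend height (15 m here) balloon soundings take over.

#' Surface-layer parameters
#'
#' @param von_karman Von Karman's constant (0.42).
#' @param roughness_height Roughness height \eqn{h_0} (m) at which the wind
#'   speed is zero; 0.05 m for a water/low-coast surface.
#' @param blend_height Height (m) above which balloon profiles replace the
#'   surface log law.
#' @return An object of class `surface_params`.
#' @export
surface_params <- function(von_karman = 0.42, roughness_height = 0.05,
                           blend_height = 15) {
  if (!is.finite(roughness_height) || roughness_height <= 0 ||
      roughness_height >= blend_height)
    abort("Require 0 < roughness_height < blend_height.",
          class = "flightscope_domain_error")
  structure(list(von_karman = von_karman,
                 roughness_height = roughness_height,
                 blend_height = blend_height),
            class = "surface_params")
}

#' Friction wind speed
#'
#' Inverts the logarithmic wind profile at the anemometer height:
#' \eqn{V_{fr} = \kappa V_{an} / \ln(h_{an}/h_0)}.
#'
#' @param speed Anemometer reading \eqn{V_{an}} (m s^-1); vectorised.
#' @param height Anemometer height above the surface (m).
#' @param params A [surface_params()].
#' @return Friction speed(s) in m s^-1.
#' @examples
#' friction_speed(6, height = 5)
#' @export
friction_speed <- function(speed, height = 5, params = surface_params()) {
  if (any(!is.finite(height)) || any(height <= params$roughness_height))
    abort("Anemometer height must exceed the roughness height.",
          class = "flightscope_domain_error")
  if (any(speed < 0))
    abort("Wind speed must be >= 0.", class = "flightscope_domain_error")
  params$von_karman * speed / log(height / params$roughness_height)
}

#' Wind speed at height from the log law
#'
#' @param h Height(s) above the surface (m), at least the roughness height.
#' @inheritParams friction_speed
#' @return Wind speed(s) at `h` in m s^-1; zero at the roughness height,
#'   exactly the anemometer reading at the anemometer height.
#' @examples
#' wind_speed_at_height(10, speed = 6, height = 5)
#' @export
wind_speed_at_height <- function(h, speed, height = 5,
                                 params = surface_params()) {
  if (any(!is.finite(h)) || any(h < params$roughness_height))
    abort("`h` must be at least the roughness height.",
          class = "flightscope_domain_error")
  vfr <- friction_speed(speed, height, params)
  (vfr / params$von_karman) * log(h / params$roughness_height)
}

#' Wind field from anemometer and balloon data
#'
#' Bundles a 1-Hz anemometer log, zero or more balloon wind profiles and
#' the surface-layer parameters into an object that can answer "what was
#' the wind vector at height h at time t".
#'
#' @param anemometer A tibble with columns `time` (s), `speed_mps`,
#'   `dir_from_deg` (meteorological FROM-direction) and `height_m`.
#' @param balloons Optional tibble of balloon levels with columns
#'   `release_time` (s), `height_m`, `speed_mps`, `dir_from_deg`; heights
#'   must increase within each profile.
#' @param surface A [surface_params()].
#' @return An object of class `wind_field`.
#' @export
wind_field <- function(anemometer, balloons = NULL,
                       surface = surface_params()) {
  anemometer <- as_tibble(anemometer)
  req <- c("time", "speed_mps", "dir_from_deg", "height_m")
  if (!all(req %in% names(anemometer)))
    abort(paste("Anemometer log needs columns:", paste(req, collapse = ", ")))
  if (nrow(anemometer) == 0)
    abort("Anemometer log is empty.")
  if (!is.null(balloons)) {
    balloons <- as_tibble(balloons)
    reqb <- c("release_time", "height_m", "speed_mps", "dir_from_deg")
    if (!all(reqb %in% names(balloons)))
      abort(paste("Balloon data needs columns:", paste(reqb, collapse = ", ")))
    bad <- balloons |>
      group_by(.data$release_time) |>
      summarise(ok = all(diff(.data$height_m) > 0) && n() >= 1) |>
      filter(!.data$ok)
    if (nrow(bad) > 0)
      abort("Balloon profile heights must be strictly increasing.",
            class = "flightscope_domain_error")
  }
  structure(list(anemometer = anemometer, balloons = balloons,
                 surface = surface),
            class = "wind_field")
}

#' @export
print.wind_field <- function(x, ...) {
  np <- if (is.null(x$balloons)) 0 else
    length(unique(x$balloons$release_time))
  cat(sprintf(
    "<wind_field> %d anemometer samples, %d balloon profile(s), blend height %g m\n",
    nrow(x$anemometer), np, x$surface$blend_height))
  invisible(x)
}

# Effective anemometer sample near `time`: vector mean of all samples in
# [time - pad, time + pad] (falling back to the time-nearest sample),
# returned as speed + FROM-direction.
effective_anemometer_sample <- function(wf, time, pad = 0) {
  an <- wf$anemometer
  sel <- an |> filter(abs(.data$time - !!time) <= pad)
  if (nrow(sel) == 0) sel <- an[which.min(abs(an$time - time)), ]
  v <- wind_from_to_vector(sel$speed_mps, sel$dir_from_deg)
  e <- mean(v$east); n <- mean(v$north)
  list(speed = sqrt(e^2 + n^2),
       dir_from = vector_to_from_dir(e, n),
       height = sel$height_m[1])
}

surface_wind_vector <- function(wf, h, sample) {
  sp <- wind_speed_at_height(h, sample$speed, sample$height, wf$surface)
  wind_from_to_vector(sp, sample$dir_from)
}

balloon_wind_vector <- function(wf, h, time) {
  if (is.null(wf$balloons))
    abort("No balloon profile available above the blend height.",
          class = "flightscope_no_profile")
  releases <- unique(wf$balloons$release_time)
  rel <- releases[which.min(abs(releases - time))]
  prof <- wf$balloons |> filter(.data$release_time == rel) |>
    arrange(.data$height_m)
  if (h <= prof$height_m[1]) {
    sp <- prof$speed_mps[1]; dir <- prof$dir_from_deg[1]
  } else if (h >= prof$height_m[nrow(prof)]) {
    # constant extrapolation above the top level
    sp <- prof$speed_mps[nrow(prof)]; dir <- prof$dir_from_deg[nrow(prof)]
  } else {
    i <- findInterval(h, prof$height_m)
    w <- (h - prof$height_m[i]) / (prof$height_m[i + 1] - prof$height_m[i])
    sp <- (1 - w) * prof$speed_mps[i] + w * prof$speed_mps[i + 1]
    dir <- interp_dir(prof$dir_from_deg[i], prof$dir_from_deg[i + 1], w)
  }
  wind_from_to_vector(sp, dir)
}

#' Wind vector at a height and time
#'
#' Below the blend height the logarithmic surface law is applied to the
#' anemometer record (optionally vector-averaged over a time window);
#' above it, the time-nearest balloon profile is interpolated linearly in
#' speed and along the shortest arc in direction, with constant
#' extrapolation above the top level. Asking for a height above the blend
#' height without balloon data is an explicit error, never a silent
#' extrapolation of the surface law.
#'
#' @param wf A [wind_field()].
#' @param h Height above the surface (m).
#' @param time Time (s) used to pick anemometer samples / balloon profile.
#' @param pad Half-width (s) of the anemometer averaging window; 0 uses
#'   the single nearest sample.
#' @return A one-row tibble with `east`, `north` (motion-toward components,
#'   m s^-1), `speed_mps`, `dir_from_deg` and `provenance`
#'   (`"surface-log-law"` or `"balloon"`).
#' @examples
#' an <- tibble::tibble(time = 0, speed_mps = 6, dir_from_deg = 250,
#'                      height_m = 5)
#' wind_at(wind_field(an), h = 10, time = 0)
#' @export
wind_at <- function(wf, h, time, pad = 0) {
  stopifnot(inherits(wf, "wind_field"))
  if (!is.finite(h) || h < wf$surface$roughness_height)
    abort("`h` must be at least the roughness height.",
          class = "flightscope_domain_error")
  if (h <= wf$surface$blend_height) {
    sample <- effective_anemometer_sample(wf, time, pad)
    v <- surface_wind_vector(wf, h, sample)
    prov <- "surface-log-law"
  } else {
    v <- balloon_wind_vector(wf, h, time)
    prov <- "balloon"
  }
  tibble(east = v$east, north = v$north,
         speed_mps = sqrt(v$east^2 + v$north^2),
         dir_from_deg = vector_to_from_dir(v$east, v$north),
         provenance = prov)
}

#' Read anemometer and balloon CSV files
#'
#' `read_anemometer_csv()` expects columns `time`, `speed_mps`,
#' `dir_from_deg`, `height_m`. `read_balloon_csv()` accepts either a tidy
#' file with a `release_time` column (several profiles per file) or a
#' single-profile file with columns `height_m`, `speed_mps`, `dir_from_deg`
#' and a `# release_time: <seconds>` comment header.
#'
#' @param path File path.
#' @return A tibble suitable for [wind_field()].
#' @export
read_anemometer_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, comment = "#")
}

#' @rdname read_anemometer_csv
#' @export
read_balloon_csv <- function(path) {
  dat <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  if (!"release_time" %in% names(dat)) {
    header <- readLines(path, n = 5)
    m <- grep("^#\\s*release_time:", header, value = TRUE)
    if (length(m) == 0)
      abort("Balloon file lacks a release_time column or header.")
    dat$release_time <- as.numeric(sub("^#\\s*release_time:\\s*", "", m[1]))
  }
  dplyr::relocate(dat, "release_time")
}
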