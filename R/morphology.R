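#' Bird morphology
#'
#' Bundle of the morphological quantities that drive the flight-mechanical
#' model: body mass, wingspan, wing area and the flight-muscle fraction.
#'
#' @param mass_kg Body mass \eqn{m} (kg).
#' @param wingspan_m Tip-to-tip wingspan \eqn{b} (m).
#' @param wing_area_m2 Total wing area \eqn{S} (m^2), both wings plus the
#'   body section between the wing roots.
#' @param muscle_fraction Flight-muscle mass as a fraction of body mass
#'   (dimensionless, in (0, 1)).
#'
#' @return An object of class `bird_morphology` (a named list).
#' @examples
#' cormorant <- bird_morphology(2.55, 1.35, 0.224, muscle_fraction = 0.136)
#' aspect_ratio(cormorant)
#' @export
bird_morphology <- function(mass_kg, wingspan_m, wing_area_m2,
                            muscle_fraction = 0.136) {
  stopifnot(length(mass_kg) == 1, length(wingspan_m) == 1,
            length(wing_area_m2) == 1, length(muscle_fraction) == 1)
  if (!is.finite(mass_kg) || mass_kg <= 0)
    abort("`mass_kg` must be strictly positive.", class = "flightscope_domain_error")
  if (!is.finite(wingspan_m) || wingspan_m <= 0)
    abort("`wingspan_m` must be strictly positive.", class = "flightscope_domain_error")
  if (!is.finite(wing_area_m2) || wing_area_m2 <= 0)
    abort("`wing_area_m2` must be strictly positive.", class = "flightscope_domain_error")
  if (!is.finite(muscle_fraction) || muscle_fraction <= 0 || muscle_fraction >= 1)
    abort("`muscle_fraction` must lie in (0, 1).", class = "flightscope_domain_error")
  if (wingspan_m^2 / wing_area_m2 <= 1)
    abort("Aspect ratio b^2/S must exceed 1.", class = "flightscope_domain_error")
  structure(
    list(mass_kg = mass_kg, wingspan_m = wingspan_m,
         wing_area_m2 = wing_area_m2, muscle_fraction = muscle_fraction),
    class = "bird_morphology"
  )
}

#' @export
print.bird_morphology <- function(x, ...) {
  cat("<bird_morphology>\n")
  cat(sprintf("  mass: %.3g kg, wingspan: %.3g m, wing area: %.3g m^2\n",
              x$mass_kg, x$wingspan_m, x$wing_area_m2))
  cat(sprintf("  muscle fraction: %.3g, aspect ratio: %.3g, wing loading: %.3g N m^-2\n",
              x$muscle_fraction, aspect_ratio(x), wing_loading(x)))
  invisible(x)
}

#' Aspect ratio and wing loading
#'
#' Aspect ratio is wingspan squared divided by wing area; wing loading is
#' weight divided by wing area.
#'
#' @param morph A [bird_morphology()].
#' @param gravity Acceleration due to gravity (m s^-2), used for wing loading.
#' @return A scalar.
#' @export
aspect_ratio <- function(morph) morph$wingspan_m^2 / morph$wing_area_m2

#' @rdname aspect_ratio
#' @export
wing_loading <- function(morph, gravity = 9.81) {
  morph$mass_kg * gravity / morph$wing_area_m2
}

#' Atmospheric conditions
#'
#' @param air_density Air density \eqn{\rho} (kg m^-3). The default is the
#'   standard sea-level value, appropriate for coastal field sites.
#' @param gravity Acceleration due to gravity \eqn{g} (m s^-2).
#' @return An object of class `atmosphere`.
#' @export
atmosphere <- function(air_density = 1.225, gravity = 9.81) {
  if (!is.finite(air_density) || air_density <= 0)
    abort("`air_density` must be strictly positive.", class = "flightscope_domain_error")
  if (!is.finite(gravity) || gravity <= 0)
    abort("`gravity` must be strictly positive.", class = "flightscope_domain_error")
  structure(list(air_density = air_density, gravity = gravity),
            class = "atmosphere")
}

#' Power-curve model parameters
#'
#' Parameters of the fixed-wing mechanical power model: the induced drag
#' factor \eqn{k} (1.2 for flapping flight), the body drag coefficient
#' \eqn{C_{Db}} referenced to body frontal area, and the constant used by
#' the constant-with-speed profile-power approximation
#' (profile power = `profile_power_constant` / aspect ratio times the
#' absolute minimum power).
#'
#' @param induced_factor Induced drag factor \eqn{k \ge 1}.
#' @param body_drag_coeff Body drag coefficient \eqn{C_{Db}} in (0, 1).
#'   Values 0.1 and 0.2 bracket current wind-tunnel evidence; 0.27 follows
#'   an older formula for large waterbirds.
#' @param profile_power_constant Profile-power constant \eqn{C_{pro}}
#'   (default 8.4).
#' @param include_profile Should profile power be added to the power curve?
#' @return An object of class `power_params`.
#' @export
power_params <- function(induced_factor = 1.2, body_drag_coeff = 0.2,
                         profile_power_constant = 8.4,
                         include_profile = TRUE) {
  if (!is.finite(induced_factor) || induced_factor < 1)
    abort("`induced_factor` must be >= 1.", class = "flightscope_domain_error")
  if (!is.finite(body_drag_coeff) || body_drag_coeff <= 0 || body_drag_coeff >= 1)
    abort("`body_drag_coeff` must lie in (0, 1).", class = "flightscope_domain_error")
  if (!is.finite(profile_power_constant) || profile_power_constant < 0)
    abort("`profile_power_constant` must be >= 0.", class = "flightscope_domain_error")
  structure(
    list(induced_factor = induced_factor, body_drag_coeff = body_drag_coeff,
         profile_power_constant = profile_power_constant,
         include_profile = isTRUE(include_profile)),
    class = "power_params"
  )
}

#' Default great cormorant morphology
#'
#' Reads the packaged plain-text configuration with the morphology of the
#' great cormorant (*Phalacrocorax carbo sinensis*) used throughout the
#' examples: mass 2.55 kg, wingspan 1.35 m, wing area 0.224 m^2, and a
#' choice of flight-muscle fractions (10.3% from drowned specimens, 13.6%
#' for a conspecific literature value, 17% the all-bird average).
#'
#' @param muscle_fraction Which muscle fraction to set on the returned
#'   object (default 0.136).
#' @param config Path to an alternative key/value (YAML) configuration.
#' @return A [bird_morphology()].
#' @export
cormorant_morphology <- function(muscle_fraction = 0.136, config = NULL) {
  path <- config %||% system.file("extdata", "cormorant.yaml",
                                  package = "flightscope")
  cfg <- yaml::read_yaml(path)
  bird_morphology(cfg$mass_kg, cfg$wingspan_m, cfg$wing_area_m2,
                  muscle_fraction = muscle_fraction)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
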