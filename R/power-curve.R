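# Fixed-wing mechanical power model. The power required for level flapping
# flight is decomposed as
#   P(V) = P_ind(V) + P_par(V) [+ P_pro],
#   P_ind = 2 k (m g)^2 / (pi b^2 rho V),   P_par = 0.5 rho V^3 S_b C_Db,
# with body frontal area S_b = 0.00813 m^0.666. Profile power, when
# included, uses the constant-with-speed closure C_pro / AR times the
# absolute minimum power P_am. Characteristic speeds follow in closed form:
# V_mp minimises P, V_mr minimises P/V; for the two-term curve
# V_mr = 3^{1/4} V_mp exactly.

#' Body frontal area
#'
#' Allometric body frontal area \eqn{S_b = 0.00813\, m^{0.666}} (m^2),
#' the reference area for body (parasite) drag.
#'
#' @param mass_kg Body mass (kg); vectorised.
#' @return Frontal area(s) in m^2.
#' @examples
#' body_frontal_area(2.55)
#' @export
body_frontal_area <- function(mass_kg) {
  if (any(!is.finite(mass_kg)) || any(mass_kg <= 0))
    abort("`mass_kg` must be strictly positive.", class = "flightscope_domain_error")
  0.00813 * mass_kg^0.666
}

# induced-power numerator A and parasite coefficient B of P = A/V + B V^3
power_curve_coefs <- function(morph, atmos, params) {
  stopifnot(inherits(morph, "bird_morphology"), inherits(atmos, "atmosphere"),
            inherits(params, "power_params"))
  mg <- morph$mass_kg * atmos$gravity
  sb <- body_frontal_area(morph$mass_kg)
  list(
    A = 2 * params$induced_factor * mg^2 /
      (pi * morph$wingspan_m^2 * atmos$air_density),
    B = 0.5 * atmos$air_density * sb * params$body_drag_coeff
  )
}

#' Minimum power speed
#'
#' The airspeed \eqn{V_{mp}} minimising mechanical power required for level
#' flight:
#' \deqn{V_{mp} = 0.807\, k^{1/4} m^{1/2} g^{1/2} \rho^{-1/2} b^{-1/2}
#'       S_b^{-1/4} C_{Db}^{-1/4}.}
#'
#' @param morph A [bird_morphology()].
#' @param atmos An [atmosphere()].
#' @param params A [power_params()].
#' @return Speed in m s^-1.
#' @examples
#' minimum_power_speed(cormorant_morphology(), atmosphere(), power_params())
#' @export
minimum_power_speed <- function(morph, atmos = atmosphere(),
                                params = power_params()) {
  cf <- power_curve_coefs(morph, atmos, params)
  (cf$A / (3 * cf$B))^0.25
}

#' Maximum range speed
#'
#' The airspeed \eqn{V_{mr}} minimising energy per unit distance
#' (\eqn{dP/dV = P/V}). For the induced-plus-parasite curve — the mechanical
#' "ultimate maximum lift-to-drag" case, excluding profile power —
#' \eqn{V_{mr} = 3^{1/4} V_{mp}} exactly.
#'
#' @inheritParams minimum_power_speed
#' @return Speed in m s^-1.
#' @export
maximum_range_speed <- function(morph, atmos = atmosphere(),
                                params = power_params()) {
  3^0.25 * minimum_power_speed(morph, atmos, params)
}

# absolute minimum power of the two-term curve, in its standard closed form
absolute_minimum_power <- function(morph, atmos, params) {
  sb <- body_frontal_area(morph$mass_kg)
  1.05 * params$induced_factor^0.75 *
    morph$mass_kg^1.5 * atmos$gravity^1.5 *
    sb^0.25 * params$body_drag_coeff^0.25 /
    (sqrt(atmos$air_density) * morph$wingspan_m^1.5)
}

profile_power <- function(morph, atmos, params) {
  if (!params$include_profile) return(0)
  (params$profile_power_constant / aspect_ratio(morph)) *
    absolute_minimum_power(morph, atmos, params)
}

#' Mechanical power breakdown
#'
#' Evaluates the power curve at one or more airspeeds, returning the
#' induced, parasite, profile and total components.
#'
#' @param speed Airspeed(s) V (m s^-1), strictly positive.
#' @inheritParams minimum_power_speed
#' @return A tibble of class `power_curve` with columns `speed`,
#'   `induced_W`, `parasite_W`, `profile_W`, `total_W`.
#' @examples
#' mechanical_power(seq(8, 25, by = 0.5), cormorant_morphology())
#' @export
mechanical_power <- function(speed, morph, atmos = atmosphere(),
                             params = power_params()) {
  if (any(!is.finite(speed)) || any(speed <= 0))
    abort("`speed` must be strictly positive.", class = "flightscope_domain_error")
  cf <- power_curve_coefs(morph, atmos, params)
  pro <- profile_power(morph, atmos, params)
  out <- tibble(
    speed = speed,
    induced_W = cf$A / speed,
    parasite_W = cf$B * speed^3,
    profile_W = pro,
    total_W = cf$A / speed + cf$B * speed^3 + pro
  )
  class(out) <- c("power_curve", class(out))
  out
}

#' Power available from the flight muscles
#'
#' @param morph A [bird_morphology()] (its `muscle_fraction` is used).
#' @param specific_power_W_per_kg Muscle-mass-specific power output
#'   (W per kg of flight muscle), e.g. 100 or 140.
#' @return Power in W.
#' @examples
#' power_available(cormorant_morphology(muscle_fraction = 0.136), 100)
#' @export
power_available <- function(morph, specific_power_W_per_kg) {
  if (!is.finite(specific_power_W_per_kg) || specific_power_W_per_kg <= 0)
    abort("`specific_power_W_per_kg` must be strictly positive.",
          class = "flightscope_domain_error")
  specific_power_W_per_kg * morph$muscle_fraction * morph$mass_kg
}

#' Muscle-power-limited maximum level airspeed
#'
#' Finds the largest airspeed at which the power required equals the power
#' available, i.e. the upper intersection of the power curve with a
#' horizontal line at `power_available_W`. When the available power lies
#' below the minimum of the curve level flight is impossible at any speed
#' and the result is marked infeasible (`NA` speed, `feasible = FALSE`) —
#' never an exception.
#'
#' @inheritParams minimum_power_speed
#' @param power_available_W Power available (W), non-negative.
#' @param ceiling_mps Upper bracket for the root search (m s^-1).
#' @param tol Root tolerance (m s^-1).
#' @return A one-row tibble with `max_speed_mps`, `feasible`,
#'   `power_available_W`, `min_power_W`.
#' @export
maximum_level_speed <- function(morph, atmos = atmosphere(),
                                params = power_params(),
                                power_available_W,
                                ceiling_mps = 60, tol = 1e-6) {
  if (!is.finite(power_available_W) || power_available_W < 0)
    abort("`power_available_W` must be >= 0.", class = "flightscope_domain_error")
  vmp <- minimum_power_speed(morph, atmos, params)
  pmin <- mechanical_power(vmp, morph, atmos, params)$total_W
  if (power_available_W < pmin) {
    return(tibble(max_speed_mps = NA_real_, feasible = FALSE,
                  power_available_W = power_available_W, min_power_W = pmin))
  }
  f <- function(v) mechanical_power(v, morph, atmos, params)$total_W -
    power_available_W
  if (f(ceiling_mps) < 0)
    abort(sprintf(
      "Power curve does not reach %.4g W below the %.4g m/s ceiling.",
      power_available_W, ceiling_mps), class = "flightscope_unbounded_error")
  root <- if (power_available_W == pmin) vmp else
    uniroot(f, lower = vmp, upper = ceiling_mps, tol = tol)$root
  tibble(max_speed_mps = root, feasible = TRUE,
         power_available_W = power_available_W, min_power_W = pmin)
}

#' Best glide speed
#'
#' The gliding airspeed maximising distance per height lost, for a glide
#' polar with body parasite drag (area \eqn{S_b C_{Db}}) and wing profile
#' drag (area \eqn{S\, C_{Dpro}}):
#' \deqn{V_{bg} = \left[\frac{4 k (m g)^2}
#'   {\rho^2 \pi b^2 (S_b C_{Db} + S\, C_{Dpro})}\right]^{1/4}.}
#' With `wing_profile_drag_coeff = 0` this reduces to the profile-free
#' maximum range speed \eqn{3^{1/4} V_{mp}}.
#'
#' @inheritParams minimum_power_speed
#' @param wing_profile_drag_coeff Wing profile drag coefficient
#'   \eqn{C_{Dpro}} referenced to wing area (>= 0).
#' @return Speed in m s^-1.
#' @export
best_glide_speed <- function(morph, atmos = atmosphere(),
                             params = power_params(),
                             wing_profile_drag_coeff = 0) {
  if (!is.finite(wing_profile_drag_coeff) || wing_profile_drag_coeff < 0)
    abort("`wing_profile_drag_coeff` must be >= 0.",
          class = "flightscope_domain_error")
  drag_area <- body_frontal_area(morph$mass_kg) * params$body_drag_coeff +
    morph$wing_area_m2 * wing_profile_drag_coeff
  if (drag_area <= 0)
    abort("Total zero-lift drag area must be positive.",
          class = "flightscope_domain_error")
  mg <- morph$mass_kg * atmos$gravity
  (4 * params$induced_factor * mg^2 /
      (atmos$air_density^2 * pi * morph$wingspan_m^2 * drag_area))^0.25
}

#' Allometric scaling of flight speed with body mass
#'
#' Ordinary least-squares regression of log airspeed on log body mass
#' across species. Under isometry characteristic speeds scale as
#' \eqn{m^{1/6}}; the fitted exponent measures how far a sample of species
#' departs from that.
#'
#' @param data A data frame with one row per species.
#' @param mass Column of body masses (kg); tidy-evaluated.
#' @param airspeed Column of mean airspeeds (m s^-1).
#' @return A one-row tibble with `slope` (the scaling exponent),
#'   `intercept`, `r_squared`, `p_value` and `n`.
#' @examples
#' cormorant_airspeed_survey() |>
#'   allometric_speed_exponent(mass_kg, airspeed_mps)
#' @export
allometric_speed_exponent <- function(data, mass = mass_kg,
                                      airspeed = airspeed_mps) {
  m <- dplyr::pull(data, {{ mass }})
  v <- dplyr::pull(data, {{ airspeed }})
  if (length(m) < 3)
    abort("At least 3 species are required.", class = "flightscope_domain_error")
  if (any(m <= 0) || any(v <= 0))
    abort("Masses and airspeeds must be strictly positive.",
          class = "flightscope_domain_error")
  if (var(log(m)) == 0)
    abort("Body masses have zero variance on the log scale.",
          class = "flightscope_domain_error")
  if (var(log(v)) == 0) {
    # constant speeds: flat relation by definition
    return(tibble(slope = 0, intercept = mean(log(v)), r_squared = 0,
                  p_value = NA_real_, n = length(m)))
  }
  fit <- lm(log(v) ~ log(m))
  sm <- summary(fit)
  r2 <- sm$r.squared
  if (!is.finite(r2)) r2 <- 0  # constant response: no variance to explain
  p <- unname(sm$coefficients[2, 4])
  tibble(
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r_squared = r2,
    p_value = if (is.finite(p)) p else NA_real_,
    n = length(m)
  )
}

#' Characteristic-speed grid
#'
#' Computes \eqn{V_{mp}} and \eqn{V_{mr}} for several body drag
#' coefficients, the usual way model sensitivity to \eqn{C_{Db}} is
#' presented.
#'
#' @inheritParams minimum_power_speed
#' @param body_drag_coeffs Body drag coefficients to tabulate.
#' @return A tibble with columns `body_drag_coeff`, `vmp_mps`, `vmr_mps`.
#' @export
predict_speeds <- function(morph, atmos = atmosphere(),
                           params = power_params(),
                           body_drag_coeffs = c(0.1, 0.2, 0.27)) {
  purrr::map(body_drag_coeffs, function(cdb) {
    p <- power_params(params$induced_factor, cdb,
                      params$profile_power_constant, params$include_profile)
    tibble(body_drag_coeff = cdb,
           vmp_mps = minimum_power_speed(morph, atmos, p),
           vmr_mps = maximum_range_speed(morph, atmos, p))
  }) |> dplyr::bind_rows()
}

#' Muscle-power feasibility grid
#'
#' Crosses body drag coefficients, flight-muscle fractions and
#' muscle-specific power outputs, and for each combination reports whether
#' sustained level flight is possible and, when it is, the maximum level
#' airspeed (profile power included by default).
#'
#' @inheritParams minimum_power_speed
#' @param body_drag_coeffs Body drag coefficients.
#' @param muscle_fractions Flight-muscle mass fractions.
#' @param specific_powers Muscle-specific powers (W kg^-1).
#' @return A tibble with one row per combination: `body_drag_coeff`,
#'   `muscle_fraction`, `specific_power_W_per_kg`, `power_available_W`,
#'   `feasible`, `max_speed_mps`.
#' @export
feasibility_grid <- function(morph, atmos = atmosphere(),
                             params = power_params(),
                             body_drag_coeffs = c(0.1, 0.2, 0.27),
                             muscle_fractions = c(0.103, 0.136, 0.17),
                             specific_powers = c(100, 140)) {
  grid <- tidyr::expand_grid(
    body_drag_coeff = body_drag_coeffs,
    muscle_fraction = muscle_fractions,
    specific_power_W_per_kg = specific_powers
  )
  purrr::pmap(grid, function(body_drag_coeff, muscle_fraction,
                             specific_power_W_per_kg) {
    m <- bird_morphology(morph$mass_kg, morph$wingspan_m, morph$wing_area_m2,
                         muscle_fraction = muscle_fraction)
    p <- power_params(params$induced_factor, body_drag_coeff,
                      params$profile_power_constant, params$include_profile)
    pav <- power_available(m, specific_power_W_per_kg)
    res <- maximum_level_speed(m, atmos, p, power_available_W = pav)
    tibble(body_drag_coeff, muscle_fraction, specific_power_W_per_kg,
           power_available_W = pav, feasible = res$feasible,
           max_speed_mps = res$max_speed_mps)
  }) |> dplyr::bind_rows()
}

#' Plot a power curve
#'
#' @param object A `power_curve` tibble from [mechanical_power()].
#' @param ... Unused.
#' @return A ggplot object with the induced, parasite, profile and total
#'   power components against airspeed.
#' @export
autoplot.power_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object),
    c("induced_W", "parasite_W", "profile_W", "total_W"),
    names_to = "component", values_to = "power_W"
  ) |>
    mutate(component = sub("_W$", "", .data$component))
  ggplot2::ggplot(long, ggplot2::aes(.data$speed, .data$power_W,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Airspeed (m/s)", y = "Mechanical power (W)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
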