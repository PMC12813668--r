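cormorant <- cormorant_morphology()

test_that("body frontal area follows the allometric formula", {
  expect_equal(body_frontal_area(1), 0.00813)
  expect_equal(body_frontal_area(2.55), 0.00813 * 2.55^0.666,
               tolerance = 1e-12)
  expect_lt(abs(body_frontal_area(2.55) - 0.015165), 1e-5)
  expect_error(body_frontal_area(0), class = "flightscope_domain_error")
  expect_error(body_frontal_area(-1), class = "flightscope_domain_error")
})

test_that("characteristic speeds obey the analytic scalings", {
  set.seed(11)
  for (i in 1:20) {
    m <- random_morphology()
    p1 <- power_params(body_drag_coeff = 0.2)
    p2 <- power_params(body_drag_coeff = 0.1)
    # halving C_Db multiplies V_mp by 2^{1/4}
    expect_equal(minimum_power_speed(m, params = p2) /
                   minimum_power_speed(m, params = p1),
                 2^0.25, tolerance = 1e-12)
    # V_mr / V_mp = 3^{1/4} exactly for the two-term curve
    expect_equal(maximum_range_speed(m, params = p1) /
                   minimum_power_speed(m, params = p1),
                 3^0.25, tolerance = 1e-12)
    # V_mp scales as sqrt(m g / b) for fixed drag terms
    expect_gt(minimum_power_speed(m, params = p1), 0)
  }
})

test_that("numeric minima of the power curve match the closed forms", {
  set.seed(21)
  atm <- atmosphere()
  for (i in 1:100) {
    m <- random_morphology()
    prm <- power_params(body_drag_coeff = runif(1, 0.05, 0.4),
                        include_profile = FALSE)
    total <- function(v) mechanical_power(v, m, atm, prm)$total_W
    vmp_num <- optimize(total, c(0.5, 80), tol = 1e-9)$minimum
    expect_equal(vmp_num, minimum_power_speed(m, atm, prm),
                 tolerance = 1e-4)
    # V_mr is the argmin of P/V (cost of transport)
    vmr_num <- optimize(function(v) total(v) / v, c(0.5, 120),
                        tol = 1e-9)$minimum
    expect_equal(vmr_num, maximum_range_speed(m, atm, prm),
                 tolerance = 1e-4)
  }
})

test_that("power components behave as their physics dictates", {
  pw1 <- mechanical_power(10, cormorant)
  pw2 <- mechanical_power(20, cormorant)
  expect_equal(pw2$induced_W, pw1$induced_W / 2)      # induced ~ 1/V
  expect_equal(pw2$parasite_W, pw1$parasite_W * 8)    # parasite ~ V^3
  expect_equal(pw1$total_W,
               pw1$induced_W + pw1$parasite_W + pw1$profile_W)
  expect_true(all(as.matrix(pw1[, -1]) >= 0))
  expect_error(mechanical_power(0, cormorant),
               class = "flightscope_domain_error")
  # profile power is constant with speed and switches off cleanly
  expect_equal(pw1$profile_W, pw2$profile_W)
  off <- mechanical_power(10, cormorant, params =
                            power_params(include_profile = FALSE))
  expect_equal(off$profile_W, 0)
})

test_that("power available is specific power times muscle mass", {
  m136 <- cormorant_morphology(muscle_fraction = 0.136)
  m17 <- cormorant_morphology(muscle_fraction = 0.17)
  expect_equal(power_available(m136, 100), 100 * 0.136 * 2.55)
  expect_equal(power_available(m17, 140), 60.69, tolerance = 1e-10)
  expect_error(power_available(m136, 0), class = "flightscope_domain_error")
})

test_that("maximum level speed is the upper power-curve intersection", {
  atm <- atmosphere()
  prm <- power_params(body_drag_coeff = 0.2)
  vmp <- minimum_power_speed(cormorant, atm, prm)
  pmin <- mechanical_power(vmp, cormorant, atm, prm)$total_W

  # tangency: power available exactly at the curve minimum gives V_mp
  tang <- maximum_level_speed(cormorant, atm, prm, power_available_W = pmin)
  expect_true(tang$feasible)
  expect_equal(tang$max_speed_mps, vmp, tolerance = 1e-6)

  # infeasible iff below the minimum
  infeas <- maximum_level_speed(cormorant, atm, prm,
                                power_available_W = pmin - 0.01)
  expect_false(infeas$feasible)
  expect_true(is.na(infeas$max_speed_mps))

  # monotone in power available, and always at least V_mp
  pav <- seq(pmin, pmin + 30, length.out = 6)
  speeds <- vapply(pav, function(p)
    maximum_level_speed(cormorant, atm, prm, power_available_W = p)$max_speed_mps,
    numeric(1))
  expect_true(all(diff(speeds) > 0))
  expect_true(all(speeds >= vmp - 1e-9))

  # solution satisfies P(V) = P_av to the stated tolerance
  sol <- maximum_level_speed(cormorant, atm, prm, power_available_W = 50)
  expect_equal(mechanical_power(sol$max_speed_mps, cormorant, atm,
                                prm)$total_W, 50, tolerance = 1e-3)

  # a ceiling too low to bracket is a distinct error, not INFEASIBLE
  expect_error(
    maximum_level_speed(cormorant, atm, prm, power_available_W = 1e5,
                        ceiling_mps = 30),
    class = "flightscope_unbounded_error")
})

test_that("best glide speed reduces to profile-free V_mr and is monotone", {
  prm <- power_params(body_drag_coeff = 0.2)
  vbg0 <- best_glide_speed(cormorant, params = prm,
                           wing_profile_drag_coeff = 0)
  expect_equal(vbg0, 3^0.25 * minimum_power_speed(cormorant, params = prm),
               tolerance = 1e-12)
  expect_equal(vbg0, 18.4, tolerance = 0.05)
  cdpro <- c(0, 0.01, 0.02, 0.05, 0.1)
  vbg <- vapply(cdpro, function(cd)
    best_glide_speed(cormorant, params = prm,
                     wing_profile_drag_coeff = cd), numeric(1))
  expect_true(all(diff(vbg) < 0))
  expect_error(best_glide_speed(cormorant, params = prm,
                                wing_profile_drag_coeff = -0.1),
               class = "flightscope_domain_error")
})

test_that("allometric exponent matches the normal-equations oracle", {
  set.seed(5)
  for (i in 1:10) {
    mass <- runif(5, 0.5, 5)
    speed <- runif(5, 8, 20)
    got <- allometric_speed_exponent(
      tibble::tibble(mass_kg = mass, airspeed_mps = speed))
    want <- ols_loglog_oracle(mass, speed)
    expect_equal(got$slope, want$slope, tolerance = 1e-10)
    expect_equal(got$r_squared, want$r2, tolerance = 1e-10)
  }
  # degenerate inputs
  expect_error(allometric_speed_exponent(
    tibble::tibble(mass_kg = c(1, 2), airspeed_mps = c(10, 11))),
    class = "flightscope_domain_error")
  expect_error(allometric_speed_exponent(
    tibble::tibble(mass_kg = c(2, 2, 2), airspeed_mps = c(10, 11, 12))),
    class = "flightscope_domain_error")
  const <- allometric_speed_exponent(
    tibble::tibble(mass_kg = c(1, 2, 4), airspeed_mps = c(12, 12, 12)))
  expect_equal(const$slope, 0, tolerance = 1e-12)
  expect_equal(const$r_squared, 0)
})

test_that("morphology and parameter invariants are enforced", {
  expect_error(bird_morphology(-1, 1, 0.2), class = "flightscope_domain_error")
  expect_error(bird_morphology(1, 1, 2), class = "flightscope_domain_error")
  expect_error(bird_morphology(1, 1, 0.2, muscle_fraction = 1.2),
               class = "flightscope_domain_error")
  expect_error(power_params(induced_factor = 0.9),
               class = "flightscope_domain_error")
  expect_error(power_params(body_drag_coeff = 1.2),
               class = "flightscope_domain_error")
  expect_equal(aspect_ratio(cormorant), 1.35^2 / 0.224)
})
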