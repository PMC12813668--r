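test_that("fix_to_position maps instrument coordinates to the local frame", {
  p <- fix_to_position(100, 90, 0, instrument_height_m = 3)
  expect_equal(unlist(p), c(east_m = 100, north_m = 0, height_m = 3),
               tolerance = 1e-9)
  z <- fix_to_position(100, 0, 90, instrument_height_m = 3)
  expect_equal(unlist(z), c(east_m = 0, north_m = 0, height_m = 103),
               tolerance = 1e-9)
  s <- fix_to_position(200, 180, 30, instrument_height_m = 0)
  expect_equal(s$east_m, 0, tolerance = 1e-9)
  expect_equal(s$north_m, -200 * cos(pi / 6), tolerance = 1e-9)
  expect_equal(round(s$north_m, 3), -173.205)
  expect_equal(s$height_m, 100, tolerance = 1e-9)
  expect_error(fix_to_position(0, 0, 0), class = "flightscope_domain_error")
  expect_error(fix_to_position(10, 0, 95), class = "flightscope_domain_error")
})

test_that("position <-> fix round trip is exact", {
  set.seed(31)
  for (i in 1:50) {
    e <- runif(1, -2000, 2000); n <- runif(1, -2000, 2000)
    h <- runif(1, 1, 300); ih <- runif(1, 0, 5)
    fx <- position_to_fix(e, n, h, ih)
    back <- fix_to_position(fx$range_m, fx$azimuth_deg, fx$elevation_deg, ih)
    expect_equal(back$east_m, e, tolerance = 1e-9)
    expect_equal(back$north_m, n, tolerance = 1e-9)
    expect_equal(back$height_m, h, tolerance = 1e-9)
  }
})

southbound_run <- function() {
  # bird due north of the instrument moving due south at 15 m/s, level
  p0 <- position_to_fix(0, 500, 10, 0)
  p1 <- position_to_fix(0, 350, 10, 0)
  tibble::tibble(time = c(0, 10),
                 range_m = c(p0$range_m, p1$range_m),
                 azimuth_deg = c(p0$azimuth_deg, p1$azimuth_deg),
                 elevation_deg = c(p0$elevation_deg, p1$elevation_deg))
}

test_that("run velocity is endpoint displacement over elapsed time", {
  rv <- run_velocity(southbound_run())
  expect_equal(rv$ground_speed, 15, tolerance = 1e-9)
  expect_equal(rv$track_deg, 180, tolerance = 1e-9)
  expect_equal(rv$vertical_speed, 0, tolerance = 1e-9)
  expect_equal(rv$altitude_m, 10, tolerance = 1e-9)

  # climbing: heights 10 -> 20 over 20 s
  c0 <- position_to_fix(0, 500, 10, 0); c1 <- position_to_fix(0, 300, 20, 0)
  climb <- tibble::tibble(time = c(0, 20),
                          range_m = c(c0$range_m, c1$range_m),
                          azimuth_deg = c(c0$azimuth_deg, c1$azimuth_deg),
                          elevation_deg = c(c0$elevation_deg, c1$elevation_deg))
  expect_equal(run_velocity(climb)$vertical_speed, 0.5, tolerance = 1e-9)

  # intermediate collinear fixes leave the endpoint vector unchanged
  mid <- position_to_fix(0, 425, 10, 0)
  three <- dplyr::bind_rows(
    southbound_run()[1, ],
    tibble::tibble(time = 5, range_m = mid$range_m,
                   azimuth_deg = mid$azimuth_deg,
                   elevation_deg = mid$elevation_deg),
    southbound_run()[2, ])
  expect_equal(run_velocity(three)$ground_speed, 15, tolerance = 1e-9)
  expect_equal(run_velocity(three)$track_deg, 180, tolerance = 1e-9)

  expect_error(run_velocity(southbound_run()[1, ]),
               class = "flightscope_domain_error")
  bad <- southbound_run(); bad$time <- c(5, 5)
  expect_error(run_velocity(bad), class = "flightscope_domain_error")
})

test_that("wind triangle subtraction yields airspeed and heading", {
  # pure tailwind: ground 15 toward 180, wind 5 toward 180
  av <- air_vector(0, -15, 0, -5)
  expect_equal(av$airspeed, 10, tolerance = 1e-12)
  expect_equal(av$heading_deg, 180, tolerance = 1e-12)

  # ground 15 toward 90, wind 5 toward 0
  av2 <- air_vector(15, 0, 0, 5)
  expect_equal(av2$airspeed, sqrt(250), tolerance = 1e-12)
  expect_equal(av2$heading_deg, flightscope:::vec_to_dir(15, -5),
               tolerance = 1e-12)
  expect_equal(round(av2$heading_deg, 1), 108.4)

  # zero wind: heading equals track, airspeed equals ground speed
  av3 <- air_vector(7, -3, 0, 0)
  expect_equal(av3$airspeed, sqrt(49 + 9), tolerance = 1e-12)
  expect_equal(av3$heading_deg, flightscope:::vec_to_dir(7, -3))

  # vanishing air vector flags the heading
  av4 <- air_vector(3, 4, 3, 4)
  expect_equal(av4$airspeed, 0)
  expect_true(is.na(av4$heading_deg))
  expect_false(av4$heading_defined)
})

test_that("tail/side decomposition is an orthogonal projection", {
  wc <- wind_components(0, -5, 180)      # wind toward 180, bird at 180
  expect_equal(wc$tail_mps, 5, tolerance = 1e-12)
  expect_equal(wc$side_mps, 0, tolerance = 1e-12)

  wc2 <- wind_components(5, 0, 180)      # wind toward 90: to the bird's left
  expect_equal(wc2$tail_mps, 0, tolerance = 1e-12)
  expect_equal(wc2$side_mps, -5, tolerance = 1e-12)

  w3 <- flightscope:::wind_from_to_vector(5, 315)  # wind toward 135
  wc3 <- wind_components(w3$east, w3$north, 180)
  expect_equal(wc3$tail_mps, 5 / sqrt(2), tolerance = 1e-12)
  expect_equal(wc3$side_mps, -5 / sqrt(2), tolerance = 1e-12)

  # tail^2 + side^2 = |w|^2 for arbitrary winds and references
  set.seed(41)
  for (i in 1:50) {
    we <- runif(1, -10, 10); wn <- runif(1, -10, 10)
    ref <- runif(1, 0, 360)
    wc <- wind_components(we, wn, ref)
    expect_equal(wc$tail_mps^2 + wc$side_mps^2, we^2 + wn^2,
                 tolerance = 1e-12)
  }
})

test_that("air and ground speeds respect the triangle inequalities", {
  set.seed(43)
  for (i in 1:50) {
    ge <- runif(1, -20, 20); gn <- runif(1, -20, 20)
    we <- runif(1, -10, 10); wn <- runif(1, -10, 10)
    av <- air_vector(ge, gn, we, wn)
    vg <- sqrt(ge^2 + gn^2); vw <- sqrt(we^2 + wn^2)
    expect_lte(vg, av$airspeed + vw + 1e-12)
    expect_gte(av$airspeed, abs(vg - vw) - 1e-12)
  }
})

test_that("processing is equivariant under frame rotation", {
  rot <- 73
  an <- tibble::tibble(time = 0:60, speed_mps = 6, dir_from_deg = 250,
                       height_m = 5)
  an_rot <- dplyr::mutate(an, dir_from_deg = (dir_from_deg + rot) %% 360)
  run <- southbound_run()
  run_rot <- dplyr::mutate(run, azimuth_deg = (azimuth_deg + rot) %% 360)
  a <- process_run(run, wind_field(an))
  b <- process_run(run_rot, wind_field(an_rot))
  expect_equal(b$track_deg, (a$track_deg + rot) %% 360, tolerance = 1e-9)
  expect_equal(b$heading_deg, (a$heading_deg + rot) %% 360, tolerance = 1e-9)
  expect_equal(b$airspeed, a$airspeed, tolerance = 1e-9)
  expect_equal(b$ground_speed, a$ground_speed, tolerance = 1e-9)
  expect_equal(b$tailwind_heading, a$tailwind_heading, tolerance = 1e-9)
  expect_equal(b$sidewind_heading, a$sidewind_heading, tolerance = 1e-9)
})

test_that("process_run composes the stages and records wind provenance", {
  still <- tibble::tibble(time = 0:60, speed_mps = 0, dir_from_deg = 0,
                          height_m = 5)
  pr <- process_run(southbound_run(), wind_field(still))
  expect_equal(pr$airspeed, pr$ground_speed, tolerance = 1e-9)
  expect_equal(pr$heading_deg, pr$track_deg, tolerance = 1e-9)
  expect_equal(pr$tailwind_heading, 0, tolerance = 1e-9)
  expect_equal(pr$sidewind_heading, 0, tolerance = 1e-9)
  # a 10-m run uses the surface log law
  expect_equal(pr$wind_provenance, "surface-log-law")
})

test_that("process_session reports failing runs instead of dropping them", {
  an <- tibble::tibble(time = 0:300, speed_mps = 6, dir_from_deg = 250,
                       height_m = 5)
  run <- southbound_run()
  session <- dplyr::bind_rows(
    dplyr::mutate(run, run_id = 1),
    tibble::tibble(run_id = 2, time = 100, range_m = 500,
                   azimuth_deg = 10, elevation_deg = 2)  # single fix: invalid
  )
  runs <- tibble::tibble(run_id = c(1, 2), species = "cormorant",
                         behaviour = "autumn_migration", flock_size = c(4, 1),
                         site = "A", instrument_height_m = 0)
  out <- process_session(session, runs, wind_field(an))
  expect_equal(nrow(out), 2)
  expect_true(is.na(out$error[1]))
  expect_match(out$error[2], "two fixes")
  expect_equal(out$log_flock_size, log(c(4, 1)))
})
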