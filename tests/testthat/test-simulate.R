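small_scenario <- function(...) {
  scenario(
    behaviours = tibble::tribble(
      ~behaviour,         ~n_runs, ~mean_airspeed, ~sd_airspeed,
      "autumn_migration", 15L,     16.87,          1.74,
      "local_movement",   15L,     17.95,          1.81
    ),
    ...
  )
}

test_that("bird motion honours the drift parameter endpoints", {
  # zero wind: heading = track = goal for any beta
  for (b in c(0, 0.5, 1)) {
    m <- make_bird_motion(15, 0, 0, beta = b, goal_deg = 197)
    expect_equal(m$heading_deg, 197, tolerance = 1e-9)
    expect_equal(m$track_deg, 197, tolerance = 1e-9)
    expect_equal(m$ground_speed, 15, tolerance = 1e-12)
  }

  # full compensation against a pure 5 m/s crosswind at 10 m/s airspeed:
  # track exactly at the goal, heading crabbed 30 degrees upwind
  w <- flightscope:::wind_from_to_vector(5, 270)  # wind toward east
  fc <- make_bird_motion(10, w$east, w$north, beta = 0, goal_deg = 180)
  expect_equal(fc$track_deg, 180, tolerance = 1e-9)
  expect_equal(abs(fc$crab_deg), 30, tolerance = 1e-9)
  expect_equal(fc$heading_deg, 210, tolerance = 1e-9)  # crabbed into the wind

  # full drift: heading equals the goal exactly
  fd <- make_bird_motion(10, w$east, w$north, beta = 1, goal_deg = 180)
  expect_equal(fd$heading_deg, 180, tolerance = 1e-12)
  expect_false(fd$infeasible_compensation)

  # crosswind above airspeed: flagged fallback to the maximum crab
  inf <- make_bird_motion(4, w$east, w$north, beta = 0, goal_deg = 180)
  expect_true(inf$infeasible_compensation)
  expect_equal(abs(inf$crab_deg), 90, tolerance = 1e-9)
})

test_that("sessions are bit-identical for identical seeds", {
  s1 <- simulate_session(small_scenario(seed = 42))
  s2 <- simulate_session(small_scenario(seed = 42))
  expect_identical(s1, s2)
  s3 <- simulate_session(small_scenario(seed = 43))
  expect_false(identical(s1$session$range_m, s3$session$range_m))
  # the design (runs, behaviours) is set by the scenario, not the seed
  expect_identical(s1$runs$behaviour, s3$runs$behaviour)
  expect_identical(nrow(s1$truth), nrow(s3$truth))
})

test_that("generated truth satisfies the wind triangle exactly", {
  sim <- simulate_session(small_scenario(seed = 7))
  tr <- sim$truth
  u_east <- sin(tr$heading_true * pi / 180)
  u_north <- cos(tr$heading_true * pi / 180)
  expect_equal(tr$ground_east - tr$wind_east, tr$airspeed_true * u_east,
               tolerance = 1e-12)
  expect_equal(tr$ground_north - tr$wind_north, tr$airspeed_true * u_north,
               tolerance = 1e-12)
})

test_that("a noise-free session is recovered exactly through the pipeline", {
  scn <- small_scenario(seed = 9, sigma_range = 0, sigma_azimuth = 0,
                        sigma_elevation = 0)
  sim <- simulate_session(scn)
  wf <- wind_field(sim$anemometer, sim$balloons)
  pt <- process_session(sim$session, sim$runs, wf)
  merged <- dplyr::left_join(pt, sim$truth, by = "run_id")
  expect_true(all(is.na(merged$error)))
  expect_lt(max(abs(merged$ground_speed - merged$ground_speed_true)), 1e-6)
  expect_lt(max(abs(merged$airspeed - merged$airspeed_true)), 1e-6)
  expect_lt(max(abs(flightscope:::angle_diff(merged$heading_deg,
                                             merged$heading_true))), 1e-6)
  expect_lt(max(abs(merged$vertical_speed - merged$vz_true)), 1e-6)
  expect_lt(max(abs(merged$altitude_m - merged$altitude_true)), 1e-6)
})

test_that("the pipeline recovers true airspeeds under default noise", {
  sim <- simulate_session(small_scenario(seed = 13))
  wf <- wind_field(sim$anemometer, sim$balloons)
  pt <- process_session(sim$session, sim$runs, wf)
  merged <- dplyr::left_join(
    pt, dplyr::select(sim$truth, run_id, airspeed_true, heading_true),
    by = "run_id")
  expect_true(all(is.na(merged$error)))
  # per-run errors stay modest; headings point the right way
  expect_lt(stats::median(abs(merged$airspeed - merged$airspeed_true)), 0.5)
  expect_lt(max(abs(flightscope:::angle_diff(merged$heading_deg,
                                             merged$heading_true))), 20)
})

test_that("estimated drift increases monotonically with the planted beta", {
  set.seed(17)
  betas <- c(0, 0.25, 0.5, 0.75, 1)
  est <- vapply(betas, function(b) {
    pop <- simulate_drift_population(400, beta = b)
    estimate_drift(pop)$b_track
  }, numeric(1))
  expect_true(all(diff(est) > 0))
  expect_lt(abs(est[1]), 0.05)
  expect_lt(abs(est[5] - 1), 0.05)
})

test_that("session files round-trip through CSV", {
  dir <- withr::local_tempdir()
  sim <- simulate_session(small_scenario(seed = 19))
  write_session(sim, dir)
  expect_setequal(list.files(dir),
                  c("session.csv", "runs.csv", "anemometer.csv",
                    "balloons.csv", "truth.csv"))
  session <- read_session_csv(file.path(dir, "session.csv"))
  expect_equal(nrow(session), nrow(sim$session))
  an <- read_anemometer_csv(file.path(dir, "anemometer.csv"))
  bl <- read_balloon_csv(file.path(dir, "balloons.csv"))
  wf <- wind_field(an, bl)
  pt <- process_session(session, read_runs_csv(file.path(dir, "runs.csv")), wf)
  expect_true(all(is.na(pt$error)))
})

test_that("scenario configuration reads from YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 5", "goal_deg: 210", "drift_beta: 0.5",
    "behaviours:",
    "  - {behaviour: autumn_migration, n_runs: 4, mean_airspeed: 16.9, sd_airspeed: 1.7}"
  ), path)
  scn <- read_scenario(path)
  expect_s3_class(scn, "flight_scenario")
  expect_equal(scn$goal_deg, 210)
  expect_equal(scn$drift_beta, 0.5)
  expect_equal(nrow(simulate_session(scn)$truth), 4)
})
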