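# Shared fixtures and independent oracles used across test files.

random_morphology <- function() {
  b <- runif(1, 0.3, 3)
  bird_morphology(
    mass_kg = runif(1, 0.1, 10),
    wingspan_m = b,
    wing_area_m2 = b^2 / runif(1, 4, 12),  # aspect ratios 4-12
    muscle_fraction = runif(1, 0.05, 0.3)
  )
}

# brute-force OLS of log(speed) on log(mass) via the normal equations
ols_loglog_oracle <- function(mass, speed) {
  x <- log(mass); y <- log(speed)
  xb <- mean(x); yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  intercept <- yb - slope * xb
  fitted <- intercept + slope * x
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - yb)^2)
  list(slope = slope, intercept = intercept, r2 = 1 - ss_res / ss_tot)
}

# sample with exact mean and sd, for t-test oracles
sample_with_moments <- function(n, mean, sd) {
  z <- seq_len(n)
  z <- (z - base::mean(z)) / stats::sd(z)
  mean + sd * z
}

# wrapped-normal angles approximating a von Mises with concentration kappa
rvonmises_deg <- function(n, mean_deg, kappa) {
  wrap_deg_test(mean_deg + 180 / pi * rnorm(n, 0, 1 / sqrt(kappa)))
}

wrap_deg_test <- function(x) {
  out <- x %% 360
  out[out < 0] <- out[out < 0] + 360
  out
}

# angle-level drift population: balanced left/right winds, headings set by
# make_bird_motion with wrapped-normal noise; returns a processed-track-like
# tibble for estimate_drift()
simulate_drift_population <- function(n_per_side, beta, goal = 197,
                                      airspeed = 17, wind_speed = 5,
                                      kappa = 50) {
  from <- c(runif(n_per_side, goal - 150, goal - 30),
            runif(n_per_side, goal + 30, goal + 150))
  wind <- flightscope:::wind_from_to_vector(wind_speed, from)
  rows <- purrr::pmap(list(wind$east, wind$north), function(we, wn) {
    m <- make_bird_motion(airspeed, we, wn, beta, goal)
    noise <- 180 / pi * rnorm(1, 0, 1 / sqrt(kappa))
    h <- wrap_deg_test(m$heading_deg + noise)
    u <- flightscope:::dir_to_unit(h)
    ge <- airspeed * u[, "east"] + we
    gn <- airspeed * u[, "north"] + wn
    tibble::tibble(heading_deg = h,
                   track_deg = flightscope:::vec_to_dir(ge, gn))
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(wind_from_deg = from)
}

# small synthetic analysis table with configurable per-behaviour effects
make_analysis_table <- function(n_per_behaviour = 100, sigma = 1,
                                tail_slope = c(spring_migration = 0,
                                               autumn_migration = 0,
                                               local_movement = 0),
                                means = c(spring_migration = 18.85,
                                          autumn_migration = 16.87,
                                          local_movement = 17.95)) {
  beh <- rep(names(means), each = n_per_behaviour)
  n <- length(beh)
  tibble::tibble(
    behaviour = beh,
    vertical_speed = rnorm(n, 0, 0.15),
    tailwind_heading = rnorm(n, 0, 3),
    sidewind_heading = rnorm(n, 0, 3),
    flock_size = pmax(1, round(exp(runif(n, 0, log(100))))),
    log_flock_size = log(flock_size),
    airspeed = means[beh] + tail_slope[beh] * tailwind_heading +
      rnorm(n, 0, sigma)
  )
}
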