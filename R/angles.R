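# Compass-angle helpers. Convention throughout the package: directions are
# degrees clockwise from north ("compass"); wind inputs are meteorological
# FROM-directions, all internal vectors describe motion TOWARD. East/north
# components are used for every vector computation; trigonometric angles
# never leak out of this file.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# wrap into [0, 360)
wrap_deg <- function(x) {
  out <- x %% 360
  out[out < 0] <- out[out < 0] + 360
  out[abs(out - 360) < 1e-12] <- 0
  out
}

# signed shortest arc, in (-180, 180]
wrap_signed <- function(x) {
  out <- (x + 180) %% 360 - 180
  out[out <= -180] <- out[out <= -180] + 360
  out
}

angle_diff <- function(a, b) wrap_signed(a - b)

# compass direction of motion -> unit vector (east, north)
dir_to_unit <- function(deg) {
  r <- deg2rad(deg)
  m <- cbind(east = sin(r), north = cos(r))
  rownames(m) <- NULL
  m
}

# (east, north) -> compass direction of motion
vec_to_dir <- function(east, north) {
  wrap_deg(rad2deg(atan2(east, north)))
}

# meteorological FROM-direction + speed -> motion-toward components.
# Wind FROM north (360 deg) moves air southward: east = 0, north < 0.
wind_from_to_vector <- function(speed, direction_from) {
  toward <- wrap_deg(direction_from + 180)
  u <- dir_to_unit(toward)
  tibble::tibble(east = as.numeric(speed * u[, "east"]),
                 north = as.numeric(speed * u[, "north"]))
}

# motion vector -> FROM-direction (for reporting wind in meteorological form)
vector_to_from_dir <- function(east, north) {
  wrap_deg(vec_to_dir(east, north) + 180)
}

# shortest-arc linear interpolation between two compass directions
interp_dir <- function(d0, d1, w) {
  wrap_deg(d0 + w * angle_diff(d1, d0))
}
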