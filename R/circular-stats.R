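# Circular statistics for flight directions: mean direction and mean
# resultant length r, the Rayleigh test of uniformity, the Watson-Williams
# two-sample F-test, and the wind-drift index
#   b_track = (T1 - T2) / (alpha1 - alpha2),  alpha_i = T_i - H_i,
# comparing tracks/headings of birds with wind from the left (group 1)
# versus right (group 2) of the overall mean track. b = 0 is full
# compensation, b = 1 full drift; all differences use the signed shortest
# arc.

#' Circular mean and resultant length
#'
#' @param angles_deg Directions in compass degrees.
#' @param weights Optional non-negative weights (default equal).
#' @return A one-row tibble with `mean_deg` (NA-flagged when the resultant
#'   vanishes), `r` (mean resultant length in \[0, 1\]) and `n`.
#' @examples
#' circular_mean_r(c(10, 20, 30))
#' @export
circular_mean_r <- function(angles_deg, weights = NULL) {
  if (length(angles_deg) == 0)
    abort("`angles_deg` must be non-empty.", class = "flightscope_domain_error")
  w <- weights %||% rep(1, length(angles_deg))
  w <- w / sum(w)
  a <- deg2rad(angles_deg)
  ce <- sum(w * sin(a)); cn <- sum(w * cos(a))
  r <- sqrt(ce^2 + cn^2)
  tibble(
    mean_deg = if (r < 1e-12) NA_real_ else vec_to_dir(ce, cn),
    r = r,
    n = length(angles_deg)
  )
}

#' Rayleigh test of angular uniformity
#'
#' Tests whether directions are uniformly distributed on the circle using
#' the statistic \eqn{Z = n r^2} with the standard series approximation for
#' the p-value.
#'
#' @param angles_deg Directions in compass degrees, n >= 3.
#' @return A one-row tibble with `Z`, `p_value`, `r`, `mean_deg`, `n` and
#'   `stars` (`***` for p < 0.001, `**` < 0.01, `*` < 0.05).
#' @export
rayleigh_test <- function(angles_deg) {
  n <- length(angles_deg)
  if (n < 3)
    abort("Rayleigh test needs n >= 3.", class = "flightscope_domain_error")
  cm <- circular_mean_r(angles_deg)
  z <- n * cm$r^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  p <- min(max(p, 0), 1)
  tibble(Z = z, p_value = p, r = cm$r, mean_deg = cm$mean_deg, n = n,
         stars = significance_stars(p))
}

significance_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "")
}

# ML approximation of the von Mises concentration from mean resultant length
vonmises_kappa <- function(r) {
  if (r < 0.53) 2 * r + r^3 + 5 * r^5 / 6
  else if (r < 0.85) -0.4 + 1.39 * r + 0.43 / (1 - r)
  else 1 / (r^3 - 4 * r^2 + 3 * r)
}

#' Watson-Williams test for equal mean directions
#'
#' One-way F-type comparison of the mean directions of two circular
#' samples, with the standard concentration correction factor
#' \eqn{1 + 3/(8\hat\kappa)}. The test assumes reasonably concentrated
#' samples; when the pooled mean resultant length falls below 0.45 a
#' validity warning is attached (reported, not fatal).
#'
#' @param angles_a_deg,angles_b_deg The two samples (compass degrees),
#'   each with at least 2 observations.
#' @return A one-row tibble with `F`, `df1`, `df2`, `p_value`, the group
#'   mean directions and sizes, and `low_concentration`.
#' @export
watson_williams_test <- function(angles_a_deg, angles_b_deg) {
  n1 <- length(angles_a_deg); n2 <- length(angles_b_deg)
  if (n1 < 2 || n2 < 2)
    abort("Each group needs at least 2 observations.",
          class = "flightscope_domain_error")
  n <- n1 + n2
  m1 <- circular_mean_r(angles_a_deg); m2 <- circular_mean_r(angles_b_deg)
  mp <- circular_mean_r(c(angles_a_deg, angles_b_deg))
  R1 <- n1 * m1$r; R2 <- n2 * m2$r; R <- n * mp$r
  rw <- (R1 + R2) / n
  low <- rw < 0.45
  if (low)
    warn("Pooled concentration is low (r < 0.45); the Watson-Williams test may be unreliable.",
         class = "flightscope_low_concentration")
  kappa <- vonmises_kappa(rw)
  correction <- 1 + 3 / (8 * kappa)
  denom <- n - (R1 + R2)
  if (denom <= 0) {
    # both groups perfectly concentrated
    f <- if (abs(angle_diff(m1$mean_deg, m2$mean_deg)) < 1e-9) 0 else Inf
  } else {
    f <- correction * (n - 2) * (R1 + R2 - R) / denom
  }
  f <- max(f, 0)
  p <- pf(f, 1, n - 2, lower.tail = FALSE)
  tibble(F = f, df1 = 1, df2 = n - 2, p_value = p,
         mean_a_deg = m1$mean_deg, mean_b_deg = m2$mean_deg,
         n_a = n1, n_b = n2, low_concentration = low)
}

#' Wind-drift index
#'
#' Compares mean tracks and headings of birds with wind from the left
#' (group 1) and right (group 2):
#' \eqn{b_{track} = (T_1 - T_2)/(\alpha_1 - \alpha_2)} with
#' \eqn{\alpha_i = T_i - H_i}, differences on the signed shortest arc.
#' \eqn{b = 0} means full compensation (tracks identical), \eqn{b = 1}
#' full drift (headings identical); values below `full_comp_threshold`
#' are classified as complete compensation.
#'
#' @param T1,H1 Mean track and heading (deg) of the wind-from-left group.
#' @param T2,H2 Mean track and heading (deg) of the wind-from-right group.
#' @param full_comp_threshold Classification threshold (default 0.1).
#' @return A one-row tibble with `b_track`, `alpha1`, `alpha2`, `defined`
#'   and `classification`.
#' @examples
#' drift_index(195, 188, 194, 203)
#' @export
drift_index <- function(T1, H1, T2, H2, full_comp_threshold = 0.1) {
  a1 <- angle_diff(T1, H1)
  a2 <- angle_diff(T2, H2)
  dT <- angle_diff(T1, T2)
  da <- a1 - a2
  if (abs(da) < 1e-12) {
    return(tibble(b_track = NA_real_, alpha1 = a1, alpha2 = a2,
                  defined = FALSE, classification = "undefined"))
  }
  b <- dT / da
  tibble(
    b_track = b, alpha1 = a1, alpha2 = a2, defined = TRUE,
    classification = dplyr::case_when(
      abs(b) < full_comp_threshold ~ "complete compensation",
      b >= 1 ~ "full drift",
      TRUE ~ "partial drift/compensation"
    )
  )
}

#' Split tracks by wind side
#'
#' Classifies each observation as having the wind from the left or right
#' of the overall mean track direction. A wind whose FROM-direction lies on
#' the shortest arc anticlockwise of the mean track (signed difference in
#' (-180, 0)) comes from the left; exact head/tail winds (difference 0 or
#' 180) are excluded and counted.
#'
#' @param data A data frame of processed tracks.
#' @param track Column of track directions (deg); tidy-evaluated.
#' @param wind_from Column of wind FROM-directions (deg).
#' @return The input with columns `wind_side`
#'   (`"left"`/`"right"`/`"excluded"`) and an attribute-free design: the
#'   overall mean track is recomputed via [circular_mean_r()] and attached
#'   as column `mean_track_deg`.
#' @export
split_by_wind_side <- function(data, track = track_deg,
                               wind_from = wind_from_deg) {
  tr <- dplyr::pull(data, {{ track }})
  wf <- dplyr::pull(data, {{ wind_from }})
  mt <- circular_mean_r(tr)$mean_deg
  d <- angle_diff(wf, mt)
  side <- dplyr::case_when(
    abs(d) < 1e-9 | abs(abs(d) - 180) < 1e-9 ~ "excluded",
    d < 0 ~ "left",
    TRUE ~ "right"
  )
  data |> mutate(wind_side = side, mean_track_deg = mt)
}

#' Estimate wind drift from a processed-track table
#'
#' End-to-end drift analysis: splits tracks by wind side relative to the
#' overall mean track, takes circular means of track and heading within
#' each side, and evaluates the drift index.
#'
#' @inheritParams split_by_wind_side
#' @param heading Column of heading directions (deg).
#' @param full_comp_threshold Classification threshold for complete
#'   compensation.
#' @return A one-row tibble with group means and sizes (`T1`, `H1`, `n1`,
#'   `T2`, `H2`, `n2`), `n_excluded`, `b_track` and `classification`.
#' @export
estimate_drift <- function(data, track = track_deg, heading = heading_deg,
                           wind_from = wind_from_deg,
                           full_comp_threshold = 0.1) {
  split <- split_by_wind_side(data, {{ track }}, {{ wind_from }})
  tr <- dplyr::pull(split, {{ track }})
  hd <- dplyr::pull(split, {{ heading }})
  left <- split$wind_side == "left"
  right <- split$wind_side == "right"
  if (sum(left) < 1 || sum(right) < 1)
    abort("Need at least one track on each wind side.",
          class = "flightscope_domain_error")
  T1 <- circular_mean_r(tr[left])$mean_deg
  H1 <- circular_mean_r(hd[left])$mean_deg
  T2 <- circular_mean_r(tr[right])$mean_deg
  H2 <- circular_mean_r(hd[right])$mean_deg
  di <- drift_index(T1, H1, T2, H2, full_comp_threshold)
  dplyr::bind_cols(
    tibble(T1 = T1, H1 = H1, n1 = sum(left),
           T2 = T2, H2 = H2, n2 = sum(right),
           n_excluded = sum(split$wind_side == "excluded"),
           mean_track_deg = split$mean_track_deg[1]),
    di
  )
}

#' Rose plot of flight directions
#'
#' @param angles_deg Directions in compass degrees.
#' @param binwidth Bin width in degrees.
#' @return A ggplot circular histogram with the mean direction marked.
#' @export
plot_flight_directions <- function(angles_deg, binwidth = 15) {
  cm <- circular_mean_r(angles_deg)
  df <- tibble(angle = wrap_deg(angles_deg))
  ggplot2::ggplot(df, ggplot2::aes(.data$angle)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = cm$mean_deg, colour = "red") +
    ggplot2::coord_polar(start = 0) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 315, by = 45)) +
    ggplot2::labs(x = NULL, y = "count",
                  subtitle = sprintf("mean %.0f deg, r = %.2f, n = %d",
                                     cm$mean_deg, cm$r, cm$n)) +
    ggplot2::theme_minimal()
}
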