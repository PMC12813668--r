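# Downstream analyses on the processed-track table: one-sample speed
# comparisons against model-predicted characteristic speeds, the
# altitude-tailwind regression, airspeed variability (CV), and the
# six-prediction scorecard of adaptive flight behaviour.

#' One-sample t-test of a mean airspeed against a reference speed
#'
#' Compares a summarised airspeed sample (mean, sd, n) against a
#' model-predicted characteristic speed, e.g. whether observed airspeeds
#' exceed the predicted minimum power speed or fall short of the maximum
#' range speed.
#'
#' @param mean,sd,n Sample summary (sd > 0, n >= 2).
#' @param reference Reference speed (m s^-1).
#' @param alternative Direction of the test: `"greater"` / `"less"` test
#'   whether the true mean is greater/less than `reference`;
#'   `"two.sided"` is available for completeness.
#' @return A one-row tibble with `t`, `abs_t`, `df`, `p_value`,
#'   `alternative`.
#' @examples
#' one_sample_speed_test(17.95, 1.81, 64, reference = 18.4,
#'                       alternative = "less")
#' @export
one_sample_speed_test <- function(mean, sd, n, reference,
                                  alternative = c("greater", "less",
                                                  "two.sided")) {
  alternative <- match.arg(alternative)
  if (n < 2) abort("Need n >= 2.", class = "flightscope_domain_error")
  if (!is.finite(sd) || sd <= 0)
    abort("`sd` must be strictly positive.", class = "flightscope_domain_error")
  t <- (mean - reference) / (sd / sqrt(n))
  df <- n - 1
  p <- switch(alternative,
              greater = pt(t, df, lower.tail = FALSE),
              less = pt(t, df),
              two.sided = 2 * pt(abs(t), df, lower.tail = FALSE))
  tibble(t = t, abs_t = abs(t), df = df, p_value = p,
         alternative = alternative)
}

#' Altitude versus tail-wind regression
#'
#' Ordinary least squares of flight altitude on the tail-wind component,
#' overall and (optionally) within each behaviour. A positive slope means
#' birds fly higher in tail winds and lower in head winds, as expected
#' from the surface wind gradient.
#'
#' @param data Processed-track table.
#' @param altitude,tailwind,behaviour Columns (tidy-evaluated).
#' @param per_behaviour Also fit within each behaviour level?
#' @param min_n Minimum rows per fitted group (default 3).
#' @return A tibble with one row per fitted group: `group`, `slope`,
#'   `intercept`, `std_error`, `t`, `p_value`, `n`.
#' @export
altitude_wind_regression <- function(data, altitude = altitude_m,
                                     tailwind = tailwind_heading,
                                     behaviour = behaviour,
                                     per_behaviour = TRUE, min_n = 3) {
  z <- dplyr::pull(data, {{ altitude }})
  tw <- dplyr::pull(data, {{ tailwind }})
  fit_group <- function(label, zz, tt) {
    if (length(zz) < min_n)
      abort(sprintf("Group '%s' has fewer than %d rows.", label, min_n),
            class = "flightscope_domain_error")
    if (var(tt) == 0 || var(zz) == 0)
      abort(sprintf("Group '%s' has degenerate variance.", label),
            class = "flightscope_domain_error")
    fit <- lm(zz ~ tt)
    cf <- summary(fit)$coefficients
    tibble(group = label, slope = cf[2, 1], intercept = cf[1, 1],
           std_error = cf[2, 2], t = cf[2, 3], p_value = cf[2, 4],
           n = length(zz))
  }
  out <- list(fit_group("all", z, tw))
  if (per_behaviour && rlang::quo_is_symbol(rlang::enquo(behaviour)) &&
      rlang::as_name(rlang::enquo(behaviour)) %in% names(data)) {
    beh <- as.character(dplyr::pull(data, {{ behaviour }}))
    for (lvl in unique(beh)) {
      sel <- beh == lvl
      if (sum(sel) >= min_n)
        out[[length(out) + 1]] <- fit_group(lvl, z[sel], tw[sel])
    }
  }
  dplyr::bind_rows(out)
}

#' Coefficient of variation
#'
#' \eqn{CV = 100 \times sd / mean} (percent), a diagnostic of how wide a
#' species' realised flight-speed scope is. Give either raw `values`
#' (sd then uses the n-1 denominator) or a (`mean`, `sd`) pair.
#'
#' @param values Numeric vector of raw values.
#' @param mean,sd Summary statistics, used when `values` is missing.
#' @return CV in percent.
#' @examples
#' coefficient_of_variation(mean = 17.5, sd = 1.98)
#' @export
coefficient_of_variation <- function(values = NULL, mean = NULL, sd = NULL) {
  if (!is.null(values)) {
    mean <- base::mean(values)
    sd <- stats::sd(values)
  }
  if (is.null(mean) || is.null(sd))
    abort("Give either `values` or both `mean` and `sd`.")
  if (!is.finite(mean) || mean <= 0)
    abort("`mean` must be strictly positive.",
          class = "flightscope_domain_error")
  100 * sd / mean
}

#' CV table across species
#'
#' @param data A table of per-species airspeed summaries.
#' @param mean,sd Columns holding the mean and standard deviation.
#' @return The input with a `cv_percent` column appended.
#' @examples
#' cv_table(ornithodolite_speed_survey(), mean_mps, sd_mps)
#' @export
cv_table <- function(data, mean = mean_mps, sd = sd_mps) {
  m <- dplyr::pull(data, {{ mean }})
  s <- dplyr::pull(data, {{ sd }})
  data |> mutate(cv_percent = purrr::map2_dbl(
    m, s, function(mm, ss) coefficient_of_variation(mean = mm, sd = ss)))
}

#' Behaviour-level airspeed summary
#'
#' Mean, sd, n and a t-based 95% confidence interval of airspeed per
#' behaviour.
#'
#' @param data Processed-track table.
#' @param airspeed,behaviour Columns (tidy-evaluated).
#' @return A tibble with one row per behaviour.
#' @export
behaviour_speed_summary <- function(data, airspeed = airspeed,
                                    behaviour = behaviour) {
  data |>
    group_by(behaviour = {{ behaviour }}) |>
    summarise(
      n = dplyr::n(),
      mean_airspeed = base::mean({{ airspeed }}),
      sd = stats::sd({{ airspeed }}),
      .groups = "drop"
    ) |>
    mutate(
      se = .data$sd / sqrt(.data$n),
      ci_low = .data$mean_airspeed - qt(0.975, .data$n - 1) * .data$se,
      ci_high = .data$mean_airspeed + qt(0.975, .data$n - 1) * .data$se
    )
}

#' Scorecard for the six adaptive-flight predictions
#'
#' Maps the fitted statistics onto the six predictions about adaptive
#' flight behaviour: (1) spring and summer airspeeds exceed autumn;
#' (2) airspeed falls with tail wind or rises with absolute side wind;
#' (3) complete wind-drift compensation (b_track below its threshold);
#' (4) airspeed falls with climb rate; (5) airspeed rises with log flock
#' size; (6) altitude rises with tail wind. Each verdict carries the
#' statistic and p-value it was decided on; missing upstream stages leave
#' explicit gaps rather than failing.
#'
#' @param model An `airspeed_model`, or `NULL`.
#' @param drift Output of [estimate_drift()], or `NULL`.
#' @param contrasts Output of [pairwise_behaviour_contrasts()], or `NULL`.
#' @param altitude Output of [altitude_wind_regression()], or `NULL`.
#' @param alpha Significance level for the verdicts.
#' @return A tibble with columns `prediction`, `description`, `supported`
#'   (logical, `NA` when the stage is missing), `statistic`, `p_value`,
#'   `evidence`.
#' @export
evaluate_predictions <- function(model = NULL, drift = NULL,
                                 contrasts = NULL, altitude = NULL,
                                 alpha = 0.05) {
  rows <- list()
  verdict_row <- function(prediction, description, supported,
                          statistic = NA_real_, p_value = NA_real_,
                          evidence = "") {
    tibble(prediction = prediction, description = description,
           supported = supported, statistic = statistic,
           p_value = p_value, evidence = evidence)
  }

  # 1: seasonal ordering of airspeeds
  if (!is.null(contrasts) && !is.null(model)) {
    lsm <- model$lsmeans
    mean_of <- function(b) lsm$lsmean[lsm$behaviour == b]
    pair_sig <- function(a, b) {
      row <- contrasts |>
        filter(grepl(a, .data$contrast) & grepl(b, .data$contrast))
      if (nrow(row) == 0) return(list(ok = NA, t = NA_real_, p = NA_real_))
      list(ok = row$p_adj[1] < alpha && mean_of(a) > mean_of(b),
           t = abs(row$t[1]), p = row$p_adj[1])
    }
    sa <- pair_sig("spring_migration", "autumn_migration")
    la <- pair_sig("local_movement", "autumn_migration")
    rows[[1]] <- verdict_row(
      1L, "spring and summer airspeeds exceed autumn",
      isTRUE(sa$ok) && isTRUE(la$ok),
      statistic = max(sa$t, la$t), p_value = max(sa$p, la$p),
      evidence = sprintf(
        "spring-autumn |t|=%.2f p=%.3g; local-autumn |t|=%.2f p=%.3g",
        sa$t, sa$p, la$t, la$p))
  } else {
    rows[[1]] <- verdict_row(1L, "spring and summer airspeeds exceed autumn",
                             NA, evidence = "contrasts not supplied")
  }

  slope_sig <- function(cov, want_sign) {
    if (is.null(model)) return(NULL)
    sl <- model$slopes |> filter(.data$covariate == cov)
    if (nrow(sl) == 0) return(list(ok = FALSE, t = NA_real_, p = NA_real_,
                                   txt = sprintf("%s eliminated", cov)))
    sig <- sl$p_value < alpha & sign(sl$estimate) == want_sign
    best <- sl |> filter(.data$p_value == min(.data$p_value)) |> dplyr::slice(1)
    list(ok = any(sig), t = best$t, p = best$p_value,
         txt = sprintf("%s slope %.3g (p=%.3g) in %s", cov, best$estimate,
                       best$p_value, best$behaviour))
  }

  if (!is.null(model)) {
    tailres <- slope_sig("tail", -1)
    sideres <- slope_sig("abs_side", +1)
    rows[[2]] <- verdict_row(
      2L, "airspeed decreases with tail wind or increases with side wind",
      isTRUE(tailres$ok) || isTRUE(sideres$ok),
      statistic = tailres$t, p_value = tailres$p,
      evidence = paste(tailres$txt, sideres$txt, sep = "; "))
    vzres <- slope_sig("vz", -1)
    rows[[4]] <- verdict_row(
      4L, "airspeed decreases with climb rate", isTRUE(vzres$ok),
      statistic = vzres$t, p_value = vzres$p, evidence = vzres$txt)
    flores <- slope_sig("logN", +1)
    rows[[5]] <- verdict_row(
      5L, "airspeed increases with log flock size", isTRUE(flores$ok),
      statistic = flores$t, p_value = flores$p, evidence = flores$txt)
  } else {
    for (i in c(2L, 4L, 5L))
      rows[[i]] <- verdict_row(i, "airspeed model not supplied", NA,
                               evidence = "model not supplied")
  }

  if (!is.null(drift)) {
    rows[[3]] <- verdict_row(
      3L, "complete compensation for wind drift",
      isTRUE(drift$classification == "complete compensation"),
      statistic = drift$b_track,
      evidence = sprintf("b_track = %.3f (%s)", drift$b_track,
                         drift$classification))
  } else {
    rows[[3]] <- verdict_row(3L, "complete compensation for wind drift", NA,
                             evidence = "drift estimate not supplied")
  }

  if (!is.null(altitude)) {
    sig <- altitude |> filter(.data$p_value < alpha & .data$slope > 0)
    best <- altitude |> arrange(.data$p_value) |> dplyr::slice(1)
    rows[[6]] <- verdict_row(
      6L, "altitude increases with tail wind", nrow(sig) > 0,
      statistic = best$slope, p_value = best$p_value,
      evidence = sprintf("slope %.3g m per m/s (p=%.3g) in group '%s'",
                         best$slope, best$p_value, best$group))
  } else {
    rows[[6]] <- verdict_row(6L, "altitude increases with tail wind", NA,
                             evidence = "altitude regression not supplied")
  }

  dplyr::bind_rows(rows) |> arrange(.data$prediction)
}

#' Scatterplot of altitude against tail wind
#'
#' @param data Processed-track table.
#' @param altitude,tailwind,behaviour Columns (tidy-evaluated).
#' @return A ggplot with per-behaviour points and the overall OLS line.
#' @export
plot_altitude_wind <- function(data, altitude = altitude_m,
                               tailwind = tailwind_heading,
                               behaviour = behaviour) {
  ggplot2::ggplot(data, ggplot2::aes({{ tailwind }}, {{ altitude }},
                                     colour = {{ behaviour }})) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(ggplot2::aes(group = 1), method = "lm",
                         formula = y ~ x, se = FALSE, colour = "black") +
    ggplot2::labs(x = "Tail-wind component on heading (m/s)",
                  y = "Altitude (m)", colour = NULL) +
    ggplot2::theme_minimal()
}
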