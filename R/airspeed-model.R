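# Nested linear model for airspeed. Behaviour (spring migration, autumn
# migration, local movement) enters as a fixed category; vertical speed,
# tail-wind component, absolute side-wind component and log flock size
# enter as fixed effects nested within behaviour (a separate slope per
# behaviour level, no shared main-effect slope). Backward elimination
# removes whole nested blocks whose block F-test p exceeds alpha, least
# significant first, refitting at each step; the behaviour category itself
# is never a removal candidate.

covariate_blocks <- c(vertical_speed = "vz", tailwind = "tail",
                      sidewind = "abs_side", log_flock = "logN")

#' Fit the nested airspeed model with backward elimination
#'
#' @param data A processed-track table; one row per run.
#' @param airspeed,behaviour,vertical_speed,tailwind,sidewind,log_flock
#'   Columns (tidy-evaluated) holding the response, the behaviour category
#'   and the four candidate covariates. The side-wind component enters as
#'   its absolute value; the tail-wind component is signed.
#' @param covariates Character subset of
#'   `c("vertical_speed", "tailwind", "sidewind", "log_flock")` naming the
#'   nested blocks to start from (default all four).
#' @param alpha Elimination threshold for the block F-tests (default 0.05).
#' @return An object of class `airspeed_model`: the final `lm` fit plus
#'   tibbles `terms` (block F-tests of the final model), `slopes`
#'   (per-behaviour slopes of retained covariates), `lsmeans`
#'   (behaviour least-squares means with 95% CI), and `history`
#'   (elimination path). Supports [tidy()], [glance()], [autoplot()].
#' @export
fit_airspeed_model <- function(data,
                               airspeed = airspeed,
                               behaviour = behaviour,
                               vertical_speed = vertical_speed,
                               tailwind = tailwind_heading,
                               sidewind = sidewind_heading,
                               log_flock = log_flock_size,
                               covariates = names(covariate_blocks),
                               alpha = 0.05) {
  if (length(covariates) > 0)
    covariates <- match.arg(covariates, names(covariate_blocks),
                            several.ok = TRUE)
  df <- tibble(
    y = dplyr::pull(data, {{ airspeed }}),
    behaviour = factor(dplyr::pull(data, {{ behaviour }}))
  )
  if ("vertical_speed" %in% covariates)
    df$vz <- dplyr::pull(data, {{ vertical_speed }})
  if ("tailwind" %in% covariates)
    df$tail <- dplyr::pull(data, {{ tailwind }})
  if ("sidewind" %in% covariates)
    df$abs_side <- abs(dplyr::pull(data, {{ sidewind }}))
  if ("log_flock" %in% covariates)
    df$logN <- dplyr::pull(data, {{ log_flock }})
  if (nlevels(df$behaviour) < 2)
    abort("At least two behaviour levels are required.",
          class = "flightscope_domain_error")

  blocks <- if (length(covariates) > 0)
    paste0("behaviour:", covariate_blocks[covariates]) else character(0)
  refit <- function(active) {
    rhs <- paste(c("behaviour", active), collapse = " + ")
    fit <- lm(formula(paste("y ~", rhs)), data = df)
    if (anyNA(coef(fit))) {
      bad <- names(coef(fit))[is.na(coef(fit))]
      abort(paste0("Design matrix is rank deficient; collinear terms: ",
                   paste(unique(bad), collapse = ", ")),
            class = "flightscope_rank_deficient")
    }
    fit
  }

  block_tests <- function(fit, active) {
    if (length(active) == 0) return(NULL)
    scope <- formula(paste("~", paste(active, collapse = " + ")))
    d1 <- drop1(fit, scope = scope, test = "F")
    tibble(term = rownames(d1)[-1], df = d1$Df[-1],
           sumsq = d1$`Sum of Sq`[-1],
           F = d1$`F value`[-1], p_value = d1$`Pr(>F)`[-1])
  }

  active <- blocks
  history <- list()
  step <- 0
  repeat {
    fit <- refit(active)
    bt <- block_tests(fit, active)
    if (is.null(bt) || all(bt$p_value <= alpha)) break
    cand <- bt |> filter(.data$p_value > alpha)
    # drop the least significant block; ties in p broken by the smaller F
    worst <- cand |> arrange(dplyr::desc(.data$p_value), .data$F) |>
      dplyr::slice(1)
    step <- step + 1
    history[[step]] <- tibble(step = step, dropped = worst$term,
                              F = worst$F, p_value = worst$p_value)
    active <- setdiff(active, worst$term)
  }

  # behaviour main-effect F from the sequential ANOVA of the final fit
  av <- anova(fit)
  beh <- tibble(term = "behaviour", df = av["behaviour", "Df"],
                sumsq = av["behaviour", "Sum Sq"],
                F = av["behaviour", "F value"],
                p_value = av["behaviour", "Pr(>F)"])
  terms_tbl <- dplyr::bind_rows(beh, block_tests(fit, active))

  structure(
    list(fit = fit, data = df, alpha = alpha,
         retained = active, candidates = blocks,
         terms = terms_tbl,
         slopes = nested_slopes(fit, active),
         lsmeans = behaviour_lsmeans(fit),
         history = if (length(history) > 0) dplyr::bind_rows(history) else
           tibble(step = integer(), dropped = character(),
                  F = double(), p_value = double())),
    class = "airspeed_model"
  )
}

# per-behaviour slope estimates of the retained nested covariates
nested_slopes <- function(fit, active) {
  if (length(active) == 0)
    return(tibble(behaviour = character(), covariate = character(),
                  estimate = double(), std_error = double(),
                  t = double(), p_value = double()))
  cf <- summary(fit)$coefficients
  purrr::map(active, function(block) {
    cov <- sub("^behaviour:", "", block)
    rows <- grepl(paste0("^behaviour.*:", cov, "$"), rownames(cf))
    tibble(
      behaviour = sub(paste0(":", cov, "$"), "",
                      sub("^behaviour", "", rownames(cf)[rows])),
      covariate = cov,
      estimate = cf[rows, 1], std_error = cf[rows, 2],
      t = cf[rows, 3], p_value = cf[rows, 4]
    )
  }) |> dplyr::bind_rows()
}

behaviour_lsmeans <- function(fit) {
  # the interaction NOTE is expected: covariates are nested in behaviour
  # by design, and means are taken at the covariate means
  em <- suppressMessages(emmeans::emmeans(fit, "behaviour"))
  as_tibble(as.data.frame(em)) |>
    rename(lsmean = "emmean", ci_low = "lower.CL", ci_high = "upper.CL")
}

#' @export
print.airspeed_model <- function(x, ...) {
  cat("Nested airspeed model (backward-eliminated at alpha =",
      x$alpha, ")\n\n")
  cat("Retained terms:", paste(c("behaviour", x$retained), collapse = ", "),
      "\n")
  if (nrow(x$history) > 0) {
    cat("Eliminated:",
        paste(sprintf("%s (p=%.3f)", x$history$dropped, x$history$p_value),
              collapse = ", "), "\n")
  }
  cat("\nBlock F-tests:\n")
  print(as.data.frame(x$terms), row.names = FALSE, digits = 4)
  if (nrow(x$slopes) > 0) {
    cat("\nPer-behaviour slopes:\n")
    print(as.data.frame(x$slopes), row.names = FALSE, digits = 4)
  }
  cat("\nBehaviour least-squares means:\n")
  print(as.data.frame(x$lsmeans), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @rdname fit_airspeed_model
#' @param x An `airspeed_model`.
#' @param ... Unused.
#' @export
tidy.airspeed_model <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble(term = rownames(cf), estimate = cf[, 1], std.error = cf[, 2],
         statistic = cf[, 3], p.value = cf[, 4])
}

#' @rdname fit_airspeed_model
#' @export
glance.airspeed_model <- function(x, ...) {
  sm <- summary(x$fit)
  tibble(
    r.squared = sm$r.squared, adj.r.squared = sm$adj.r.squared,
    sigma = sm$sigma,
    statistic = unname(sm$fstatistic[1]),
    df = unname(sm$fstatistic[2]), df.residual = unname(sm$fstatistic[3]),
    nobs = nrow(x$data),
    n_terms_retained = length(x$retained),
    n_terms_dropped = nrow(x$history)
  )
}

#' @rdname fit_airspeed_model
#' @param object An `airspeed_model`.
#' @export
autoplot.airspeed_model <- function(object, ...) {
  ggplot2::ggplot(object$lsmeans,
                  ggplot2::aes(.data$behaviour, .data$lsmean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::labs(x = NULL, y = "Airspeed least-squares mean (m/s)") +
    ggplot2::theme_minimal()
}

#' Tukey HSD contrasts between behaviours
#'
#' Pairwise differences of the behaviour least-squares means of a fitted
#' airspeed model, with Tukey adjustment of the p-values.
#'
#' @param model An `airspeed_model` from [fit_airspeed_model()].
#' @return A tibble with one row per behaviour pair: `contrast`,
#'   `estimate`, `std_error`, `df`, `t`, `p_adj`.
#' @export
pairwise_behaviour_contrasts <- function(model) {
  stopifnot(inherits(model, "airspeed_model"))
  if (nlevels(model$data$behaviour) < 2)
    abort("Need at least two behaviour levels.",
          class = "flightscope_domain_error")
  em <- suppressMessages(emmeans::emmeans(model$fit, "behaviour"))
  pr <- emmeans::contrast(em, method = "pairwise", adjust = "tukey")
  as_tibble(as.data.frame(pr)) |>
    rename(std_error = "SE", t = "t.ratio", p_adj = "p.value")
}
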