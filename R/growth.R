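#' Four-parameter logistic growth curve on the log-biomass scale
#'
#' Log biomass at day `t` under the four-parameter logistic model:
#' `log M(t) = M0 + (K - M0) / (1 + exp((xmid - t) / r))`, where `M0` is the
#' lower asymptote (log biomass as t -> -Inf), `K` the upper asymptote
#' (log biomass as t -> +Inf), `xmid` the inflection day (day of maximum
#' relative growth rate) and `r` a time-scale parameter in days.
#'
#' @param t day of year (numeric vector).
#' @param M0,K lower and upper log-biomass asymptotes.
#' @param xmid inflection day.
#' @param r time-scale parameter, days; must be positive.
#' @return Log biomass at each `t`.
#' @seealso [rgr_logistic()] for the analytic daily RGR.
#' @export
logistic_log_biomass <- function(t, M0, K, xmid, r) {
  stopifnot(r > 0)
  M0 + (K - M0) * stats::plogis((t - xmid) / r)
}

#' Analytic daily relative growth rate of the logistic curve
#'
#' RGR is the time derivative of log biomass. For the four-parameter
#' logistic this is `(K - M0) * u / (r * (1 + u)^2)` with
#' `u = exp((xmid - t) / r)`; evaluated here in the numerically stable form
#' `(K - M0)/r * p * (1 - p)` with `p = plogis((t - xmid)/r)`. The maximum,
#' `(K - M0) / (4 r)`, occurs at `t = xmid`.
#'
#' @inheritParams logistic_log_biomass
#' @return RGR at each `t`, in day^-1.
#' @export
rgr_logistic <- function(t, M0, K, xmid, r) {
  stopifnot(r > 0)
  p <- stats::plogis((t - xmid) / r)
  (K - M0) / r * p * (1 - p)
}

#' Two-point relative growth rate
#'
#' Classical interval RGR from two biomass measurements:
#' `ln(b1 / b0) / dt`. Used as a model-free robustness check on the
#' curve-derived daily RGR; it equals the mean of the daily RGR over the
#' interval when growth follows any smooth curve.
#'
#' @param b0,b1 first and second biomass measurements (same units); positive.
#' @param dt days elapsed between the two measurements; positive.
#' @return RGR in day^-1.
#' @export
simple_rgr <- function(b0, b1, dt) {
  if (any(!is.finite(b0)) || any(b0 <= 0) ||
      any(!is.finite(b1)) || any(b1 <= 0)) {
    stop("simple_rgr(): biomass values must be positive and finite",
         call. = FALSE)
  }
  if (any(!is.finite(dt)) || any(dt <= 0)) {
    stop("simple_rgr(): dt must be positive", call. = FALSE)
  }
  log(b1 / b0) / dt
}

# Start-value heuristic for the logistic fit: lower/upper asymptotes from the
# observed extremes, xmid at the steepest observed rise of mean log biomass,
# r from the day span.
logistic_start <- function(day, logb) {
  ml <- tapply(logb, day, mean)
  d <- as.numeric(names(ml))
  slopes <- diff(ml) / diff(d)
  k <- which.max(slopes)
  span <- diff(range(d))
  list(
    M0 = min(logb), K = max(logb),
    xmid = (d[k] + d[k + 1]) / 2,
    r = max(span / 6, 1)
  )
}

fit_logistic_single <- function(day, logb, n_starts = 10L, seed = 1L) {
  start <- logistic_start(day, logb)
  spread <- max(stats::sd(logb), 0.1)
  span <- diff(range(day))
  df <- data.frame(day = day, logb = logb)

  starts <- vector("list", n_starts + 1L)
  starts[[1L]] <- start
  jit <- withr::with_seed(seed, list(
    M0 = stats::rnorm(n_starts, 0, spread / 2),
    K = stats::rnorm(n_starts, 0, spread / 2),
    xmid = stats::runif(n_starts, -span / 8, span / 8),
    r = stats::runif(n_starts, -0.5, 0.5)
  ))
  for (i in seq_len(n_starts)) {
    starts[[i + 1L]] <- list(
      M0 = start$M0 + jit$M0[i], K = start$K + jit$K[i],
      xmid = start$xmid + jit$xmid[i], r = start$r * exp(jit$r[i])
    )
  }

  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        logb ~ M0 + (K - M0) / (1 + exp((xmid - day) / r)),
        data = df, start = s,
        lower = c(M0 = -Inf, K = -Inf, xmid = -Inf, r = 1e-3),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(coef = stats::coef(fit), rss = rss)
    }
  }
  best
}

#' Fit the four-parameter logistic growth curve for one species x treatment
#'
#' Least-squares fit of [logistic_log_biomass()] to natural-log biomass
#' through time, with a multi-start Levenberg-Marquardt optimisation
#' (documented start heuristic plus jittered restarts; best residual sum of
#' squares wins). Under `aggregation = "pooled"` all plots are fitted
#' jointly; under `"per_plot_then_average"` each plot is fitted separately
#' and the parameters averaged, mirroring per-replicate curve averaging.
#'
#' @param series data frame with columns `day`, `biomass` and (for the
#'   per-plot aggregation) `plot`, for a single species x treatment.
#' @param config a [run_config()] list; uses `aggregation` and `seed`.
#' @return One-row tibble: `species`, `treatment` (if present in `series`),
#'   `M0`, `K`, `xmid`, `r`, `rss` (log scale), `n_obs`, `converged`.
#' @export
fit_logistic <- function(series, config = run_config()) {
  stopifnot(all(c("day", "biomass") %in% names(series)))
  if (any(series$biomass <= 0)) {
    stop("fit_logistic(): biomass must be positive", call. = FALSE)
  }
  n_days <- length(unique(series$day))
  if (n_days < 5L) {
    stop("fit_logistic(): need >= 5 distinct days, got ", n_days,
         call. = FALSE)
  }
  logb <- log(series$biomass)
  if (stats::sd(logb) < 1e-12) {
    stop("fit_logistic(): degenerate data (all log biomass equal)",
         call. = FALSE)
  }

  fit_one <- function(day, lb) {
    fit_logistic_single(day, lb, seed = config$seed)
  }

  if (identical(config$aggregation, "per_plot_then_average") &&
      "plot" %in% names(series)) {
    parts <- split(series, series$plot)
    fits <- lapply(parts, function(p) fit_one(p$day, log(p$biomass)))
    ok <- !vapply(fits, is.null, logical(1))
    if (!any(ok)) {
      cf <- c(M0 = NA_real_, K = NA_real_, xmid = NA_real_, r = NA_real_)
      rss <- NA_real_
    } else {
      mat <- vapply(fits[ok], function(f) f$coef, numeric(4))
      cf <- rowMeans(mat)
      rss <- sum(vapply(fits[ok], function(f) f$rss, numeric(1)))
    }
    conv <- any(ok)
  } else {
    best <- fit_one(series$day, logb)
    if (is.null(best)) {
      cf <- c(M0 = NA_real_, K = NA_real_, xmid = NA_real_, r = NA_real_)
      rss <- NA_real_
      conv <- FALSE
    } else {
      cf <- best$coef
      rss <- best$rss
      conv <- TRUE
    }
  }

  tibble::tibble(
    species = if ("species" %in% names(series)) series$species[1] else NA_character_,
    treatment = if ("treatment" %in% names(series)) series$treatment[1] else NA_character_,
    M0 = unname(cf["M0"]), K = unname(cf["K"]),
    xmid = unname(cf["xmid"]), r = unname(cf["r"]),
    rss = rss, n_obs = nrow(series), converged = conv
  )
}

#' Fit growth curves for every species x treatment in a biomass table
#'
#' Groups a long biomass table by species and treatment and applies
#' [fit_logistic()] to each group. Groups whose fit fails (too few days,
#' degenerate data, no optimiser convergence) are returned with
#' `converged = FALSE` and a warning, and are excluded by downstream steps.
#'
#' @param observations biomass observation table
#'   (`study,treatment,species,plot,day,biomass`).
#' @param config a [run_config()] list.
#' @return Tibble of fits, one row per species x treatment.
#' @export
fit_growth_curves <- function(observations, config = run_config()) {
  groups <- split(
    observations,
    list(observations$species, observations$treatment),
    drop = TRUE
  )
  rows <- lapply(groups, function(g) {
    tryCatch(
      fit_logistic(g, config),
      error = function(e) {
        warning("growth fit failed for ", g$species[1], " / ",
                g$treatment[1], ": ", conditionMessage(e), call. = FALSE)
        tibble::tibble(
          species = g$species[1], treatment = g$treatment[1],
          M0 = NA_real_, K = NA_real_, xmid = NA_real_, r = NA_real_,
          rss = NA_real_, n_obs = nrow(g), converged = FALSE
        )
      }
    )
  })
  n_bad <- sum(!vapply(rows, function(r) r$converged, logical(1)))
  if (n_bad > 0) {
    warning(n_bad, " species x treatment fit(s) did not converge; ",
            "they are excluded downstream", call. = FALSE)
  }
  dplyr::bind_rows(rows)
}

#' Daily RGR series from a fitted logistic curve
#'
#' Evaluates the analytic RGR ([rgr_logistic()]) on every integer day of an
#' inclusive day range: one value per day between the first and last day.
#'
#' @param fit one-row fit as returned by [fit_logistic()]; must have
#'   `converged = TRUE`.
#' @param day_range inclusive integer interval `c(first, last)`.
#' @return Tibble with `species`, `treatment`, `day`, `rgr` (day^-1), one
#'   row per day; `last - first + 1` rows.
#' @export
rgr_curve <- function(fit, day_range) {
  stopifnot(length(day_range) == 2L, day_range[1] < day_range[2])
  if (!isTRUE(fit$converged[1])) {
    stop("rgr_curve(): fit did not converge", call. = FALSE)
  }
  days <- seq.int(day_range[1], day_range[2])
  tibble::tibble(
    species = fit$species[1],
    treatment = fit$treatment[1],
    day = days,
    rgr = rgr_logistic(days, fit$M0[1], fit$K[1], fit$xmid[1], fit$r[1])
  )
}

#' Daily RGR table for all converged fits
#'
#' @param fits tibble of fits from [fit_growth_curves()]; non-converged rows
#'   are dropped.
#' @inheritParams rgr_curve
#' @return Long tibble `species, treatment, day, rgr`.
#' @export
rgr_table <- function(fits, day_range) {
  fits <- fits[fits$converged, , drop = FALSE]
  if (nrow(fits) == 0L) stop("rgr_table(): no converged fits", call. = FALSE)
  dplyr::bind_rows(lapply(
    seq_len(nrow(fits)),
    function(i) rgr_curve(fits[i, ], day_range)
  ))
}
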