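#' Single-day regression of biomass ratios on RGR ratios
#'
#' Ordinary least squares of the harvest biomass log ratio on the RGR log
#' ratio at one day (a normal-error GLM with identity link). The simple
#' model fits one common slope; the interaction model adds treatment main
#' effects and a treatment x RGR-ratio interaction and reports one slope
#' row per treatment plus the interaction contrast(s) against the reference
#' treatment (first level in radix order). Confidence intervals use the t
#' distribution at `ci_level`.
#'
#' @param records pair-day records for a single day (columns `delta_rgr`,
#'   `delta_b`, and `treatment` for the interaction model).
#' @param model `"simple"` or `"with_treatment_interaction"`.
#' @param ci_level confidence level; default 0.95.
#' @return Tibble with one row per reported term: `term, slope, ci_low,
#'   ci_high, r2, f_stat, df_num, df_den, p, n`. `r2`, the F statistic and
#'   its p-value describe the whole regression.
#' @export
fit_day <- function(records, model = c("simple", "with_treatment_interaction"),
                    ci_level = 0.95) {
  model <- match.arg(model)
  n <- nrow(records)
  if (model == "simple" && n < 3L) {
    stop("fit_day(): need >= 3 records", call. = FALSE)
  }
  if (stats::var(records$delta_rgr) < 1e-24) {
    stop("fit_day(): degenerate regression (zero predictor variance)",
         call. = FALSE)
  }
  alpha <- 1 - ci_level

  if (model == "simple") {
    fit <- stats::lm(delta_b ~ delta_rgr, data = records)
    s <- summary(fit)
    est <- s$coefficients["delta_rgr", ]
    tq <- stats::qt(1 - alpha / 2, fit$df.residual)
    if (stats::var(records$delta_b) < 1e-24) {
      # a variance-free response leaves nothing to explain
      return(tibble::tibble(
        term = "delta_rgr", slope = unname(est["Estimate"]),
        ci_low = unname(est["Estimate"]), ci_high = unname(est["Estimate"]),
        r2 = 0, f_stat = 0, df_num = 1,
        df_den = as.numeric(fit$df.residual), p = 1, n = n
      ))
    }
    f <- s$fstatistic
    return(tibble::tibble(
      term = "delta_rgr",
      slope = unname(est["Estimate"]),
      ci_low = unname(est["Estimate"] - tq * est["Std. Error"]),
      ci_high = unname(est["Estimate"] + tq * est["Std. Error"]),
      r2 = s$r.squared,
      f_stat = unname(f["value"]),
      df_num = unname(f["numdf"]), df_den = unname(f["dendf"]),
      p = stats::pf(f["value"], f["numdf"], f["dendf"], lower.tail = FALSE),
      n = n
    ))
  }

  trts <- sort(unique(records$treatment), method = "radix")
  if (length(trts) < 2L) {
    stop("fit_day(): interaction model needs >= 2 treatments", call. = FALSE)
  }
  counts <- table(records$treatment)
  if (any(counts < 2L)) {
    stop("fit_day(): interaction model needs >= 2 records per treatment",
         call. = FALSE)
  }
  records$treatment <- factor(records$treatment, levels = trts)
  fit <- stats::lm(delta_b ~ delta_rgr * treatment, data = records)
  s <- summary(fit)
  V <- stats::vcov(fit)
  cf <- stats::coef(fit)
  tq <- stats::qt(1 - alpha / 2, fit$df.residual)
  f <- s$fstatistic

  row_for <- function(term, est, se) {
    tibble::tibble(
      term = term, slope = est,
      ci_low = est - tq * se, ci_high = est + tq * se,
      r2 = s$r.squared, f_stat = unname(f["value"]),
      df_num = unname(f["numdf"]), df_den = unname(f["dendf"]),
      p = stats::pf(f["value"], f["numdf"], f["dendf"], lower.tail = FALSE),
      n = n
    )
  }

  out <- list(row_for(paste0("slope:", trts[1]), unname(cf["delta_rgr"]),
                      sqrt(V["delta_rgr", "delta_rgr"])))
  for (tr in trts[-1]) {
    int <- paste0("delta_rgr:treatment", tr)
    est <- unname(cf["delta_rgr"] + cf[int])
    se <- sqrt(V["delta_rgr", "delta_rgr"] + V[int, int] +
                 2 * V["delta_rgr", int])
    out[[length(out) + 1L]] <- row_for(paste0("slope:", tr), est, se)
    out[[length(out) + 1L]] <- row_for(paste0("interaction:", tr),
                                       unname(cf[int]), sqrt(V[int, int]))
  }
  dplyr::bind_rows(out)
}

#' Day-by-day regression sweep over the growing season
#'
#' Runs [fit_day()] for every day of the inclusive range, producing exactly
#' one result row per day (per term for the interaction model). Degenerate
#' days (too few records, zero predictor variance) are recorded as NA rows
#' with the failure message rather than aborting the sweep, and the sweep
#' summary (maximum-R^2 day, slope sign-switch day) is computed from the
#' remaining days.
#'
#' @param pair_table pair-day records from [build_pair_table()].
#' @param day_range inclusive integer interval; defaults to the range of
#'   days present.
#' @inheritParams fit_day
#' @return List: `results` (tibble, one row per day x term, plus a `note`
#'   column for degenerate days) and `summary`
#'   (`max_r2_day, max_r2, switch_day`).
#' @export
sweep_days <- function(pair_table, day_range = NULL,
                       model = c("simple", "with_treatment_interaction"),
                       ci_level = 0.95) {
  model <- match.arg(model)
  if (nrow(pair_table) == 0L) {
    stop("sweep_days(): empty pair table", call. = FALSE)
  }
  if (is.null(day_range)) day_range <- range(pair_table$day)
  days <- seq.int(day_range[1], day_range[2])

  na_row <- function(day, msg) {
    tibble::tibble(
      day = day, term = NA_character_, slope = NA_real_,
      ci_low = NA_real_, ci_high = NA_real_, r2 = NA_real_,
      f_stat = NA_real_, df_num = NA_real_, df_den = NA_real_,
      p = NA_real_, n = 0L, note = msg
    )
  }
  rows <- lapply(days, function(d) {
    rec <- pair_table[pair_table$day == d, , drop = FALSE]
    res <- tryCatch(
      fit_day(rec, model = model, ci_level = ci_level),
      error = function(e) conditionMessage(e)
    )
    if (is.character(res)) return(na_row(d, res))
    res$day <- d
    res$note <- NA_character_
    res[, c("day", "term", "slope", "ci_low", "ci_high", "r2", "f_stat",
            "df_num", "df_den", "p", "n", "note")]
  })
  results <- dplyr::bind_rows(rows)

  slope_rows <- if (model == "simple") {
    results[results$term %in% "delta_rgr", , drop = FALSE]
  } else {
    # summary on the whole-model R^2; one row per day suffices
    results[!duplicated(results$day) & !is.na(results$term), , drop = FALSE]
  }
  summary <- tibble::tibble(
    max_r2_day = tryCatch(find_max_r2_day(slope_rows),
                          error = function(e) NA_integer_),
    max_r2 = if (all(is.na(slope_rows$r2))) NA_real_ else
      max(slope_rows$r2, na.rm = TRUE),
    switch_day = if (model == "simple") find_switch_day(slope_rows)
                 else NA_integer_
  )
  log_stage("sweep_days", nrow(results), " regression row(s) over ",
            length(days), " days")
  list(results = results, summary = summary)
}

#' Day at which the sweep's R-squared is maximal
#'
#' @param results sweep result tibble with columns `day` and `r2`.
#' @return The day of maximum R^2; ties broken to the earliest day.
#' @export
find_max_r2_day <- function(results) {
  ok <- results[!is.na(results$r2), , drop = FALSE]
  if (nrow(ok) == 0L) {
    stop("find_max_r2_day(): no non-degenerate results", call. = FALSE)
  }
  ok <- ok[order(ok$day), , drop = FALSE]
  as.integer(ok$day[which.max(ok$r2)])
}

#' First day at which the sweep slope switches from positive to non-positive
#'
#' Scans consecutive days and returns the first day `d` with
#' `slope(d - 1) > 0` and `slope(d) <= 0`. With `rule = "ci"` the switch
#' additionally requires the confidence interval at `d - 1` to lie entirely
#' above zero and the interval at `d` entirely at or below zero.
#'
#' @param results sweep result tibble (columns `day`, `slope`, and for the
#'   CI rule `ci_low`, `ci_high`).
#' @param rule `"point"` (default, point-estimate sign) or `"ci"`.
#' @return Integer day, or `NA` if the slope never switches.
#' @export
find_switch_day <- function(results, rule = c("point", "ci")) {
  rule <- match.arg(rule)
  ok <- results[!is.na(results$slope), , drop = FALSE]
  ok <- ok[order(ok$day), , drop = FALSE]
  if (nrow(ok) < 2L) return(NA_integer_)
  for (i in 2:nrow(ok)) {
    if (ok$day[i] - ok$day[i - 1L] != 1L) next
    hit <- if (rule == "point") {
      ok$slope[i - 1L] > 0 && ok$slope[i] <= 0
    } else {
      ok$ci_low[i - 1L] > 0 && ok$ci_high[i] <= 0
    }
    if (hit) return(as.integer(ok$day[i]))
  }
  NA_integer_
}
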