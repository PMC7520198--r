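#' Convert a presence table into loss records
#'
#' Keeps records of species present at the first census and exposes the
#' persistence outcome (1 = present at both censuses, 0 = present at the
#' first and absent at the second).
#'
#' @param presence tibble
#'   (`treatment, plot, species, present_start, present_end`).
#' @return Tibble (`treatment, plot, species, outcome`).
#' @export
loss_records_from_presence <- function(presence) {
  keep <- presence$present_start == 1L
  if (!all(keep)) {
    warning("loss_records_from_presence(): dropped ", sum(!keep),
            " record(s) absent at the first census", call. = FALSE)
  }
  df <- presence[keep, , drop = FALSE]
  tibble::tibble(
    treatment = df$treatment, plot = df$plot, species = df$species,
    outcome = as.integer(df$present_end)
  )
}

#' Quasibinomial regression of persistence on daily RGR for one day
#'
#' Logit-link binomial GLM of the persistence outcome on the species'
#' daily RGR, with the dispersion estimated as Pearson chi-squared over
#' residual degrees of freedom (quasibinomial). Standard errors and the
#' confidence interval are scaled by the square root of the dispersion,
#' with a t reference; significance uses the F-type test on the
#' dispersion-scaled deviance change. A negative slope means species with
#' higher RGR at this day are the excluders: records (each a species in a
#' plot) with low RGR are the ones lost. Perfect separation is flagged and
#' the bounded optimiser estimate reported.
#'
#' @param records tibble with columns `outcome` (0/1) and `rgr`.
#' @param ci_level confidence level; default 0.95.
#' @return One-row tibble: `slope, ci_low, ci_high, pseudo_r2, dispersion,
#'   f_stat, df_num, df_den, p, n, separation`. `pseudo_r2` is
#'   `1 - residual deviance / null deviance`.
#' @export
fit_loss_day <- function(records, ci_level = 0.95) {
  n <- nrow(records)
  if (n < 3L) stop("fit_loss_day(): need >= 3 records", call. = FALSE)
  if (length(unique(records$outcome)) < 2L) {
    stop("fit_loss_day(): degenerate outcomes (single class)", call. = FALSE)
  }
  if (stats::var(records$rgr) < 1e-24) {
    stop("fit_loss_day(): zero variance in RGR", call. = FALSE)
  }
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(outcome ~ rgr, family = stats::quasibinomial(),
               data = records,
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  s <- summary(fit)
  est <- s$coefficients["rgr", ]
  tq <- stats::qt(1 - (1 - ci_level) / 2, fit$df.residual)
  disp <- s$dispersion
  dev_drop <- fit$null.deviance - fit$deviance
  f_stat <- (dev_drop / 1) / disp
  tibble::tibble(
    slope = unname(est["Estimate"]),
    ci_low = unname(est["Estimate"] - tq * est["Std. Error"]),
    ci_high = unname(est["Estimate"] + tq * est["Std. Error"]),
    pseudo_r2 = 1 - fit$deviance / fit$null.deviance,
    dispersion = disp,
    f_stat = f_stat, df_num = 1, df_den = fit$df.residual,
    p = stats::pf(f_stat, 1, fit$df.residual, lower.tail = FALSE),
    n = n, separation = sep
  )
}

#' Day-by-day sweep of the species-loss model
#'
#' Joins each species' daily RGR (species x treatment level, shared across
#' plots within a treatment) to the loss records and fits
#' [fit_loss_day()] for every day of the range. Degenerate days
#' (single-class outcomes, missing RGR) are recorded as NA rows; the
#' summary reports the day of maximum pseudo-R^2.
#'
#' @param records loss records (`treatment, plot, species, outcome`) from
#'   [loss_records_from_presence()]; typically one treatment at a time.
#' @param rgr long daily RGR table (`species, treatment, day, rgr`).
#' @param day_range inclusive integer interval.
#' @param ci_level confidence level; default 0.95.
#' @return List: `results` (one row per day) and `summary`
#'   (`max_r2_day, max_r2`).
#' @export
sweep_loss <- function(records, rgr, day_range, ci_level = 0.95) {
  stopifnot(length(day_range) == 2L, day_range[1] < day_range[2])
  if (nrow(records) == 0L) {
    stop("sweep_loss(): no loss records", call. = FALSE)
  }
  days <- seq.int(day_range[1], day_range[2])
  na_row <- function(day, msg) {
    tibble::tibble(
      day = day, slope = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
      pseudo_r2 = NA_real_, dispersion = NA_real_, f_stat = NA_real_,
      df_num = NA_real_, df_den = NA_real_, p = NA_real_, n = 0L,
      separation = NA, note = msg
    )
  }
  rows <- lapply(days, function(d) {
    rd <- rgr[rgr$day == d, c("species", "treatment", "rgr")]
    rec <- dplyr::inner_join(records, rd, by = c("species", "treatment"))
    res <- tryCatch(
      fit_loss_day(rec, ci_level = ci_level),
      error = function(e) conditionMessage(e)
    )
    if (is.character(res)) return(na_row(d, res))
    res$day <- d
    res$note <- NA_character_
    res[, c("day", "slope", "ci_low", "ci_high", "pseudo_r2", "dispersion",
            "f_stat", "df_num", "df_den", "p", "n", "separation", "note")]
  })
  results <- dplyr::bind_rows(rows)
  ok <- results[!is.na(results$pseudo_r2), , drop = FALSE]
  summary <- tibble::tibble(
    max_r2_day = if (nrow(ok) == 0L) NA_integer_ else
      as.integer(ok$day[which.max(ok$pseudo_r2)]),
    max_r2 = if (nrow(ok) == 0L) NA_real_ else max(ok$pseudo_r2)
  )
  log_stage("sweep_loss", nrow(results), " loss regression(s) over ",
            length(days), " days")
  list(results = results, summary = summary)
}
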