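test_that("noise-free logistic data recover the generating parameters", {
  truth <- tibble::tibble(species = "sp01", treatment = "ambient",
                          M0 = 2, K = 6, xmid = 120, r = 10, sigma = 0)
  obs <- generate_monoculture_series(truth, garden_days(), 1L, seed = 1L)
  fit <- fit_logistic(obs, run_config())
  expect_true(fit$converged)
  expect_lt(abs(fit$M0 - 2), 1e-4)
  expect_lt(abs(fit$K - 6), 1e-4)
  expect_lt(abs(fit$xmid - 120), 1e-4)
  expect_lt(abs(fit$r - 10), 1e-4)
  expect_lt(fit$rss, 1e-10)
})

test_that("deficient or degenerate series are refused", {
  few <- tibble::tibble(day = rep(120L, 6), biomass = exp(rnorm(6, 4, 0.1)))
  expect_error(fit_logistic(few), ">= 5 distinct days")
  flat <- tibble::tibble(day = garden_days(), biomass = 5)
  expect_error(fit_logistic(flat), "degenerate")
})

test_that("per-plot aggregation averages plot-level parameters", {
  truth <- tibble::tibble(species = "sp01", treatment = "ambient",
                          M0 = 1, K = 5, xmid = 115, r = 12, sigma = 0.1)
  obs <- generate_monoculture_series(truth, garden_days(), 5L, seed = 2L)
  cfg <- run_config(aggregation = "per_plot_then_average", seed = 2L)
  fit <- fit_logistic(obs, cfg)
  expect_true(fit$converged)
  expect_lt(abs(fit$xmid - 115), 10)
  per_plot <- lapply(split(obs, obs$plot), fit_logistic, config = run_config(seed = 2L))
  expect_equal(fit$K, mean(vapply(per_plot, function(f) f$K, numeric(1))),
               tolerance = 1e-8)
})

test_that("the analytic RGR matches its closed form and the curve derivative", {
  fit <- tibble::tibble(species = "s", treatment = "t", M0 = 2, K = 6,
                        xmid = 120, r = 10, rss = 0, n_obs = 11L,
                        converged = TRUE)
  # maximum at the inflection day: (K - M0) / (4 r) = 4 / 40
  expect_equal(rgr_logistic(120, 2, 6, 120, 10), 0.1, tolerance = 1e-12)

  rc <- rgr_curve(fit, c(53L, 171L))
  expect_equal(nrow(rc), 119L)
  expect_equal(rc$rgr[rc$day == 120], 0.1, tolerance = 1e-12)
  expect_true(all(rc$rgr > 0))

  # central finite difference of the log curve, h = 1e-4
  set.seed(31)
  for (i in 1:20) {
    M0 <- runif(1, -1, 1); K <- M0 + runif(1, 2, 6)
    xmid <- runif(1, 90, 150); r <- runif(1, 5, 25)
    t <- runif(1, 53, 171); h <- 1e-4
    num <- (logistic_log_biomass(t + h, M0, K, xmid, r) -
              logistic_log_biomass(t - h, M0, K, xmid, r)) / (2 * h)
    expect_equal(rgr_logistic(t, M0, K, xmid, r), num, tolerance = 1e-6)
  }

  expect_error(rgr_curve(dplyr::mutate(fit, converged = FALSE), c(53L, 171L)),
               "converge")
})

test_that("daily RGR integrates back to the log-biomass change", {
  # trapezoid sum of the derivative recovers the curve increment
  M0 <- 0.5; K <- 5; xmid <- 118; r <- 9
  days <- 53:171
  rgr <- rgr_logistic(days, M0, K, xmid, r)
  trap <- sum((rgr[-1] + rgr[-length(rgr)]) / 2)
  delta_log <- logistic_log_biomass(171, M0, K, xmid, r) -
    logistic_log_biomass(53, M0, K, xmid, r)
  expect_lt(abs(trap - delta_log), 1e-3 * (171 - 53) / 100)

  # symmetric about the inflection day
  for (d in c(1, 5, 20, 60)) {
    expect_equal(rgr_logistic(xmid + d, M0, K, xmid, r),
                 rgr_logistic(xmid - d, M0, K, xmid, r), tolerance = 1e-12)
  }
})

test_that("two-point RGR has its closed form and approximates the daily mean", {
  expect_equal(simple_rgr(10, 10, 14), 0)
  expect_equal(simple_rgr(10, 20, 14), log(2) / 14, tolerance = 1e-12)
  expect_error(simple_rgr(0, 10, 14), "positive")
  expect_error(simple_rgr(10, 10, 0), "dt")

  # over an interval no longer than r, the two-point RGR matches the mean
  # daily RGR because RGR is the derivative of log biomass
  M0 <- 1; K <- 5; xmid <- 120; r <- 14
  t0 <- 55; t1 <- 67
  b0 <- exp(logistic_log_biomass(t0, M0, K, xmid, r))
  b1 <- exp(logistic_log_biomass(t1, M0, K, xmid, r))
  two_point <- simple_rgr(b0, b1, t1 - t0)
  daily_mean <- mean(rgr_logistic(t0:t1, M0, K, xmid, r))
  expect_lt(abs(two_point - daily_mean) / daily_mean, 0.05)
})

test_that("parameters are recovered from noisy replicated series", {
  # 200 replicates at the garden design: sigma 0.15, 5 plots, 11 days
  xmid_err <- k_rel_err <- numeric(200)
  for (rep in 1:200) {
    truth <- withr::with_seed(rep, {
      M0 <- runif(1, -1, 1)
      tibble::tibble(
        species = "s", treatment = "t",
        M0 = M0, K = M0 + runif(1, 2, 6), xmid = runif(1, 100, 140),
        r = runif(1, 5, 25), sigma = 0.15
      )
    })
    obs <- generate_monoculture_series(truth, garden_days(), 5L,
                                       seed = 10000L + rep)
    fit <- tryCatch(fit_logistic(obs, run_config(seed = rep)),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      xmid_err[rep] <- NA; k_rel_err[rep] <- NA
    } else {
      xmid_err[rep] <- abs(fit$xmid - truth$xmid)
      k_rel_err[rep] <- abs(fit$K - truth$K) / abs(truth$K)
    }
  }
  expect_lt(median(xmid_err, na.rm = TRUE), 5)
  expect_lt(median(k_rel_err, na.rm = TRUE), 0.05)
})

test_that("fit_growth_curves flags and skips failing groups", {
  truth <- generate_truth(2L, "ambient", seed = 40L)$species
  obs <- generate_monoculture_series(truth, garden_days(), 2L, seed = 41L)
  # sabotage one group: too few distinct days
  bad <- obs[obs$species == "sp01" & obs$day %in% garden_days()[1:3], ]
  keep <- rbind(bad, obs[obs$species == "sp02", ])
  w <- capture_warnings(fits <- fit_growth_curves(keep, run_config()))
  expect_true(any(grepl("did not converge|failed", w)))
  expect_false(fits$converged[fits$species == "sp01"])
  expect_true(fits$converged[fits$species == "sp02"])
  rt <- rgr_table(fits, c(53L, 171L))
  expect_setequal(unique(rt$species), "sp02")
})
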