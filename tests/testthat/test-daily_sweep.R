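test_that("single-day regression handles exact and null relationships", {
  exact <- tibble::tibble(delta_rgr = c(-2, -1, 0, 1, 2),
                          delta_b = 2 * c(-2, -1, 0, 1, 2))
  res <- suppressWarnings(fit_day(exact))  # exact fit: zero residual
  expect_equal(res$slope, 2, tolerance = 1e-10)
  expect_equal(res$r2, 1, tolerance = 1e-10)
  expect_lt(res$ci_high - res$ci_low, 1e-6)

  set.seed(91)
  null <- tibble::tibble(delta_rgr = rnorm(20), delta_b = 1)
  res0 <- suppressWarnings(fit_day(null))
  expect_equal(res0$slope, 0, tolerance = 1e-10)
  expect_equal(res0$r2, 0, tolerance = 1e-10)

  expect_error(fit_day(exact[1:2, ]), ">= 3 records")
  degen <- tibble::tibble(delta_rgr = rep(1, 5), delta_b = rnorm(5))
  expect_error(fit_day(degen), "degenerate")
})

test_that("fit_day agrees with the closed-form normal equations to 1e-10", {
  set.seed(92)
  for (case in 1:5) {
    d <- tibble::tibble(delta_rgr = rnorm(10), delta_b = rnorm(10))
    res <- fit_day(d, ci_level = 0.95)
    o <- ols_oracle(d$delta_rgr, d$delta_b, 0.95)
    expect_equal(res$slope, o$slope, tolerance = 1e-10)
    expect_equal(res$ci_low, o$ci_low, tolerance = 1e-10)
    expect_equal(res$ci_high, o$ci_high, tolerance = 1e-10)
    expect_equal(res$r2, o$r2, tolerance = 1e-10)
  }
})

test_that("the treatment-interaction model reports per-treatment slopes", {
  set.seed(93)
  x <- rnorm(40)
  trt <- rep(c("ambient", "fertilized"), each = 20)
  y <- ifelse(trt == "ambient", 0.5, 0.9) * x + rnorm(40, 0, 0.05)
  d <- tibble::tibble(delta_rgr = x, treatment = trt, delta_b = y)
  res <- fit_day(d, model = "with_treatment_interaction")
  sl <- setNames(res$slope, res$term)
  expect_equal(unname(sl["slope:ambient"]), 0.5, tolerance = 0.05)
  expect_equal(unname(sl["slope:fertilized"]), 0.9, tolerance = 0.05)
  expect_equal(unname(sl["interaction:fertilized"]),
               unname(sl["slope:fertilized"] - sl["slope:ambient"]),
               tolerance = 1e-10)
  # per-treatment slopes equal separate per-treatment OLS fits
  oa <- ols_oracle(x[trt == "ambient"], y[trt == "ambient"])
  expect_equal(unname(sl["slope:ambient"]), oa$slope, tolerance = 1e-10)
})

test_that("sweeps cover each day of the range, recording degenerate days", {
  tr <- generate_truth(5L, "fertilized", seed = 94L)
  harvest <- generate_mixture_harvest(tr$species, tr$competition, 60L,
                                      seed = 95L, n_reps = 2L,
                                      mixtures = "pairwise")
  rgr <- truth_rgr_table(tr$species, c(53L, 171L))
  pt <- suppressMessages(build_pair_table(rgr, harvest, c(53L, 171L)))
  sw <- suppressMessages(sweep_days(pt, c(53L, 171L)))
  expect_equal(nrow(sw$results), 119L)
  expect_equal(sw$results$day, 53:171)

  tr_f <- generate_truth(5L, "N", seed = 96L, design = "field")
  rgr_f <- truth_rgr_table(tr_f$species, c(146L, 254L))
  harv_f <- generate_mixture_harvest(tr_f$species, tr_f$competition, 200L,
                                     seed = 97L, n_reps = 2L,
                                     mixtures = "pairwise")
  pt_f <- suppressMessages(build_pair_table(rgr_f, harv_f, c(146L, 254L)))
  sw_f <- suppressMessages(sweep_days(pt_f, c(146L, 254L)))
  expect_equal(nrow(sw_f$results), 109L)

  expect_error(sweep_days(pt[0, ], c(53L, 171L)), "empty")
})

test_that("the maximum-R2 day is the argmax with earliest-day ties", {
  res <- tibble::tibble(day = c(10L, 11L, 12L), r2 = c(0.1, 0.5, 0.3))
  expect_equal(find_max_r2_day(res), 11L)
  tie <- tibble::tibble(day = c(10L, 11L), r2 = c(0.5, 0.5))
  expect_equal(find_max_r2_day(tie), 10L)

  set.seed(98)
  rand <- tibble::tibble(day = 53:171, r2 = runif(119))
  brute <- rand$day[order(-rand$r2, rand$day)][1]  # exhaustive scan
  expect_equal(find_max_r2_day(rand), brute)
  expect_error(find_max_r2_day(tibble::tibble(day = 1L, r2 = NA_real_)),
               "non-degenerate")
})

test_that("the switch day is the first positive-to-nonpositive transition", {
  res <- tibble::tibble(day = 1:4, slope = c(1, 0.5, -0.2, -1))
  expect_equal(find_switch_day(res), 3L)
  pos <- tibble::tibble(day = 1:4, slope = c(1, 0.5, 0.2, 0.1))
  expect_true(is.na(find_switch_day(pos)))
})

test_that("crossing RGR curves place the switch day at the crossing", {
  # three species pairs with symmetric inflection days around 115.5 and a
  # common scale: every pair's RGR log ratio crosses zero at t = 115.5
  xm <- rbind(c(100, 131), c(105, 126), c(110, 121))
  truth <- tibble::tibble(
    species = sprintf("sp%02d", 1:6), treatment = "ambient",
    M0 = 0, K = 4, xmid = as.vector(t(xm)), r = 15, sigma = 0
  )
  rgr <- truth_rgr_table(truth, c(53L, 171L))
  harvest <- dplyr::bind_rows(lapply(1:3, function(k) {
    i <- 2 * k - 1; j <- 2 * k
    d_rgr <- log(rgr_logistic(60, 0, 4, xm[k, 1], 15) /
                   rgr_logistic(60, 0, 4, xm[k, 2], 15))
    share <- plogis(d_rgr)  # lambda = 1, noise-free
    tibble::tibble(treatment = "ambient",
                   mixture_id = sprintf("m%d", k),
                   species = truth$species[c(i, j)],
                   biomass = 100 * c(share, 1 - share))
  }))
  pt <- suppressMessages(build_pair_table(rgr, harvest, c(53L, 171L)))
  sw <- suppressWarnings(suppressMessages(sweep_days(pt, c(53L, 171L))))  # exact fits
  switch_day <- sw$summary$switch_day
  expect_false(is.na(switch_day))
  expect_lte(abs(switch_day - 115.5), 2)
})

test_that("the slope error at the generating day shrinks with the noise", {
  # scaling a fixed noise vector scales the OLS slope error linearly
  set.seed(99)
  x <- rnorm(50)
  z <- rnorm(50)
  errs <- vapply(c(0.2, 0.02, 0.002), function(eps) {
    d <- tibble::tibble(delta_rgr = x, delta_b = 0.8 * x + eps * z)
    abs(fit_day(d)$slope - 0.8)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})
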