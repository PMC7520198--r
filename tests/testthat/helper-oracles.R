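# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: closed-form normal equations instead of lm(),
# direct likelihood maximisation instead of glm(), explicit permutation
# enumeration instead of the subset-weight formula.

# Textbook OLS of y on x: slope, t-based CI, R^2.
ols_oracle <- function(x, y, ci_level = 0.95) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  se <- sqrt(rss / (n - 2) / sxx)
  tq <- qt(1 - (1 - ci_level) / 2, n - 2)
  list(
    slope = slope,
    ci_low = slope - tq * se, ci_high = slope + tq * se,
    r2 = 1 - rss / tss
  )
}

# Bernoulli logit log-likelihood for outcome y given linear predictor.
logit_loglik <- function(par, x, y) {
  eta <- par[1] + par[2] * x
  sum(y * eta - log1p(exp(eta)))
}

# Maximum-likelihood logistic slope by direct optimisation (analytic
# gradient; parameters scaled by the predictor spread so the intercept and
# slope are optimised on comparable scales).
logit_ml_oracle <- function(x, y) {
  grad <- function(p) {
    pr <- plogis(p[1] + p[2] * x)
    -c(sum(y - pr), sum((y - pr) * x))
  }
  opt <- optim(c(0, 0), function(p) -logit_loglik(p, x, y), gr = grad,
               method = "BFGS",
               control = list(maxit = 10000, reltol = 1e-15,
                              parscale = c(1, 1 / sd(x))))
  opt$par
}

# LMG shares by brute-force averaging of sequential R^2 increments over
# every ordering of the predictors.
lmg_orderings_oracle <- function(data, response, predictors) {
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  r2_of <- function(sub) {
    if (length(sub) == 0L) return(0)
    summary(lm(reformulate(sub, response = response), data = data))$r.squared
  }
  orders <- perms(predictors)
  shares <- setNames(numeric(length(predictors)), predictors)
  for (ord in orders) {
    prev <- 0
    for (i in seq_along(ord)) {
      cur <- r2_of(ord[seq_len(i)])
      shares[ord[i]] <- shares[ord[i]] + (cur - prev)
      prev <- cur
    }
  }
  shares / length(orders)
}

# Long daily RGR table computed directly from ground-truth parameters,
# bypassing the curve-fitting stage.
truth_rgr_table <- function(truth, day_range) {
  days <- seq.int(day_range[1], day_range[2])
  dplyr::bind_rows(lapply(seq_len(nrow(truth)), function(i) {
    s <- truth[i, ]
    tibble::tibble(
      species = s$species, treatment = s$treatment, day = days,
      rgr = rgr_logistic(days, s$M0, s$K, s$xmid, s$r)
    )
  }))
}

# A small deterministic sweep-style result table for io round-trips.
toy_sweep_table <- function() {
  set.seed(42)
  tibble::tibble(
    day = 53:62,
    term = "delta_rgr",
    slope = rnorm(10),
    ci_low = rnorm(10) - 1,
    ci_high = rnorm(10) + 1,
    r2 = runif(10),
    p = runif(10),
    n = 50L
  )
}
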