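---
title: "Methods: daily growth rates and the timing of competitive dominance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: daily growth rates and the timing of competitive dominance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`rgrsweep` links differences in plant relative growth rate (RGR) through a
growing season to short-term competitive outcomes — dominance in mixtures
and local extinction under nutrient addition. This vignette documents the
models, the choices behind them, and what the synthetic validation does and
does not demonstrate.

## Growth model and daily RGR

Log biomass of each species × nutrient treatment follows a four-parameter
logistic,

$$\log M(t) = M_0 + \frac{K - M_0}{1 + e^{(x_{mid}-t)/r}},$$

chosen because seasonal growth rises, saturates, and does so asymmetrically
in time. The parameters have direct ecological readings: $M_0$ and $K$ are
the early- and late-season log-biomass asymptotes (log g), $x_{mid}$ the
inflection day at which growth is fastest, $r$ a time scale (days)
controlling how concentrated the growth period is. Fitting is least squares
on the natural-log scale, which makes the multiplicative sampling noise of
clipped-quadrat biomass approximately homoscedastic.

RGR is *defined* as $\mathrm{d}\log M/\mathrm{d}t$, so the fitted curve
yields an analytic daily value

$$\mathrm{RGR}_t = \frac{(K-M_0)\,u}{r\,(1+u)^2}, \qquad u = e^{(x_{mid}-t)/r},$$

maximal at $t = x_{mid}$ with value $(K-M_0)/(4r)$, strictly positive
whenever $K > M_0$, and symmetric about $x_{mid}$. Two consequences are used
as internal checks: the trapezoid sum of daily RGR reproduces the
log-biomass change between any two days, and the analytic value agrees with
a finite-difference derivative of the curve.

**Fitting strategy.** The original analysis style for such data is a
nonlinear mixed-effects fit with species and treatment random effects on
all four parameters. This package instead fits each species × treatment
independently (by default pooling replicate plots; per-plot fitting with
parameter averaging is available via `aggregation`). The downstream
quantities are per-group parameter values, not variance components, and
independent fits recover them without the fragility of a 4-dimensional
random-effect covariance on 5–20 groups; this is a deliberate
simplification, and variance components are explicitly out of scope.

**Numerical choices.** Start values: $M_0^{(0)}$ and $K^{(0)}$ from the
observed extremes of log biomass, $x_{mid}^{(0)}$ at the steepest observed
rise of the day-mean log biomass, $r^{(0)}$ = day span / 6. Ten jittered
restarts (seeded from the run configuration) are added and the
Levenberg–Marquardt solution with the lowest residual sum of squares wins;
$r$ is bounded below at $10^{-3}$ days. A fit needs at least 5 distinct
days (one per parameter plus one); series with constant biomass are
refused as degenerate. Non-converged groups are flagged and excluded
downstream with a warning rather than silently dropped. Fits with
$K \le M_0$ (declining series) are retained but produce non-positive RGR,
which the pairwise stage excludes record by record with a logged count.

The two-point RGR $\ln(B_1/B_0)/\Delta t$ is provided as a model-free
robustness check; because RGR is the derivative of log biomass it equals
the interval mean of the daily values for any smooth growth curve.

## Pairwise log response ratios

Dominance at harvest is $\Delta B_{ij} = \ln(B_i/B_j)$ and the daily
predictor $\Delta \mathrm{RGR}_{tij} = \ln(\mathrm{RGR}_{ti}/\mathrm{RGR}_{tj})$.
Each unordered pair enters once, in a fixed (radix) label order: including
both directions would duplicate every record with flipped signs and force
the intercept to zero mechanically. The choice is covered by a sign-
invariance property — relabelling species reverses both ratios and leaves
every slope and $R^2$ unchanged. In multi-species mixtures all
within-mixture pairs share the same harvest. Replicate mixtures contribute
replicate-level records rather than being averaged first; means would
discard between-replicate variation that the regression's error term
should see.

## The daily regression sweep

For each day, $\Delta B$ is regressed on $\Delta \mathrm{RGR}_t$ by OLS —
a normal-error GLM with identity link, so "GLM" and OLS are the same
estimator here — with t-based confidence intervals at `ci_level` (default
0.95) and the regression F test. The interaction model adds treatment main
effects and a treatment × predictor interaction (treatment-coded, first
treatment in radix order as reference) and reports per-treatment slopes
with delta-method intervals plus the interaction contrasts. For the
four-treatment field layout, treatments are swept separately and compared
informally, without a formal between-treatment test.

Degenerate days — too few records, zero predictor variance after
exclusions — are recorded as gaps with the failure message and the sweep
continues; late-season exclusions are expected when declining fits produce
non-positive RGR. If the response itself has zero variance the day is
reported with $R^2 = 0$ (nothing to explain) rather than an unstable
0/0 ratio. The maximum-$R^2$ day breaks ties toward the earliest day. The
slope switch day is the first day whose *point estimate* turns
non-positive after a positive predecessor, matching how such switches are
usually annotated on sweep figures; a stricter variant requiring the CIs
to exclude zero on both sides is available (`rule = "ci"`).

## Species-loss model

Persistence between two censuses (1 = present at both, 0 = lost) is
modelled per plot × species record by a logit-link GLM with quasibinomial
dispersion (Pearson $\chi^2$/df), the convention for over/under-dispersed
presence data. Confidence intervals scale the standard error by
$\sqrt{\text{dispersion}}$ with a t reference, and significance uses the
F-type test on the dispersion-scaled deviance drop. The reported
pseudo-$R^2$ is $1 - D_{res}/D_{null}$ — a documented choice among several
"R²" analogues for binomial models. The predictor is the species ×
treatment daily RGR shared across plots: the growth curves are estimated
at that level, and pretending plot-level precision would understate the
predictor's granularity. Perfect separation is flagged and the bounded
estimate reported rather than hidden.

## Trait variance partition

Height, SLA (leaf area / leaf dry mass, mm²/mg) and LDMC (leaf dry mass /
leaf fresh mass) enter, like RGR, as natural-log pair ratios. The
full-model $R^2$ of $\Delta B$ on the four predictors is decomposed by
averaging sequential sums-of-squares increments over predictor orderings
(Lindeman–Merenda–Gold). With four predictors the decomposition is exact
and cheap via the subset formulation ($2^4$ subset fits with Shapley
weights); the test suite checks it against explicit enumeration of all 24
orderings. Shares are nonnegative, order-invariant, and sum to the full
$R^2$; they are reported as percentages of $R^2$. The partition day is
each treatment's maximum-$R^2$ day from the dominance sweep. Traits are
treated as static species × treatment attributes; where trait and
abundance measurements come from different years this assumes temporal
stability of the trait ranking.

## Synthetic data and what validation shows

The generator reproduces the two standard layouts. Garden: 5 species × 2
treatments (`ambient`, `fertilized`) × 5 plots with 11 harvest days
between day 53 and 171; pairwise mixtures (5 replicates) plus a
five-species mixture. Field: 20 species × 4 treatments (`control`, `N`,
`P`, `NP`) with 8 harvest days between day 146 and 254, 12 sampled
individuals per day treated as replicate plots, community mixtures in 6
plots, loss records over 6 plots, and traits.

Ground truth: $M_0 \sim U(-1,1)$, $K - M_0 \sim U(2,6)$,
$x_{mid} \sim U(90,150)$ (garden) or $U(150,210)$ (field),
$r \sim U(5,25)$ days. Biomass noise is Normal on the log scale with
$\sigma = 0.15$ — a documented default (field studies of this type do not
publish their residual SDs) giving ±15% multiplicative scatter, typical of
clipped-quadrat biomass. Dominance is injected at a reference day (60
garden, 160 field): $\Delta B = \lambda_t \Delta\mathrm{RGR}_{ref} +
\varepsilon$, $\varepsilon \sim N(0, 0.4)$, with $\lambda_t = 0.9$ in
productive treatments (`fertilized`, `N`, `NP`) and $0.5$ otherwise —
chosen once to mirror the qualitative contrast the method targets (steeper
dominance under fertilization). Pair biomasses are reconstructed from the
ratio at a fixed pair total, since only the ratio is analysed; community
mixtures use per-species log biomass $\lambda_t \log \mathrm{RGR}_{ref} +
\varepsilon/\sqrt2$, which induces the same pairwise structure with
realistic within-community correlation. Persistence is Bernoulli with
logit $\alpha + \beta\,\mathrm{RGR}_{ref}$, $\alpha = 2.5$ and
$\beta = -30$ in productive treatments (0 otherwise), so that roughly
10–40% of records are lost and losses concentrate on particular growth
ranks. Traits are drawn with target log-scale correlations to log RGR of
+0.15 (height), −0.31 (SLA), +0.26 (LDMC).

What passing recovery tests show: the sweep machinery estimates the
generating slope with nominal CI coverage, localises the generating day,
and signs the loss relationship correctly *under the generator's
assumptions* — lognormal noise, a single injected reference day, logistic
growth. Real data violate all three in degree: growth can be multi-phase,
dominance accrues over windows rather than a single day, and harvest noise
has outliers. The validation therefore certifies the statistical
machinery, not the biological model; the day-resolution of real sweeps
should be read as indicative, with adjacent days heavily correlated.

Problem sizes in the shipped tests and acceptance script (500 replicates
for CI coverage at a single day, 100 full-sweep replicates for
localisation, 200 for null coverage) were chosen so Monte-Carlo error is
small relative to the tested bounds while a full run stays comfortably
interactive.

## Known limitations

* No random-effect covariance between growth parameters; uncertainty in
  RGR is not propagated into the sweep (daily regressions treat
  $\Delta\mathrm{RGR}_t$ as fixed). Slopes are therefore attenuated when
  curve-fit error is large relative to between-species RGR spread.
* The sweep's per-day inferences are not corrected for multiplicity across
  days, matching standard practice for these figures; switch and max-$R^2$
  days are point summaries without uncertainty intervals.
* Species dropping out of sampling mid-season (e.g. at flowering) is
  supported only as missing harvest days; no informative-dropout
  correction is attempted.
* The loss model ignores recolonisation and multi-census dynamics.
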