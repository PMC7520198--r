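# rgrsweep

Does growing faster *early* in the season decide who wins? In fertilized
grasslands, competition is largely for light, and a species that
accumulates biomass quickly in spring can shade out its neighbours long
before peak standing biomass. `rgrsweep` implements the full statistical
pipeline for testing this idea with sequential-harvest biomass data: it
estimates each species' daily relative growth rate (RGR) from a fitted
growth curve, asks on *which day* of the season growth-rate differences
best predict competitive dominance in mixtures, and extends the same logic
to the probability that a species is competitively excluded after
fertilization.

The package is aimed at plant community ecologists with time-resolved
biomass data: monoculture (or mixture) harvests repeated through a growing
season, mixture harvests at peak biomass, presence records across censuses,
and standard leaf traits.

## The model and statistics

**Growth curves.** Aboveground dry biomass `M(t)` for each species ×
nutrient treatment is modelled on the natural-log scale with a
four-parameter logistic,

    log M(t) = M0 + (K − M0) / (1 + exp((xmid − t) / r))

with lower asymptote `M0`, upper asymptote `K` (log grams), inflection day
`xmid`, and time scale `r` (days). Because RGR is by definition
d log M / dt, the fitted curve gives an analytic daily RGR,

    RGR_t = (K − M0) · u / (r (1 + u)²),   u = exp((xmid − t) / r)

which peaks at `t = xmid` with value `(K − M0)/(4r)`. One RGR value is
produced for every day between the first and last harvest (119 values for
a day-53–171 season; 109 for day 146–254).

**Dominance sweep.** For species pairs (i, j) grown together, dominance at
harvest is the log response ratio `ΔB_ij = ln(B_i/B_j)` and the daily
predictor is `ΔRGR_tij = ln(RGR_ti/RGR_tj)`. `ΔB` is regressed on `ΔRGR_t`
separately for every day `t` (OLS; slope, t-based 95% CI, R², F). The day
with maximal R² locates when growth differences matter most; the first day
the slope turns non-positive marks when early advantages reverse.

**Exclusion model.** Persistence between two censuses (1 = still present,
0 = lost) is regressed on the species' daily RGR with a quasibinomial
(logit link, Pearson-χ²/df dispersion) GLM, again swept day by day.

**Trait partition.** The variance in `ΔB` explained jointly by log ratios
of RGR, specific leaf area (SLA), leaf dry matter content (LDMC) and
height is split into per-predictor shares by averaging sequential R²
increments over all predictor orderings (LMG decomposition), reported as
percentages of the full-model R².

A seeded synthetic-data generator reproduces both study layouts (garden:
5 species × 2 treatments × 5 plots × 11 harvest days; field: 20 species ×
4 treatments × 8 harvest days with loss records and traits) with known
ground truth, so every stage can be validated by parameter recovery.

## Worked example

```r
library(rgrsweep)
run <- run_garden_pipeline(seed = 1)

run$fits[run$fits$treatment == "fertilized",
         c("species", "M0", "K", "xmid", "r", "converged")]
#>   species     M0     K  xmid     r converged
#> 1 sp01     0.688  4.79  110.  11.8 TRUE
#> 2 sp02    -0.793  2.22  148.  34.3 TRUE
#> ...

fert <- run$sweeps[["fertilized"]]
fert$summary
#>   max_r2_day max_r2 switch_day
#> 1         72  0.835        117

fert$results[fert$results$day %in% c(60, 100, 140),
             c("day", "slope", "ci_low", "ci_high", "r2")]
#>     day  slope ci_low ci_high    r2
#> 1    60  0.782  0.692   0.872 0.751
#> 2   100  0.618  0.407   0.830 0.256
#> 3   140 -0.995 -1.21   -0.783 0.470
```

Each fitted row gives one species' growth curve under fertilization; the
sweep shows that RGR differences around day 60–72 predict three quarters
of the variance in final biomass ratios (slope ≈ 0.78, close to the
generator's true dominance slope of 0.9 at its reference day 60), the
relationship weakens through mid-season, and by day 117 it has switched
sign: late-season growth differences run *against* final dominance, since
early winners have already peaked while slow starters are still growing.

`run_field_pipeline(seed = 1)` adds per-treatment exclusion sweeps (under
N addition the persistence slope at the reference day is negative: the
records of slow-growing species are the ones lost), RGR–trait
correlations, and the LMG partition, in which the RGR log ratio dominates
the trait predictors.

## Command line

A thin CLI over the same functions lives at
`inst/scripts/rgrsweep-cli.R` with subcommands `simulate`, `fit-growth`,
`pair-table`, `sweep`, `exclude`, `partition` and `run-all`, sharing the
flags `--config` (YAML), `--seed`, `--out-dir`, `--day-start`,
`--day-end`, `--design`. Inputs are CSV; results are written as TSV
(`fits.tsv`, `rgr_daily.tsv`, `pair_table.tsv`, `sweep.tsv`,
`exclusion_sweep.tsv`, `partition.tsv`).
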