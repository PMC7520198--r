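#' Run the full garden analysis on simulated or supplied data
#'
#' End-to-end: simulate (or accept) monoculture biomass series and mixture
#' harvests, fit the logistic growth curves, derive daily RGR over days
#' 53..171, build the pair table, and sweep the daily regression both per
#' treatment (simple model) and jointly with the treatment interaction.
#'
#' @param seed integer seed for the simulation.
#' @param config a [run_config()]; day range defaults to `c(53, 171)`.
#' @param sim optional pre-built simulation (from
#'   [simulate_study()]`("garden", ...)`); when supplied, `seed` is ignored
#'   for data generation.
#' @return List: `sim`, `fits`, `rgr`, `pair_table`, `sweeps` (per
#'   treatment: `results` + `summary`), `sweep_interaction`.
#' @export
run_garden_pipeline <- function(seed = 1L,
                                config = run_config(day_range = c(53L, 171L),
                                                    seed = seed),
                                sim = NULL) {
  if (is.null(sim)) sim <- simulate_study("garden", seed = seed)
  fits <- fit_growth_curves(sim$biomass, config)
  rgr <- rgr_table(fits, config$day_range)
  pair_table <- build_pair_table(rgr, sim$mixture_harvest, config$day_range)
  sweeps <- lapply(
    stats::setNames(nm = sort(unique(pair_table$treatment), method = "radix")),
    function(tr) sweep_days(pair_table[pair_table$treatment == tr, ],
                            config$day_range, model = "simple",
                            ci_level = config$ci_level)
  )
  sweep_interaction <- sweep_days(pair_table, config$day_range,
                                  model = "with_treatment_interaction",
                                  ci_level = config$ci_level)
  list(sim = sim, fits = fits, rgr = rgr, pair_table = pair_table,
       sweeps = sweeps, sweep_interaction = sweep_interaction)
}

#' Run the full field analysis on simulated or supplied data
#'
#' End-to-end for the field design: growth fits and daily RGR over days
#' 146..254, per-treatment dominance sweeps (models fitted separately per
#' treatment), per-treatment species-loss sweeps, RGR-trait correlations,
#' and the variance partition of biomass ratios among RGR and the leaf
#' traits at each treatment's maximum-R^2 day.
#'
#' @inheritParams run_garden_pipeline
#' @param sim optional pre-built simulation from
#'   [simulate_study()]`("field", ...)`.
#' @return List: `sim`, `fits`, `rgr`, `pair_table`, `sweeps`,
#'   `loss_sweeps`, `trait_correlations`, `partitions` (per treatment).
#' @export
run_field_pipeline <- function(seed = 1L,
                               config = run_config(day_range = c(146L, 254L),
                                                   seed = seed),
                               sim = NULL) {
  if (is.null(sim)) sim <- simulate_study("field", seed = seed)
  fits <- fit_growth_curves(sim$biomass, config)
  rgr <- rgr_table(fits, config$day_range)
  pair_table <- build_pair_table(rgr, sim$mixture_harvest, config$day_range)
  treatments <- sort(unique(pair_table$treatment), method = "radix")

  sweeps <- lapply(stats::setNames(nm = treatments), function(tr) {
    sweep_days(pair_table[pair_table$treatment == tr, ], config$day_range,
               model = "simple", ci_level = config$ci_level)
  })

  loss <- loss_records_from_presence(sim$presence)
  loss_sweeps <- lapply(stats::setNames(nm = treatments), function(tr) {
    sweep_loss(loss[loss$treatment == tr, ], rgr, config$day_range,
               ci_level = config$ci_level)
  })

  # correlations on the species x treatment level, log scale, at the
  # reference partition day of each treatment
  partitions <- lapply(stats::setNames(nm = treatments), function(tr) {
    d <- sweeps[[tr]]$summary$max_r2_day
    if (is.na(d)) return(NULL)
    recs <- pair_table[pair_table$treatment == tr & pair_table$day == d, ]
    tab <- build_trait_partition_table(recs, sim$traits)
    partition_r2(tab, "delta_b", c("delta_rgr", "d_sla", "d_ldmc",
                                   "d_height"))
  })

  der <- derive_leaf_traits(sim$traits$leaf_area, sim$traits$leaf_dry_mass,
                            sim$traits$leaf_fresh_mass)
  ref <- dplyr::inner_join(
    tibble::tibble(treatment = sim$traits$treatment,
                   species = sim$traits$species,
                   height = log(sim$traits$height),
                   sla = log(der$sla), ldmc = log(der$ldmc)),
    rgr[rgr$day == sim$ref_day, c("species", "treatment", "rgr")],
    by = c("species", "treatment")
  )
  ref$rgr <- log(ref$rgr)
  trait_correlations <- correlate_rgr_traits(
    ref[, c("rgr", "height", "sla", "ldmc")], ci_level = config$ci_level
  )

  list(sim = sim, fits = fits, rgr = rgr, pair_table = pair_table,
       sweeps = sweeps, loss_sweeps = loss_sweeps,
       trait_correlations = trait_correlations, partitions = partitions)
}

#' Write the standard result tables of a pipeline run
#'
#' Collects the fitted curves, daily RGR values, pair table, dominance
#' sweep, loss sweep and variance partition into the standard TSV set
#' (`fits.tsv`, `rgr_daily.tsv`, `pair_table.tsv`, `sweep.tsv`,
#' `exclusion_sweep.tsv`, `partition.tsv`; absent stages are skipped).
#'
#' @param run result of [run_garden_pipeline()] or [run_field_pipeline()].
#' @param dir output directory.
#' @return Manifest tibble from [write_results()].
#' @export
write_pipeline_results <- function(run, dir) {
  bind_named <- function(lst, col, elem) {
    dplyr::bind_rows(lapply(names(lst), function(nm) {
      x <- lst[[nm]][[elem]]
      if (is.null(x)) return(NULL)
      x[[col]] <- nm
      x
    }))
  }
  tables <- list(
    fits = run$fits,
    rgr_daily = run$rgr,
    pair_table = run$pair_table,
    sweep = bind_named(run$sweeps, "treatment", "results")
  )
  if (!is.null(run$loss_sweeps)) {
    tables$exclusion_sweep <- bind_named(run$loss_sweeps, "treatment",
                                         "results")
  }
  if (!is.null(run$partitions)) {
    parts <- run$partitions[!vapply(run$partitions, is.null, logical(1))]
    tables$partition <- dplyr::bind_rows(lapply(names(parts), function(nm) {
      p <- parts[[nm]]
      p$treatment <- nm
      p
    }))
  }
  if (!is.null(run$trait_correlations)) {
    tables$correlations <- run$trait_correlations
  }
  write_results(tables, dir)
}
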