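#' Sequential-harvest day schedules for the two study designs
#'
#' The garden design samples monocultures on 11 days between day 53 and 171
#' (five species, two nutrient treatments, five replicate plots); the field
#' design samples individuals on 8 days between day 146 and 254 (twenty
#' species, four nutrient treatments).
#'
#' @return Integer vector of days of the year.
#' @export
garden_days <- function() c(53L, 67L, 88L, 109L, 116L, 123L, 130L, 145L,
                            152L, 162L, 171L)

#' @rdname garden_days
#' @export
field_days <- function() c(146L, 157L, 167L, 177L, 197L, 207L, 238L, 254L)

# Default competition ground truth. Productive treatments (NPK-fertilized
# garden subplots; N and NP field plots) get a steeper biomass~RGR slope and
# a nonzero loss slope; unproductive ones a shallower slope and no
# RGR-dependent loss, echoing the qualitative contrast the analysis targets.
default_competition <- function(treatments) {
  productive <- treatments %in% c("fertilized", "productive", "N", "NP")
  list(
    lambda_t = stats::setNames(ifelse(productive, 0.9, 0.5), treatments),
    eps_sigma = 0.4,
    alpha_loss = 2.5,
    beta_loss = stats::setNames(ifelse(productive, -30, 0), treatments)
  )
}

#' Draw ground-truth growth parameters for a synthetic community
#'
#' Draws one four-parameter logistic parameter set per species x treatment:
#' `M0 ~ U(-1, 1)`, `K - M0 ~ U(2, 6)`, `xmid ~ U(90, 150)` (garden season)
#' or `U(150, 210)` (field season), `r ~ U(5, 25)` days, with a common
#' lognormal biomass noise SD `sigma` on the log scale. Also returns the
#' competition ground truth (per-treatment slope `lambda_t` linking RGR
#' ratios at a reference day to biomass ratios, pair noise SD `eps_sigma`,
#' and the persistence logit intercept/slope `alpha_loss`, `beta_loss`).
#' Deterministic given `seed`.
#'
#' @param n_species number of species (>= 2).
#' @param treatments character vector of treatment labels.
#' @param seed integer seed.
#' @param design `"garden"` or `"field"`; sets the `xmid` window.
#' @param sigma lognormal noise SD on log biomass; default 0.15.
#' @param competition optional list overriding the default competition
#'   truth (`lambda_t`, `eps_sigma`, `alpha_loss`, `beta_loss`).
#' @return List with `species` (tibble of `SpeciesTruth` rows) and
#'   `competition`.
#' @export
generate_truth <- function(n_species, treatments, seed,
                           design = c("garden", "field"),
                           sigma = 0.15, competition = NULL) {
  design <- match.arg(design)
  if (n_species < 2L) {
    stop("generate_truth(): need at least 2 species", call. = FALSE)
  }
  xmid_rng <- if (design == "garden") c(90, 150) else c(150, 210)
  species <- sprintf("sp%02d", seq_len(n_species))
  grid <- expand.grid(species = species, treatment = treatments,
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  truth <- withr::with_seed(seed, {
    M0 <- stats::runif(n, -1, 1)
    tibble::tibble(
      species = grid$species, treatment = grid$treatment,
      M0 = M0, K = M0 + stats::runif(n, 2, 6),
      xmid = stats::runif(n, xmid_rng[1], xmid_rng[2]),
      r = stats::runif(n, 5, 25),
      sigma = sigma
    )
  })
  comp <- default_competition(treatments)
  if (!is.null(competition)) comp[names(competition)] <- competition
  list(species = truth, competition = comp)
}

# True RGR at a day for each truth row.
truth_rgr <- function(truth, day) {
  rgr_logistic(day, truth$M0, truth$K, truth$xmid, truth$r)
}

#' Simulate monoculture biomass time series from ground truth
#'
#' For every truth row, plot and harvest day, draws log biomass as the
#' logistic curve value plus independent `Normal(0, sigma)` noise
#' (multiplicative lognormal noise on the biomass scale, matching the
#' log-transform used for fitting). Biomass is strictly positive by
#' construction.
#'
#' @param truth tibble of `SpeciesTruth` rows (from [generate_truth()]).
#' @param days ascending integer harvest days.
#' @param n_plots replicate plots per species x treatment.
#' @param seed integer seed.
#' @param study study label stored in the output; default `"synthetic"`.
#' @return Biomass observation tibble
#'   (`study, treatment, species, plot, day, biomass`).
#' @export
generate_monoculture_series <- function(truth, days, n_plots, seed,
                                        study = "synthetic") {
  if (length(days) == 0L || is.unsorted(days, strictly = TRUE)) {
    stop("generate_monoculture_series(): days must be nonempty and ascending",
         call. = FALSE)
  }
  grid <- tidyr::crossing(
    truth[, c("species", "treatment", "M0", "K", "xmid", "r", "sigma")],
    plot = sprintf("p%02d", seq_len(n_plots)),
    day = as.integer(days)
  )
  logb <- withr::with_seed(seed, {
    mu <- logistic_log_biomass(grid$day, grid$M0, grid$K, grid$xmid, grid$r)
    mu + stats::rnorm(nrow(grid), 0, grid$sigma)
  })
  tibble::tibble(
    study = study, treatment = grid$treatment, species = grid$species,
    plot = grid$plot, day = grid$day, biomass = exp(logb)
  )
}

#' Simulate mixture harvest biomass with a known RGR-dominance slope
#'
#' For each unordered species pair within each treatment and replicate,
#' the log biomass ratio at harvest is generated as
#' `delta_b = lambda_t * delta_rgr(ref_day) + Normal(0, eps_sigma)`, with
#' `delta_rgr` the log RGR ratio of the pair at the reference day computed
#' from the ground-truth curves. Per-species biomasses are then
#' reconstructed to match that ratio at a fixed pair total, since only the
#' ratio carries information downstream. Community mixtures (all species
#' together, the field situation) are generated from per-species log
#' biomass `lambda_t * log RGR + Normal(0, eps_sigma/sqrt(2))`, which gives
#' every within-community pair the same expected ratio structure.
#'
#' @param truth tibble of `SpeciesTruth` rows.
#' @param comp competition truth list (see [generate_truth()]).
#' @param ref_day reference day at which the dominance slope acts.
#' @param seed integer seed.
#' @param n_reps replicate mixtures per composition; default 5.
#' @param mixtures `"pairwise"`, `"community"`, or `"both"` (pairwise plus
#'   one all-species mixture per replicate).
#' @param pair_total fixed total biomass per pair mixture, grams.
#' @return Mixture harvest tibble
#'   (`treatment, mixture_id, species, biomass`).
#' @export
generate_mixture_harvest <- function(truth, comp, ref_day, seed,
                                     n_reps = 5L,
                                     mixtures = c("pairwise", "community",
                                                  "both"),
                                     pair_total = 100) {
  mixtures <- match.arg(mixtures)
  rgr_ref <- truth_rgr(truth, ref_day)
  if (any(!is.finite(rgr_ref) | rgr_ref <= 0)) {
    bad <- truth$species[!is.finite(rgr_ref) | rgr_ref <= 0][1]
    stop("generate_mixture_harvest(): undefined RGR at day ", ref_day,
         " for species ", bad, call. = FALSE)
  }
  truth <- dplyr::mutate(truth, .rgr_ref = rgr_ref)

  build_treatment <- function(tr) {
    sub <- truth[truth$treatment == tr, , drop = FALSE]
    sub <- sub[order(sub$species, method = "radix"), , drop = FALSE]
    lambda <- unname(comp$lambda_t[tr])
    if (is.na(lambda)) {
      stop("generate_mixture_harvest(): no lambda_t for treatment ", tr,
           call. = FALSE)
    }
    out <- list()
    if (mixtures %in% c("pairwise", "both")) {
      pairs <- utils::combn(nrow(sub), 2L)
      for (k in seq_len(ncol(pairs))) {
        i <- pairs[1L, k]; j <- pairs[2L, k]
        d_rgr <- log(sub$.rgr_ref[i] / sub$.rgr_ref[j])
        for (rep in seq_len(n_reps)) {
          d_b <- lambda * d_rgr + stats::rnorm(1L, 0, comp$eps_sigma)
          share <- stats::plogis(d_b)
          out[[length(out) + 1L]] <- tibble::tibble(
            treatment = tr,
            mixture_id = sprintf("%s.%s_r%d", sub$species[i],
                                 sub$species[j], rep),
            species = c(sub$species[i], sub$species[j]),
            biomass = pair_total * c(share, 1 - share)
          )
        }
      }
    }
    if (mixtures %in% c("community", "both")) {
      for (rep in seq_len(n_reps)) {
        eps <- stats::rnorm(nrow(sub), 0, comp$eps_sigma / sqrt(2))
        logb <- lambda * log(sub$.rgr_ref) + eps
        b <- exp(logb)
        b <- b / sum(b) * pair_total * nrow(sub) / 2
        out[[length(out) + 1L]] <- tibble::tibble(
          treatment = tr,
          mixture_id = sprintf("community_r%d", rep),
          species = sub$species, biomass = b
        )
      }
    }
    dplyr::bind_rows(out)
  }

  withr::with_seed(seed, {
    dplyr::bind_rows(lapply(unique(truth$treatment), build_treatment))
  })
}

#' Simulate species persistence records between two censuses
#'
#' Every species is present at the first census (`present_start = 1`); its
#' persistence to the second census is Bernoulli with
#' `P(persist) = plogis(alpha_loss + beta_loss * RGR(ref_day))`, drawn
#' independently per plot. A negative `beta_loss` makes fast-growing
#' species the survivors' competitors: it lowers the persistence of the
#' species carrying the record as its own RGR rises.
#'
#' @inheritParams generate_mixture_harvest
#' @param n_plots plots per treatment (>= 1).
#' @return Presence tibble
#'   (`treatment, plot, species, present_start, present_end`).
#' @export
generate_loss_records <- function(truth, comp, ref_day, n_plots, seed) {
  if (n_plots < 1L) {
    stop("generate_loss_records(): n_plots must be >= 1", call. = FALSE)
  }
  grid <- tidyr::crossing(
    truth[, c("species", "treatment", "M0", "K", "xmid", "r")],
    plot = sprintf("p%02d", seq_len(n_plots))
  )
  rgr <- rgr_logistic(ref_day, grid$M0, grid$K, grid$xmid, grid$r)
  beta <- unname(comp$beta_loss[grid$treatment])
  p <- stats::plogis(comp$alpha_loss + beta * rgr)
  outcome <- withr::with_seed(seed, stats::rbinom(nrow(grid), 1L, p))
  tibble::tibble(
    treatment = grid$treatment, plot = grid$plot, species = grid$species,
    present_start = 1L, present_end = outcome
  )
}

#' Simulate leaf traits and height with chosen correlations to RGR
#'
#' Trait values are species x treatment attributes generated on the log (or
#' logit, for LDMC) scale as `rho * z + sqrt(1 - rho^2) * noise`, where `z`
#' is the within-treatment standardised log RGR at the reference day, so the
#' population correlation between log RGR and each log trait equals `rho`.
#' Defaults mimic the weak correlations typical of alpine-meadow forbs:
#' height +0.15, SLA -0.31, LDMC +0.26. Leaf measurements are reported as
#' the raw triplet (fresh mass, dry mass, area in mg / mm^2) so that SLA
#' and LDMC must be derived downstream.
#'
#' @inheritParams generate_mixture_harvest
#' @param cor_height,cor_sla,cor_ldmc target correlations with log RGR.
#' @return Trait tibble (`treatment, species, height, leaf_fresh_mass,
#'   leaf_dry_mass, leaf_area`).
#' @export
generate_traits <- function(truth, ref_day, seed,
                            cor_height = 0.15, cor_sla = -0.31,
                            cor_ldmc = 0.26) {
  mix <- function(z, rho, noise) rho * z + sqrt(1 - rho^2) * noise
  withr::with_seed(seed, {
    out <- lapply(split(truth, truth$treatment), function(sub) {
      lr <- log(truth_rgr(sub, ref_day))
      z <- as.numeric(scale(lr))
      n <- nrow(sub)
      x_h <- mix(z, cor_height, stats::rnorm(n))
      x_s <- mix(z, cor_sla, stats::rnorm(n))
      x_l <- mix(z, cor_ldmc, stats::rnorm(n))
      dry <- exp(log(15) + 0.2 * stats::rnorm(n))          # mg
      sla <- exp(log(20) + 0.3 * x_s)                      # mm^2 / mg
      ldmc <- stats::plogis(stats::qlogis(0.25) + 0.5 * x_l)
      tibble::tibble(
        treatment = sub$treatment, species = sub$species,
        height = exp(log(30) + 0.35 * x_h),                # cm
        leaf_fresh_mass = dry / ldmc,
        leaf_dry_mass = dry,
        leaf_area = sla * dry
      )
    })
    dplyr::bind_rows(out)
  })
}

#' Simulate a full study with known ground truth
#'
#' One call produces every input table the pipeline consumes, under the two
#' standard designs. The garden design: 5 species x 2 treatments
#' (`ambient`, `fertilized`) x 5 plots, 11 harvest days 53..171, pairwise
#' plus five-species mixtures, dominance reference day 60. The field
#' design: 20 species x 4 treatments (`control`, `N`, `P`, `NP`) x 12
#' sampled individuals treated as plots, 8 harvest days 146..254, community
#' mixtures in 6 replicate plots, loss records over 6 plots, traits, and
#' dominance/loss reference day 160. All randomness derives from `seed`.
#'
#' @param design `"garden"` or `"field"`.
#' @param seed integer seed.
#' @param sigma lognormal biomass noise SD; default 0.15.
#' @param competition optional competition-truth overrides.
#' @return List: `biomass`, `mixture_harvest`, `presence` (field only),
#'   `traits` (field only), `truth` (list of `species` and `competition`),
#'   `ref_day`, `days`.
#' @export
simulate_study <- function(design = c("garden", "field"), seed = 1L,
                           sigma = 0.15, competition = NULL) {
  design <- match.arg(design)
  sub_seeds <- withr::with_seed(seed, sample.int(2147483646L, 5L))
  if (design == "garden") {
    truth <- generate_truth(5L, c("ambient", "fertilized"), sub_seeds[1],
                            design = "garden", sigma = sigma,
                            competition = competition)
    days <- garden_days()
    ref_day <- 60L
    biomass <- generate_monoculture_series(truth$species, days, 5L,
                                           sub_seeds[2], study = "garden")
    harvest <- generate_mixture_harvest(truth$species, truth$competition,
                                        ref_day, sub_seeds[3],
                                        n_reps = 5L, mixtures = "both")
    presence <- NULL
    traits <- NULL
  } else {
    truth <- generate_truth(20L, c("control", "N", "P", "NP"), sub_seeds[1],
                            design = "field", sigma = sigma,
                            competition = competition)
    days <- field_days()
    ref_day <- 160L
    biomass <- generate_monoculture_series(truth$species, days, 12L,
                                           sub_seeds[2], study = "field")
    harvest <- generate_mixture_harvest(truth$species, truth$competition,
                                        ref_day, sub_seeds[3],
                                        n_reps = 6L, mixtures = "community")
    presence <- generate_loss_records(truth$species, truth$competition,
                                      ref_day, 6L, sub_seeds[4])
    traits <- generate_traits(truth$species, ref_day, sub_seeds[5])
  }
  list(
    biomass = biomass, mixture_harvest = harvest,
    presence = presence, traits = traits,
    truth = truth, ref_day = ref_day, days = days
  )
}

#' Write a simulated study to CSV inputs plus a ground-truth sidecar
#'
#' @param sim result of [simulate_study()].
#' @param dir output directory.
#' @return Manifest tibble from [write_results()] plus the CSV paths.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(sim$biomass, file.path(dir, "biomass.csv"),
                   progress = FALSE)
  readr::write_csv(sim$mixture_harvest, file.path(dir, "mixture_harvest.csv"),
                   progress = FALSE)
  if (!is.null(sim$presence)) {
    readr::write_csv(sim$presence, file.path(dir, "presence.csv"),
                     progress = FALSE)
  }
  if (!is.null(sim$traits)) {
    readr::write_csv(sim$traits, file.path(dir, "traits.csv"),
                     progress = FALSE)
  }
  readr::write_tsv(sim$truth$species, file.path(dir, "truth.tsv"),
                   progress = FALSE)
  invisible(dir)
}
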