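#' Derive specific leaf area and leaf dry matter content
#'
#' SLA is leaf area per unit dry mass; LDMC is dry mass per unit fresh
#' mass. With area in mm^2 and masses in mg, SLA is in mm^2/mg and LDMC is
#' a dimensionless fraction at most 1.
#'
#' @param leaf_area leaf area, mm^2.
#' @param dry_mass leaf dry mass, mg.
#' @param fresh_mass leaf fresh mass, mg; at least `dry_mass`.
#' @return Tibble with columns `sla` and `ldmc`, vectorised over inputs.
#' @export
derive_leaf_traits <- function(leaf_area, dry_mass, fresh_mass) {
  if (any(!is.finite(leaf_area)) || any(leaf_area <= 0) ||
      any(!is.finite(dry_mass)) || any(dry_mass <= 0) ||
      any(!is.finite(fresh_mass)) || any(fresh_mass <= 0)) {
    stop("derive_leaf_traits(): measurements must be positive and finite",
         call. = FALSE)
  }
  if (any(dry_mass > fresh_mass)) {
    stop("derive_leaf_traits(): dry mass exceeds fresh mass", call. = FALSE)
  }
  tibble::tibble(sla = leaf_area / dry_mass, ldmc = dry_mass / fresh_mass)
}

#' Correlate daily RGR with each functional trait
#'
#' Pearson product-moment correlation of the `rgr` column against every
#' other numeric column, with the confidence interval from Fisher's
#' variance-stabilising z transform and `df = n - 2`.
#'
#' @param records tibble with a numeric `rgr` column and one numeric column
#'   per trait (at least 4 complete rows).
#' @param ci_level confidence level; default 0.95.
#' @return Tibble (`trait, r, ci_low, ci_high, df, p`).
#' @export
correlate_rgr_traits <- function(records, ci_level = 0.95) {
  stopifnot("rgr" %in% names(records))
  if (nrow(records) < 4L) {
    stop("correlate_rgr_traits(): need >= 4 records", call. = FALSE)
  }
  if (stats::var(records$rgr) < 1e-24) {
    stop("correlate_rgr_traits(): zero variance in rgr", call. = FALSE)
  }
  traits <- setdiff(names(records)[vapply(records, is.numeric, logical(1))],
                    "rgr")
  rows <- lapply(traits, function(tr) {
    x <- records[[tr]]
    if (stats::var(x) < 1e-24) {
      stop("correlate_rgr_traits(): zero variance in ", tr, call. = FALSE)
    }
    ct <- stats::cor.test(records$rgr, x, conf.level = ci_level)
    tibble::tibble(
      trait = tr, r = unname(ct$estimate),
      ci_low = ct$conf.int[1], ci_high = ct$conf.int[2],
      df = unname(ct$parameter), p = ct$p.value
    )
  })
  dplyr::bind_rows(rows)
}

# R^2 of the OLS of `response` on the predictor subset `sub` (possibly
# empty -> 0).
subset_r2 <- function(data, response, sub) {
  if (length(sub) == 0L) return(0)
  f <- stats::reformulate(sub, response = response)
  summary(stats::lm(f, data = data))$r.squared
}

#' Partition explained variance among predictors (LMG decomposition)
#'
#' Decomposes the full-model R^2 of an OLS regression into per-predictor
#' shares by averaging each predictor's sequential R^2 increment over all
#' orderings of the predictors (the Lindeman-Merenda-Gold scheme),
#' implemented exactly through the subset formulation: the increment of
#' predictor k over subset S is weighted by `|S|! (p - |S| - 1)! / p!`.
#' Shares are nonnegative, independent of input order, and sum to the full
#' R^2; they are reported both absolutely and as percentages of R^2.
#'
#' @param data data frame holding the response and predictor columns
#'   (typically natural-log response ratios); at least 6 rows.
#' @param response name of the response column.
#' @param predictors names of the predictor columns.
#' @return Tibble (`predictor, lmg, share_pct, full_r2`), with
#'   `sum(share_pct) == 100`.
#' @export
partition_r2 <- function(data, response, predictors) {
  p <- length(predictors)
  stopifnot(p >= 1L)
  if (nrow(data) < 6L) {
    stop("partition_r2(): need >= 6 records", call. = FALSE)
  }
  X <- stats::model.matrix(stats::reformulate(predictors), data = data)
  if (qr(X)$rank < ncol(X)) {
    stop("partition_r2(): predictors perfectly collinear: ",
         paste(predictors, collapse = ", "), call. = FALSE)
  }

  subsets <- lapply(0:(2^p - 1), function(m) {
    predictors[bitwAnd(m, 2^(seq_len(p) - 1L)) > 0L]
  })
  r2 <- vapply(subsets, function(s) subset_r2(data, response, s),
               numeric(1))
  key <- function(s) paste(sort(s), collapse = "+")
  keys <- vapply(subsets, key, character(1))
  lookup <- function(s) r2[match(key(s), keys)]

  lmg <- vapply(predictors, function(k) {
    tot <- 0
    for (s in subsets) {
      if (k %in% s) next
      w <- factorial(length(s)) * factorial(p - length(s) - 1L) /
        factorial(p)
      tot <- tot + w * (lookup(c(s, k)) - lookup(s))
    }
    tot
  }, numeric(1))

  full <- lookup(predictors)
  tibble::tibble(
    predictor = predictors,
    lmg = unname(lmg),
    share_pct = if (full > 0) unname(100 * lmg / full) else NA_real_,
    full_r2 = full
  )
}

#' Pair-level log trait ratios joined to the dominance records
#'
#' For each pair-day record (usually at the single partition day), joins
#' the species traits within the pair's treatment and computes natural-log
#' response ratios of height, SLA and LDMC (species i over species j),
#' alongside the existing `delta_rgr` and `delta_b`. This is the input for
#' [partition_r2()] with response `delta_b` and predictors
#' `delta_rgr, d_sla, d_ldmc, d_height`.
#'
#' @param pair_records pair-day records (one day) from
#'   [build_pair_table()].
#' @param traits trait table (`treatment, species, height,
#'   leaf_fresh_mass, leaf_dry_mass, leaf_area`).
#' @return Tibble with added columns `d_height, d_sla, d_ldmc`.
#' @export
build_trait_partition_table <- function(pair_records, traits) {
  der <- derive_leaf_traits(traits$leaf_area, traits$leaf_dry_mass,
                            traits$leaf_fresh_mass)
  tt <- tibble::tibble(
    treatment = traits$treatment, species = traits$species,
    height = traits$height, sla = der$sla, ldmc = der$ldmc
  )
  tab <- dplyr::left_join(
    pair_records,
    dplyr::rename(tt, species_i = "species", height_i = "height",
                  sla_i = "sla", ldmc_i = "ldmc"),
    by = c("treatment", "species_i")
  )
  tab <- dplyr::left_join(
    tab,
    dplyr::rename(tt, species_j = "species", height_j = "height",
                  sla_j = "sla", ldmc_j = "ldmc"),
    by = c("treatment", "species_j")
  )
  miss <- is.na(tab$height_i) | is.na(tab$height_j)
  if (any(miss)) {
    warning("build_trait_partition_table(): dropped ", sum(miss),
            " record(s) lacking trait measurements", call. = FALSE)
    tab <- tab[!miss, , drop = FALSE]
  }
  tab$d_height <- log(tab$height_i / tab$height_j)
  tab$d_sla <- log(tab$sla_i / tab$sla_j)
  tab$d_ldmc <- log(tab$ldmc_i / tab$ldmc_j)
  tab[, c("treatment", "mixture_id", "species_i", "species_j", "day",
          "delta_rgr", "delta_b", "d_height", "d_sla", "d_ldmc")]
}
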