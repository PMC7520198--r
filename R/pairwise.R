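#' Log response ratio of harvest biomass for a species pair
#'
#' `ln(b_i / b_j)`: positive when species i dominates the mixture at
#' harvest, negative when species j does, zero at equal biomass. The log
#' ratio is antisymmetric under swapping the pair.
#'
#' @param b_i,b_j harvest biomass of species i and j; strictly positive.
#' @return Log ratio (dimensionless), vectorised.
#' @export
delta_abundance <- function(b_i, b_j) {
  if (any(!is.finite(b_i)) || any(b_i <= 0) ||
      any(!is.finite(b_j)) || any(b_j <= 0)) {
    stop("delta_abundance(): biomass must be positive and finite",
         call. = FALSE)
  }
  log(b_i / b_j)
}

#' Log response ratio of monoculture RGR for a species pair
#'
#' `ln(RGR_i / RGR_j)` at a given day: positive when species i grows
#' relatively faster at that day.
#'
#' @param rgr_i,rgr_j daily RGR of species i and j (day^-1); strictly
#'   positive.
#' @return Log ratio (dimensionless), vectorised.
#' @export
delta_rgr <- function(rgr_i, rgr_j) {
  if (any(!is.finite(rgr_i)) || any(rgr_i <= 0) ||
      any(!is.finite(rgr_j)) || any(rgr_j <= 0)) {
    stop("delta_rgr(): RGR values must be positive and finite",
         call. = FALSE)
  }
  log(rgr_i / rgr_j)
}

#' Build the pairwise day-resolved predictor/response table
#'
#' For every mixture, every unordered species pair within it (entered once,
#' in canonical radix order of the labels) and every day of the range,
#' produces one record pairing the harvest biomass log ratio (constant
#' across days, measured once at harvest) with the daily monoculture RGR
#' log ratio. Species with zero or missing harvest biomass drop their pairs
#' with a warning; pair-days with non-positive RGR (declining fits) are
#' excluded with a warning rather than imputed.
#'
#' @param rgr long daily RGR table (`species, treatment, day, rgr`) from
#'   [rgr_table()].
#' @param harvest mixture harvest table
#'   (`treatment, mixture_id, species, biomass`).
#' @param day_range inclusive integer interval `c(first, last)`.
#' @return Tibble of pair-day records (`treatment, mixture_id, species_i,
#'   species_j, day, delta_rgr, delta_b`).
#' @export
build_pair_table <- function(rgr, harvest, day_range) {
  stopifnot(length(day_range) == 2L, day_range[1] < day_range[2])
  days <- seq.int(day_range[1], day_range[2])

  harvest <- harvest[is.finite(harvest$biomass), , drop = FALSE]
  absent <- harvest$biomass <= 0
  if (any(absent)) {
    warning("build_pair_table(): ", sum(absent),
            " zero-biomass species record(s) excluded from their pairs",
            call. = FALSE)
    harvest <- harvest[!absent, , drop = FALSE]
  }

  have_rgr <- unique(rgr[, c("species", "treatment")])
  need <- unique(harvest[, c("species", "treatment")])
  miss <- dplyr::anti_join(need, have_rgr, by = c("species", "treatment"))
  if (nrow(miss) > 0L) {
    stop("build_pair_table(): no RGR series for species ", miss$species[1],
         " in treatment ", miss$treatment[1], call. = FALSE)
  }

  pair_one <- function(mix) {
    mix <- mix[order(mix$species, method = "radix"), , drop = FALSE]
    if (nrow(mix) < 2L) return(NULL)
    idx <- utils::combn(nrow(mix), 2L)
    tibble::tibble(
      treatment = mix$treatment[1],
      mixture_id = mix$mixture_id[1],
      species_i = mix$species[idx[1L, ]],
      species_j = mix$species[idx[2L, ]],
      delta_b = delta_abundance(mix$biomass[idx[1L, ]],
                                mix$biomass[idx[2L, ]])
    )
  }
  pairs <- dplyr::bind_rows(lapply(
    split(harvest, list(harvest$treatment, harvest$mixture_id), drop = TRUE),
    pair_one
  ))

  rgr_sub <- rgr[rgr$day %in% days, c("species", "treatment", "day", "rgr")]
  tab <- tidyr::crossing(pairs, day = days)
  tab <- dplyr::left_join(
    tab, dplyr::rename(rgr_sub, species_i = "species", rgr_i = "rgr"),
    by = c("treatment", "species_i", "day")
  )
  tab <- dplyr::left_join(
    tab, dplyr::rename(rgr_sub, species_j = "species", rgr_j = "rgr"),
    by = c("treatment", "species_j", "day")
  )
  bad <- is.na(tab$rgr_i) | is.na(tab$rgr_j) |
    tab$rgr_i <= 0 | tab$rgr_j <= 0
  if (any(bad)) {
    warning("build_pair_table(): excluded ", sum(bad),
            " pair-day record(s) with non-positive or missing RGR",
            call. = FALSE)
    tab <- tab[!bad, , drop = FALSE]
  }
  tab$delta_rgr <- delta_rgr(tab$rgr_i, tab$rgr_j)
  log_stage("build_pair_table", nrow(tab), " pair-day records over ",
            length(days), " days")
  tab[, c("treatment", "mixture_id", "species_i", "species_j", "day",
          "delta_rgr", "delta_b")]
}
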