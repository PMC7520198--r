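#' @importFrom rlang .data
NULL

# Validate presence of required columns; error names the first missing one.
check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("schema error in ", what, ": missing column '", missing[1], "'",
         call. = FALSE)
  }
  invisible(df)
}

# Drop invalid rows with a warning listing data line numbers (header = line 1).
reject_rows <- function(df, bad, reason, what) {
  if (any(bad)) {
    lines <- which(bad) + 1L
    warning(sprintf(
      "%s: rejected %d row(s) (%s) at line(s) %s",
      what, sum(bad), reason,
      paste(utils::head(lines, 20L), collapse = ", ")
    ), call. = FALSE)
  }
  df[!bad, , drop = FALSE]
}

#' Read a long-format biomass time-series table
#'
#' Comma-separated input with columns
#' `study, treatment, species, plot, day, biomass` (dry mass, grams; `day`
#' is 1-based integer day of year). Rows violating the invariants
#' (non-positive or non-finite biomass, day outside 1..366, duplicated
#' `study x treatment x species x plot x day` key) are rejected with a
#' warning carrying their line numbers; they are never silently dropped.
#'
#' @param path CSV file path.
#' @return Tibble of validated biomass observations.
#' @export
read_biomass_table <- function(path) {
  if (!file.exists(path)) {
    stop("read_biomass_table(): no such file: ", path, call. = FALSE)
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("study", "treatment", "species", "plot", "day",
                      "biomass"), "biomass table")
  df$day <- as.integer(df$day)
  df$plot <- as.character(df$plot)
  df <- reject_rows(df, !is.finite(df$biomass) | df$biomass <= 0,
                    "non-positive biomass", "biomass table")
  df <- reject_rows(df, is.na(df$day) | df$day < 1L | df$day > 366L,
                    "day outside 1..366", "biomass table")
  key <- paste(df$study, df$treatment, df$species, df$plot, df$day,
               sep = "\r")
  df <- reject_rows(df, duplicated(key), "duplicate key", "biomass table")
  log_stage("read_biomass_table", nrow(df), " observations from ", path)
  tibble::as_tibble(df)
}

#' Read a mixture harvest table
#'
#' Columns `treatment, mixture_id, species, biomass`: per-species dry
#' biomass harvested from each mixture plot. Non-positive biomass rows are
#' rejected with a warning (such species are treated as absent from the
#' harvested mixture by [build_pair_table()]).
#'
#' @param path CSV file path.
#' @return Tibble.
#' @export
read_mixture_table <- function(path) {
  if (!file.exists(path)) {
    stop("read_mixture_table(): no such file: ", path, call. = FALSE)
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("treatment", "mixture_id", "species", "biomass"),
                "mixture table")
  df <- reject_rows(df, !is.finite(df$biomass) | df$biomass <= 0,
                    "non-positive biomass", "mixture table")
  tibble::as_tibble(df)
}

#' Read a species presence (persistence) table
#'
#' Columns `treatment, plot, species, present_start, present_end`, with the
#' presence flags 0/1. Only species present at the first census
#' (`present_start == 1`) are retained; `present_end` is the persistence
#' outcome (1 = still present at the second census, 0 = lost).
#'
#' @param path CSV file path.
#' @return Tibble.
#' @export
read_presence_table <- function(path) {
  if (!file.exists(path)) {
    stop("read_presence_table(): no such file: ", path, call. = FALSE)
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("treatment", "plot", "species", "present_start",
                      "present_end"), "presence table")
  df$plot <- as.character(df$plot)
  df <- reject_rows(df, !(df$present_start %in% c(0, 1)) |
                      !(df$present_end %in% c(0, 1)),
                    "presence flags must be 0/1", "presence table")
  tibble::as_tibble(df)
}

#' Read a leaf trait table
#'
#' Columns `treatment, species, height, leaf_fresh_mass, leaf_dry_mass,
#' leaf_area` (height in cm, masses in mg, area in mm^2). Rows with
#' non-positive measurements or dry mass exceeding fresh mass are rejected
#' with a warning.
#'
#' @param path CSV file path.
#' @return Tibble.
#' @export
read_traits_table <- function(path) {
  if (!file.exists(path)) {
    stop("read_traits_table(): no such file: ", path, call. = FALSE)
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("treatment", "species", "height", "leaf_fresh_mass",
                      "leaf_dry_mass", "leaf_area"), "traits table")
  num <- c("height", "leaf_fresh_mass", "leaf_dry_mass", "leaf_area")
  bad <- Reduce(`|`, lapply(df[num], function(x) !is.finite(x) | x <= 0)) |
    df$leaf_dry_mass > df$leaf_fresh_mass
  df <- reject_rows(df, bad, "invalid trait measurement", "traits table")
  tibble::as_tibble(df)
}

#' Write result tables as tab-separated files
#'
#' Writes each named table to `<dir>/<name>.tsv` (UTF-8, "." decimal,
#' shortest round-trip numeric representation, so re-reading yields
#' value-identical tables). The directory is checked for writability before
#' any file is written.
#'
#' @param tables named list of data frames; names become file stems.
#' @param dir output directory (created if absent).
#' @return Manifest tibble (`table`, `path`, `n_rows`), invisibly an empty
#'   manifest for an empty table set.
#' @export
write_results <- function(tables, dir) {
  stopifnot(is.list(tables))
  if (length(tables) > 0L && is.null(names(tables))) {
    stop("write_results(): tables must be named", call. = FALSE)
  }
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("write_results(): cannot create ", dir, call. = FALSE)
  }
  if (file.access(dir, mode = 2L) != 0L) {
    stop("write_results(): directory not writable: ", dir, call. = FALSE)
  }
  paths <- file.path(dir, paste0(names(tables), ".tsv"))
  for (i in seq_along(tables)) {
    readr::write_tsv(tables[[i]], paths[i], progress = FALSE)
  }
  manifest <- tibble::tibble(
    table = as.character(names(tables)),
    path = as.character(paths),
    n_rows = vapply(tables, nrow, integer(1), USE.NAMES = FALSE)
  )
  log_stage("write_results", nrow(manifest), " table(s) written to ", dir)
  manifest
}

#' Read back a TSV result table written by [write_results()]
#'
#' @param path TSV file path.
#' @return Tibble.
#' @export
read_result_table <- function(path) {
  if (!file.exists(path)) {
    stop("read_result_table(): no such file: ", path, call. = FALSE)
  }
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
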