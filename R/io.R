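# Reading and writing the tidy CSV schemas, plus derived columns shared by
# all downstream analyses.

.pair_cols <- c("site_year", "level", "active_species", "active_status",
                "passive_species", "passive_status", "weight",
                "active_height_mm", "passive_height_mm", "pair_id",
                "quadrat_id")
.census_cols <- c("site_year", "level", "quadrat_id", "species", "status",
                  "older_than_one_year", "infected", "shell_height_mm")

.add_pair_derived <- function(pairs) {
  pairs$stratum <- paste(pairs$site_year, pairs$level, sep = ":")
  pairs$passive_label <- category_label(pairs$passive_species,
                                        pairs$passive_status)
  pairs$mating_class <- classify_pair(pairs$active_species,
                                      pairs$passive_species,
                                      pairs$passive_status)
  pairs
}

#' Read a copulating-pair record table
#'
#' Reads the tidy CSV of weighted copulation records (one row per record; an
#' unordered male-male pair contributes two rows of weight 0.5 sharing a
#' `pair_id`), validates categories and weights, and attaches the derived
#' columns `stratum`, `passive_label` and `mating_class`.
#'
#' @param path path to a pairs CSV with the columns
#'   `r paste0('\x60', .pair_cols, '\x60', collapse = ", ")`.
#' @return a data frame of validated records.
#' @seealso [premate_example()] for the packaged worked-example data.
#' @export
read_pairs <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(setdiff(.pair_cols, c("active_height_mm",
    "passive_height_mm", "quadrat_id")), names(raw))
  if (length(missing))
    stop("pairs file lacks required column(s): ",
         paste(missing, collapse = ", "))
  for (col in c("active_height_mm", "passive_height_mm", "quadrat_id"))
    if (!col %in% names(raw)) raw[[col]] <- NA
  validate_pairs(raw[.pair_cols])
}

#' Validate an in-memory pair-record table
#'
#' @param pairs data frame in the pairs schema (see [read_pairs()]).
#' @return the validated table with derived columns attached.
#' @export
validate_pairs <- function(pairs) {
  if (nrow(pairs) == 0) return(.add_pair_derived(pairs))
  if (any(!pairs$active_status %in% "male"))
    stop("active partners must have status 'male'")
  if (any(!pairs$active_species %in% premate_species))
    stop("malformed active species label in row(s) ",
         paste(utils::head(which(!pairs$active_species %in% premate_species), 5),
               collapse = ", "))
  .validate_categories(pairs$passive_species, pairs$passive_status,
                       "pairs table")
  if (any(!pairs$weight %in% c(0.5, 1)))
    stop("record weights must be 0.5 (male-male half) or 1.0; offending row(s) ",
         paste(utils::head(which(!pairs$weight %in% c(0.5, 1)), 5),
               collapse = ", "))
  half <- pairs$weight == 0.5
  if (any(half)) {
    per_id <- tapply(pairs$weight[half], pairs$pair_id[half], sum)
    if (any(per_id != 1))
      warning("male-male half-records do not pair up to weight 1 for pair_id ",
              paste(names(per_id)[per_id != 1], collapse = ", "),
              "; weighted totals will not count whole physical pairs")
    if (any(pairs$passive_status[half] != "male"))
      stop("0.5-weight records are reserved for male-male pairs")
  }
  hts <- c(pairs$active_height_mm, pairs$passive_height_mm)
  if (any(!is.na(hts) & hts <= 0)) stop("shell heights must be positive")
  .add_pair_derived(pairs)
}

#' Read a quadrat-census table
#'
#' @param path path to a census CSV with the columns
#'   `r paste0('\x60', .census_cols, '\x60', collapse = ", ")`. ITC
#'   individuals carry their species-group token (`saxatilis_group`,
#'   `obtusata_group`) in the `species` column.
#' @return a data frame of validated individual records with derived columns
#'   `stratum` and `label`.
#' @export
read_census <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.census_cols, names(raw))
  if (length(missing))
    stop("census file lacks required column(s): ",
         paste(missing, collapse = ", "))
  validate_census(raw[.census_cols])
}

#' Validate an in-memory census table
#' @param census data frame in the census schema (see [read_census()]).
#' @return the validated table with derived columns attached.
#' @export
validate_census <- function(census) {
  if (nrow(census)) {
    .validate_categories(census$species, census$status, "census table")
    if (any(!is.na(census$shell_height_mm) & census$shell_height_mm <= 0))
      stop("shell heights must be positive")
    census$older_than_one_year <- as.logical(census$older_than_one_year)
    census$infected <- as.logical(census$infected)
  }
  census$stratum <- paste(census$site_year, census$level, sep = ":")
  census$label <- category_label(census$species, census$status)
  census
}

#' Write pair records back to CSV
#'
#' Inverse of [read_pairs()]; derived columns are dropped so that a
#' write/read round trip is the identity on the schema columns.
#'
#' @param pairs validated pairs table.
#' @param path output path.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.csv(pairs[intersect(.pair_cols, names(pairs))], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' Write census records to CSV
#' @param census validated census table.
#' @param path output path.
#' @export
write_census <- function(census, path) {
  utils::write.csv(census[intersect(.census_cols, names(census))], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' Path to a packaged example data file
#'
#' The package ships two small plain-text fixtures: `table2_pairs.csv`, a
#' record-level transcription of the published copulation table for the three
#' site-years (record-level detail such as the decomposition of male-male
#' counts into physical pairs is a synthetic reconstruction consistent with
#' every published cell and aggregate), and `table3_combinations.csv`, the
#' published presence/absence matrix of partner-type combinations.
#'
#' @param file file name; with no argument, lists the available files.
#' @return full path to the file.
#' @examples
#' pairs <- read_pairs(premate_example("table2_pairs.csv"))
#' @export
premate_example <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "premate")))
  path <- system.file("extdata", file, package = "premate")
  if (path == "") stop("no packaged file called ", file)
  path
}
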