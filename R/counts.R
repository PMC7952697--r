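# Observed-frequency tabulation and the worked-example count aggregates.

#' Tabulate observed copulation frequencies for one stratum
#'
#' Arranges the weighted records of a stratum as a matrix with passive
#' partner categories in rows and active male species in columns; cells are
#' sums of record weights, so the grand total equals the number of physical
#' pairs collected in the stratum.
#'
#' @param pairs validated pairs table (see [read_pairs()]).
#' @param site_year,level stratum selector; `NULL` pools all records.
#' @param passive_levels,active_levels optional row/column universes; by
#'   default the categories observed in the selection, in canonical order.
#' @return numeric matrix of weighted frequencies.
#' @export
tabulate_pairs <- function(pairs, site_year = NULL, level = NULL,
                           passive_levels = NULL, active_levels = NULL) {
  sel <- .select_stratum(pairs, site_year, level)
  if (is.null(passive_levels))
    passive_levels <- intersect(.passive_order, unique(sel$passive_label))
  if (is.null(active_levels))
    active_levels <- intersect(premate_species, unique(sel$active_species))
  out <- matrix(0, length(passive_levels), length(active_levels),
                dimnames = list(passive_levels, active_levels))
  if (nrow(sel)) {
    agg <- tapply(sel$weight,
                  list(factor(sel$passive_label, passive_levels),
                       factor(sel$active_species, active_levels)), sum)
    agg[is.na(agg)] <- 0
    out[] <- agg
  }
  out
}

.select_stratum <- function(x, site_year = NULL, level = NULL) {
  keep <- rep(TRUE, nrow(x))
  if (!is.null(site_year)) keep <- keep & x$site_year %in% site_year
  if (!is.null(level)) keep <- keep & x$level %in% level
  x[keep, , drop = FALSE]
}

#' Aggregate counts over a pair-record table
#'
#' Weighted counts of the worked-example aggregates: total pairs, pairs per
#' site-year and per stratum, the four-way mating-class split, active totals
#' per species group, the heterosexual vs male-male decomposition (a
#' male-male pair counts once, its two 0.5 halves summing to 1), and the
#' number of heterospecific male-male pairs (partners of different species,
#' the 1.5-row morphotype counting as its own).
#'
#' @param pairs validated pairs table.
#' @return object of class `mating_counts` (a list of named numeric vectors).
#' @examples
#' counts <- summary_counts(read_pairs(premate_example("table2_pairs.csv")))
#' counts$total_pairs
#' @export
summary_counts <- function(pairs) {
  stopifnot(nrow(pairs) >= 1)
  w <- pairs$weight
  by_class <- tapply(w, pairs$mating_class, sum, default = 0)
  mm <- pairs[pairs$mating_class == "male_male", , drop = FALSE]
  het_mm <- sum(mm$weight[mm$active_species != mm$passive_species])
  out <- list(
    total_pairs = sum(w),
    by_site_year = tapply(w, pairs$site_year, sum),
    by_stratum = tapply(w, pairs$stratum, sum),
    by_class = by_class,
    by_active_group = tapply(w, species_group(pairs$active_species), sum,
                             default = 0),
    heterosexual_pairs = sum(by_class[c("conspecific_female",
                                        "heterospecific_female")]),
    male_male_pairs = unname(by_class["male_male"]),
    heterospecific_male_male_pairs = het_mm,
    by_active_species = tapply(w, pairs$active_species, sum))
  class(out) <- "mating_counts"
  out
}

#' @export
print.mating_counts <- function(x, ...) {
  cat("Copulating-pair counts\n")
  cat("  total pairs:", x$total_pairs, "\n")
  cat("  by site-year:",
      paste(names(x$by_site_year), x$by_site_year, collapse = "; "), "\n")
  cat("  mating classes:",
      paste(names(x$by_class), x$by_class, collapse = "; "), "\n")
  cat("  heterosexual:", x$heterosexual_pairs,
      " male-male:", x$male_male_pairs,
      paste0("(heterospecific: ", x$heterospecific_male_male_pairs, ")"), "\n")
  invisible(x)
}

#' @export
as.data.frame.mating_counts <- function(x, ...) {
  flat <- c(total_pairs = x$total_pairs,
            stats::setNames(as.vector(x$by_site_year),
                            paste0("pairs_", names(x$by_site_year))),
            stats::setNames(as.vector(x$by_stratum),
                            paste0("pairs_", gsub(":", "_", names(x$by_stratum)))),
            stats::setNames(as.vector(x$by_class),
                            paste0("class_", names(x$by_class))),
            stats::setNames(as.vector(x$by_active_group),
                            paste0("active_", names(x$by_active_group))),
            heterosexual_pairs = x$heterosexual_pairs,
            male_male_pairs = x$male_male_pairs,
            heterospecific_male_male_pairs = x$heterospecific_male_male_pairs)
  data.frame(quantity = names(flat), weighted_count = unname(flat))
}
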