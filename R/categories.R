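#' @keywords internal
"_PACKAGE"

# Category taxonomy ----------------------------------------------------------
#
# Six male morphotypes act as active partners; passive partners are males,
# mature females, or immature/trematode-castrated (ITC) snails identifiable
# only to cryptic-species group. "saxatilis_1p5" marks males with 1.5 rows of
# penial glands (presumed saxatilis x arcana hybrids); it occurs only as a
# male morphotype, and both saxatilis and arcana females count as conspecific
# for it.

premate_species <- c("saxatilis", "saxatilis_1p5", "arcana", "compressa",
                     "obtusata", "fabalis")
premate_groups  <- c("saxatilis_group", "obtusata_group")
premate_statuses <- c("male", "female", "immature_or_castrated")

.group_of <- c(
  saxatilis = "saxatilis_group", saxatilis_1p5 = "saxatilis_group",
  arcana = "saxatilis_group", compressa = "saxatilis_group",
  obtusata = "obtusata_group", fabalis = "obtusata_group",
  saxatilis_group = "saxatilis_group", obtusata_group = "obtusata_group")

.conspecific_females <- list(
  saxatilis = "saxatilis", saxatilis_1p5 = c("saxatilis", "arcana"),
  arcana = "arcana", compressa = "compressa",
  obtusata = "obtusata", fabalis = "fabalis")

#' Species group of a species or group token
#'
#' @param species character vector of species tokens (one of
#'   `r paste0('\x60', premate_species, '\x60', collapse = ", ")`) or of the
#'   group tokens `saxatilis_group` / `obtusata_group` used for
#'   immature-or-castrated (ITC) individuals.
#' @return character vector of group tokens.
#' @export
species_group <- function(species) {
  out <- .group_of[species]
  if (anyNA(out)) stop("unknown species token(s): ",
                       paste(unique(species[is.na(out)]), collapse = ", "))
  unname(out)
}

# A category is a (species, status) pair. ITC individuals carry the group
# token in the species field, all others a species token.
.validate_categories <- function(species, status, context = "record") {
  ok_status <- status %in% premate_statuses
  if (any(!ok_status))
    stop("invalid status in ", context, ": ",
         paste(unique(status[!ok_status]), collapse = ", "))
  itc <- status == "immature_or_castrated"
  bad_sp <- (!itc & !species %in% premate_species) |
            (itc & !species %in% premate_groups)
  if (any(bad_sp))
    stop("invalid species label in ", context, " (row ",
         paste(utils::head(which(bad_sp), 5), collapse = ", "), "): ",
         paste(unique(species[bad_sp]), collapse = ", "))
  if (any(species == "saxatilis_1p5" & status == "female"))
    stop("saxatilis_1p5 occurs only as a male morphotype")
  invisible(TRUE)
}

#' Canonical category label
#'
#' Collapses a (species, status) pair into the single token used for row and
#' column names throughout the package, e.g. `"saxatilis_female"`,
#' `"arcana_male"`, `"obtusata_group_itc"`.
#'
#' @param species,status character vectors (recycled to common length).
#' @return character vector of labels.
#' @export
category_label <- function(species, status) {
  ifelse(status == "immature_or_castrated", paste0(species, "_itc"),
         paste(species, status, sep = "_"))
}

# canonical passive-category ordering: per species female then male, ITC last
.passive_order <- c(
  t(outer(premate_species, c("female", "male"), function(s, x)
    ifelse(s == "saxatilis_1p5" & x == "female", NA, paste(s, x, sep = "_")))),
  paste0(premate_groups, "_itc"))
.passive_order <- .passive_order[!is.na(.passive_order)]

#' Classify a copulation record
#'
#' Assigns each (active male, passive partner) record to one of the four
#' mating classes: a potentially productive mating with a conspecific mature
#' female, a mating with a heterospecific female, a male-male mating, or a
#' mating with an immature/castrated (ITC) individual. For 1.5-row males both
#' *L. saxatilis* and *L. arcana* females are conspecific.
#'
#' @param active_species active male species token.
#' @param passive_species passive partner species (or group token for ITC).
#' @param passive_status passive partner status.
#' @return factor with levels `conspecific_female`, `heterospecific_female`,
#'   `male_male`, `immature_or_castrated`.
#' @examples
#' classify_pair("saxatilis_1p5", "arcana", "female")  # conspecific_female
#' @export
classify_pair <- function(active_species, passive_species, passive_status) {
  n <- max(length(active_species), length(passive_species),
           length(passive_status))
  active_species <- rep_len(active_species, n)
  passive_species <- rep_len(passive_species, n)
  passive_status <- rep_len(passive_status, n)
  if (any(!active_species %in% premate_species))
    stop("active partner must be one of the male species tokens")
  .validate_categories(passive_species, passive_status, "passive category")
  consp <- mapply(function(a, p) p %in% .conspecific_females[[a]],
                  active_species, passive_species, USE.NAMES = FALSE)
  out <- ifelse(passive_status == "male", "male_male",
         ifelse(passive_status == "immature_or_castrated",
                "immature_or_castrated",
         ifelse(consp, "conspecific_female", "heterospecific_female")))
  factor(out, levels = c("conspecific_female", "heterospecific_female",
                         "male_male", "immature_or_castrated"))
}

#' Expand an unordered male-male pair into two half-weight records
#'
#' Male-male pairs are collected without knowing which partner was the active
#' (penis-inserting) one, so the pair is recorded as 0.5 counts for both
#' possible active/passive role assignments.
#'
#' @param species1,species2 male species tokens of the two partners.
#' @param site_year,level stratum of the pair.
#' @param pair_id identifier shared by the two emitted records.
#' @param height1_mm,height2_mm optional shell heights of the two partners.
#' @param quadrat_id optional quadrat label.
#' @return a two-row data frame in the pair-record schema, weights 0.5 each.
#' @export
expand_male_male <- function(species1, species2, site_year, level,
                             pair_id, height1_mm = NA_real_,
                             height2_mm = NA_real_,
                             quadrat_id = NA_character_) {
  stopifnot(length(species1) == 1, length(species2) == 1)
  if (!species1 %in% premate_species || !species2 %in% premate_species)
    stop("both partners of a male-male pair must be male species tokens")
  data.frame(
    site_year = site_year, level = level,
    active_species = c(species1, species2), active_status = "male",
    passive_species = c(species2, species1), passive_status = "male",
    weight = 0.5,
    active_height_mm = c(height1_mm, height2_mm),
    passive_height_mm = c(height2_mm, height1_mm),
    pair_id = pair_id, quadrat_id = quadrat_id,
    stringsAsFactors = FALSE)
}
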