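# Synthetic censuses and copulating-pair datasets.
#
# The generator emulates the sampling design the analysis assumes: quadrat
# censuses with species-specific densities, sex ratios, immature/castrated
# fractions and log-normal shell heights, and a mating process in which an
# active male category is drawn in proportion to activity weight x male
# abundance, and the passive partner in proportion to composition x a
# species-preference weight x a Gaussian kernel in height difference. With
# uniform preferences, no size kernel and a male-male rate matching the male
# share of the composition, the generated cell frequencies converge to the
# random-mating null expectations.

#' Build a simulation configuration
#'
#' @param species_table data frame with one row per stratum x species:
#'   columns `site_year`, `level`, `species`, `density` (Poisson mean count
#'   per quadrat), `prop_female` (fraction of non-ITC individuals that are
#'   female), `prop_itc` (immature-or-castrated fraction), `meanlog`,
#'   `sdlog` (log-normal shell height, mm).
#' @param n_quadrats quadrats per stratum.
#' @param n_pairs copulating pairs to generate per stratum.
#' @param activity named vector of activity weights per male species
#'   (default 1 for every species in the table).
#' @param preference matrix of non-negative preference weights, active male
#'   species in rows, passive category labels in columns (default uniform;
#'   see [uniform_preference()]).
#' @param beta size-assortment strength (per mm^2, >= 0).
#' @param delta target active-minus-passive height offset (mm); negative
#'   values make males prefer larger partners.
#' @param male_male_rate probability that a generated pair is an unordered
#'   male-male pair; `NA` (default) matches the male share of the eligible
#'   composition, which is the random-mating value.
#' @param seed default seed carried by the configuration.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(species_table, n_quadrats = 10, n_pairs = 200,
                              activity = NULL, preference = NULL,
                              beta = 0, delta = 0, male_male_rate = NA,
                              seed = 1) {
  stopifnot(all(c("site_year", "level", "species", "density", "prop_female",
                  "prop_itc", "meanlog", "sdlog") %in% names(species_table)),
            all(species_table$species %in% premate_species),
            all(species_table$density >= 0),
            all(species_table$prop_female >= 0 & species_table$prop_female <= 1),
            all(species_table$prop_itc >= 0 & species_table$prop_itc <= 1),
            beta >= 0, n_quadrats >= 1, n_pairs >= 1)
  if (any(species_table$species == "saxatilis_1p5" &
          species_table$prop_female > 0))
    stop("saxatilis_1p5 is a male morphotype: prop_female must be 0")
  if (is.null(activity))
    activity <- stats::setNames(rep(1, length(unique(species_table$species))),
                                unique(species_table$species))
  if (is.null(preference)) preference <- uniform_preference()
  if (any(preference < 0)) stop("preference weights must be non-negative")
  structure(list(species_table = species_table, n_quadrats = n_quadrats,
                 n_pairs = n_pairs, activity = activity,
                 preference = preference, beta = beta, delta = delta,
                 male_male_rate = male_male_rate, seed = seed),
            class = "simulation_config")
}

#' Uniform preference matrix
#'
#' All-ones preference weights: every active male category values every
#' passive category equally, the random-mating setting.
#' @return matrix with active male species in rows and the full set of
#'   passive category labels in columns.
#' @export
uniform_preference <- function() {
  matrix(1, length(premate_species), length(.passive_order),
         dimnames = list(premate_species, .passive_order))
}

#' Diagonal (species-faithful) preference matrix
#'
#' Zero weight on heterospecific females; own-species females (both
#' saxatilis and arcana for 1.5-row males) get `female_weight`, male and ITC
#' categories get the corresponding background weights.
#'
#' @param female_weight weight on conspecific females.
#' @param male_weight,itc_weight background weights on male / ITC passive
#'   categories.
#' @export
diagonal_preference <- function(female_weight = 1, male_weight = 0.3,
                                itc_weight = 0.3) {
  psi <- uniform_preference()
  psi[, grepl("_female$", colnames(psi))] <- 0
  psi[, grepl("_male$", colnames(psi))] <- male_weight
  psi[, grepl("_itc$", colnames(psi))] <- itc_weight
  for (sp in premate_species)
    psi[sp, intersect(.consp_labels(sp), colnames(psi))] <- female_weight
  psi
}

#' Preset simulation scenarios
#'
#' * `random`: uniform preferences, no size assortment — the null model.
#' * `assortative`: zero cross-species female weight (diagonal preference).
#' * `arcana_asymmetric`: *L. arcana* males strongly prefer *L. saxatilis*
#'   females over their own, while *L. saxatilis* males favour conspecifics —
#'   the asymmetric pattern that drives a negative arcana FI.
#' * `size_assortative`: uniform preferences with a Gaussian size kernel
#'   (beta = 0.5 per mm^2, delta = -1 mm: males slightly smaller than
#'   partners).
#'
#' All presets share one stratum (`SIM`, lower shore) with five species at
#' field-like densities per 0.04 m^2 quadrat, 10 quadrats, 200 pairs.
#'
#' @param name scenario name.
#' @param n_pairs,n_quadrats,seed optional overrides.
#' @return a [simulation_config()].
#' @export
scenario <- function(name = c("random", "assortative", "arcana_asymmetric",
                              "size_assortative"),
                     n_pairs = 200, n_quadrats = 10, seed = NULL) {
  name <- match.arg(name)
  tab <- data.frame(
    site_year = "SIM", level = "lower",
    species = c("saxatilis", "arcana", "compressa", "obtusata", "fabalis"),
    density = c(25, 8, 4, 15, 6),
    prop_female = c(0.5, 0.6, 0.5, 0.5, 0.5),
    prop_itc = 0.2,
    meanlog = log(c(8, 8, 6, 10, 9)), sdlog = 0.25)
  base_seed <- switch(name, random = 100, assortative = 101,
                      arcana_asymmetric = 102, size_assortative = 103)
  psi <- switch(name,
    random = uniform_preference(),
    assortative = diagonal_preference(),
    arcana_asymmetric = {
      p <- uniform_preference()
      p["arcana", "saxatilis_female"] <- 10
      p["arcana", "arcana_female"] <- 0.5
      p["saxatilis", "saxatilis_female"] <- 3
      p
    },
    size_assortative = uniform_preference())
  simulation_config(tab, n_quadrats = n_quadrats, n_pairs = n_pairs,
                    preference = psi,
                    beta = if (name == "size_assortative") 0.5 else 0,
                    delta = if (name == "size_assortative") -1 else 0,
                    seed = if (is.null(seed)) base_seed else seed)
}

#' Simulate a quadrat census
#'
#' Per quadrat and species, draws a Poisson count, assigns ITC status with
#' the configured fraction and sex by the configured ratio otherwise, and
#' draws log-normal shell heights. All individuals are older than one year.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed (defaults to the configuration's).
#' @return validated census table.
#' @export
simulate_population <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  st <- config$species_table
  out <- list()
  for (i in seq_len(nrow(st))) {
    for (q in seq_len(config$n_quadrats)) {
      n <- stats::rpois(1, st$density[i])
      if (n == 0) next
      itc <- stats::runif(n) < st$prop_itc[i]
      female <- !itc & stats::runif(n) < st$prop_female[i]
      status <- ifelse(itc, "immature_or_castrated",
                       ifelse(female, "female", "male"))
      species <- ifelse(itc, species_group(rep(st$species[i], n)),
                        st$species[i])
      out[[length(out) + 1L]] <- data.frame(
        site_year = st$site_year[i], level = st$level[i],
        quadrat_id = paste0("Q", q),
        species = species, status = status,
        older_than_one_year = TRUE, infected = FALSE,
        shell_height_mm = stats::rlnorm(n, st$meanlog[i], st$sdlog[i]))
    }
  }
  if (!length(out)) stop("configuration produced an empty census")
  validate_census(do.call(rbind, out))
}

.simulate_matings_stratum <- function(pop, config, sy, lv) {
  psi <- config$preference
  eligible <- pop[pop$older_than_one_year, , drop = FALSE]
  is_male <- eligible$status == "male"
  if (!any(is_male)) stop("no mature males in stratum ", sy, " ", lv)
  male_cats <- table(eligible$species[is_male])
  act_w <- config$activity[names(male_cats)]
  act_w[is.na(act_w)] <- 0
  act_prob <- as.vector(male_cats) * act_w
  if (sum(act_prob) == 0) stop("no active male category has positive weight")
  mmr <- config$male_male_rate
  if (is.na(mmr)) mmr <- mean(is_male)
  n <- config$n_pairs

  act_cat <- sample(names(male_cats), n, replace = TRUE,
                    prob = act_prob / sum(act_prob))
  is_mm <- stats::runif(n) < mmr
  # active individual only contributes a height; sample per category
  male_rows <- split(which(is_male), eligible$species[is_male])
  act_row <- integer(n)
  for (sp in names(male_rows)) {
    k <- which(act_cat == sp)
    if (length(k))
      act_row[k] <- male_rows[[sp]][sample.int(length(male_rows[[sp]]),
                                               length(k), replace = TRUE)]
  }
  act_h <- eligible$shell_height_mm[act_row]

  lab_rows <- split(seq_len(nrow(eligible)), eligible$label)
  male_labs <- names(lab_rows)[grepl("_male$", names(lab_rows))]
  het_labs <- setdiff(names(lab_rows), male_labs)
  pas_row <- integer(n)
  if (config$beta == 0) {
    # passive choice depends only on (active category, pair type): sample
    # labels from the categorical composition x preference distribution,
    # then individuals uniformly (with replacement: polygamy) within label
    for (sp in unique(act_cat)) for (mm in c(TRUE, FALSE)) {
      k <- which(act_cat == sp & is_mm == mm)
      if (!length(k)) next
      labs <- if (mm) male_labs else het_labs
      if (!length(labs)) stop("no eligible passive partners in stratum")
      w <- lengths(lab_rows[labs]) * psi[sp, labs]
      if (all(w == 0))
        stop("preference row of ", sp,
             " is zero over every available passive partner")
      chosen <- sample(labs, length(k), replace = TRUE, prob = w / sum(w))
      for (l in unique(chosen)) {
        kk <- k[chosen == l]
        pas_row[kk] <- lab_rows[[l]][sample.int(length(lab_rows[[l]]),
                                                length(kk), replace = TRUE)]
      }
    }
  } else {
    for (k in seq_len(n)) {
      rows <- unlist(lab_rows[if (is_mm[k]) male_labs else het_labs],
                     use.names = FALSE)
      if (!length(rows)) stop("no eligible passive partners in stratum")
      w <- psi[act_cat[k], eligible$label[rows]] *
        exp(-config$beta *
              (act_h[k] - eligible$shell_height_mm[rows] - config$delta)^2)
      if (all(w == 0))
        stop("preference row of ", act_cat[k],
             " is zero over every available passive partner")
      pas_row[k] <- rows[sample.int(length(rows), 1, prob = w)]
    }
  }

  pas_sp <- eligible$species[pas_row]
  pas_st <- eligible$status[pas_row]
  pas_h <- eligible$shell_height_mm[pas_row]
  pas_q <- eligible$quadrat_id[pas_row]
  pid <- sprintf("%s_%s_S%05d", sy, lv, seq_len(n))
  # male-male pairs expand into two half-weight records with roles swapped
  two <- ifelse(is_mm, 2L, 1L)
  i <- rep(seq_len(n), two)
  second <- duplicated(i)
  data.frame(
    site_year = sy, level = lv,
    active_species = ifelse(second, pas_sp[i], act_cat[i]),
    active_status = "male",
    passive_species = ifelse(second, act_cat[i], pas_sp[i]),
    passive_status = ifelse(is_mm[i], "male", pas_st[i]),
    weight = ifelse(is_mm[i], 0.5, 1),
    active_height_mm = ifelse(second, pas_h[i], act_h[i]),
    passive_height_mm = ifelse(second, act_h[i], pas_h[i]),
    pair_id = pid[i], quadrat_id = pas_q[i],
    stringsAsFactors = FALSE)
}

#' Simulate copulating pairs from a census
#'
#' See the package-level description of the mating process. Emitted records
#' follow the pairs schema; an unordered male-male pair contributes two
#' 0.5-weight records, so total emitted weight equals `n_pairs` per stratum.
#'
#' @param population census table (e.g. from [simulate_population()]).
#' @param config a [simulation_config()].
#' @param seed integer seed (defaults to the configuration's, offset by one
#'   so that population and matings drawn from the same config differ).
#' @return validated pairs table.
#' @export
simulate_matings <- function(population, config, seed = config$seed + 1) {
  stopifnot(inherits(config, "simulation_config"), nrow(population) > 0)
  set.seed(seed)
  strata <- unique(population[, c("site_year", "level")])
  out <- lapply(seq_len(nrow(strata)), function(i) {
    pop <- .select_stratum(population, strata$site_year[i], strata$level[i])
    .simulate_matings_stratum(pop, config, strata$site_year[i],
                              strata$level[i])
  })
  validate_pairs(do.call(rbind, out))
}
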