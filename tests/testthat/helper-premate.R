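# Builders and independent oracles shared across test files.

# quick pair-record constructor (weight-1 heterosexual/ITC records)
make_pairs <- function(active, passive_species, passive_status,
                       site_year = "S1", level = "lower",
                       weight = 1, active_h = NA_real_, passive_h = NA_real_,
                       pair_id = NULL, quadrat_id = NA_character_) {
  n <- max(length(active), length(passive_species), length(passive_status),
           length(weight))
  if (is.null(pair_id)) pair_id <- sprintf("T%03d", seq_len(n))
  validate_pairs(data.frame(
    site_year = site_year, level = level,
    active_species = rep_len(active, n), active_status = "male",
    passive_species = rep_len(passive_species, n),
    passive_status = rep_len(passive_status, n),
    weight = rep_len(weight, n),
    active_height_mm = rep_len(active_h, n),
    passive_height_mm = rep_len(passive_h, n),
    pair_id = pair_id, quadrat_id = rep_len(quadrat_id, n),
    stringsAsFactors = FALSE))
}

# census builder: `counts` is a named vector over "species|status" keys
make_census <- function(counts, site_year = "S1", level = "lower",
                        quadrat_id = "Q1", heights = 8, mature = TRUE) {
  sp <- sub("\\|.*", "", names(counts))
  st <- sub(".*\\|", "", names(counts))
  n <- sum(counts)
  validate_census(data.frame(
    site_year = site_year, level = level,
    quadrat_id = rep_len(quadrat_id, n),
    species = rep(sp, counts), status = rep(st, counts),
    older_than_one_year = rep_len(mature, n), infected = FALSE,
    shell_height_mm = rep_len(heights, n), stringsAsFactors = FALSE))
}

table2_pairs <- function() read_pairs(premate_example("table2_pairs.csv"))

table3_matrix <- function() {
  t3 <- utils::read.csv(premate_example("table3_combinations.csv"),
                        check.names = FALSE)
  m <- as.matrix(t3[, -1])
  rownames(m) <- t3$passive
  storage.mode(m) <- "integer"
  m
}

# independent brute-force SMC: explicit f11/f10/f01/f00 bookkeeping
oracle_smc <- function(a, b) {
  f11 <- sum(a == 1 & b == 1); f10 <- sum(a == 1 & b == 0)
  f01 <- sum(a == 0 & b == 1); f00 <- sum(a == 0 & b == 0)
  (f10 + f01) / (f11 + f10 + f01 + f00)
}

# independent FI for one focal male: raw aggregation over a record table,
# against a fixed passive composition
oracle_fi_male <- function(pairs, p_passive, focal, consp_labels) {
  af <- sum(pairs$weight[pairs$active_species == focal])
  if (af == 0) return(NA_real_)
  oc <- sum(pairs$weight[pairs$active_species == focal &
                           pairs$passive_label %in% consp_labels])
  tt <- sum(pairs$weight)
  sc <- sum(p_passive[intersect(consp_labels, names(p_passive))]) *
    (af / tt) * tt
  (oc - sc) / ((af / tt) * tt)
}
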