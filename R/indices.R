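# Fidelity Index and precopulatory isolation index, with bootstrap inference.
#
# Both indices compare observed copulation frequencies with the expectations
# of the random-mating null model. FI for a focal male category is
# (O_consp - S_consp) / sum_i S_i,focal: the excess of conspecific-female
# matings over expectation, scaled by the focal male's total expected
# matings (which, by construction of the null model, equals his observed
# weighted total). I_PC for a species pair is the joint isolation index
# computed on the ratios r_ij = O_ij / S_ij of the four male x mature-female
# cells: (r_XX + r_YY - r_XY - r_YX) / (r_XX + r_YY + r_XY + r_YX).

.consp_labels <- function(species)
  paste0(.conspecific_females[[species]], "_female")

#' Fidelity Index of a focal male category
#'
#' @param object a fitted [mating_null()] object.
#' @param species focal male species token. For `saxatilis_1p5` both
#'   *L. saxatilis* and *L. arcana* females count as conspecific.
#' @param site_year,level stratum.
#' @return FI in \[-1, 1\]: -1 avoidance, 0 random mating, 1 assortative.
#' @export
fidelity_index <- function(object, species, site_year, level) {
  st <- .get_stratum(object, site_year, level)
  if (!species %in% colnames(st$observed))
    stop("no copulations with active ", species, " males in stratum")
  consp <- intersect(.consp_labels(species), rownames(st$observed))
  if (!length(consp))
    stop("conspecific female category of ", species,
         " absent from the stratum table")
  denom <- sum(st$expected[, species])
  if (denom == 0) stop("FI undefined: zero expected total for ", species)
  (sum(st$observed[consp, species]) - sum(st$expected[consp, species])) / denom
}

#' Fidelity Index of a focal female category
#'
#' Mirror of [fidelity_index()] with the roles swapped: how frequently
#' females of the focal species were engaged by conspecific males, relative
#' to the expected matings they receive from all male categories. Conspecific
#' males of a female are males of her own species; 1.5-row males are
#' conspecific to no female category (their species is uncertain).
#'
#' @inheritParams fidelity_index
#' @param species focal female species token (one of the five species).
#' @export
fidelity_index_female <- function(object, species, site_year, level) {
  st <- .get_stratum(object, site_year, level)
  lab <- paste0(species, "_female")
  if (!lab %in% rownames(st$observed))
    stop(lab, " absent from the stratum table")
  denom <- sum(st$expected[lab, ])
  if (denom == 0) stop("FI undefined: zero expected total for ", lab)
  o <- if (species %in% colnames(st$observed)) st$observed[lab, species] else 0
  s <- if (species %in% colnames(st$expected)) st$expected[lab, species] else 0
  (o - s) / denom
}

#' Precopulatory isolation index for a species pair
#'
#' Computed on the four active-male x mature-conspecific-female cells of the
#' two species; 1.5-row males and non-female passive categories play no part.
#' If any of the four expected frequencies is zero the pair-stratum is not
#' computable and `NA` is returned with a message (such combinations are
#' excluded, as categories absent from the census cannot enter the null
#' model).
#'
#' @inheritParams fidelity_index
#' @param species_pair character vector of two species tokens.
#' @return I_PC in \[-1, 1\] (-1 disassortative, 0 random, 1 assortative),
#'   or `NA` if not computable.
#' @export
ipc <- function(object, species_pair, site_year, level) {
  stopifnot(length(species_pair) == 2)
  st <- .get_stratum(object, site_year, level)
  x <- species_pair[1]; y <- species_pair[2]
  rows <- paste0(c(x, y), "_female")
  if (!all(species_pair %in% colnames(st$observed)) ||
      !all(rows %in% rownames(st$observed))) {
    message("I_PC ", x, "-", y, " ", site_year, " ", level,
            ": required categories missing; excluded")
    return(NA_real_)
  }
  S <- st$expected[rows, species_pair]
  if (any(S == 0)) {
    message("I_PC ", x, "-", y, " ", site_year, " ", level,
            ": zero expected cell; excluded")
    return(NA_real_)
  }
  r <- st$observed[rows, species_pair] / S
  # r[female j, male i]; homotypic cells are the diagonal
  (r[1, 1] + r[2, 2] - r[1, 2] - r[2, 1]) /
    (r[1, 1] + r[2, 2] + r[1, 2] + r[2, 1])
}

# ---------------------------------------------------------------------------
# Bootstrap. The resampling unit is the physical copulating pair: the two
# 0.5-weight halves of a male-male pair travel together, and the census
# composition (hence P_passive) is held fixed. Each replicate resamples n
# pairs with replacement within the stratum, re-tabulates observed counts and
# active-male frequencies, and recomputes the statistic.

# per-pair contribution matrix for the statistic, so a replicate is a single
# colSums over sampled rows
.pair_units <- function(sel) {
  split(seq_len(nrow(sel)), sel$pair_id)
}

.boot_setup <- function(sel, p_passive, statistic, focal, species_pair) {
  units <- .pair_units(sel)
  n <- length(units)
  if (statistic == "fi_male") {
    consp <- .consp_labels(focal)
    pc <- sum(p_passive[intersect(consp, names(p_passive))])
    C <- cbind(
      oc = vapply(units, function(r) sum(sel$weight[r][
        sel$active_species[r] == focal & sel$passive_label[r] %in% consp]), 0),
      af = vapply(units, function(r) sum(sel$weight[r][
        sel$active_species[r] == focal]), 0))
    eval_stat <- function(s) if (s["af"] == 0) NA_real_ else
      s[["oc"]] / s[["af"]] - pc
  } else if (statistic == "fi_female") {
    lab <- paste0(focal, "_female")
    pl <- if (lab %in% names(p_passive)) p_passive[[lab]] else
      stop(lab, " absent from census composition")
    C <- cbind(
      oc = vapply(units, function(r) sum(sel$weight[r][
        sel$active_species[r] == focal & sel$passive_label[r] == lab]), 0),
      af = vapply(units, function(r) sum(sel$weight[r][
        sel$active_species[r] == focal]), 0),
      t = vapply(units, function(r) sum(sel$weight[r]), 0))
    eval_stat <- function(s) if (s[["t"]] == 0) NA_real_ else
      (s[["oc"]] - pl * s[["af"]]) / (pl * s[["t"]])
  } else { # ipc
    x <- species_pair[1]; y <- species_pair[2]
    labs <- paste0(c(x, y), "_female")
    if (!all(labs %in% names(p_passive)))
      stop("female categories of ", x, " and ", y,
           " must be present in the census composition")
    cellw <- function(act, pas) vapply(units, function(r) sum(sel$weight[r][
      sel$active_species[r] == act & sel$passive_label[r] == pas]), 0)
    C <- cbind(oxx = cellw(x, labs[1]), oxy = cellw(x, labs[2]),
               oyx = cellw(y, labs[1]), oyy = cellw(y, labs[2]),
               ax = vapply(units, function(r) sum(sel$weight[r][
                 sel$active_species[r] == x]), 0),
               ay = vapply(units, function(r) sum(sel$weight[r][
                 sel$active_species[r] == y]), 0))
    px <- p_passive[[labs[1]]]; py <- p_passive[[labs[2]]]
    eval_stat <- function(s) {
      if (s[["ax"]] == 0 || s[["ay"]] == 0) return(NA_real_)
      # r_ij = O_ij / (a_i * P_passive[j female]); t cancels
      rxx <- s[["oxx"]] / (s[["ax"]] * px)
      rxy <- s[["oxy"]] / (s[["ax"]] * py)
      ryx <- s[["oyx"]] / (s[["ay"]] * px)
      ryy <- s[["oyy"]] / (s[["ay"]] * py)
      tot <- rxx + ryy + rxy + ryx
      if (tot == 0) return(NA_real_)
      (rxx + ryy - rxy - ryx) / tot
    }
  }
  list(C = C, eval_stat = eval_stat, n = n)
}

#' Bootstrap inference for a mating index
#'
#' Resamples physical copulating pairs with replacement within one stratum
#' (the two half-records of a male-male pair stay together; the census
#' composition is held fixed), recomputes observed counts and active-male
#' frequencies, and re-evaluates the index in each replicate.
#'
#' The replicate stream is reproducible: after `set.seed(seed)` each
#' replicate draws its pair indices with `sample(n, n, replace = TRUE)` in
#' order. Replicates in which the index is undefined (zero denominator) are
#' dropped and counted; if more than half are dropped the estimate is flagged
#' invalid. The two-tail p-value for H0: index = 0 is
#' `2 * min(#{rep <= 0} + 1, #{rep >= 0} + 1) / (B_kept + 1)`, capped at 1.
#'
#' @param pairs validated pairs table.
#' @param census validated census table.
#' @param statistic `"fi_male"`, `"fi_female"` or `"ipc"`.
#' @param focal focal species token (FI statistics).
#' @param species_pair two species tokens (I_PC).
#' @param site_year,level stratum.
#' @param B number of bootstrap iterations (default 10000).
#' @param seed integer seed (required: resampling must be reproducible).
#' @param pool composition estimator, see [passive_composition()].
#' @return object of class `index_estimate` with fields `point`,
#'   `boot_mean`, `boot_sd`, `p_two_tail`, `n_iter`, `n_dropped`, `valid`,
#'   `replicates`, `seed`.
#' @export
bootstrap_index <- function(pairs, census,
                            statistic = c("fi_male", "fi_female", "ipc"),
                            focal = NULL, species_pair = NULL,
                            site_year, level, B = 10000, seed,
                            pool = c("pool", "average")) {
  statistic <- match.arg(statistic)
  pool <- match.arg(pool)
  stopifnot(B >= 1)
  if (missing(seed)) stop("an explicit seed is required")
  if (statistic %in% c("fi_male", "fi_female") && is.null(focal))
    stop("FI statistics need a focal species")
  if (statistic == "ipc" && length(species_pair) != 2)
    stop("ipc needs a species pair")
  sel <- .select_stratum(pairs, site_year, level)
  if (nrow(sel) == 0) stop("no pairs in stratum ", site_year, " ", level)
  p_pas <- passive_composition(census, site_year, level, pool)
  setup <- .boot_setup(sel, p_pas, statistic, focal, species_pair)
  point <- setup$eval_stat(colSums(setup$C))
  set.seed(seed)
  reps <- vapply(seq_len(B), function(b) {
    idx <- sample(setup$n, setup$n, replace = TRUE)
    setup$eval_stat(colSums(setup$C[idx, , drop = FALSE]))
  }, 0)
  kept <- reps[!is.na(reps)]
  n_drop <- B - length(kept)
  p <- if (length(kept)) min(1, 2 * min(sum(kept <= 0) + 1,
                                        sum(kept >= 0) + 1) /
                                (length(kept) + 1)) else NA_real_
  structure(list(
    index_name = statistic,
    focal = if (statistic == "ipc") paste(species_pair, collapse = "-")
            else focal,
    site_year = site_year, level = level,
    point = point,
    boot_mean = if (length(kept)) mean(kept) else NA_real_,
    boot_sd = if (length(kept) > 1) stats::sd(kept) else 0,
    p_two_tail = p,
    n_iter = B, n_dropped = n_drop,
    valid = n_drop <= B / 2 && !is.na(point),
    replicates = reps, seed = seed), class = "index_estimate")
}

#' @export
print.index_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("%s [%s] %s %s: %.3f (boot %.3f +/- %.3f, p = %.4g, B = %d%s)%s\n",
              toupper(x$index_name), x$focal, x$site_year, x$level,
              x$point, x$boot_mean, x$boot_sd, x$p_two_tail, x$n_iter,
              if (x$n_dropped) paste0(", dropped ", x$n_dropped) else "",
              if (!x$valid) " [INVALID: >50% replicates undefined]" else ""))
  invisible(x)
}

#' @export
as.data.frame.index_estimate <- function(x, ...) {
  data.frame(index = x$index_name, focal = x$focal, site_year = x$site_year,
             level = x$level, point = x$point, boot_mean = x$boot_mean,
             boot_sd = x$boot_sd, p_two_tail = x$p_two_tail,
             n_iter = x$n_iter, n_dropped = x$n_dropped, valid = x$valid,
             seed = x$seed)
}
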