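# Size-structure analyses: paired partner-size differences, permutation
# correlation of partner sizes, a within-quadrat random-pairing Monte-Carlo
# null, and a permutation test of spatial segregation by size.

#' Paired partner-size differences
#'
#' Paired t-tests of active-minus-passive shell height in heterosexual
#' records (conspecific female, heterospecific female or ITC passive
#' partner), separately for each active species x passive class x stratum
#' group with at least `min_pairs` complete height pairs. Smaller groups and
#' records lacking a height are skipped with a message.
#'
#' @param pairs validated pairs table with shell heights.
#' @param min_pairs minimum complete pairs per group (default 5).
#' @return data frame with one row per tested group: n_pairs,
#'   mean_difference_mm, t statistic, df, two-tail p.
#' @export
paired_size_difference <- function(pairs, min_pairs = 5) {
  sel <- pairs[pairs$mating_class != "male_male", , drop = FALSE]
  ok <- !is.na(sel$active_height_mm) & !is.na(sel$passive_height_mm)
  if (any(!ok))
    message(sum(!ok), " record(s) without both heights skipped")
  sel <- sel[ok, , drop = FALSE]
  key <- interaction(sel$site_year, sel$level, sel$active_species,
                     sel$mating_class, drop = TRUE)
  out <- lapply(split(sel, key), function(g) {
    if (nrow(g) < min_pairs) {
      message("group ", g$site_year[1], " ", g$level[1], " ",
              g$active_species[1], " x ", g$mating_class[1], ": only ",
              nrow(g), " pairs, skipped")
      return(NULL)
    }
    d <- g$active_height_mm - g$passive_height_mm
    if (stats::sd(d) == 0) {
      # degenerate case: constant difference has no within-group variance
      tt <- list(estimate = mean(d),
                 statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                 parameter = length(d) - 1,
                 p.value = if (mean(d) == 0) 1 else 0)
    } else {
      tt <- stats::t.test(g$active_height_mm, g$passive_height_mm,
                          paired = TRUE)
    }
    data.frame(site_year = g$site_year[1], level = g$level[1],
               active_species = g$active_species[1],
               mating_class = as.character(g$mating_class[1]),
               n_pairs = nrow(g),
               mean_difference_mm = unname(tt$estimate),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  out <- if (length(out)) do.call(rbind, c(out, make.row.names = FALSE))
  if (is.null(out))
    out <- data.frame(site_year = character(), level = character(),
                      active_species = character(),
                      mating_class = character(), n_pairs = integer(),
                      mean_difference_mm = numeric(), t = numeric(),
                      df = numeric(), p_value = numeric())
  out
}

#' Permutation test of partner-size correlation
#'
#' Pearson correlation of active and passive shell heights, with
#' significance from shuffling the passive heights `n_perm` times:
#' `p = (#{|r*| >= |r_obs|} + 1) / (n_perm + 1)`.
#'
#' @param active_height,passive_height numeric vectors of equal length
#'   (>= 3, no missing values).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed (required).
#' @return list with `r`, `p_value`, `n`, `n_perm`, `seed`.
#' @export
size_correlation_perm <- function(active_height, passive_height,
                                  n_perm = 10000, seed) {
  stopifnot(length(active_height) == length(passive_height),
            !anyNA(active_height), !anyNA(passive_height))
  if (missing(seed)) stop("an explicit seed is required")
  n <- length(active_height)
  if (n < 3) stop("need at least 3 pairs")
  if (stats::sd(active_height) == 0 || stats::sd(passive_height) == 0)
    stop("correlation undefined: zero variance in heights")
  r_obs <- stats::cor(active_height, passive_height)
  set.seed(seed)
  r_star <- vapply(seq_len(n_perm), function(i)
    stats::cor(active_height, sample(passive_height)), 0)
  p <- (sum(abs(r_star) >= abs(r_obs)) + 1) / (n_perm + 1)
  list(r = r_obs, p_value = p, n = n, n_perm = n_perm, seed = seed)
}

#' Monte-Carlo random pairing within quadrats
#'
#' Null distribution of the partner-size correlation when males and mature
#' conspecific females mate at random *within* census quadrats. Per
#' iteration, each quadrat contributes `min(#males, #females)` random
#' male-female pairs drawn without replacement; the pairs are pooled across
#' quadrats and their size correlation computed. The p-value is the
#' (+1-corrected) proportion of iterations with `|r*| >= |r_obs|`.
#' Iterations yielding fewer than 3 pooled pairs are dropped and counted.
#'
#' @param census validated census table with quadrat ids and heights.
#' @param observed_r observed correlation in real pairs.
#' @param species focal species token.
#' @param site_year,level stratum.
#' @param n_iter number of iterations (default 10000).
#' @param seed integer seed (required).
#' @return list with `p_value`, `observed_r`, `n_iter`, `n_used`,
#'   `n_dropped`, `r_star` (the simulated correlations), `seed`.
#' @export
random_pairing_mc <- function(census, observed_r, species, site_year, level,
                              n_iter = 10000, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  sel <- .select_stratum(census, site_year, level)
  sel <- sel[sel$species == species & sel$older_than_one_year, , drop = FALSE]
  males <- split(sel$shell_height_mm[sel$status == "male"],
                 sel$quadrat_id[sel$status == "male"])
  females <- split(sel$shell_height_mm[sel$status == "female"],
                   sel$quadrat_id[sel$status == "female"])
  quads <- intersect(names(males), names(females))
  if (!length(quads))
    stop("no quadrat contains both males and mature females of ", species)
  set.seed(seed)
  r_star <- vapply(seq_len(n_iter), function(i) {
    hm <- numeric(0); hf <- numeric(0)
    for (q in quads) {
      k <- min(length(males[[q]]), length(females[[q]]))
      hm <- c(hm, sample(males[[q]])[seq_len(k)])
      hf <- c(hf, sample(females[[q]])[seq_len(k)])
    }
    if (length(hm) < 3 || stats::sd(hm) == 0 || stats::sd(hf) == 0)
      return(NA_real_)
    stats::cor(hm, hf)
  }, 0)
  used <- r_star[!is.na(r_star)]
  p <- (sum(abs(used) >= abs(observed_r)) + 1) / (length(used) + 1)
  list(p_value = p, observed_r = observed_r, n_iter = n_iter,
       n_used = length(used), n_dropped = n_iter - length(used),
       r_star = r_star, seed = seed)
}

#' Permutation test of spatial segregation by size
#'
#' Individuals of the focal species are split at the stratum-wide median
#' shell height into small (rank 0, height < median) and large (rank 1,
#' height >= median). The test statistic is the mean over quadrats (with at
#' least two individuals) of the per-quadrat population variance of ranks;
#' low values mean quadrats tend to hold one size class only, i.e. spatial
#' segregation by size. The null distribution shuffles ranks across quadrats
#' holding quadrat sizes fixed;
#' `p = (#{mean variance* < observed} + 1) / (n_perm + 1)`.
#'
#' @param census validated census table.
#' @param species focal species token.
#' @param site_year,level stratum.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed (required).
#' @return object of class `segregation_test`: a list with
#'   `observed_mean_rank_variance`, `p_value`, `n_perm`, `n_samples_used`,
#'   `degenerate` (TRUE when all individuals fall on one side of the
#'   median), `seed`.
#' @export
segregation_test <- function(census, species, site_year, level,
                             n_perm = 10000, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  sel <- .select_stratum(census, site_year, level)
  sel <- sel[sel$species == species, , drop = FALSE]
  stopifnot(nrow(sel) > 0)
  med <- stats::median(sel$shell_height_mm)
  ranks <- as.integer(sel$shell_height_mm >= med)
  sizes <- table(sel$quadrat_id)
  keep <- names(sizes)[sizes >= 2]
  if (length(keep) < 2)
    stop("need at least two quadrats with two or more individuals")
  sel_in <- sel$quadrat_id %in% keep
  ranks <- ranks[sel_in]
  quad <- factor(sel$quadrat_id[sel_in])
  pop_var <- function(x) mean((x - mean(x))^2)
  stat <- function(r) mean(tapply(r, quad, pop_var))
  obs <- stat(ranks)
  degenerate <- length(unique(ranks)) == 1
  if (degenerate)
    warning("all individuals on one side of the median; statistic is ",
            "identically zero under permutation")
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) stat(sample(ranks)), 0)
  p <- (sum(perm < obs) + 1) / (n_perm + 1)
  structure(list(species = species, site_year = site_year, level = level,
                 observed_mean_rank_variance = obs, p_value = p,
                 n_perm = n_perm, n_samples_used = length(keep),
                 degenerate = degenerate, seed = seed),
            class = "segregation_test")
}

#' @export
print.segregation_test <- function(x, ...) {
  cat(sprintf(paste0("Spatial segregation by size: %s, %s %s\n",
                     "  mean rank variance = %.4f over %d quadrats, ",
                     "p = %.4g (%d permutations)%s\n"),
              x$species, x$site_year, x$level,
              x$observed_mean_rank_variance, x$n_samples_used, x$p_value,
              x$n_perm, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Box plot of shell heights by partner category
#'
#' Presentation helper: heights of copulating individuals grouped by
#' category (active and passive pooled), male-male passive partners
#' included as their male category.
#'
#' @param pairs validated pairs table with heights.
#' @param ... passed to [graphics::boxplot].
#' @export
plot_height_by_category <- function(pairs, ...) {
  act <- data.frame(label = paste0(pairs$active_species, "_male"),
                    height = pairs$active_height_mm)
  pas <- data.frame(label = pairs$passive_label,
                    height = pairs$passive_height_mm)
  all <- rbind(act, pas)
  all <- all[!is.na(all$height), , drop = FALSE]
  if (!nrow(all)) stop("no height data to plot")
  graphics::boxplot(height ~ label, data = all, las = 2,
                    ylab = "shell height (mm)", xlab = "", ...)
  invisible(all)
}
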