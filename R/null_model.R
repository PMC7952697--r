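# The random-mating null model.
#
# Expected copulation frequencies in a stratum (site-year x intertidal level)
# are the outer product S_ij = P_active[j] * P_passive[i] * t, where
# P_passive comes from the quadrat-census composition of potential passive
# partners (all individuals older than one year: males, females and ITC of
# every species), P_active from the weighted frequencies of active male
# morphotypes among the copulating pairs themselves, and t is the total
# weighted pair count. Encounter rates, habitat preference and timing are
# deliberately absent: the model measures the chance of meeting partners of
# each category if mating were random within the stratum.

#' Passive-partner composition of a stratum
#'
#' Probabilities of being a potential passive partner, proportional to the
#' census counts of eligible individuals (older than one year) per category.
#'
#' @param census validated census table (see [read_census()]).
#' @param site_year,level stratum selector.
#' @param pool `"pool"` (default) pools individuals across quadrats;
#'   `"average"` averages per-quadrat proportions (sensitivity option —
#'   quadrat areas are equal, so pooling is the natural estimator).
#' @return named probability vector over passive-category labels, summing
#'   to 1.
#' @export
passive_composition <- function(census, site_year = NULL, level = NULL,
                                pool = c("pool", "average")) {
  pool <- match.arg(pool)
  sel <- .select_stratum(census, site_year, level)
  sel <- sel[sel$older_than_one_year, , drop = FALSE]
  if (nrow(sel) == 0)
    stop("no eligible (older-than-one-year) individuals in the census; ",
         "expected frequencies are undefined")
  if (pool == "pool") {
    counts <- table(sel$label)
    p <- counts / sum(counts)
  } else {
    prop <- prop.table(table(sel$quadrat_id, sel$label), margin = 1)
    p <- colMeans(prop)
    p <- p / sum(p)
  }
  lv <- intersect(.passive_order, names(p))
  stats::setNames(as.vector(p[lv]), lv)
}

#' Active-male copulation frequencies of a stratum
#'
#' Probability of each active male morphotype, equal to its weighted
#' copulation count divided by the total weighted pair count t.
#'
#' @param pairs validated pairs table.
#' @param site_year,level stratum selector.
#' @return named probability vector over active male species, summing to 1.
#' @export
active_frequencies <- function(pairs, site_year = NULL, level = NULL) {
  sel <- .select_stratum(pairs, site_year, level)
  t_tot <- sum(sel$weight)
  if (t_tot <= 0) stop("no copulating pairs in the stratum (t = 0)")
  a <- tapply(sel$weight, sel$active_species, sum)
  lv <- intersect(premate_species, names(a))
  stats::setNames(as.vector(a[lv]) / t_tot, lv)
}

#' Expected copulation frequencies under random mating
#'
#' @param p_active,p_passive probability vectors (each summing to 1).
#' @param t total weighted pair count.
#' @return matrix `S` with passive categories in rows and active species in
#'   columns, `S[i, j] = p_passive[i] * p_active[j] * t`.
#' @export
expected_table <- function(p_active, p_passive, t) {
  stopifnot(t > 0, all(p_active >= 0), all(p_passive >= 0),
            isTRUE(all.equal(sum(p_active), 1)),
            isTRUE(all.equal(sum(p_passive), 1)))
  outer(p_passive, p_active) * t
}

#' Fit the random-mating null model
#'
#' For every stratum represented in `pairs`, tabulates observed weighted
#' copulation frequencies and the expected frequencies under random mating.
#' Passive categories observed in copulation but absent from the census make
#' expected frequencies incomputable; such rows are dropped from the
#' stratum's table and recorded in the `dropped` field (mirroring the
#' exclusion of census-absent categories in the field analysis).
#'
#' @param pairs validated pairs table (see [read_pairs()]).
#' @param census validated census table (see [read_census()]).
#' @param pool composition estimator passed to [passive_composition()].
#' @return an object of class `mating_null`: a list with one entry per
#'   stratum (each holding `observed`, `expected`, `p_active`, `p_passive`,
#'   `t`, `dropped`) plus the call. Methods: `print`, `summary`, `fitted`,
#'   `residuals`, `simulate`, `plot`, `as.data.frame`.
#' @examples
#' \dontrun{
#' fit <- mating_null(pairs, census)
#' fidelity_index(fit, "saxatilis", "DZ2015", "upper")
#' }
#' @export
mating_null <- function(pairs, census, pool = c("pool", "average")) {
  pool <- match.arg(pool)
  stopifnot(nrow(pairs) > 0, nrow(census) > 0)
  strata <- unique(pairs[, c("site_year", "level")])
  strata <- strata[order(strata$site_year, strata$level), , drop = FALSE]
  fits <- lapply(seq_len(nrow(strata)), function(i) {
    sy <- strata$site_year[i]; lv <- strata$level[i]
    p_act <- active_frequencies(pairs, sy, lv)
    p_pas <- passive_composition(census, sy, lv, pool)
    sel <- .select_stratum(pairs, sy, lv)
    t_tot <- sum(sel$weight)
    rows <- union(names(p_pas), unique(sel$passive_label))
    rows <- intersect(.passive_order, rows)
    obs <- tabulate_pairs(sel, passive_levels = rows,
                          active_levels = names(p_act))
    dropped <- setdiff(rows, names(p_pas))
    if (length(dropped)) {
      message(sy, " ", lv, ": passive categor",
              if (length(dropped) > 1) "ies" else "y", " ",
              paste(dropped, collapse = ", "),
              " observed in copulation but absent from the census; dropped")
      obs <- obs[setdiff(rownames(obs), dropped), , drop = FALSE]
    }
    # dropped categories were never in the census, so p_pas already sums to 1
    # over the retained rows
    exp_m <- expected_table(p_act, p_pas, t_tot)[rownames(obs), , drop = FALSE]
    list(site_year = sy, level = lv, t = t_tot, observed = obs,
         expected = exp_m, p_active = p_act, p_passive = p_pas,
         dropped = dropped)
  })
  names(fits) <- paste(strata$site_year, strata$level, sep = ":")
  structure(list(strata = fits, pool = pool, call = match.call()),
            class = "mating_null")
}

.get_stratum <- function(object, site_year, level) {
  key <- paste(site_year, level, sep = ":")
  st <- object$strata[[key]]
  if (is.null(st)) stop("no fitted stratum ", key)
  st
}

#' @export
print.mating_null <- function(x, ...) {
  cat("Random-mating null model (", length(x$strata), " strata, composition: ",
      x$pool, "ed quadrats)\n", sep = "")
  for (st in x$strata) {
    cat("  ", st$site_year, " ", st$level, ": t = ", st$t, ", ",
        ncol(st$observed), " active x ", nrow(st$observed),
        " passive categories", sep = "")
    if (length(st$dropped))
      cat(" [dropped: ", paste(st$dropped, collapse = ", "), "]", sep = "")
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.mating_null <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$strata, function(st) {
    data.frame(site_year = st$site_year, level = st$level, t = st$t,
               n_active = ncol(st$observed), n_passive = nrow(st$observed),
               n_dropped = length(st$dropped),
               max_abs_residual = max(abs(st$observed - st$expected)))
  }))
  rownames(tab) <- NULL
  structure(list(table = tab, pool = object$pool),
            class = "summary.mating_null")
}

#' @export
print.summary.mating_null <- function(x, ...) {
  cat("Random-mating null model -- per-stratum summary\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
fitted.mating_null <- function(object, ...) {
  lapply(object$strata, `[[`, "expected")
}

#' @export
residuals.mating_null <- function(object, ...) {
  lapply(object$strata, function(st) st$observed - st$expected)
}

#' Long-format observed/expected table
#'
#' One row per (stratum, passive category, active species) cell with the
#' observed and expected weighted frequencies — the table an ordination of
#' mating combinations (e.g. partial CCA) would consume.
#'
#' @param x a fitted [mating_null()] object.
#' @param ... unused.
#' @export
as.data.frame.mating_null <- function(x, ...) {
  do.call(rbind, c(lapply(x$strata, function(st) {
    grid <- expand.grid(passive = rownames(st$observed),
                        active = colnames(st$observed),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    data.frame(site_year = st$site_year, level = st$level, grid,
               observed = as.vector(st$observed),
               expected = as.vector(st$expected))
  }), make.row.names = FALSE))
}

#' Simulate random matings from the fitted null model
#'
#' Draws `nsim` independent matings per stratum, sampling the active species
#' from `p_active` and the passive category from `p_passive`, and returns the
#' resulting cell counts — the Monte-Carlo counterpart of the closed-form
#' expected table.
#'
#' @param object a fitted [mating_null()] object.
#' @param nsim number of matings per stratum.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of count matrices, one per stratum, with the dimensions of
#'   the stratum's expected table.
#' @export
simulate.mating_null <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(object$strata, function(st) {
    act <- sample(names(st$p_active), nsim, replace = TRUE,
                  prob = st$p_active)
    pas <- sample(names(st$p_passive), nsim, replace = TRUE,
                  prob = st$p_passive)
    cnt <- table(factor(pas, rownames(st$expected)),
                 factor(act, colnames(st$expected)))
    m <- matrix(as.vector(cnt), nrow(st$expected), ncol(st$expected),
                dimnames = dimnames(st$expected))
    m
  })
}

#' @export
plot.mating_null <- function(x, ...) {
  long <- as.data.frame(x)
  graphics::plot(long$expected, long$observed,
                 xlab = "expected frequency (random mating)",
                 ylab = "observed frequency",
                 main = "Observed vs expected copulation frequencies", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(long)
}
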