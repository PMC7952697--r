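# End-to-end orchestration: ingest -> null model -> indices -> clustering ->
# size tests -> report bundle with a machine-readable manifest.

#' Run the full mating-pattern analysis pipeline
#'
#' Ingests pair and census tables (or generates them from a named
#' simulation scenario), then runs the enabled stages and writes their
#' outputs to `out_dir`: summary counts (CSV + JSON), the long-format
#' observed/expected table, index tables (FI for males and females, I_PC per
#' species pair, with bootstrap inference when `B > 0`), SMC distance
#' matrices and UPGMA trees for both margins, size-test tables, and a
#' manifest with an MD5 checksum per output file.
#'
#' @param pairs_csv,census_csv input paths (see [read_pairs()],
#'   [read_census()]); alternatively give `scenario_name`.
#' @param scenario_name a [scenario()] preset to simulate instead of reading
#'   inputs.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed governing every resampling stage (required).
#' @param B bootstrap iterations for the index stage; 0 = point estimates
#'   only.
#' @param n_perm,n_iter permutation / Monte-Carlo iterations for the size
#'   stage.
#' @param stages character vector of stages to run, a subset of
#'   `c("summarize", "expected", "indices", "cluster", "sizes")`.
#' @param strata optional character vector of `"site_year:level"` keys to
#'   restrict the analysis to.
#' @return invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(pairs_csv = NULL, census_csv = NULL,
                         scenario_name = NULL, out_dir, seed,
                         B = 10000, n_perm = 10000, n_iter = 10000,
                         stages = c("summarize", "expected", "indices",
                                    "cluster", "sizes"),
                         strata = NULL) {
  if (missing(seed)) stop("an explicit seed is required")
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit_csv <- function(x, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(x, path, row.names = FALSE, na = "")
    outputs <<- c(outputs, path)
    path
  }
  in_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", stage, " failed: ", conditionMessage(e), call. = FALSE))
  }

  census <- NULL
  if (!is.null(scenario_name)) {
    cfg <- in_stage("simulate", scenario(scenario_name, seed = seed))
    census <- in_stage("simulate", simulate_population(cfg))
    pairs <- in_stage("simulate", simulate_matings(census, cfg))
    emit_csv(census[intersect(.census_cols, names(census))], "census.csv")
    emit_csv(pairs[intersect(.pair_cols, names(pairs))], "pairs.csv")
  } else {
    if (is.null(pairs_csv)) stop("stage ingest failed: no pairs input")
    pairs <- in_stage("ingest", read_pairs(pairs_csv))
    if (!is.null(census_csv))
      census <- in_stage("ingest", read_census(census_csv))
  }
  if (!is.null(strata)) {
    pairs <- pairs[pairs$stratum %in% strata, , drop = FALSE]
    if (!is.null(census))
      census <- census[census$stratum %in% strata, , drop = FALSE]
    if (nrow(pairs) == 0) stop("stage ingest failed: strata filter left no pairs")
  }

  results <- list(pairs = pairs, census = census)

  if ("summarize" %in% stages) {
    counts <- in_stage("summarize", summary_counts(pairs))
    results$counts <- counts
    emit_csv(as.data.frame(counts), "summary_counts.csv")
    path <- file.path(out_dir, "summary_counts.json")
    jsonlite::write_json(as.list(as.data.frame(counts)$weighted_count),
                         path, auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, path)
  }

  fit <- NULL
  if (any(c("expected", "indices") %in% stages)) {
    if (is.null(census))
      stop("stage null_model failed: the census input is required to fit ",
           "the random-mating null model")
    fit <- in_stage("null_model", mating_null(pairs, census))
    results$fit <- fit
    if ("expected" %in% stages)
      emit_csv(as.data.frame(fit), "expected_frequencies.csv")
  }

  if ("indices" %in% stages) {
    results$indices <- in_stage("indices",
      .pipeline_indices(pairs, census, fit, B, seed))
    emit_csv(results$indices, "mating_indices.csv")
  }

  if ("cluster" %in% stages) {
    in_stage("cluster", {
      pres <- combination_presence(pairs)
      emit_csv(data.frame(passive = rownames(pres), pres,
                          check.names = FALSE), "combination_presence.csv")
      for (margin in c("columns", "rows")) {
        if ((if (margin == "columns") ncol(pres) else nrow(pres)) < 2) next
        d <- smc_dist(pres, margin)
        tag <- if (margin == "columns") "active" else "passive"
        emit_csv(data.frame(label = labels(d), as.matrix(d),
                            check.names = FALSE),
                 paste0("smc_", tag, ".csv"))
        path <- file.path(out_dir, paste0("upgma_", tag, ".nwk"))
        write_newick(upgma(d), path)
        outputs <- c(outputs, path)
      }
    })
  }

  if ("sizes" %in% stages) {
    in_stage("sizes", {
      results$sizes <- .pipeline_sizes(pairs, census, n_perm, n_iter, seed)
      for (nm in names(results$sizes))
        if (nrow(results$sizes[[nm]]))
          emit_csv(results$sizes[[nm]], paste0("size_", nm, ".csv"))
    })
  }

  manifest <- list(
    seed = seed, B = B, n_perm = n_perm, n_iter = n_iter,
    stages = stages,
    package_version = as.character(utils::packageVersion("premate")),
    files = lapply(stats::setNames(outputs, basename(outputs)), function(f)
      unname(tools::md5sum(f))))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}

.pipeline_indices <- function(pairs, census, fit, B, seed) {
  rows <- list()
  counter <- 0
  boot_or_point <- function(stat, focal, pair_sp, sy, lv, point) {
    counter <<- counter + 1
    if (B > 0) {
      est <- bootstrap_index(pairs, census, stat, focal = focal,
                             species_pair = pair_sp, site_year = sy,
                             level = lv, B = B, seed = seed + counter)
      as.data.frame(est)
    } else {
      data.frame(index = stat,
                 focal = if (stat == "ipc") paste(pair_sp, collapse = "-")
                         else focal,
                 site_year = sy, level = lv, point = point,
                 boot_mean = NA_real_, boot_sd = NA_real_,
                 p_two_tail = NA_real_, n_iter = 0L, n_dropped = 0L,
                 valid = !is.na(point), seed = NA_integer_)
    }
  }
  for (st in fit$strata) {
    sy <- st$site_year; lv <- st$level
    actives <- setdiff(colnames(st$observed), "saxatilis_1p5")
    for (sp in actives) {
      ok <- length(intersect(.consp_labels(sp), rownames(st$observed))) > 0
      if (ok)
        rows[[length(rows) + 1]] <- boot_or_point(
          "fi_male", sp, NULL, sy, lv, fidelity_index(fit, sp, sy, lv))
    }
    fem <- sub("_female$", "",
               grep("_female$", rownames(st$observed), value = TRUE))
    for (sp in intersect(fem, actives))
      rows[[length(rows) + 1]] <- boot_or_point(
        "fi_female", sp, NULL, sy, lv,
        fidelity_index_female(fit, sp, sy, lv))
    if (length(actives) >= 2) {
      cmb <- utils::combn(sort(actives), 2)
      for (j in seq_len(ncol(cmb))) {
        point <- suppressMessages(ipc(fit, cmb[, j], sy, lv))
        if (!is.na(point))
          rows[[length(rows) + 1]] <- boot_or_point(
            "ipc", NULL, cmb[, j], sy, lv, point)
      }
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

.pipeline_sizes <- function(pairs, census, n_perm, n_iter, seed) {
  out <- list(paired = data.frame(), correlation = data.frame(),
              segregation = data.frame())
  has_h <- !is.na(pairs$active_height_mm) & !is.na(pairs$passive_height_mm)
  out$paired <- suppressMessages(paired_size_difference(pairs))
  cons <- pairs[has_h & pairs$mating_class == "conspecific_female", ,
                drop = FALSE]
  counter <- 0
  for (key in unique(cons$stratum)) for (sp in unique(
       cons$active_species[cons$stratum == key])) {
    g <- cons[cons$stratum == key & cons$active_species == sp, , drop = FALSE]
    if (nrow(g) < 3 || stats::sd(g$active_height_mm) == 0 ||
        stats::sd(g$passive_height_mm) == 0) next
    counter <- counter + 1
    ct <- size_correlation_perm(g$active_height_mm, g$passive_height_mm,
                                n_perm = n_perm, seed = seed + counter)
    row <- data.frame(site_year = g$site_year[1], level = g$level[1],
                      species = sp, n = ct$n, r = ct$r,
                      p_perm = ct$p_value, p_random_pairing = NA_real_)
    if (!is.null(census)) {
      mc <- tryCatch(random_pairing_mc(census, ct$r, sp, g$site_year[1],
                                       g$level[1], n_iter = n_iter,
                                       seed = seed + counter),
                     error = function(e) NULL)
      if (!is.null(mc)) row$p_random_pairing <- mc$p_value
    }
    out$correlation <- rbind(out$correlation, row)
  }
  if (!is.null(census)) {
    eligible <- census[census$older_than_one_year &
                       census$species %in% premate_species, , drop = FALSE]
    for (key in unique(eligible$stratum)) for (sp in unique(
         eligible$species[eligible$stratum == key])) {
      g <- eligible[eligible$stratum == key & eligible$species == sp, ,
                    drop = FALSE]
      counter <- counter + 1
      sg <- tryCatch(suppressWarnings(
        segregation_test(census, sp, g$site_year[1], g$level[1],
                         n_perm = n_perm, seed = seed + counter)),
        error = function(e) NULL)
      if (!is.null(sg))
        out$segregation <- rbind(out$segregation, data.frame(
          site_year = sg$site_year, level = sg$level, species = sg$species,
          mean_rank_variance = sg$observed_mean_rank_variance,
          p_value = sg$p_value, n_perm = sg$n_perm,
          n_samples_used = sg$n_samples_used, degenerate = sg$degenerate))
    }
  }
  out
}
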