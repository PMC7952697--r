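# Presence/absence clustering of observed partner-type combinations.

#' Presence/absence matrix of partner-type combinations
#'
#' A combination (passive category x active species) is present if it occurs
#' with non-zero weight anywhere in the records, pooling all strata.
#'
#' @param pairs validated pairs table.
#' @param drop_empty drop passive categories never observed as passive and
#'   active species never observed as active (default `TRUE`, which
#'   reproduces the published layout of the combination table).
#' @return integer 0/1 matrix, passive categories in rows (canonical order),
#'   active species in columns.
#' @export
combination_presence <- function(pairs, drop_empty = TRUE) {
  stopifnot(nrow(pairs) > 0)
  m <- (tabulate_pairs(pairs,
                       passive_levels = .passive_order,
                       active_levels = premate_species) > 0) * 1L
  if (drop_empty)
    m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  m
}

#' Simple mismatch coefficient distances
#'
#' SMC between two binary vectors is the fraction of positions at which they
#' disagree, `(f10 + f01) / (f11 + f10 + f01 + f00)` — the complement of the
#' simple matching similarity, joint absences included in the denominator.
#'
#' @param mat binary matrix (e.g. from [combination_presence()]).
#' @param margin `"columns"` compares active-species columns, `"rows"`
#'   passive-category rows.
#' @return a [stats::dist] object with values in \[0, 1\].
#' @export
smc_dist <- function(mat, margin = c("columns", "rows")) {
  margin <- match.arg(margin)
  x <- if (margin == "columns") t(mat) else mat
  if (nrow(x) < 2) stop("need at least two ", margin, " to compare")
  if (ncol(x) < 1) stop("zero-length comparison vectors are not allowed")
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[j, i] <- d[i, j] <- mean(x[i, ] != x[j, ])
  stats::as.dist(d)
}

#' UPGMA clustering of a distance matrix
#'
#' Average-linkage agglomeration via [stats::hclust], returned as a rooted
#' ultrametric `phylo` tree (heights halved, so two leaves at distance d join
#' at height d/2 and cophenetic distances on the tree reproduce the
#' agglomeration). Labels are sorted lexicographically before clustering so
#' that ties are broken deterministically.
#'
#' @param d a [stats::dist] object or symmetric distance matrix.
#' @return an [ape] `phylo` tree; the underlying `hclust` object is attached
#'   as attribute `"hclust"`.
#' @export
upgma <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) < 2) stop("need at least two labels to cluster")
  ord <- order(rownames(m))
  hc <- stats::hclust(stats::as.dist(m[ord, ord]), method = "average")
  tree <- ape::as.phylo(hc)
  attr(tree, "hclust") <- hc
  tree
}

#' Write a tree to a Newick file
#'
#' @param tree a `phylo` tree (e.g. from [upgma()]).
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
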