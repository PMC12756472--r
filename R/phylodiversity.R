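#' Faith's phylogenetic diversity of an assemblage
#'
#' Sum of branch lengths over the union of edges on the paths from each
#' assemblage tip to the root (root-inclusive convention: the subtree is
#' always anchored at the root, so the PD of a single species is its
#' root-to-tip path length and the PD of all tips is the total branch
#' length). A root edge, if present on the `phylo` object, is never
#' counted.
#'
#' @param tree Dated `phylo` object.
#' @param taxa Non-empty character vector of tip names.
#' @return PD in Ma.
#' @export
faith_pd <- function(tree, taxa) {
  if (length(taxa) == 0L) stop("PD undefined for an empty assemblage")
  idx <- match(taxa, tree$tip.label)
  if (anyNA(idx)) {
    stop("unknown tip name(s): ",
         paste(utils::head(taxa[is.na(idx)], 5L), collapse = ", "))
  }
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  parent <- integer(nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  elen <- numeric(nnode)
  elen[tree$edge[, 2L]] <- tree$edge.length
  root <- ntip + 1L
  visited <- logical(nnode)
  total <- 0
  for (t in idx) {
    n <- t
    while (n != root && !visited[n]) {
      visited[n] <- TRUE
      total <- total + elen[n]
      n <- parent[n]
    }
  }
  total
}

#' SES of Faith's PD for a grid cell
#'
#' Standardizes the observed PD against null assemblages of equal species
#' richness drawn uniformly from the regional species pool:
#' `SES-PD = (PD_obs - mean(PD_null)) / sd(PD_null)`. Values above +1.96
#' indicate significantly higher phylogenetic dispersion (more distantly
#' related species) than expected at that richness; values below -1.96
#' indicate significant clustering.
#'
#' @param tree Dated `phylo` object.
#' @param taxa Tip names present in the cell.
#' @param pool Character vector: the regional species pool (tree tips).
#' @param config A [null_config()].
#' @param stream_seed Optional integer RNG substream for this cell.
#' @return A `"ses_result"`.
#' @export
ses_pd <- function(tree, taxa, pool, config, stream_seed = NULL) {
  observed <- faith_pd(tree, taxa)
  standardized_effect(observed, function(s) faith_pd(tree, s),
                      pool, length(taxa), config, stream_seed = stream_seed)
}

#' Correlation between species richness and PD across cells
#'
#' Pearson correlation with a two-sided test, across grid cells.
#'
#' @param sr Integer vector of species richness per cell.
#' @param pd Numeric vector of PD per cell (same length/order).
#' @return List with `r`, `p_value`, `n`.
#' @export
sr_pd_correlation <- function(sr, pd) {
  stopifnot(length(sr) == length(pd))
  if (length(sr) < 3L) stop("need at least 3 cells")
  if (stats::sd(sr) == 0 || stats::sd(pd) == 0) {
    stop("SR-PD correlation undefined: zero variance")
  }
  ct <- stats::cor.test(sr, pd, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(sr))
}
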