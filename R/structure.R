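#' Pairwise patristic distances between tips
#'
#' `d(i, j)` is the sum of branch lengths on the path between tips *i* and
#' *j*; for an ultrametric tree this equals twice the age of their most
#' recent common ancestor. Symmetric, zero diagonal.
#'
#' @param tree Dated `phylo` object.
#' @return Numeric matrix with tip names as dimnames.
#' @export
patristic_distances <- function(tree) {
  stats::cophenetic(tree)
}

#' Write a patristic distance matrix to CSV
#' @param dist Square matrix from [patristic_distances()].
#' @param path Output path.
#' @export
write_distance_matrix <- function(dist, path) {
  utils::write.csv(dist, path, quote = FALSE)
  invisible(path)
}

#' Mean pairwise phylogenetic distance of an assemblage
#'
#' Mean of `d(i, j)` over all unordered tip pairs within the assemblage.
#'
#' @param taxa Character vector of >= 2 tip names.
#' @param dist Distance matrix from [patristic_distances()].
#' @return MPD in Ma.
#' @export
mpd <- function(taxa, dist) {
  if (length(taxa) < 2L) stop("MPD undefined for fewer than 2 taxa")
  d <- dist[taxa, taxa]
  mean(d[upper.tri(d)])
}

#' Mean nearest-taxon distance of an assemblage
#'
#' Mean, over tips in the assemblage, of the distance to the closest other
#' assemblage member. Equals MPD for two-taxon assemblages.
#'
#' @inheritParams mpd
#' @return MNTD in Ma.
#' @export
mntd <- function(taxa, dist) {
  if (length(taxa) < 2L) stop("MNTD undefined for fewer than 2 taxa")
  d <- dist[taxa, taxa]
  diag(d) <- Inf
  mean(apply(d, 1L, min))
}

#' NRI and NTI of a grid cell under a shared null stream
#'
#' Draws one sequence of null assemblages (equal richness, uniform from the
#' pool) and evaluates both MPD and MNTD on every draw, then
#' `NRI = -1 * (MPD_obs - mean(MPD_null)) / sd(MPD_null)` and likewise NTI
#' with MNTD. NRI reflects deep (tree-wide) relatedness, NTI terminal
#' (nearest-neighbour) structure. Positive values mean phylogenetic
#' clustering, negative overdispersion; |value| > 1.96 (strict) is
#' significant at P < 0.05. Sharing the draw stream makes NRI = NTI hold
#' exactly for two-taxon cells, where MPD = MNTD.
#'
#' In the returned `"ses_result"`s the `ses` field carries the NRI/NTI
#' value itself (the negated SES); `observed`, `null_mean` and `null_sd`
#' describe the underlying MPD/MNTD, and `p_rank` is the rank P of the
#' observed distance in the tail its raw SES points to.
#'
#' @param taxa Character vector of >= 2 tip names present in the cell.
#' @param pool Character vector: the regional species pool.
#' @param dist Distance matrix from [patristic_distances()].
#' @param config A [null_config()].
#' @param stream_seed Optional integer RNG substream for this cell.
#' @return List with elements `nri` and `nti` (each a `"ses_result"` whose
#'   `ses` is the index value).
#' @export
nri_nti <- function(taxa, pool, dist, config, stream_seed = NULL) {
  if (length(taxa) < 2L) stop("NRI/NTI undefined for fewer than 2 taxa")
  pool <- sort(pool)
  k <- length(taxa)
  if (k > length(pool)) stop("richness exceeds pool size")
  obs_mpd <- mpd(taxa, dist)
  obs_mntd <- mntd(taxa, dist)
  seed <- if (is.null(stream_seed)) config$seed else stream_seed
  nulls <- withr::with_seed(seed, {
    vapply(seq_len(config$n_reps), function(i) {
      s <- draw_null_assemblage(pool, k)
      c(mpd = mpd(s, dist), mntd = mntd(s, dist))
    }, numeric(2L))
  })
  list(nri = negate_ses(summarize_null(obs_mpd, nulls["mpd", ], config), config),
       nti = negate_ses(summarize_null(obs_mntd, nulls["mntd", ], config), config))
}

# Flip a ses_result into its -1 x SES index form (NRI/NTI convention).
negate_ses <- function(res, config) {
  ses <- if (is.finite(res$ses)) -res$ses else NA_real_
  new_ses_result(res$observed, res$null_mean, res$null_sd, ses,
                 res$p_rank, res$n_reps, config$significance_z)
}

#' Net relatedness index of a cell
#'
#' Convenience wrapper around [nri_nti()] returning only the NRI result.
#' @inheritParams nri_nti
#' @return A `"ses_result"` whose `ses` field is the NRI.
#' @export
nri <- function(taxa, pool, dist, config, stream_seed = NULL) {
  nri_nti(taxa, pool, dist, config, stream_seed = stream_seed)$nri
}

#' Nearest taxon index of a cell
#'
#' Convenience wrapper around [nri_nti()] returning only the NTI result.
#' @inheritParams nri_nti
#' @return A `"ses_result"` whose `ses` field is the NTI.
#' @export
nti <- function(taxa, pool, dist, config, stream_seed = NULL) {
  nri_nti(taxa, pool, dist, config, stream_seed = stream_seed)$nti
}

#' Classify a cell's phylogenetic structure from NRI and NTI
#'
#' The sign pair of NRI and NTI assigns one of four categories
#' (`both_positive`, `both_negative`, `nri_pos_nti_neg`,
#' `nri_neg_nti_pos`; an exact zero counts as positive), and each index is
#' significant when its absolute value exceeds the threshold (strictly).
#' Significant clustering on both scales is labelled habitat filtering;
#' significant overdispersion on both, competitive exclusion.
#'
#' @param nri_result,nti_result `"ses_result"`s from [nri_nti()].
#' @param significance_z Threshold on |index| (default 1.96).
#' @return List of class `"structure_classification"`: `nri`, `nti`,
#'   `category`, `nri_significant`, `nti_significant`, `label`.
#' @export
classify_structure <- function(nri_result, nti_result, significance_z = 1.96) {
  v_nri <- nri_result$ses
  v_nti <- nti_result$ses
  if (!is.finite(v_nri) || !is.finite(v_nti)) {
    return(structure(list(
      nri = v_nri, nti = v_nti, category = "undefined",
      nri_significant = FALSE, nti_significant = FALSE,
      label = "undefined"), class = "structure_classification"))
  }
  category <- if (v_nri >= 0 && v_nti >= 0) "both_positive"
    else if (v_nri < 0 && v_nti < 0) "both_negative"
    else if (v_nri >= 0) "nri_pos_nti_neg"
    else "nri_neg_nti_pos"
  sig_nri <- abs(v_nri) > significance_z
  sig_nti <- abs(v_nti) > significance_z
  label <- if (category == "both_positive" && sig_nri && sig_nti) {
    "habitat_filtering"
  } else if (category == "both_negative" && sig_nri && sig_nti) {
    "competitive_exclusion"
  } else {
    category
  }
  structure(list(nri = v_nri, nti = v_nti, category = category,
                 nri_significant = sig_nri, nti_significant = sig_nti,
                 label = label),
            class = "structure_classification")
}
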