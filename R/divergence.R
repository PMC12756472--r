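#' Genus divergence times from a dated tree
#'
#' For a genus with two or more tips, the age is the crown age: the node
#' age of the most recent common ancestor of its tips (also defined, as the
#' MRCA age, when the genus is not monophyletic on the tree). A crown age
#' is undefined for a monotypic genus, so its age falls back to the stem:
#' the age of the tip's parent node, and the genus is flagged.
#'
#' @param tree Dated `phylo` object; every tip should map to a genus.
#' @param genus_map Named character vector (genus named by species); tips
#'   absent from the map cause an error, genera with no tips on the tree
#'   are dropped with a warning.
#' @return Data frame with columns `genus`, `age` (Ma), `monotypic`,
#'   `n_tips`, one row per genus, ordered by genus name.
#' @export
genus_crown_ages <- function(tree, genus_map) {
  tips <- tree$tip.label
  unmapped <- setdiff(tips, names(genus_map))
  if (length(unmapped)) {
    stop("tree tip(s) without genus assignment: ",
         paste(utils::head(unmapped, 5L), collapse = ", "))
  }
  empty <- setdiff(unique(genus_map), unique(genus_map[tips]))
  if (length(empty)) {
    warning("genus(era) with no tips on the tree omitted: ",
            paste(empty, collapse = ", "))
  }
  ages <- node_ages(tree)
  ntip <- length(tips)
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  by_genus <- split(seq_len(ntip), genus_map[tips])
  res <- lapply(names(by_genus), function(g) {
    idx <- by_genus[[g]]
    if (length(idx) == 1L) {
      data.frame(genus = g, age = ages[parent[idx]], monotypic = TRUE,
                 n_tips = 1L)
    } else {
      mrca <- ape::getMRCA(tree, idx)
      data.frame(genus = g, age = ages[mrca], monotypic = FALSE,
                 n_tips = length(idx))
    }
  })
  out <- do.call(rbind, res)
  out[order(out$genus), , drop = FALSE]
}

#' Genus age lookup vector
#' @param age_table Data frame from [genus_crown_ages()].
#' @return Named numeric vector of ages (Ma), named by genus.
#' @export
genus_age_vector <- function(age_table) {
  stats::setNames(age_table$age, age_table$genus)
}

#' Per-cell genus species counts
#'
#' Aggregates the species present in one grid cell to genera: `S_i`, the
#' number of species of genus *i* in the cell.
#'
#' @param species Character vector of species present in the cell.
#' @param genus_map Named character vector (genus named by species).
#' @return Named integer vector of counts, named by genus, sorted by genus
#'   name.
#' @export
cell_genus_counts <- function(species, genus_map) {
  unmapped <- setdiff(species, names(genus_map))
  if (length(unmapped)) {
    stop("species without genus assignment: ",
         paste(utils::head(unmapped, 5L), collapse = ", "))
  }
  tab <- table(genus_map[species])
  stats::setNames(as.integer(tab), names(tab))
}

#' Mean divergence time of a grid cell
#'
#' The species-count-weighted mean of genus ages,
#' `MDT = sum(AGE_i * S_i) / sum(S_i)`, where `AGE_i` is the divergence
#' time of genus *i* and `S_i` the number of its species present in the
#' cell. Equals the unweighted mean of ages when all `S_i` are equal, and
#' is invariant to rescaling all `S_i` by a constant.
#'
#' @param counts Named integer vector from [cell_genus_counts()].
#' @param ages Named numeric vector of genus ages (Ma).
#' @return MDT in Ma.
#' @export
mdt <- function(counts, ages) {
  if (length(counts) == 0L) stop("MDT undefined for an empty cell")
  g <- names(counts)
  missing <- setdiff(g, names(ages))
  if (length(missing)) {
    stop("genus without age: ", paste(missing, collapse = ", "))
  }
  sum(ages[g] * counts) / sum(counts)
}

#' Mean ages of the youngest and oldest genus quartiles of a cell
#'
#' Genera are ranked by age (ties broken by genus name for determinism);
#' the youngest and oldest `ceiling(n/4)` genera are averaged, unweighted
#' by species counts. With fewer than 4 genera a quartile is not
#' meaningful: both means equal the mean of all the cell's genus ages and
#' the result is flagged.
#'
#' @inheritParams mdt
#' @return List with `young_mean`, `old_mean` (Ma), `flagged` (fewer than
#'   4 genera).
#' @export
quartile_mean_ages <- function(counts, ages) {
  if (length(counts) == 0L) stop("quartile ages undefined for an empty cell")
  g <- names(counts)
  a <- ages[g]
  n <- length(g)
  if (n < 4L) {
    m <- mean(a)
    return(list(young_mean = m, old_mean = m, flagged = TRUE))
  }
  ord <- order(a, g)
  q <- ceiling(n / 4)
  list(young_mean = mean(a[ord[seq_len(q)]]),
       old_mean = mean(a[ord[seq(n - q + 1L, n)]]),
       flagged = FALSE)
}

# Quartile means of a plain age vector (used inside the null loop, where
# the drawn genera carry no species counts).
quartile_means_of_ages <- function(a) {
  n <- length(a)
  if (n < 4L) {
    m <- mean(a)
    return(c(young = m, old = m))
  }
  a <- sort(a)
  q <- ceiling(n / 4)
  c(young = mean(a[seq_len(q)]), old = mean(a[seq(n - q + 1L, n)]))
}

#' SES of the mean divergence time (and quartile ages) of a cell
#'
#' Null replicate: draw as many genera as the cell holds, uniformly without
#' replacement from the regional genus pool, and reassign the cell's
#' observed multiset of species counts `S_i` to the drawn genera in draw
#' order (the counts are taken in genus-name order of the observed cell).
#' The SES of MDT follows `(MDT_obs - mean(MDT_null)) / sd(MDT_null)`;
#' `SES-MDT > 1.96` flags a significantly ancient-biased cell and
#' `SES-MDT < -1.96` a significantly young-biased one. The same null draws
#' also standardize the unweighted mean ages of the youngest and oldest
#' genus quartiles, reported as auxiliary SES values.
#'
#' @param counts Named integer vector from [cell_genus_counts()].
#' @param pool_ages Named numeric vector of ages for the full genus pool.
#' @param config A [null_config()].
#' @param stream_seed Optional integer RNG substream for this cell.
#' @return List with `mdt`, `young`, `old` (each a `"ses_result"`),
#'   `quartiles_flagged`, and `classification` in
#'   `{"ancient-biased", "young-biased", "nonsignificant", "undefined"}`.
#' @export
ses_mdt <- function(counts, pool_ages, config, stream_seed = NULL) {
  if (length(counts) == 0L) stop("SES-MDT undefined for an empty cell")
  pool <- sort(names(pool_ages))
  n_gen <- length(counts)
  if (n_gen > length(pool)) stop("cell has more genera than the pool")
  s_weights <- as.numeric(counts[order(names(counts))])
  obs_mdt <- mdt(counts, pool_ages)
  obs_q <- quartile_mean_ages(counts, pool_ages)
  seed <- if (is.null(stream_seed)) config$seed else stream_seed
  nulls <- withr::with_seed(seed, {
    vapply(seq_len(config$n_reps), function(i) {
      drawn <- draw_null_assemblage(pool, n_gen)
      a <- pool_ages[drawn]
      q <- quartile_means_of_ages(a)
      c(mdt = sum(a * s_weights) / sum(s_weights), q)
    }, numeric(3L))
  })
  res_mdt <- summarize_null(obs_mdt, nulls["mdt", ], config)
  res_young <- summarize_null(obs_q$young_mean, nulls["young", ], config)
  res_old <- summarize_null(obs_q$old_mean, nulls["old", ], config)
  classification <- if (!is.finite(res_mdt$ses)) {
    "undefined"
  } else if (res_mdt$ses > config$significance_z) {
    "ancient-biased"
  } else if (res_mdt$ses < -config$significance_z) {
    "young-biased"
  } else {
    "nonsignificant"
  }
  list(mdt = res_mdt, young = res_young, old = res_old,
       quartiles_flagged = obs_q$flagged, classification = classification)
}
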