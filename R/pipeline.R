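#' Tabulate genus ages into geological age bins
#'
#' Bins are half-open and lower-inclusive: `[0, e1), [e1, e2), ...,
#' [e_k, Inf)`, so an age exactly on an edge falls in the older bin. The
#' defaults are the Neogene/Paleogene/Cretaceous boundaries 23.03, 66.00
#' and 145.00 Ma.
#'
#' @param ages Numeric vector of genus ages (Ma).
#' @param edges Strictly increasing bin edges (Ma).
#' @return Data frame with `bin` (label), `count`, `percentage`.
#' @export
age_bin_summary <- function(ages, edges = c(23.03, 66, 145)) {
  if (length(ages) == 0L) stop("empty age table")
  if (is.unsorted(edges, strictly = TRUE)) {
    stop("bin edges must be strictly increasing")
  }
  breaks <- c(0, edges, Inf)
  labels <- c(
    sprintf("[0, %g)", edges[1L]),
    if (length(edges) > 1L) {
      sprintf("[%g, %g)", edges[-length(edges)], edges[-1L])
    },
    sprintf("[%g, Inf)", edges[length(edges)])
  )
  idx <- findInterval(ages, breaks, left.open = FALSE)
  counts <- tabulate(idx, nbins = length(labels))
  data.frame(bin = labels, count = counts,
             percentage = 100 * counts / length(ages))
}

#' Run the full per-cell community-phylogenetics analysis
#'
#' For every grid cell with at least one tree-matched species this
#' computes: species richness (SR), Faith's PD and SES-PD, the mean
#' divergence time (MDT) with SES-MDT and the quartile-age SES values,
#' MPD, MNTD, NRI and NTI, and the NRI/NTI sign-pair classification. All
#' null models share one richness-preserving pool-draw scheme with
#' `n_reps` replicates; each (cell, metric) pair gets its own RNG
#' substream derived from `seed`, so results are deterministic and
#' independent of cell processing order (removing a cell changes only that
#' cell's report).
#'
#' Species absent from the tree are dropped with a warning; cells left
#' empty are skipped. Cells with SR = 1 get `NA` for MPD/MNTD/NRI/NTI;
#' a zero-variance null (e.g. a cell holding the whole pool) flags the
#' corresponding SES undefined.
#'
#' @param tree Dated `phylo` (e.g. [read_newick()]).
#' @param comm Binary cell x species matrix ([read_community_matrix()]).
#' @param genus_map Named character vector ([read_genus_map()]).
#' @param n_reps Null replicates (default 999).
#' @param seed Master seed for all null streams.
#' @param significance_z Two-sided |SES| threshold (default 1.96).
#' @param age_bins Edges for the genus-age summary (Ma).
#' @return List of class `"commphylo_run"` with
#'   \describe{
#'     \item{cell_reports}{data frame, one row per analysed cell, columns
#'       as in [write_cell_reports()].}
#'     \item{summary}{list: genus-age statistics (`mean`, `sd`, `median`),
#'       `age_bins` table, `sr_pd` correlation, per-metric sign /
#'       significance tallies and the NRI/NTI category counts.}
#'     \item{validation}{the [validate_inputs()] report.}
#'     \item{genus_ages}{the [genus_crown_ages()] table.}
#'   }
#' @export
run_analysis <- function(tree, comm, genus_map, n_reps = 999L, seed = 1L,
                         significance_z = 1.96,
                         age_bins = c(23.03, 66, 145)) {
  config <- null_config(n_reps = n_reps, seed = seed,
                        significance_z = significance_z)
  report <- validate_inputs(comm, tree, genus_map)
  if (length(report$species_missing_from_tree)) {
    warning(length(report$species_missing_from_tree),
            " species in the matrix are absent from the tree and were dropped")
  }
  matched <- intersect(colnames(comm), tree$tip.label)
  if (length(matched) == 0L) stop("no species shared between matrix and tree")
  comm <- comm[, matched, drop = FALSE]
  keep <- rowSums(comm) > 0
  if (!any(keep)) stop("no cell holds any tree-matched species")
  if (any(!keep)) {
    warning(sum(!keep), " cell(s) without tree-matched species were skipped")
  }
  comm <- comm[keep, , drop = FALSE]

  missing_genus <- setdiff(matched, names(genus_map))
  if (length(missing_genus)) {
    stop("tree-matched species without genus assignment: ",
         paste(utils::head(missing_genus, 5L), collapse = ", "))
  }
  # genus ages from the tree restricted to the analysed flora (tips outside
  # the matrix need no genus assignment); pool = genera occurring in the matrix
  age_tree <- if (length(matched) < length(tree$tip.label) &&
                  length(matched) >= 2L) {
    ape::keep.tip(tree, matched)
  } else {
    tree
  }
  age_table <- genus_crown_ages(age_tree, genus_map)
  ages <- genus_age_vector(age_table)
  pool_genera <- sort(unique(genus_map[matched]))
  pool_ages <- ages[pool_genera]
  dmat <- patristic_distances(tree)
  species_pool <- matched

  rows <- lapply(rownames(comm), function(cell) {
    taxa <- matched[comm[cell, ] == 1L]
    sr <- length(taxa)
    pd_obs <- faith_pd(tree, taxa)
    res_pd <- ses_pd(tree, taxa, species_pool, config,
                     stream_seed = derive_seed(config$seed, paste0(cell, "\rpd")))
    counts <- cell_genus_counts(taxa, genus_map)
    res_mdt <- ses_mdt(counts, pool_ages, config,
                       stream_seed = derive_seed(config$seed, paste0(cell, "\rmdt")))
    if (sr >= 2L) {
      res_str <- nri_nti(taxa, species_pool, dmat, config,
                         stream_seed = derive_seed(config$seed, paste0(cell, "\rstructure")))
      cls <- classify_structure(res_str$nri, res_str$nti, config$significance_z)
      mpd_v <- res_str$nri$observed
      mntd_v <- res_str$nti$observed
      nri_v <- res_str$nri$ses
      nti_v <- res_str$nti$ses
      label <- cls$label
    } else {
      mpd_v <- mntd_v <- nri_v <- nti_v <- NA_real_
      label <- "undefined"
    }
    data.frame(
      cell = cell, SR = sr, PD = pd_obs, SES_PD = res_pd$ses,
      MDT = res_mdt$mdt$observed, SES_MDT = res_mdt$mdt$ses,
      SES_young_quartile = res_mdt$young$ses,
      SES_old_quartile = res_mdt$old$ses,
      MPD = mpd_v, MNTD = mntd_v, NRI = nri_v, NTI = nti_v,
      classification = label,
      stringsAsFactors = FALSE)
  })
  reports <- do.call(rbind, rows)

  z <- config$significance_z
  tally <- function(v) {
    ok <- is.finite(v)
    list(n = sum(ok),
         positive = sum(v[ok] >= 0),
         negative = sum(v[ok] < 0),
         significant_high = sum(v[ok] > z),
         significant_low = sum(v[ok] < -z),
         undefined = sum(!ok))
  }
  categories <- table(factor(
    reports$classification,
    levels = c("both_positive", "both_negative", "nri_pos_nti_neg",
               "nri_neg_nti_pos", "habitat_filtering",
               "competitive_exclusion", "undefined")))
  sr_pd <- if (nrow(reports) >= 3L && stats::sd(reports$SR) > 0 &&
               stats::sd(reports$PD) > 0) {
    sr_pd_correlation(reports$SR, reports$PD)
  } else NULL
  summary <- list(
    n_cells = nrow(reports),
    genus_ages = list(mean = mean(pool_ages), sd = stats::sd(pool_ages),
                      median = stats::median(pool_ages),
                      n_genera = length(pool_ages)),
    age_bins = age_bin_summary(pool_ages, age_bins),
    sr_pd = sr_pd,
    ses_pd = tally(reports$SES_PD),
    ses_mdt = tally(reports$SES_MDT),
    nri = tally(reports$NRI),
    nti = tally(reports$NTI),
    categories = as.list(categories),
    config = unclass(config)
  )
  structure(list(cell_reports = reports, summary = summary,
                 validation = report, genus_ages = age_table),
            class = "commphylo_run")
}

#' @export
print.commphylo_run <- function(x, ...) {
  s <- x$summary
  cat("Community-phylogenetics run:", s$n_cells, "cells,",
      s$genus_ages$n_genera, "genera,", s$config$n_reps, "null reps\n")
  cat(sprintf("  genus ages: mean %.2f +/- %.2f Ma, median %.2f Ma\n",
              s$genus_ages$mean, s$genus_ages$sd, s$genus_ages$median))
  if (!is.null(s$sr_pd)) {
    cat(sprintf("  SR-PD Pearson r = %.3f (P = %.3g)\n",
                s$sr_pd$r, s$sr_pd$p_value))
  }
  cat("  NRI/NTI sign-pair categories:\n")
  for (nm in names(s$categories)) {
    if (s$categories[[nm]] > 0) cat(sprintf("    %-22s %d\n", nm, s$categories[[nm]]))
  }
  invisible(x)
}

#' Write the run summary as JSON
#' @param run A `"commphylo_run"` from [run_analysis()].
#' @param path Output path.
#' @export
write_run_summary <- function(run, path) {
  jsonlite::write_json(run$summary, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
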