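#' Read a grid-cell x species presence-absence matrix
#'
#' The expected CSV dialect is fixed so round trips are bit-exact: UTF-8,
#' comma-delimited, first column the grid-cell id, header row the species
#' names, body entries 0, 1 or empty (empty means absent). Species or cell
#' names containing commas are not supported and are rejected.
#'
#' @param path Path to the CSV file.
#' @return An integer matrix with cell ids as rownames and species names as
#'   colnames; entries in `{0L, 1L}`.
#' @export
read_community_matrix <- function(path) {
  if (!file.exists(path)) stop("community matrix file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("community matrix needs a header and >= 1 cell row")
  if (any(grepl('"', lines, fixed = TRUE))) {
    stop("quoted fields are not supported in the community matrix CSV")
  }
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  species <- header[-1L]
  if (length(species) == 0L) stop("no species columns in header")
  if (any(!nzchar(species))) stop("empty species name in header")
  if (anyDuplicated(species)) {
    stop("duplicate species name(s) in header: ",
         paste(unique(species[duplicated(species)]), collapse = ", "))
  }
  body <- strsplit(lines[-1L], ",", fixed = TRUE)
  cells <- vapply(body, `[`, character(1L), 1L)
  if (any(!nzchar(cells))) stop("empty cell id")
  if (anyDuplicated(cells)) {
    stop("duplicate cell id(s): ",
         paste(unique(cells[duplicated(cells)]), collapse = ", "))
  }
  occ <- matrix(0L, nrow = length(cells), ncol = length(species),
                dimnames = list(cells, species))
  for (i in seq_along(body)) {
    vals <- body[[i]][-1L]
    # trailing empty fields are dropped by strsplit; pad them back
    if (length(vals) < length(species)) {
      vals <- c(vals, rep("", length(species) - length(vals)))
    }
    if (length(vals) != length(species)) {
      stop("row ", i + 1L, " ('", cells[i], "') has ", length(vals),
           " entries, expected ", length(species))
    }
    bad <- which(!(vals %in% c("", "0", "1")))
    if (length(bad)) {
      stop("non-binary entry '", vals[bad[1L]], "' at row ", i + 1L,
           " (cell '", cells[i], "'), column ", bad[1L] + 1L,
           " (species '", species[bad[1L]], "')")
    }
    occ[i, ] <- as.integer(vals == "1")
  }
  occ
}

#' Write a presence-absence matrix in the package CSV dialect
#'
#' Inverse of [read_community_matrix()]; `read(write(m))` is identity on
#' occupancy.
#'
#' @param comm Binary matrix with cell rownames and species colnames.
#' @param path Output path.
#' @export
write_community_matrix <- function(comm, path) {
  stopifnot(is.matrix(comm), !is.null(rownames(comm)), !is.null(colnames(comm)))
  lines <- c(
    paste(c("cell", colnames(comm)), collapse = ","),
    vapply(seq_len(nrow(comm)), function(i) {
      paste(c(rownames(comm)[i], as.integer(comm[i, ])), collapse = ",")
    }, character(1L))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a species-to-genus map
#'
#' Two-column CSV (`species,genus`), one row per species, with a header.
#'
#' @param path Path to the CSV file.
#' @return Named character vector: genus names, named by species.
#' @export
read_genus_map <- function(path) {
  if (!file.exists(path)) stop("genus map file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  if (ncol(df) < 2L) stop("genus map needs columns species,genus")
  sp <- df[[1L]]
  gen <- df[[2L]]
  if (anyDuplicated(sp)) {
    stop("duplicate species in genus map: ",
         paste(unique(sp[duplicated(sp)]), collapse = ", "))
  }
  if (any(!nzchar(gen))) stop("empty genus name in genus map")
  stats::setNames(gen, sp)
}

#' Write a species-to-genus map
#' @param genus_map Named character vector (genus named by species).
#' @param path Output path.
#' @export
write_genus_map <- function(genus_map, path) {
  utils::write.csv(
    data.frame(species = names(genus_map), genus = unname(genus_map)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cross-validate a community matrix, dated tree and genus map
#'
#' Side-effect-free reporting: which matrix species are missing from the
#' tree (and would be dropped from analysis), which tree tips never occur
#' in the matrix, which cells would be left empty after dropping unmatched
#' species, which species lack a genus assignment, and how far the tree is
#' from ultrametric.
#'
#' @param comm Binary matrix from [read_community_matrix()].
#' @param tree `phylo` object from [read_newick()].
#' @param genus_map Named character vector from [read_genus_map()], or
#'   `NULL` to skip genus checks.
#' @return A list of class `"validation_report"` with elements
#'   `species_missing_from_tree`, `tips_not_in_matrix`, `cells_emptied`,
#'   `species_missing_genus`, `ultrametric_deviation`.
#' @export
validate_inputs <- function(comm, tree, genus_map = NULL) {
  sp <- colnames(comm)
  tips <- tree$tip.label
  missing_tree <- setdiff(sp, tips)
  matched <- intersect(sp, tips)
  emptied <- if (length(matched)) {
    rn <- rownames(comm)
    rn[rowSums(comm[, matched, drop = FALSE]) == 0 & rowSums(comm) > 0]
  } else {
    rownames(comm)[rowSums(comm) > 0]
  }
  missing_genus <- if (is.null(genus_map)) character(0) else {
    setdiff(matched, names(genus_map))
  }
  structure(list(
    species_missing_from_tree = missing_tree,
    tips_not_in_matrix = setdiff(tips, sp),
    cells_emptied = emptied,
    species_missing_genus = missing_genus,
    ultrametric_deviation = ultrametric_deviation(tree)
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Input validation report\n")
  cat("  species in matrix missing from tree:", length(x$species_missing_from_tree), "\n")
  cat("  tree tips absent from matrix:       ", length(x$tips_not_in_matrix), "\n")
  cat("  cells emptied by pruning:           ", length(x$cells_emptied), "\n")
  cat("  species without genus assignment:   ", length(x$species_missing_genus), "\n")
  cat(sprintf("  ultrametricity deviation (relative): %.3g\n", x$ultrametric_deviation))
  invisible(x)
}

#' Write per-cell result reports to CSV
#'
#' One row per grid cell with the fixed column order
#' `cell, SR, PD, SES_PD, MDT, SES_MDT, SES_young_quartile,
#' SES_old_quartile, MPD, MNTD, NRI, NTI, classification`.
#' Floats are written at 6 significant digits, so a written file re-read
#' with [utils::read.csv()] reproduces values to that precision.
#'
#' @param reports Data frame of cell reports (from [run_analysis()]).
#' @param path Output path.
#' @export
write_cell_reports <- function(reports, path) {
  if (is.null(reports) || nrow(reports) == 0L) {
    stop("no cell reports to write")
  }
  cols <- c("cell", "SR", "PD", "SES_PD", "MDT", "SES_MDT",
            "SES_young_quartile", "SES_old_quartile",
            "MPD", "MNTD", "NRI", "NTI", "classification")
  missing <- setdiff(cols, names(reports))
  if (length(missing)) stop("reports lack column(s): ", paste(missing, collapse = ", "))
  out <- reports[, cols]
  for (nm in cols) {
    if (is.numeric(out[[nm]]) && nm != "SR") {
      out[[nm]] <- signif(out[[nm]], 6L)
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
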