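#' Simulate a dated pure-birth (Yule) tree with genus structure
#'
#' A pure-birth topology with exponential waiting times is simulated
#' (via [ape::rphylo()] with zero extinction) and rescaled so every tip
#' sits at age 0 and the root at `depth` Ma. Tips are then relabelled
#' `g<i>_s<j>` along the ladderized (cladewise) tip order, partitioned
#' into contiguous blocks of 1-5 tips per genus. Blocks of adjacent tips
#' are usually clades but occasionally straddle one, which mirrors the
#' mildly non-monophyletic genera of real mega-tree floras and exercises
#' both the crown-age and the monotypic stem-age path of
#' [genus_crown_ages()].
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Integer seed; identical seeds give identical trees.
#' @param depth Root age in Ma.
#' @return A dated `phylo` object with `g<i>_s<j>` tip labels.
#' @export
simulate_yule_tree <- function(n_tips, seed, depth = 100) {
  n_tips <- as.integer(n_tips)
  if (is.na(n_tips) || n_tips < 2L) stop("n_tips must be an integer >= 2")
  if (!is.finite(depth) || depth <= 0) stop("depth must be positive")
  withr::with_seed(as.integer(seed), {
    tree <- ape::rphylo(n_tips, birth = 1, death = 0)
    tree$edge.length <- tree$edge.length * (depth / tree_depth(tree))
    tree <- ape::ladderize(tree)
    # cladewise tip order (order tips appear in the edge matrix)
    tip_order <- tree$edge[tree$edge[, 2L] <= n_tips, 2L]
    sizes <- integer(0)
    while (sum(sizes) < n_tips) {
      sizes <- c(sizes, sample.int(5L, 1L))
    }
    sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n_tips)
    sizes <- sizes[sizes > 0L]
    genus_of_pos <- rep(seq_along(sizes), times = sizes)
    labels <- character(n_tips)
    for (g in seq_along(sizes)) {
      pos <- which(genus_of_pos == g)
      labels[tip_order[pos]] <- sprintf("g%03d_s%d", g, seq_along(pos))
    }
    tree$tip.label <- labels
    tree
  })
}

#' Genus map implied by `g<i>_s<j>` tip labels
#' @param tree Tree from [simulate_yule_tree()].
#' @return Named character vector (genus named by species).
#' @export
genus_map_from_labels <- function(tree) {
  tips <- tree$tip.label
  stats::setNames(sub("_s[0-9]+$", "", tips), tips)
}

#' Landscape scenario configuration
#'
#' @param scenario One of `"random"`, `"filtering"`, `"overdispersion"`,
#'   `"age_gradient"`.
#' @param n_cells Number of grid cells.
#' @param richness_min,richness_max Per-cell richness is drawn uniformly
#'   from this range (inclusive).
#' @param strength Scenario strength in `[0, 1]`; 0 reduces every scenario
#'   to the random one.
#' @param seed Integer seed.
#' @return A list of class `"scenario_config"`.
#' @export
scenario_config <- function(scenario = c("random", "filtering",
                                         "overdispersion", "age_gradient"),
                            n_cells = 40L, richness_min = 5L,
                            richness_max = 25L, strength = 1,
                            seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(n_cells >= 1L, richness_min >= 1L,
            richness_min <= richness_max,
            strength >= 0, strength <= 1)
  structure(list(scenario = scenario, n_cells = as.integer(n_cells),
                 richness_min = as.integer(richness_min),
                 richness_max = as.integer(richness_max),
                 strength = strength, seed = as.integer(seed)),
            class = "scenario_config")
}

#' Simulate a grid-cell landscape with a known assembly regime
#'
#' Per cell, a richness is drawn uniformly from the configured range and
#' taxa are sampled from the tree's tips according to the scenario:
#' \describe{
#'   \item{random}{uniform without replacement.}
#'   \item{filtering}{a seed tip is drawn uniformly, then the remaining
#'     taxa with weight `exp(-d(i, seed) * strength * kappa)` where
#'     `kappa = 5 / tree depth` — a clade-restricted (phylogenetically
#'     clustered) assemblage, as under environmental filtering.}
#'   \item{overdispersion}{greedy max-min-distance selection: at each step,
#'     with probability `strength`, the candidate maximizing the minimum
#'     distance to the already-selected set is taken (ties to the first in
#'     tip-name order), otherwise a uniform draw — spacing out the
#'     assemblage, as under competitive exclusion.}
#'   \item{age_gradient}{species are weighted through their genus age,
#'     `exp(gamma * AGE * kappa)`, with `gamma` sweeping linearly from
#'     `-strength` (young-biased) to `+strength` (ancient-biased) across
#'     the cell index; the same `kappa = 5 / tree depth` normalization
#'     keeps the exponent dimensionless.}
#' }
#'
#' @param tree Tree from [simulate_yule_tree()] (tips labelled
#'   `g<i>_s<j>`).
#' @param config A [scenario_config()].
#' @return List with `comm` (binary cell x species matrix, cells named
#'   `cell_001`, ...), `genus_map`, and `config`.
#' @export
simulate_landscape <- function(tree, config) {
  stopifnot(inherits(config, "scenario_config"))
  tips <- tree$tip.label
  n <- length(tips)
  if (config$richness_max > n) stop("richness_max exceeds number of tips")
  genus_map <- genus_map_from_labels(tree)
  kappa <- 5 / tree_depth(tree)
  needs_dist <- config$scenario %in% c("filtering", "overdispersion")
  dmat <- if (needs_dist) patristic_distances(tree)[tips, tips] else NULL
  age_of_species <- if (config$scenario == "age_gradient") {
    ages <- genus_age_vector(genus_crown_ages(tree, genus_map))
    unname(ages[genus_map[tips]])
  } else NULL
  cells <- sprintf("cell_%03d", seq_len(config$n_cells))
  comm <- matrix(0L, nrow = config$n_cells, ncol = n,
                 dimnames = list(cells, tips))
  withr::with_seed(config$seed, {
    for (ci in seq_len(config$n_cells)) {
      rng <- config$richness_min:config$richness_max
      k <- rng[sample.int(length(rng), 1L)]
      picked <- switch(config$scenario,
        random = sample.int(n, k),
        filtering = sample_filtered(dmat, k, config$strength, kappa),
        overdispersion = sample_overdispersed(dmat, k, config$strength),
        age_gradient = {
          gamma <- if (config$n_cells == 1L) 0 else {
            -config$strength + 2 * config$strength * (ci - 1) / (config$n_cells - 1)
          }
          w <- exp(gamma * age_of_species * kappa)
          sample.int(n, k, prob = w)
        })
      comm[ci, picked] <- 1L
    }
  })
  list(comm = comm, genus_map = genus_map, config = config)
}

sample_filtered <- function(dmat, k, strength, kappa) {
  n <- nrow(dmat)
  seed_tip <- sample.int(n, 1L)
  if (k == 1L) return(seed_tip)
  rest <- setdiff(seq_len(n), seed_tip)
  w <- exp(-dmat[rest, seed_tip] * strength * kappa)
  c(seed_tip, rest[sample.int(length(rest), k - 1L, prob = w)])
}

sample_overdispersed <- function(dmat, k, strength) {
  n <- nrow(dmat)
  picked <- sample.int(n, 1L)
  while (length(picked) < k) {
    rest <- setdiff(seq_len(n), picked)
    nxt <- if (stats::runif(1L) < strength) {
      mind <- apply(dmat[rest, picked, drop = FALSE], 1L, min)
      rest[which.max(mind)]
    } else {
      rest[sample.int(length(rest), 1L)]
    }
    picked <- c(picked, nxt)
  }
  picked
}

#' Write a simulated dataset to disk
#'
#' Materializes `tree.nwk`, `matrix.csv`, `genus_map.csv` and a
#' `provenance.json` (scenario config + seed) in `dir`.
#'
#' @param tree Tree from [simulate_yule_tree()].
#' @param landscape Result of [simulate_landscape()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(tree, landscape, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ape::write.tree(tree, file.path(dir, "tree.nwk"))
  write_community_matrix(landscape$comm, file.path(dir, "matrix.csv"))
  write_genus_map(landscape$genus_map, file.path(dir, "genus_map.csv"))
  jsonlite::write_json(unclass(landscape$config),
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
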