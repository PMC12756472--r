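# Brute-force oracles, independent of the package's implementations:
# PD by explicit edge-set union, patristic distance by explicit path sum,
# MPD/MNTD by pair loops, exact SES by complete subset enumeration.

fixture_newick <- "((A:1.0,B:1.0):2.0,(C:2.0,D:2.0):1.0);"

fixture_tree <- function() {
  path <- tempfile(fileext = ".nwk")
  writeLines(fixture_newick, path)
  read_newick(path)
}

# edge length of the edge joining adjacent nodes a, b
edge_length_between <- function(tree, a, b) {
  hit <- (tree$edge[, 1] == a & tree$edge[, 2] == b) |
         (tree$edge[, 1] == b & tree$edge[, 2] == a)
  tree$edge.length[which(hit)]
}

oracle_pd <- function(tree, taxa) {
  root <- length(tree$tip.label) + 1L
  edges <- character(0)
  total <- 0
  for (tip in match(taxa, tree$tip.label)) {
    path <- ape::nodepath(tree, from = tip, to = root)
    for (i in seq_len(length(path) - 1L)) {
      key <- paste(sort(c(path[i], path[i + 1L])), collapse = "-")
      if (!(key %in% edges)) {
        edges <- c(edges, key)
        total <- total + edge_length_between(tree, path[i], path[i + 1L])
      }
    }
  }
  total
}

oracle_patristic <- function(tree, a, b) {
  ia <- match(a, tree$tip.label)
  ib <- match(b, tree$tip.label)
  if (ia == ib) return(0)
  path <- ape::nodepath(tree, from = ia, to = ib)
  total <- 0
  for (i in seq_len(length(path) - 1L)) {
    total <- total + edge_length_between(tree, path[i], path[i + 1L])
  }
  total
}

oracle_mpd <- function(tree, taxa) {
  pairs <- utils::combn(taxa, 2L)
  mean(apply(pairs, 2L, function(p) oracle_patristic(tree, p[1], p[2])))
}

oracle_mntd <- function(tree, taxa) {
  mean(vapply(taxa, function(a) {
    min(vapply(setdiff(taxa, a),
               function(b) oracle_patristic(tree, a, b), numeric(1)))
  }, numeric(1)))
}

# Exact null distribution of a statistic over ALL richness-k subsets of the
# pool (equally likely under the pool-draw null); population s.d., which is
# what the Monte-Carlo sample s.d. estimates.
oracle_exact_null <- function(statistic, pool, k) {
  vals <- apply(utils::combn(pool, k), 2L, statistic)
  list(mean = mean(vals),
       sd = sqrt(mean((vals - mean(vals))^2)),
       values = vals)
}

oracle_exact_ses <- function(observed, statistic, pool, k) {
  nd <- oracle_exact_null(statistic, pool, k)
  (observed - nd$mean) / nd$sd
}
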