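test_that("Yule simulator produces dated ultrametric trees with genus labels", {
  tr2 <- simulate_yule_tree(2, seed = 1, depth = 80)
  expect_equal(length(tr2$tip.label), 2L)
  expect_equal(tree_depth(tr2), 80)

  tr <- simulate_yule_tree(100, seed = 6, depth = 100)
  expect_equal(length(tr$tip.label), 100L)
  expect_equal(tr$Nnode, 99L)
  depths <- ape::node.depth.edgelength(tr)[1:100]
  expect_true(all(abs(depths - 100) < 1e-9))
  expect_true(all(grepl("^g[0-9]+_s[0-9]+$", tr$tip.label)))
  gm <- genus_map_from_labels(tr)
  expect_true(all(table(gm) >= 1 & table(gm) <= 5))

  expect_identical(ape::write.tree(tr),
                   ape::write.tree(simulate_yule_tree(100, seed = 6, depth = 100)))
  expect_error(simulate_yule_tree(1, seed = 1), ">= 2")
})

test_that("generated landscapes validate cleanly and are reproducible", {
  tr <- simulate_yule_tree(80, seed = 2, depth = 90)
  for (sc in c("random", "filtering", "overdispersion", "age_gradient")) {
    ls <- simulate_landscape(tr, scenario_config(sc, n_cells = 8,
                                                 richness_min = 4,
                                                 richness_max = 12, seed = 5))
    rep <- validate_inputs(ls$comm, tr, ls$genus_map)
    expect_length(rep$species_missing_from_tree, 0)
    expect_length(rep$cells_emptied, 0)
    expect_true(all(rowSums(ls$comm) >= 4 & rowSums(ls$comm) <= 12))
    ls2 <- simulate_landscape(tr, scenario_config(sc, n_cells = 8,
                                                  richness_min = 4,
                                                  richness_max = 12, seed = 5))
    expect_identical(ls$comm, ls2$comm)
  }
  expect_error(
    simulate_landscape(tr, scenario_config("random", richness_min = 5,
                                           richness_max = 90)),
    "exceeds")
})

test_that("overdispersion scenario spaces assemblages out relative to random", {
  tr <- simulate_yule_tree(120, seed = 9, depth = 100)
  dm <- patristic_distances(tr)
  mean_mpd <- function(ls) {
    mean(vapply(seq_len(nrow(ls$comm)), function(i) {
      mpd(colnames(ls$comm)[ls$comm[i, ] == 1L], dm)
    }, numeric(1)))
  }
  # paired at equal richness via shared richness draw range and seed count
  cells <- 200L
  rnd <- simulate_landscape(tr, scenario_config("random", n_cells = cells,
                                                richness_min = 6,
                                                richness_max = 6, seed = 21))
  ovr <- simulate_landscape(tr, scenario_config("overdispersion",
                                                n_cells = cells,
                                                richness_min = 6,
                                                richness_max = 6,
                                                strength = 1, seed = 21))
  mpd_r <- vapply(seq_len(cells), function(i)
    mpd(colnames(rnd$comm)[rnd$comm[i, ] == 1L], dm), numeric(1))
  mpd_o <- vapply(seq_len(cells), function(i)
    mpd(colnames(ovr$comm)[ovr$comm[i, ] == 1L], dm), numeric(1))
  expect_gt(mean(mpd_o), mean(mpd_r))
  # sign test on paired cells, p < 0.01
  wins <- sum(mpd_o > mpd_r)
  p <- stats::binom.test(wins, cells, 0.5, alternative = "greater")$p.value
  expect_lt(p, 0.01)
})

test_that("strength 0 reduces every scenario to the random draw", {
  tr <- simulate_yule_tree(100, seed = 14, depth = 100)
  dm <- patristic_distances(tr)
  pool <- tr$tip.label
  cfg <- null_config(n_reps = 99L, seed = 2L)
  mean_nri <- function(sc) {
    ls <- simulate_landscape(tr, scenario_config(sc, n_cells = 100,
                                                 richness_min = 8,
                                                 richness_max = 8,
                                                 strength = 0, seed = 33))
    mean(vapply(seq_len(nrow(ls$comm)), function(i) {
      taxa <- colnames(ls$comm)[ls$comm[i, ] == 1L]
      nri_nti(taxa, pool, dm, cfg, stream_seed = 7000L + i)$nri$ses
    }, numeric(1)))
  }
  for (sc in c("filtering", "overdispersion", "age_gradient")) {
    expect_lt(abs(mean_nri(sc)), 0.15)
  }
})

test_that("simulated datasets round trip through the file formats", {
  tr <- simulate_yule_tree(30, seed = 19, depth = 50)
  ls <- simulate_landscape(tr, scenario_config("random", n_cells = 5,
                                               richness_min = 3,
                                               richness_max = 8, seed = 4))
  dir <- tempfile()
  write_simulated_dataset(tr, ls, dir)
  tr_back <- read_newick(file.path(dir, "tree.nwk"))
  comm_back <- read_community_matrix(file.path(dir, "matrix.csv"))
  gm_back <- read_genus_map(file.path(dir, "genus_map.csv"))
  expect_setequal(tr_back$tip.label, tr$tip.label)
  expect_equal(total_branch_length(tr_back), total_branch_length(tr),
               tolerance = 1e-6)
  expect_identical(comm_back, ls$comm)
  expect_identical(gm_back[names(ls$genus_map)], ls$genus_map)
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"))
  expect_equal(prov$seed, 4L)
  expect_equal(prov$scenario, "random")
})
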