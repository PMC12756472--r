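test_that("genus ages come from crown nodes, stems for monotypics, MRCA otherwise", {
  tr <- fixture_tree()
  ages <- genus_crown_ages(tr, c(A = "g1", B = "g1", C = "g2", D = "g2"))
  expect_equal(genus_age_vector(ages), c(g1 = 1.0, g2 = 2.0))
  expect_false(any(ages$monotypic))

  mono <- genus_crown_ages(tr, c(A = "gA", B = "gB", C = "gC", D = "gD"))
  v <- genus_age_vector(mono)
  expect_equal(unname(v[c("gA", "gB", "gC", "gD")]), c(1, 1, 2, 2))
  expect_true(all(mono$monotypic))

  # non-monophyletic genus {A, C}: MRCA is the root (age 3),
  # verified against a brute-force pairwise-path MRCA oracle
  nonmono <- genus_crown_ages(tr, c(A = "gx", C = "gx", B = "gB", D = "gD"))
  expect_equal(unname(genus_age_vector(nonmono)["gx"]), 3.0)
  expect_equal(oracle_patristic(tr, "A", "C") / 2, 3.0)  # ultrametric: d/2 = MRCA age

  expect_warning(
    genus_crown_ages(tr, c(A = "g1", B = "g1", C = "g2", D = "g2",
                           ZZZ = "ghost")),
    "no tips")
  expect_error(genus_crown_ages(tr, c(A = "g1")), "without genus")
})

test_that("MDT is the species-count-weighted mean of genus ages", {
  expect_equal(mdt(c(g1 = 3L), c(g1 = 10)), 10)
  expect_equal(mdt(c(g1 = 1L, g2 = 1L), c(g1 = 10, g2 = 30)), 20)
  expect_equal(mdt(c(g1 = 1L, g2 = 2L, g3 = 3L), c(g1 = 10, g2 = 20, g3 = 30)),
               (10 + 40 + 90) / 6)
  expect_error(mdt(integer(0), c(g1 = 10)), "empty")

  # unweighted mean when all S equal; invariant to rescaling S
  ages <- c(a = 5, b = 17, c = 40)
  expect_equal(mdt(c(a = 2L, b = 2L, c = 2L), ages), mean(ages))
  expect_equal(mdt(c(a = 3L, b = 6L, c = 9L), ages),
               mdt(c(a = 1L, b = 2L, c = 3L), ages))
  # bounded by the cell's age range
  m <- mdt(c(a = 1L, b = 5L, c = 2L), ages)
  expect_gte(m, min(ages)); expect_lte(m, max(ages))
})

test_that("quartile means follow the ceiling(n/4) rule with name tie-breaks", {
  ages8 <- stats::setNames(1:8, paste0("g", 1:8))
  counts8 <- stats::setNames(rep(1L, 8), names(ages8))
  q8 <- quartile_mean_ages(counts8, ages8)
  expect_equal(q8$young_mean, 1.5)
  expect_equal(q8$old_mean, 7.5)
  expect_false(q8$flagged)

  ages4 <- stats::setNames(c(2, 4, 6, 8), paste0("g", 1:4))
  q4 <- quartile_mean_ages(stats::setNames(rep(1L, 4), names(ages4)), ages4)
  expect_equal(q4$young_mean, 2)
  expect_equal(q4$old_mean, 8)

  ages5 <- stats::setNames(c(1, 2, 3, 4, 10), paste0("g", 1:5))
  q5 <- quartile_mean_ages(stats::setNames(rep(1L, 5), names(ages5)), ages5)
  expect_equal(q5$young_mean, 1.5)  # ceiling(5/4) = 2 youngest
  expect_equal(q5$old_mean, 7.0)

  # < 4 genera: flagged, both equal to the overall mean
  q2 <- quartile_mean_ages(c(g1 = 1L, g2 = 1L), c(g1 = 4, g2 = 10))
  expect_true(q2$flagged)
  expect_equal(q2$young_mean, 7)
  expect_equal(q2$old_mean, 7)

  expect_lte(q8$young_mean, q8$old_mean)
})

test_that("SES-MDT handles degenerate pools and recovers known biases", {
  cfg <- null_config(n_reps = 199L, seed = 1L)
  flat <- stats::setNames(rep(15.0, 8), paste0("g", 1:8))
  res <- ses_mdt(c(g1 = 2L, g3 = 1L), flat, cfg)
  expect_true(is.na(res$mdt$ses))
  expect_equal(res$classification, "undefined")

  # cell = the oldest ceiling(12/4) genera of a 12-genus pool: SES > 0,
  # sign predicted by exhaustive null enumeration
  pool <- stats::setNames(c(2, 4, 6, 8, 10, 12, 15, 20, 30, 45, 60, 90),
                          paste0("g", sprintf("%02d", 1:12)))
  old3 <- names(sort(pool, decreasing = TRUE))[1:3]
  counts <- stats::setNames(rep(1L, 3), old3)
  res2 <- ses_mdt(counts, pool, null_config(n_reps = 999L, seed = 2L))
  expect_gt(res2$mdt$ses, 0)
  exact <- oracle_exact_ses(mdt(counts, pool),
                            function(g) mean(pool[g]), names(pool), 3L)
  expect_gt(exact, 0)
  expect_lt(abs(res2$mdt$ses - exact), 0.35)  # 999-rep Monte-Carlo noise

  expect_equal(res2$classification,
               if (res2$mdt$ses > 1.96) "ancient-biased" else "nonsignificant")
})

test_that("MDT recovers an imposed age gradient across cells", {
  tr <- simulate_yule_tree(150, seed = 21, depth = 120)
  ls <- simulate_landscape(tr, scenario_config("age_gradient", n_cells = 30,
                                               richness_min = 8,
                                               richness_max = 20,
                                               strength = 1, seed = 5))
  ages <- genus_age_vector(genus_crown_ages(tr, ls$genus_map))
  mdts <- vapply(rownames(ls$comm), function(cell) {
    sp <- colnames(ls$comm)[ls$comm[cell, ] == 1L]
    mdt(cell_genus_counts(sp, ls$genus_map), ages)
  }, numeric(1))
  rho <- stats::cor(seq_along(mdts), mdts, method = "spearman")
  expect_gt(rho, 0.8)  # gradient runs young -> ancient with cell index
})
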