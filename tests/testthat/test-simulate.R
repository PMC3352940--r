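test_that("tree simulation is seed-deterministic with the unique 3-taxon case", {
  t3a <- simulate_tree(3, seed = 1)
  t3b <- simulate_tree(3, seed = 42)
  expect_identical(ape::write.tree(t3a), ape::write.tree(t3b))
  expect_identical(ape::write.tree(simulate_tree(9, seed = 5)),
                   ape::write.tree(simulate_tree(9, seed = 5)))
  expect_false(identical(ape::write.tree(simulate_tree(9, seed = 5)),
                         ape::write.tree(simulate_tree(9, seed = 6))))
  y <- simulate_tree(8, seed = 2, method = "yule")
  expect_true(ape::is.binary(y))
  expect_identical(sort(y$tip.label), sort(paste0("t", 1:8)))
})

test_that("uniform mode covers all 105 six-taxon topologies", {
  keys <- vapply(1:3150, function(s) {
    paste(sort(tree_bipartitions(simulate_tree(6, seed = s))), collapse = ";")
  }, "")
  tab <- table(keys)
  expect_identical(length(tab), 105L)
  expect_gt(stats::chisq.test(as.vector(tab))$p.value, 0.001)
})

test_that("zero change rate gives a constant matrix with S = 0 everywhere", {
  cfg <- simulation_config(n_taxa = 6, n_char = 10, rate = 0,
                           missing_fraction = 0, fragmentary_count = 0,
                           polymorphism_fraction = 0, seed = 4)
  m <- evolve_characters(simulate_tree(6, seed = 4), cfg)
  expect_identical(tree_length(simulate_tree(6, seed = 99), m), 0L)
  st <- homoplasy_stats(m, simulate_tree(6, seed = 99))
  expect_true(st$ensemble$no_variation)
})

test_that("evolution records ground truth and respects the seed", {
  cfg <- simulation_config(n_taxa = 7, n_char = 30, seed = 11,
                           missing_fraction = 0, fragmentary_count = 0,
                           polymorphism_fraction = 0)
  tre <- simulate_tree(7, seed = 11)
  a <- evolve_characters(tre, cfg)
  b <- evolve_characters(tre, cfg)
  expect_identical(a$cells, b$cells)
  expect_identical(ape::write.tree(attr(a, "true_tree")), ape::write.tree(tre))
  expect_s3_class(attr(a, "true_changes"), "data.frame")
})

test_that("degradation hits the requested missing fraction and is logged", {
  cfg <- simulation_config(n_taxa = 12, n_char = 400, seed = 3,
                           missing_fraction = 0.25, fragmentary_count = 0,
                           polymorphism_fraction = 0)
  m <- evolve_characters(simulate_tree(12, seed = 3), cfg)
  d <- degrade_matrix(m, cfg)
  frac <- mean(d$flags == 1L)
  expect_lt(abs(frac - 0.25), 0.01)
  # zero degradation is the identity
  cfg0 <- simulation_config(n_taxa = 12, n_char = 50, seed = 3,
                            missing_fraction = 0, fragmentary_count = 0,
                            polymorphism_fraction = 0)
  m0 <- evolve_characters(simulate_tree(12, seed = 3), cfg0)
  d0 <- degrade_matrix(m0, cfg0)
  expect_identical(m0$cells, d0$cells)
  expect_identical(m0$flags, d0$flags)
  # total loss warns and flags the taxon
  cfg1 <- simulation_config(n_taxa = 5, n_char = 10, seed = 7,
                            missing_fraction = 0, fragmentary_count = 1,
                            fragmentary_missing = 1, polymorphism_fraction = 0)
  m1 <- evolve_characters(simulate_tree(5, seed = 7), cfg1)
  expect_warning(d1 <- degrade_matrix(m1, cfg1), "no remaining data")
  expect_identical(attr(d1, "data_free_taxa"), "t5")
})

test_that("tree recovery improves with more characters", {
  sizes <- c(25, 100, 400)
  mean_rf <- vapply(sizes, function(nc) {
    errs <- vapply(1:6, function(seed) {
      cfg <- simulation_config(n_taxa = 8, n_char = nc, seed = seed,
                               rate = 0.1, missing_fraction = 0.1,
                               fragmentary_count = 0,
                               polymorphism_fraction = 0)
      tre <- simulate_tree(8, seed = seed)
      m <- degrade_matrix(evolve_characters(tre, cfg), cfg)
      hs <- heuristic_search(m, search_config(replicates = 2, seed = seed))
      mean(vapply(hs$trees, rf_distance, 0L, b = ape::unroot(tre)))
    }, 0)
    mean(errs)
  }, 0)
  expect_lte(mean_rf[3], mean_rf[1])
})
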