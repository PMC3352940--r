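test_that("exhaustive enumeration visits the known topology counts", {
  m4 <- sim_matrix(4, 6, seed = 1)
  expect_identical(exhaustive_search(m4)$n_topologies, 3)
  m6 <- sim_matrix(6, 6, seed = 1)
  expect_identical(exhaustive_search(m6)$n_topologies, 105)
  m10 <- sim_matrix(10, 6, seed = 1)
  expect_error(exhaustive_search(m10), "2027025")
})

test_that("random addition is deterministic and exact on 3 taxa", {
  m3 <- sim_matrix(4, 8, seed = 2)
  m3 <- prune_taxa(m3, "t4")
  t_a <- random_addition(m3, seed = 5)
  t_b <- random_addition(m3, seed = 99)
  expect_identical(tree_bipartitions(t_a), tree_bipartitions(t_b))
  m <- sim_matrix(7, 20, seed = 3)
  expect_identical(ape::write.tree(random_addition(m, seed = 7)),
                   ape::write.tree(random_addition(m, seed = 7)))
})

test_that("random addition attains the optimum on homoplasy-free data", {
  tre <- simulate_tree(6, seed = 8)
  clean <- evolve_characters(tre, simulation_config(n_taxa = 6, n_char = 12,
                                                    seed = 8), clean = TRUE)
  st <- homoplasy_stats(clean, random_addition(clean, seed = 3))
  lower_bound <- st$ensemble$M
  expect_identical(tree_length(random_addition(clean, seed = 3), clean),
                   lower_bound)
})

test_that("branch swapping from an optimal start recovers all co-optimal trees", {
  m <- sim_matrix(5, 10, seed = 4, rate = 0.35)
  ex <- exhaustive_search(m, config = search_config(collapse = "never"))
  bs <- branch_swap(ex$trees[[1]], m, search_config(collapse = "never"))
  expect_identical(bs$best_length, ex$best_length)
  keyset <- function(trees) sort(vapply(trees, function(tr) {
    paste(sort(tree_bipartitions(tr)), collapse = ";")
  }, ""))
  expect_identical(keyset(bs$trees), keyset(ex$trees))
})

test_that("NNI, SPR and TBR neighborhoods are nested", {
  keyset <- function(l) unique(vapply(l, caudotheca:::nst_key, ""))
  for (seed in 1:4) {
    tr <- simulate_tree(7, seed = seed)
    nst <- caudotheca:::phylo_to_nst(tr, tr$tip.label)
    nni <- keyset(caudotheca:::nst_nni_neighbors(nst))
    spr <- keyset(caudotheca:::nst_spr_neighbors(nst))
    tbr <- keyset(caudotheca:::nst_tbr_neighbors(nst))
    expect_true(all(nni %in% spr))
    expect_true(all(spr %in% tbr))
  }
  # result lengths are monotone non-increasing across the enum order
  m <- sim_matrix(7, 15, seed = 31, rate = 0.4)
  start <- random_addition(m, seed = 1)
  lens <- vapply(c("nni", "spr", "tbr"), function(sw) {
    branch_swap(start, m, search_config(swap = sw))$best_length
  }, 0L)
  expect_true(all(diff(lens) <= 0))
  expect_lte(lens[["nni"]], tree_length(start, m))
})

test_that("every retained tree rescores to the best length", {
  m <- sim_matrix(7, 18, seed = 6, rate = 0.3)
  for (rule in c("min", "never")) {
    hs <- heuristic_search(m, search_config(replicates = 4, seed = 2,
                                            collapse = rule))
    for (tr in hs$trees) {
      expect_identical(tree_length(tr, m), hs$best_length)
    }
    expect_lte(hs$n_mpt, hs$n_binary)
  }
})

test_that("search is reproducible: same config gives identical results", {
  m <- sim_matrix(8, 20, seed = 10, rate = 0.3)
  cfg <- search_config(replicates = 4, seed = 17)
  a <- heuristic_search(m, cfg)
  b <- heuristic_search(m, cfg)
  expect_identical(a$best_length, b$best_length)
  expect_identical(a$replicate_log, b$replicate_log)
  expect_identical(lapply(a$trees, ape::write.tree),
                   lapply(b$trees, ape::write.tree))
})

test_that("maxtrees truncates the pool with a flag, not an error", {
  m <- sim_matrix(8, 6, seed = 12, rate = 0.05)  # flat landscape, many ties
  hs <- heuristic_search(m, search_config(replicates = 2, seed = 3,
                                          maxtrees = 3, collapse = "never"))
  expect_true(hs$truncated)
  expect_lte(hs$n_binary, 3L)
})

test_that("clean matrices with an informative character per edge give the true tree", {
  for (seed in c(2, 14)) {
    tre <- simulate_tree(7, seed = seed)
    clean <- evolve_characters(tre, simulation_config(n_taxa = 7, n_char = 16,
                                                      seed = seed),
                               clean = TRUE)
    hs <- heuristic_search(clean, search_config(replicates = 3, seed = 1))
    expect_identical(hs$n_mpt, 1L)
    expect_identical(rf_distance(hs$trees[[1]], ape::unroot(tre)), 0L)
    expect_identical(homoplasy_stats(clean, hs$trees[[1]])$ensemble$CI, 1)
  }
})

test_that("strict consensus is the bipartition intersection", {
  t1 <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  expect_identical(sort(tree_bipartitions(strict_consensus(list(t1)))),
                   sort(tree_bipartitions(t1)))
  t2 <- ape::read.tree(text = "((A,C),(B,(D,E)));")  # conflicts in one clade
  cons <- strict_consensus(list(t1, t2))
  expect_identical(tree_bipartitions(cons),
                   intersect(tree_bipartitions(t1), tree_bipartitions(t2)))
  expect_identical(length(tree_bipartitions(cons)), 1L)  # only D,E survives
  # independent oracle: ape's strict consensus
  for (seed in 1:3) {
    m <- sim_matrix(7, 12, seed = seed, rate = 0.35)
    ex <- exhaustive_search(m, config = search_config(collapse = "never"))
    mine <- strict_consensus(ex$trees)
    theirs <- ape::consensus(lapply(ex$trees, ape::unroot), p = 1)
    expect_setequal(tree_bipartitions(mine), tree_bipartitions(theirs))
  }
  t3 <- ape::read.tree(text = "((A,B),(C,(D,F)));")
  expect_error(strict_consensus(list(t1, t3)), "leaf set")
})
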