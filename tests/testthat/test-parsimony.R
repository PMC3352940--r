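test_that("simple character lengths match hand-checkable cases", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  expect_identical(character_length(tr, c(A = "0", B = "0", C = "0", D = "0")), 0L)
  expect_identical(character_length(tr, c(A = "0", B = "0", C = "1", D = "1")), 1L)
  expect_error(character_length(tr, c(A = "0", B = "1", C = "0")), "lacks data")
})

test_that("character_length equals brute-force assignment enumeration", {
  for (seed in 1:12) {
    tr <- simulate_tree(6, seed = seed)
    col <- random_column(6, 4, seed = seed + 100)
    expect_identical(
      character_length(tr, col),
      brute_character_length(tr, col, n_state = 4),
      info = paste("seed", seed)
    )
  }
})

test_that("Fitch equals Sankoff under uniform unit costs", {
  for (seed in 1:20) {
    n <- sample(5:8, 1)
    tr <- simulate_tree(n, seed = seed)
    col <- random_column(n, sample(2:4, 1), seed = seed + 500)
    expect_identical(
      character_length(tr, col, method = "fitch"),
      character_length(tr, col, method = "sankoff"),
      info = paste("seed", seed)
    )
  }
})

test_that("ordered characters use linear step costs", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  col <- c(A = "0", B = "2", C = "0", D = "2")
  expect_identical(character_length(tr, col, ordered = TRUE, method = "sankoff"),
                   brute_character_length(tr, col, ordered = TRUE, n_state = 3))
  # 0 vs 2 split costs 2 under ordered, 1 under unordered
  expect_identical(character_length(tr, c(A = "0", B = "0", C = "2", D = "2"),
                                    ordered = TRUE, method = "sankoff"), 2L)
})

test_that("tree_length is invariant to rerooting and child order", {
  m <- sim_matrix(7, 20, seed = 9)
  tr <- random_addition(m, seed = 2)
  s <- tree_length(tr, m)
  for (og in m$taxa[2:4]) {
    expect_identical(tree_length(root_at_outgroup(tr, og), m), s)
  }
  rot <- ape::read.tree(text = ape::write.tree(ape::rotateConstr(
    ape::unroot(tr), rev(sort(tr$tip.label)))))
  expect_identical(tree_length(rot, m), s)
})

test_that("char_bounds follows the k-1 rule and the star-tree maximum", {
  b <- char_bounds(c("0", "1", "2", "0", "1"))
  expect_identical(b[["m"]], 2L)
  # g for (0,0,1,1,2) checked against exhaustive maximization over topologies
  col <- stats::setNames(c("0", "0", "1", "1", "2"), paste0("t", 1:5))
  b2 <- char_bounds(col)
  expect_identical(b2[["g"]], 3L)
  expect_identical(b2[["g"]], max_length_over_trees(col, n_state = 3))
  # all-missing column: (0, 0) and uninformative
  b3 <- char_bounds(c("?", "?", "?", "?"))
  expect_identical(as.integer(b3), c(0L, 0L))
  expect_true(attr(b3, "uninformative"))
})

test_that("bound ambiguity resolution minimizes m and g", {
  # {01} can collapse onto either state: one observed state suffices
  b <- char_bounds(c("{01}", "0", "0", "{01}"))
  expect_identical(b[["m"]], 0L)
  expect_identical(b[["g"]], 0L)
  # and maximizes the modal frequency for g
  col <- stats::setNames(c("{01}", "1", "0", "2", "1"), paste0("t", 1:5))
  expect_identical(char_bounds(col)[["g"]],
                   max_length_over_trees(col, n_state = 3))
})

test_that("g from char_bounds equals the exhaustive maximum on random columns", {
  for (seed in 1:8) {
    col <- random_column(5, 3, seed = seed + 900)
    expect_identical(char_bounds(col, n_state = 3)[["g"]],
                     max_length_over_trees(col, n_state = 3),
                     info = paste("seed", seed))
  }
})

test_that("m <= s <= g for every character on every tree", {
  for (seed in 1:6) {
    m <- sim_matrix(6, 15, seed = seed, rate = 0.3)
    tr <- simulate_tree(6, seed = seed + 50)
    s <- tree_length(tr, m, per_character = TRUE)
    st <- homoplasy_stats(m, tr)
    expect_true(all(st$per_character$m <= s))
    expect_true(all(s <= st$per_character$g))
  }
})

test_that("ensemble identities hold exactly and CI = 1 iff no homoplasy", {
  tre <- simulate_tree(7, seed = 21)
  clean <- evolve_characters(tre, simulation_config(n_taxa = 7, n_char = 20,
                                                    seed = 21), clean = TRUE)
  st <- homoplasy_stats(clean, ape::unroot(tre))
  expect_identical(st$ensemble$CI, 1)
  expect_identical(st$ensemble$HI, 0)
  expect_identical(st$ensemble$RI, 1)
  expect_identical(st$ensemble$RC, 1)
  for (seed in 1:5) {
    m <- sim_matrix(7, 25, seed = seed, rate = 0.3)
    st <- homoplasy_stats(m, random_addition(m, seed))
    e <- st$ensemble
    expect_lt(abs(e$CI + e$HI - 1), 1e-12)
    expect_lt(abs(e$RC - e$CI * e$RI), 1e-12)
    expect_true(e$CI > 0 && e$CI <= 1)
    expect_identical(e$CI == 1, e$S == e$M)
  }
})

test_that("a variation-free matrix yields an explicit no-variation result", {
  tok <- matrix("0", 4, 3, dimnames = list(paste0("t", 1:4), NULL))
  m <- char_matrix(tok)
  st <- homoplasy_stats(m, simulate_tree(4, seed = 1))
  expect_true(st$ensemble$no_variation)
  expect_true(is.na(st$ensemble$CI))
})

test_that("uninformative characters can be excluded from the ensemble", {
  m <- sim_matrix(6, 30, seed = 13, rate = 0.25)
  tr <- random_addition(m, 1)
  a <- homoplasy_stats(m, tr, include_uninformative = TRUE)
  b <- homoplasy_stats(m, tr, include_uninformative = FALSE)
  expect_identical(b$ensemble$M,
                   sum(a$per_character$m[a$per_character$informative]))
  expect_true(b$ensemble$CI <= a$ensemble$CI)
})

test_that("removing a taxon never increases the optimal tree length", {
  for (seed in 1:4) {
    m <- sim_matrix(6, 10, seed = seed, rate = 0.35)
    full <- exhaustive_search(m)$best_length
    for (drop in m$taxa[c(2, 5)]) {
      red <- exhaustive_search(prune_taxa(m, drop))$best_length
      expect_lte(red, full)
    }
  }
})
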