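test_that("a single clean origin reconstructs identically under both modes", {
  tr <- root_at_outgroup(ape::read.tree(text = "((A,B),(C,(D,E)));"), "A")
  col <- c(A = "0", B = "0", C = "1", D = "1", E = "1")
  acc <- optimize_states(tr, col, "ACCTRAN")
  del <- optimize_states(tr, col, "DELTRAN")
  expect_identical(acc$states, del$states)
  expect_identical(acc$steps, 1L)
  expect_identical(nrow(acc$changes), 1L)
})

test_that("unrooted trees are refused", {
  tr <- ape::unroot(ape::read.tree(text = "((A,B),(C,D));"))
  expect_error(optimize_states(tr, c(A = "0", B = "0", C = "1", D = "1")),
               "rooted")
})

test_that("both modes achieve the minimum change count on random instances", {
  for (seed in 1:10) {
    n <- sample(5:7, 1)
    tr <- root_at_outgroup(simulate_tree(n, seed = seed), "t1")
    col <- random_column(n, 3, seed = seed + 300)
    truth <- brute_character_length(tr, col, n_state = 3)
    for (mode in c("ACCTRAN", "DELTRAN")) {
      rec <- optimize_states(tr, col, mode)
      expect_identical(rec$steps, truth)
      expect_identical(nrow(rec$changes), truth)
    }
  }
})

test_that("reconstructions are members of the brute-force optimum set", {
  for (seed in 1:6) {
    tr <- root_at_outgroup(simulate_tree(6, seed = seed), "t1")
    col <- random_column(6, 3, seed = seed + 700, p_missing = 0)
    brute <- brute_min_assignments(tr, col, n_state = 3)
    nT <- length(tr$tip.label)
    for (mode in c("ACCTRAN", "DELTRAN")) {
      rec <- optimize_states(tr, col, mode)
      internal <- unname(rec$states[(nT + 1):length(rec$states)])
      hit <- apply(brute$assignments, 1L, function(a) all(a == internal))
      expect_true(any(hit), info = paste(mode, "seed", seed))
    }
  }
})

test_that("branch-change sets are invariant to child order", {
  m <- sim_matrix(6, 12, seed = 23, rate = 0.3)
  tr <- root_at_outgroup(random_addition(m, 2), "t1")
  perm <- ape::read.tree(text = ape::write.tree(
    ape::rotateConstr(tr, rev(sort(tr$tip.label)))))
  perm <- root_at_outgroup(perm, "t1")
  for (j in c(1, 5, 9)) {
    col <- matrix_column(m, j)
    for (mode in c("ACCTRAN", "DELTRAN")) {
      a <- optimize_states(tr, col, mode)
      b <- optimize_states(perm, col, mode)
      # compare as sets of (clade-below-child, from, to)
      sig <- function(rec, tree) {
        nT <- length(tree$tip.label)
        apply(rec$changes, 1L, function(r) {
          tips <- if (r[["child"]] <= nT) tree$tip.label[r[["child"]]]
          else sort(ape::extract.clade(tree, r[["child"]])$tip.label)
          paste(paste(tips, collapse = ","), r[["from"]], r[["to"]])
        })
      }
      expect_setequal(sig(a, tr), sig(b, perm))
    }
  }
})

test_that("ACCTRAN places ambiguous changes rootward of DELTRAN", {
  differing <- 0L
  for (seed in 1:8) {
    m <- sim_matrix(7, 10, seed = seed, rate = 0.3)
    tr <- root_at_outgroup(random_addition(m, seed), "t1")
    depth <- ape::node.depth.edgelength(ape::compute.brlen(tr, 1))
    for (j in seq_len(m$n_char)) {
      col <- matrix_column(m, j)
      a <- optimize_states(tr, col, "ACCTRAN")
      d <- optimize_states(tr, col, "DELTRAN")
      if (!identical(a$changes, d$changes)) {
        differing <- differing + 1L
        expect_lte(sum(depth[a$changes$child]), sum(depth[d$changes$child]))
      }
    }
  }
  expect_gt(differing, 0L)
})

test_that("synapomorphy listing flags mode-dependent support", {
  tre <- simulate_tree(6, seed = 31)
  clean <- evolve_characters(tre, simulation_config(n_taxa = 6, n_char = 8,
                                                    seed = 31), clean = TRUE)
  rt <- root_at_outgroup(ape::unroot(tre), "t1")
  # pick an internal clade off the root
  nT <- length(rt$tip.label)
  node <- setdiff(rt$edge[, 2], seq_len(nT))[2]
  tab <- synapomorphy_list(rt, clean, node)
  if (nrow(tab) > 0L) {
    expect_true(all(tab$support_mode == "both"))
  }
  expect_error(synapomorphy_list(rt, clean, 1L), "leaf")
})
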