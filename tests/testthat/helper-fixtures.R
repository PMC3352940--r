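# Shared fixtures and independent oracles, all generated in code.

# A simulated matrix with no degradation (single states only) unless asked.
sim_matrix <- function(n_taxa, n_char, seed, rate = 0.2, states = 3,
                       fraction_ordered = 0) {
  cfg <- simulation_config(
    n_taxa = n_taxa, n_char = n_char, states_per_char = states, rate = rate,
    fraction_ordered = fraction_ordered, missing_fraction = 0,
    fragmentary_count = 0, polymorphism_fraction = 0, seed = seed
  )
  evolve_characters(simulate_tree(n_taxa, seed = seed), cfg)
}

# Column j of a char_matrix as a named list of state sets (NA = missing).
matrix_column <- function(x, j) {
  stats::setNames(lapply(seq_along(x$taxa), function(i) {
    if (x$flags[i, j] != 0L) NA else cell_states(x, i, j)
  }), x$taxa)
}

# Brute-force parsimony length: enumerate every internal-node assignment;
# tip ambiguity is resolved per pendant edge (exact for additive costs).
brute_character_length <- function(tree, column, ordered = FALSE,
                                   n_state = NULL) {
  cm <- caudotheca:::column_masks(column, tree$tip.label, n_state)
  k <- cm$n_state
  cost <- if (ordered) {
    function(a, b) abs(a - b)
  } else {
    function(a, b) as.numeric(a != b)
  }
  nT <- length(tree$tip.label)
  nI <- tree$Nnode
  E <- tree$edge
  sets <- lapply(cm$masks, caudotheca:::mask_to_states, n_state = k)
  best <- Inf
  grid <- rep(0L, nI)
  repeat {
    assign_of <- function(v) if (v <= nT) NA else grid[v - nT]
    tot <- 0
    for (e in seq_len(nrow(E))) {
      p <- grid[E[e, 1L] - nT]
      ch <- E[e, 2L]
      tot <- tot + if (ch <= nT) {
        min(vapply(sets[[ch]], cost, 0, b = p))
      } else {
        cost(grid[ch - nT], p)
      }
    }
    best <- min(best, tot)
    # increment mixed-radix counter
    i <- 1L
    while (i <= nI) {
      grid[i] <- grid[i] + 1L
      if (grid[i] < k) break
      grid[i] <- 0L
      i <- i + 1L
    }
    if (i > nI) break
  }
  as.integer(best)
}

# All minimum-change full assignments (internal nodes only), as a matrix of
# 0-based states with one row per optimal assignment.
brute_min_assignments <- function(tree, column, ordered = FALSE,
                                  n_state = NULL) {
  cm <- caudotheca:::column_masks(column, tree$tip.label, n_state)
  k <- cm$n_state
  cost <- if (ordered) {
    function(a, b) abs(a - b)
  } else {
    function(a, b) as.numeric(a != b)
  }
  nT <- length(tree$tip.label)
  nI <- tree$Nnode
  E <- tree$edge
  sets <- lapply(cm$masks, caudotheca:::mask_to_states, n_state = k)
  res <- list()
  best <- Inf
  grid <- rep(0L, nI)
  repeat {
    tot <- 0
    for (e in seq_len(nrow(E))) {
      p <- grid[E[e, 1L] - nT]
      ch <- E[e, 2L]
      tot <- tot + if (ch <= nT) {
        min(vapply(sets[[ch]], cost, 0, b = p))
      } else {
        cost(grid[ch - nT], p)
      }
    }
    if (tot < best - 1e-9) {
      best <- tot
      res <- list(grid)
    } else if (tot <= best + 1e-9) {
      res[[length(res) + 1L]] <- grid
    }
    i <- 1L
    while (i <= nI) {
      grid[i] <- grid[i] + 1L
      if (grid[i] < k) break
      grid[i] <- 0L
      i <- i + 1L
    }
    if (i > nI) break
  }
  list(steps = as.integer(best), assignments = do.call(rbind, res))
}

# Exact optimum over ALL unrooted topologies by direct enumeration (used as
# an oracle independent of exhaustive_search's scorer path).
brute_best_length <- function(x) {
  n <- length(x$taxa)
  trees <- caudotheca:::nst_enumerate(n)
  min(vapply(trees, function(nst) {
    tr <- ape::unroot(caudotheca:::nst_to_phylo(nst, x$taxa))
    sum(vapply(seq_len(x$n_char), function(j) {
      brute_character_length(
        if (ape::is.rooted(tr)) tr else
          ape::root(tr, outgroup = x$taxa[1], resolve.root = TRUE),
        matrix_column(x, j), x$ordered[j]
      )
    }, 0L))
  }, 0))
}

# Maximum single-character length over all topologies (oracle for g).
max_length_over_trees <- function(column, ordered = FALSE, n_state = NULL) {
  taxa <- names(column)
  n <- length(taxa)
  trees <- caudotheca:::nst_enumerate(n)
  max(vapply(trees, function(nst) {
    tr <- caudotheca:::nst_to_phylo(nst, taxa)
    brute_character_length(tr, column, ordered, n_state)
  }, 0L))
}

# Decay oracle: enumerate all topologies, bin by clade presence.
brute_decay <- function(x, clade) {
  n <- length(x$taxa)
  trees <- caudotheca:::nst_enumerate(n)
  key <- caudotheca:::split_key_from_taxa(clade, x$taxa)
  lens <- vapply(trees, function(nst) {
    tree_length(ape::unroot(caudotheca:::nst_to_phylo(nst, x$taxa)), x)
  }, 0L)
  has <- vapply(trees, function(nst) {
    tr <- ape::unroot(caudotheca:::nst_to_phylo(nst, x$taxa))
    key %in% caudotheca:::phylo_split_keys(tr)
  }, TRUE)
  min(lens[!has]) - min(lens)
}

# Random per-taxon column tokens incl. ambiguity and missing cells.
random_column <- function(n_taxa, k, seed, p_poly = 0.15, p_missing = 0.1) {
  set.seed(seed)
  taxa <- paste0("t", seq_len(n_taxa))
  toks <- vapply(seq_len(n_taxa), function(i) {
    u <- stats::runif(1)
    if (u < p_missing) return("?")
    if (u < p_missing + p_poly) {
      st <- sort(sample.int(k, 2L) - 1L)
      return(paste0("{", paste(st, collapse = ""), "}"))
    }
    as.character(sample.int(k, 1L) - 1L)
  }, "")
  stats::setNames(toks, taxa)
}

rf_distance <- function(a, b) {
  ka <- tree_bipartitions(a)
  kb <- tree_bipartitions(b)
  length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}
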