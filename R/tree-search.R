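# Heuristic and exact most-parsimonious tree search: random stepwise
# addition, NNI/SPR/TBR branch swapping with retention of all equally short
# trees, exhaustive enumeration for small instances, the zero-length-branch
# collapse rule used when counting trees, and strict consensus.

PENALTY <- 1e7  # added to the length of trees violating a converse constraint

#' Search configuration
#'
#' @param replicates Number of random addition-sequence replicates.
#' @param seed Master seed; per-replicate seeds are drawn from it by a fixed
#'   splitting rule so runs are reproducible.
#' @param swap Branch-swapping neighborhood: `"tbr"` (default), `"spr"` or
#'   `"nni"`.
#' @param maxtrees Cap on the number of equally parsimonious trees retained
#'   during swapping (`Inf` = no limit).
#' @param collapse Rule applied before counting/deduplicating trees:
#'   `"min"` collapses internal branches whose minimum optimized length is
#'   zero; `"never"` keeps all binary resolutions.
#' @param steepest Take the best neighbor instead of the first improvement.
#' @return A `search_config` object.
#' @export
search_config <- function(replicates = 20L, seed = 1L,
                          swap = c("tbr", "spr", "nni"), maxtrees = Inf,
                          collapse = c("min", "never"), steepest = FALSE) {
  swap <- match.arg(swap)
  collapse <- match.arg(collapse)
  stopifnot(replicates >= 1L, maxtrees >= 1)
  structure(
    list(replicates = as.integer(replicates), seed = as.integer(seed),
         swap = swap, maxtrees = maxtrees, collapse = collapse,
         steepest = isTRUE(steepest)),
    class = "search_config"
  )
}

# Scorer factory: compresses duplicate unordered columns for the Fitch
# kernel, scores ordered columns by Sankoff, and (optionally) penalizes
# trees containing a forbidden clade.  Works on nested trees whose tip ids
# index rows of `ids` (global matrix rows); ids[1] is the handle.
make_scorer <- function(x, forbidden = NULL) {
  unord_idx <- which(!x$ordered)
  ord_idx <- which(x$ordered)
  cells_u <- x$cells[, unord_idx, drop = FALSE]
  w <- numeric(0)
  tipmask_u <- cells_u
  if (length(unord_idx) > 0L) {
    key <- apply(cells_u, 2L, paste, collapse = "|")
    rep_cols <- !duplicated(key)
    grp <- match(key, key[rep_cols])
    w <- as.numeric(tabulate(grp, nbins = sum(rep_cols)))
    tipmask_u <- cells_u[, rep_cols, drop = FALSE]
  }
  forbidden_ids <- if (!is.null(forbidden)) {
    sort(match(forbidden, x$taxa))
  } else NULL

  function(nst, ids) {
    k <- length(ids)
    post <- nst_postorder(nst, k)
    s <- 0
    if (length(w) > 0L) {
      s <- fitch_total(tipmask_u[ids, , drop = FALSE],
                       post$child1, post$child2, w)
    }
    if (length(ord_idx) > 0L) {
      tr <- nst_to_phylo(nst, as.character(seq_len(k)))
      for (j in ord_idx) {
        s <- s + sankoff_length(tr, x$cells[ids, j], x$n_state, TRUE)
      }
    }
    if (!is.null(forbidden_ids) && all(forbidden_ids %in% ids)) {
      local_clade <- sort(which(ids %in% forbidden_ids))
      if (length(local_clade) >= 2L && k - length(local_clade) >= 2L) {
        sides <- nst_splits(nst)
        target <- paste(local_clade, collapse = ",")
        comp <- paste(sort(setdiff(seq_len(k), local_clade)), collapse = ",")
        keys <- vapply(sides, paste, "", collapse = ",")
        if (target %in% keys || comp %in% keys) s <- s + PENALTY
      }
    }
    s
  }
}

# Random stepwise addition (internal core): returns nested tree in the
# global id space (handle = taxon 1) plus the addition order used.
random_addition_core <- function(x, seed, scorer = make_scorer(x)) {
  n <- length(x$taxa)
  if (n < 3L) stop("stepwise addition requires at least 3 taxa")
  set.seed(seed)
  ord <- sample.int(n)
  nst <- list(2L, 3L)
  if (n > 3L) {
    for (k in 4:n) {
      cands <- nst_insert_everywhere(nst, k)
      sc <- vapply(cands, scorer, 0, ids = ord[seq_len(k)])
      nst <- cands[[which.min(sc)]]  # ties: lowest enumeration index
    }
  }
  # relabel into global ids and re-hang on global taxon 1
  relabel <- function(node) {
    if (nst_is_tip(node)) return(ord[node])
    list(relabel(node[[1]]), relabel(node[[2]]))
  }
  g <- relabel(nst)
  tr <- nst_to_phylo_raw(g, ord[1L], n)
  list(nst = phylo_to_nst(tr, as.character(seq_len(n))), order = ord)
}

# nested with arbitrary handle taxon -> rooted binary phylo over n tips
# labelled "1".."n"-style by global id; used only to re-hang on taxon 1.
nst_to_phylo_raw <- function(nst, handle_id, n) {
  taxa <- as.character(seq_len(n))
  # build a nested structure in a space where the handle is `handle_id`
  edges <- matrix(0L, 2L * n - 2L, 2L)
  nextn <- n + 1L
  rowi <- 0L
  rec <- function(node, parent) {
    if (nst_is_tip(node)) {
      rowi <<- rowi + 1L
      edges[rowi, ] <<- c(parent, node)
      return(invisible())
    }
    nextn <<- nextn + 1L
    id <- nextn
    rowi <<- rowi + 1L
    edges[rowi, ] <<- c(parent, id)
    rec(node[[1]], id)
    rec(node[[2]], id)
    invisible()
  }
  root <- n + 1L
  rowi <- rowi + 1L
  edges[rowi, ] <- c(root, handle_id)
  rec(nst, root)
  tr <- list(edge = edges, tip.label = taxa, Nnode = n - 1L)
  class(tr) <- "phylo"
  attr(tr, "order") <- "cladewise"
  tr
}

#' Build a starting tree by random stepwise addition
#'
#' Taxa are added in a seeded random order, each at the attachment point of
#' minimum incremental parsimony length (ties broken by the first position
#' in a fixed enumeration of edges).  Deterministic given the seed.
#'
#' @param x A [char_matrix()] with at least 3 taxa.
#' @param seed Integer seed.
#' @return An unrooted binary `phylo`.
#' @export
random_addition <- function(x, seed = 1L) {
  stopifnot(inherits(x, "char_matrix"))
  core <- random_addition_core(x, seed)
  ape::unroot(nst_to_phylo(core$nst, x$taxa))
}

# Breadth-first branch swapping retaining all trees of length <= current
# best; restarts from improved trees.  Works in the global nested space.
swap_search <- function(nst0, scorer, n, swap, maxtrees = Inf,
                        steepest = FALSE) {
  ids <- seq_len(n)
  key0 <- nst_key(nst0)
  s0 <- scorer(nst0, ids)
  pool <- new.env(hash = TRUE, parent = emptyenv())
  assign(key0, nst0, envir = pool)
  queue <- list(nst0)
  best <- s0
  truncated <- FALSE
  qi <- 1L
  while (qi <= length(queue)) {
    cur <- queue[[qi]]
    qi <- qi + 1L
    nbs <- nst_neighbors(cur, swap)
    restart <- FALSE
    if (steepest) {
      sc <- vapply(nbs, scorer, 0, ids = ids)
      mn <- min(sc)
      if (mn < best - 1e-9) {
        best <- mn
        nb <- nbs[[which.min(sc)]]
        pool <- new.env(hash = TRUE, parent = emptyenv())
        assign(nst_key(nb), nb, envir = pool)
        queue <- list(nb)
        qi <- 1L
        next
      }
      keep <- which(sc <= best + 1e-9)
      for (i in keep) {
        k <- nst_key(nbs[[i]])
        if (!exists(k, envir = pool, inherits = FALSE)) {
          if (length(ls(pool)) >= maxtrees) {
            truncated <- TRUE
          } else {
            assign(k, nbs[[i]], envir = pool)
            queue[[length(queue) + 1L]] <- nbs[[i]]
          }
        }
      }
    } else {
      for (nb in nbs) {
        s <- scorer(nb, ids)
        if (s < best - 1e-9) {
          best <- s
          pool <- new.env(hash = TRUE, parent = emptyenv())
          assign(nst_key(nb), nb, envir = pool)
          queue <- list(nb)
          qi <- 1L
          restart <- TRUE
          break
        }
        if (s <= best + 1e-9) {
          k <- nst_key(nb)
          if (!exists(k, envir = pool, inherits = FALSE)) {
            if (length(ls(pool)) >= maxtrees) {
              truncated <- TRUE
            } else {
              assign(k, nb, envir = pool)
              queue[[length(queue) + 1L]] <- nb
            }
          }
        }
      }
      if (restart) next
    }
  }
  keys <- ls(pool)
  list(best = best, trees = lapply(keys, get, envir = pool), keys = keys,
       truncated = truncated)
}

finalize_result <- function(x, best, nsts, keys, config, replicate_log = NULL,
                            truncated = FALSE, n_topologies = NA_integer_,
                            islands = NA_integer_) {
  trees <- lapply(nsts, function(nst) ape::unroot(nst_to_phylo(nst, x$taxa)))
  n_binary <- length(trees)
  if (config$collapse == "min") {
    collapsed <- lapply(trees, collapse_tree, x = x)
    ckeys <- vapply(collapsed, function(tr) {
      paste(sort(phylo_split_keys(tr)), collapse = ";")
    }, "")
    keep <- !duplicated(ckeys)
    trees <- collapsed[keep]
  }
  structure(
    list(best_length = as.integer(round(best)), trees = trees,
         n_mpt = length(trees), n_binary = n_binary,
         replicate_log = replicate_log, islands = islands,
         truncated = truncated, n_topologies = n_topologies,
         config = config),
    class = "search_result"
  )
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("search_result: best length %d, %d tree(s) (%d binary resolutions)\n",
              x$best_length, x$n_mpt, x$n_binary))
  if (!is.null(x$replicate_log)) {
    cat(sprintf("  %d replicates, %s swapping, %d island(s)%s\n",
                nrow(x$replicate_log), x$config$swap,
                if (is.na(x$islands)) 1L else x$islands,
                if (x$truncated) " [maxtrees reached]" else ""))
  }
  invisible(x)
}

#' Branch swapping from a starting tree
#'
#' Explores the NNI/SPR/TBR neighborhood of the start tree, keeping every
#' tree whose length is less than or equal to the current best, restarting
#' from improved trees until the neighborhood of every retained tree has
#' been examined.  Hitting `maxtrees` flags the result truncated rather than
#' raising an error.
#'
#' @param start A binary `phylo` over the matrix taxa.
#' @param x A [char_matrix()].
#' @param config A [search_config()].
#' @return A `search_result`; its length never exceeds the start tree's.
#' @export
branch_swap <- function(start, x, config = search_config()) {
  stopifnot(inherits(x, "char_matrix"))
  start <- prep_tree(start, x$taxa)
  if (!ape::is.binary(ape::unroot(start))) {
    start <- ape::multi2di(start)
  }
  nst0 <- phylo_to_nst(start, x$taxa)
  scorer <- make_scorer(x)
  res <- swap_search(nst0, scorer, length(x$taxa), config$swap,
                     config$maxtrees, config$steepest)
  finalize_result(x, res$best, res$trees, res$keys, config,
                  truncated = res$truncated)
}

#' Heuristic search for most-parsimonious trees
#'
#' Runs [random_addition()] followed by branch swapping in each of
#' `config$replicates` replicates (per-replicate seeds split
#' deterministically from the master seed), pools trees of the global best
#' length, deduplicates them under the canonical bipartition comparison,
#' and applies the configured collapse rule.
#'
#' @param x A [char_matrix()] with at least 4 taxa.
#' @param config A [search_config()].
#' @param forbidden_clade Optional character vector of taxon names: search is
#'   restricted to trees NOT containing this clade (converse constraint, used
#'   for decay indices).
#' @return A `search_result` with replicate log and island assignments.
#' @export
heuristic_search <- function(x, config = search_config(),
                             forbidden_clade = NULL) {
  stopifnot(inherits(x, "char_matrix"))
  n <- length(x$taxa)
  if (n < 4L) stop("heuristic search requires at least 4 taxa")
  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max, config$replicates)
  scorer <- make_scorer(x, forbidden = forbidden_clade)
  best <- Inf
  pool_keys <- character(0)
  pool <- list()
  log <- vector("list", config$replicates)
  islands <- 0L
  island_of <- integer(config$replicates)
  truncated <- FALSE
  contributed <- list()
  for (r in seq_len(config$replicates)) {
    core <- random_addition_core(x, rep_seeds[r], scorer)
    start_len <- scorer(core$nst, seq_len(n))
    res <- swap_search(core$nst, scorer, n, config$swap, config$maxtrees,
                       config$steepest)
    truncated <- truncated || res$truncated
    log[[r]] <- data.frame(replicate = r, seed = rep_seeds[r],
                           start_length = as.integer(round(start_len)),
                           final_length = as.integer(round(res$best)))
    if (res$best < best - 1e-9) {
      best <- res$best
      pool <- res$trees
      pool_keys <- res$keys
      islands <- 1L
      island_of[] <- 0L
      island_of[r] <- 1L
      contributed <- list(res$keys)
    } else if (res$best <= best + 1e-9) {
      new <- !(res$keys %in% pool_keys)
      pool <- c(pool, res$trees[new])
      pool_keys <- c(pool_keys, res$keys[new])
      if (length(pool) > config$maxtrees) {
        pool <- pool[seq_len(config$maxtrees)]
        pool_keys <- pool_keys[seq_len(config$maxtrees)]
        truncated <- TRUE
      }
      hit <- vapply(contributed, function(k) any(res$keys %in% k), TRUE)
      if (any(hit)) {
        island_of[r] <- which(hit)[1L]
        contributed[[which(hit)[1L]]] <-
          union(contributed[[which(hit)[1L]]], res$keys)
      } else {
        islands <- islands + 1L
        island_of[r] <- islands
        contributed[[islands]] <- res$keys
      }
    }
  }
  if (best >= PENALTY) {
    stop("no tree satisfying the constraint was found")
  }
  replicate_log <- do.call(rbind, log)
  replicate_log$island <- ifelse(island_of == 0L, NA_integer_, island_of)
  finalize_result(x, best, pool, pool_keys, config,
                  replicate_log = replicate_log, truncated = truncated,
                  islands = islands)
}

#' Exhaustive search over all unrooted binary topologies
#'
#' Enumerates all (2n-5)!! topologies and returns the exact optimum and
#' every optimal tree.  Refuses instances above the cap, reporting how many
#' topologies would be required.
#'
#' @param x A [char_matrix()].
#' @param cap Maximum number of taxa (default 9).
#' @param config Collapse rule etc.; replicates are ignored.
#' @param forbidden_clade Optional converse constraint as in
#'   [heuristic_search()].
#' @return A `search_result` with `n_topologies` filled in.
#' @export
exhaustive_search <- function(x, cap = 9L, config = search_config(),
                              forbidden_clade = NULL) {
  stopifnot(inherits(x, "char_matrix"))
  n <- length(x$taxa)
  if (n < 3L) stop("need at least 3 taxa")
  n_topo <- if (n == 3L) 1 else prod(seq(3, 2 * n - 5, by = 2))
  if (n > cap) {
    stop(sprintf("exhaustive search refused: %d taxa would require %.0f topologies (cap %d taxa)",
                 n, n_topo, cap))
  }
  scorer <- make_scorer(x, forbidden = forbidden_clade)
  trees <- nst_enumerate(n)
  ids <- seq_len(n)
  sc <- vapply(trees, scorer, 0, ids = ids)
  best <- min(sc)
  if (best >= PENALTY) stop("no tree satisfies the constraint")
  opt <- which(sc <= best + 1e-9)
  nsts <- trees[opt]
  keys <- vapply(nsts, nst_key, "")
  finalize_result(x, best, nsts, keys, config, n_topologies = n_topo)
}

#' Collapse internal branches of minimum optimized length zero
#'
#' For every internal edge, computes the minimum number of changes assigned
#' to it over all most-parsimonious reconstructions of every character; edges
#' whose total is zero are collapsed into polytomies.  This is the rule under
#' which distinct binary resolutions that are not supported by any character
#' count as one tree.
#'
#' @param tree A `phylo` over the matrix taxa.
#' @param x A [char_matrix()].
#' @return A `phylo`, possibly with polytomies.
#' @export
collapse_tree <- function(tree, x) {
  stopifnot(inherits(x, "char_matrix"))
  tree <- prep_tree(tree, x$taxa)
  tipmask <- x$cells[match(tree$tip.label, x$taxa), , drop = FALSE]
  key <- apply(rbind(tipmask, as.integer(x$ordered)), 2L, paste, collapse = "|")
  rep_cols <- which(!duplicated(key))
  wts <- tabulate(match(key, key[rep_cols]), nbins = length(rep_cols))
  po <- ape::reorder.phylo(tree, "postorder")$edge
  tot <- numeric(nrow(po))
  for (i in seq_along(rep_cols)) {
    j <- rep_cols[i]
    ud <- sankoff_updown(tree, tipmask[, j], x$n_state, x$ordered[j])
    tot <- tot + wts[i] * ud$edge_min
  }
  # map postorder edge minima onto the tree's edge matrix
  pk <- paste(po[, 1L], po[, 2L])
  ek <- paste(tree$edge[, 1L], tree$edge[, 2L])
  tree$edge.length <- tot[match(ek, pk)]
  out <- ape::di2multi(tree, tol = 1e-9)
  out$edge.length <- NULL
  out
}

#' Strict consensus of a set of trees
#'
#' Returns the tree whose bipartitions are exactly those present in every
#' input tree, with polytomies where the inputs conflict.
#'
#' @param trees A list of `phylo` objects (or a `multiPhylo`) sharing one
#'   leaf set.
#' @return A `phylo`.
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  stopifnot(length(trees) >= 1L)
  taxa <- sort(trees[[1L]]$tip.label)
  for (tr in trees) {
    if (!setequal(tr$tip.label, taxa)) {
      stop("trees do not share one leaf set")
    }
  }
  keys <- phylo_split_keys(trees[[1L]])
  for (tr in trees[-1L]) keys <- intersect(keys, phylo_split_keys(tr))
  clades <- lapply(keys, function(k) strsplit(k, "|", fixed = TRUE)[[1L]])
  build_clade_tree(taxa, clades)
}

# Build a phylo from a compatible set of clades (sides not containing the
# alphabetically first taxon), plus a basal polytomy holding everything else.
build_clade_tree <- function(taxa_sorted, clades) {
  n <- length(taxa_sorted)
  clades <- clades[order(lengths(clades), decreasing = TRUE)]
  k <- length(clades)
  # node ids: tips 1..n, root n+1, clade i -> n+1+i
  parent_of <- function(members) {
    # smallest strict superset = last match in decreasing-size order
    best <- NA_integer_
    for (i in seq_len(k)) {
      if (length(clades[[i]]) > length(members) &&
          all(members %in% clades[[i]])) {
        best <- i
      }
    }
    if (is.na(best)) n + 1L else n + 1L + best
  }
  edges <- matrix(0L, 0L, 2L)
  for (i in seq_len(k)) {
    edges <- rbind(edges, c(parent_of(clades[[i]]), n + 1L + i))
  }
  for (t in seq_len(n)) {
    edges <- rbind(edges, c(parent_of(taxa_sorted[t]), t))
  }
  tr <- list(edge = edges, tip.label = taxa_sorted, Nnode = k + 1L)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' Canonical bipartitions of a tree
#'
#' Non-trivial bipartitions as canonical string keys: for each internal
#' edge, the side not containing the alphabetically first taxon, sorted and
#' joined by `"|"`.
#' @param tree A `phylo`.
#' @return Character vector of split keys.
#' @export
tree_bipartitions <- function(tree) phylo_split_keys(tree)
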