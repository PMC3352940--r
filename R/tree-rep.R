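# Internal representation of unrooted binary trees used by the search engine.
#
# An unrooted binary tree over taxa 1..n is stored as a "nested" structure
# over taxa 2..n: either a bare integer tip id, or list(left, right).  Taxon 1
# (the "handle") is implicitly attached to the edge above the nested root, so
# every unrooted binary topology corresponds to exactly one nested structure
# (up to child order).  All functions here are internal.

nst_is_tip <- function(x) !is.list(x)

nst_tips <- function(x) {
  if (nst_is_tip(x)) return(x)
  c(nst_tips(x[[1]]), nst_tips(x[[2]]))
}

nst_ntips <- function(x) length(nst_tips(x))

# Canonical string key (child subtrees sorted); unique per unrooted topology
# because the handle fixes the rooting.
nst_key <- function(x) {
  if (nst_is_tip(x)) return(as.character(x))
  a <- nst_key(x[[1]])
  b <- nst_key(x[[2]])
  if (a <= b) paste0("(", a, ",", b, ")") else paste0("(", b, ",", a, ")")
}

# Postorder child arrays for the tree rooted on the handle edge: the root has
# children {tip 1, nested root}.  Tip ids 1..n_tips index rows of the tip-mask
# matrix; internal ids follow in postorder.
nst_postorder <- function(x, n_tips) {
  n_int <- n_tips - 1L
  c1 <- integer(n_int)
  c2 <- integer(n_int)
  nid <- n_tips
  rec <- function(node) {
    if (nst_is_tip(node)) return(node)
    a <- rec(node[[1]])
    b <- rec(node[[2]])
    nid <<- nid + 1L
    c1[nid - n_tips] <<- a
    c2[nid - n_tips] <<- b
    nid
  }
  r <- rec(x)
  nid <- nid + 1L
  c1[nid - n_tips] <- 1L
  c2[nid - n_tips] <- r
  list(child1 = c1, child2 = c2)
}

# Splits (as sorted integer tip-id vectors, the side away from the handle) of
# all internal edges.  The edge above the nested root is the handle's pendant
# edge and is excluded.
nst_splits <- function(x) {
  out <- list()
  rec <- function(node, is_root) {
    if (nst_is_tip(node)) return(node)
    a <- rec(node[[1]], FALSE)
    b <- rec(node[[2]], FALSE)
    tips <- sort(c(a, b))
    if (!is_root) out[[length(out) + 1L]] <<- tips
    tips
  }
  rec(x, TRUE)
  out
}

nst_split_keys <- function(x) {
  vapply(nst_splits(x), paste, "", collapse = ",")
}

# Insert tip id `t` above every node of x (including the nested root, which
# corresponds to insertion on the handle edge).  Returns list of trees in a
# fixed deterministic enumeration order.
nst_insert_everywhere <- function(x, t) {
  res <- list(list(x, t))
  if (!nst_is_tip(x)) {
    for (y in nst_insert_everywhere(x[[1]], t)) {
      res[[length(res) + 1L]] <- list(y, x[[2]])
    }
    for (y in nst_insert_everywhere(x[[2]], t)) {
      res[[length(res) + 1L]] <- list(x[[1]], y)
    }
  }
  res
}

# Insert a whole subtree `sub` above every node of x.
nst_insert_subtree_everywhere <- function(x, sub) {
  res <- list(list(x, sub))
  if (!nst_is_tip(x)) {
    for (y in nst_insert_subtree_everywhere(x[[1]], sub)) {
      res[[length(res) + 1L]] <- list(y, x[[2]])
    }
    for (y in nst_insert_subtree_everywhere(x[[2]], sub)) {
      res[[length(res) + 1L]] <- list(x[[1]], y)
    }
  }
  res
}

# All unrooted binary topologies over n taxa (handle convention), built by
# recursive stepwise insertion.  Counts follow (2n-5)!!.
nst_enumerate <- function(n) {
  stopifnot(n >= 3)
  trees <- list(list(2L, 3L))
  if (n == 3) return(trees)
  for (t in 4:n) {
    nxt <- vector("list", length(trees) * (2L * (t - 1L) - 3L))
    k <- 0L
    for (tr in trees) {
      for (y in nst_insert_everywhere(tr, t)) {
        k <- k + 1L
        nxt[[k]] <- y
      }
    }
    trees <- nxt[seq_len(k)]
  }
  trees
}

# Prune every proper subtree (every node except the nested root).  Each entry
# is list(sub = pruned subtree, rest = remaining nested tree with the parent
# junction suppressed).
nst_all_prunes <- function(x) {
  res <- list()
  rec <- function(node, rebuild) {
    if (nst_is_tip(node)) return(invisible())
    a <- node[[1]]
    b <- node[[2]]
    res[[length(res) + 1L]] <<- list(sub = a, rest = rebuild(b))
    res[[length(res) + 1L]] <<- list(sub = b, rest = rebuild(a))
    rec(a, function(r) rebuild(list(r, b)))
    rec(b, function(r) rebuild(list(a, r)))
    invisible()
  }
  rec(x, identity)
  res
}

# All rerootings of the unrooted fragment consisting of x plus a stub above
# its root: one nested structure per edge of the fragment (2k-3 for k >= 2
# leaves).  Used by TBR reconnection and by moves of the handle taxon.
nst_rerootings <- function(x) {
  if (nst_is_tip(x)) return(list(x))
  hang_in <- function(sub, ctx) {
    if (nst_is_tip(sub)) return(list())
    a <- sub[[1]]
    b <- sub[[2]]
    res <- list(list(a, list(b, ctx)), list(b, list(a, ctx)))
    c(res, hang_in(a, list(b, ctx)), hang_in(b, list(a, ctx)))
  }
  c(list(x), hang_in(x[[1]], x[[2]]), hang_in(x[[2]], x[[1]]))
}

# Branch-swap neighborhoods ------------------------------------------------

nst_nni_neighbors <- function(x) {
  res <- list()
  rec <- function(p, rebuild) {
    # p is an internal node; the internal edge above each internal child of p
    # yields two exchanges of that child's children with its sibling
    u <- p[[1]]
    w <- p[[2]]
    if (!nst_is_tip(u)) {
      a <- u[[1]]
      b <- u[[2]]
      res[[length(res) + 1L]] <<- rebuild(list(list(w, b), a))
      res[[length(res) + 1L]] <<- rebuild(list(list(a, w), b))
      rec(u, function(np) rebuild(list(np, w)))
    }
    if (!nst_is_tip(w)) {
      cc <- w[[1]]
      d <- w[[2]]
      res[[length(res) + 1L]] <<- rebuild(list(cc, list(u, d)))
      res[[length(res) + 1L]] <<- rebuild(list(d, list(cc, u)))
      rec(w, function(np) rebuild(list(u, np)))
    }
    invisible()
  }
  rec(x, identity)
  res
}

nst_spr_neighbors <- function(x) {
  res <- list()
  for (pr in nst_all_prunes(x)) {
    for (y in nst_insert_subtree_everywhere(pr$rest, pr$sub)) {
      res[[length(res) + 1L]] <- y
    }
  }
  # moves of the handle taxon: reattach it on every edge of the remainder
  c(res, nst_rerootings(x))
}

nst_tbr_neighbors <- function(x) {
  res <- list()
  for (pr in nst_all_prunes(x)) {
    for (sub in nst_rerootings(pr$sub)) {
      for (y in nst_insert_subtree_everywhere(pr$rest, sub)) {
        res[[length(res) + 1L]] <- y
      }
    }
  }
  c(res, nst_rerootings(x))
}

nst_neighbors <- function(x, swap) {
  switch(swap,
    nni = nst_nni_neighbors(x),
    spr = nst_spr_neighbors(x),
    tbr = nst_tbr_neighbors(x),
    stop("unknown swap algorithm: ", swap)
  )
}

# Conversions ---------------------------------------------------------------

# nested -> rooted binary phylo (rooted on the handle edge).
nst_to_phylo <- function(x, taxa) {
  n <- length(taxa)
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
  edges[rowi, ] <- c(root, 1L)
  rec(x, root)
  tr <- list(edge = edges, tip.label = taxa, Nnode = n - 1L)
  class(tr) <- "phylo"
  attr(tr, "order") <- "cladewise"
  tr
}

# phylo -> nested, relabelling tips by their position in `taxa`.  Degree-2
# nodes (a rooted input's root) are suppressed; polytomies are refused.
phylo_to_nst <- function(tree, taxa) {
  ids <- match(tree$tip.label, taxa)
  if (anyNA(ids)) {
    stop("tree tips not found among matrix taxa: ",
         paste(tree$tip.label[is.na(ids)], collapse = ", "))
  }
  if (length(setdiff(taxa, tree$tip.label)) > 0L) {
    stop("matrix taxa missing from tree: ",
         paste(setdiff(taxa, tree$tip.label), collapse = ", "))
  }
  nT <- length(tree$tip.label)
  E <- tree$edge
  adj <- vector("list", nT + tree$Nnode)
  for (i in seq_len(nrow(E))) {
    adj[[E[i, 1L]]] <- c(adj[[E[i, 1L]]], E[i, 2L])
    adj[[E[i, 2L]]] <- c(adj[[E[i, 2L]]], E[i, 1L])
  }
  start <- which(ids == 1L)
  rec <- function(node, parent) {
    nb <- setdiff(adj[[node]], parent)
    if (length(nb) == 0L) return(ids[node])
    subs <- lapply(nb, rec, parent = node)
    if (length(subs) == 1L) return(subs[[1L]])  # suppress degree-2 node
    if (length(subs) > 2L) {
      stop("tree contains a polytomy; resolve it (e.g. ape::multi2di) first")
    }
    list(subs[[1L]], subs[[2L]])
  }
  rec(adj[[start]][1L], start)
}

# Canonical bipartition keys of a (possibly multifurcating) phylo, computed
# against the sorted taxon list; each key is the side not containing the
# alphabetically first taxon, as sorted names joined by "|".
phylo_split_keys <- function(tree) {
  labs <- tree$tip.label
  all_sorted <- sort(labs)
  first <- all_sorted[1L]
  nT <- length(labs)
  E <- tree$edge
  po <- ape::reorder.phylo(tree, "postorder")$edge
  below <- vector("list", nT + tree$Nnode)
  for (i in seq_len(nT)) below[[i]] <- labs[i]
  for (i in seq_len(nrow(po))) {
    p <- po[i, 1L]
    ch <- po[i, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  keys <- character(0)
  for (i in seq_len(nrow(E))) {
    ch <- E[i, 2L]
    if (ch <= nT) next                      # pendant edge
    side <- below[[ch]]
    if (length(side) <= 1L || length(side) >= nT - 1L) next  # trivial
    if (first %in% side) side <- setdiff(all_sorted, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

split_key_from_taxa <- function(clade, all_taxa) {
  all_sorted <- sort(all_taxa)
  side <- sort(clade)
  if (all_sorted[1L] %in% side) side <- setdiff(all_sorted, side)
  paste(side, collapse = "|")
}
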