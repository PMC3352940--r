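# ACCTRAN/DELTRAN ancestral-state optimization and synapomorphy listing on a
# rooted tree.  Both modes resolve the set of most-parsimonious
# reconstructions exactly (preorder resolution of the Sankoff recursion) and
# always achieve the minimum change count; they differ only in where
# ambiguous changes are placed: ACCTRAN accelerates them toward the root
# (favoring reversals), DELTRAN delays them toward the tips (favoring
# parallelisms).

#' Root a tree on an outgroup taxon
#'
#' @param tree A `phylo`.
#' @param outgroup Taxon name (default: first tip).
#' @return A rooted `phylo`.
#' @export
root_at_outgroup <- function(tree, outgroup = tree$tip.label[1L]) {
  if (!outgroup %in% tree$tip.label) stop("unknown outgroup: ", outgroup)
  ape::root(ape::unroot(tree), outgroup = outgroup, resolve.root = TRUE)
}

#' Ancestral-state optimization under ACCTRAN or DELTRAN
#'
#' Assigns a state to every node of a rooted tree such that the implied
#' number of changes equals the character's parsimony length, resolving
#' ambiguity by the mode's convention.  Ties after the mode preference are
#' broken toward the lowest state label; the root takes the lowest-label
#' optimal state.  Deterministic and invariant to child order.
#'
#' @param tree A rooted `phylo` (apply [root_at_outgroup()] first if needed).
#' @param column Per-taxon states as in [character_length()].
#' @param mode `"ACCTRAN"` or `"DELTRAN"`.
#' @param ordered Additive character?
#' @return A `reconstruction` object: `$states` (named by tip label or node
#'   id), `$changes` (data frame: parent, child, from, to), `$steps`.
#' @export
optimize_states <- function(tree, column, mode = c("ACCTRAN", "DELTRAN"),
                            ordered = FALSE) {
  mode <- match.arg(mode)
  if (!ape::is.rooted(tree)) {
    stop("tree must be rooted; use root_at_outgroup()")
  }
  cm <- column_masks(column, tree$tip.label)
  d <- sankoff_down(tree, cm$masks, cm$n_state, ordered)
  S <- d$S
  cost <- d$cost
  po <- d$edge_po
  nN <- nrow(S)
  states <- integer(nN)
  root <- d$root
  # lowest-label optimal root state
  states[root] <- which.min(S[root, ] + (0:(cm$n_state - 1L)) * 1e-7) - 1L
  total <- min(S[root, ])
  for (e in rev(seq_len(nrow(po)))) {   # preorder: parent assigned first
    p <- po[e, 1L]
    ch <- po[e, 2L]
    ps <- states[p]
    val <- S[ch, ] + cost[ps + 1L, ]
    cand <- which(abs(val - min(val)) < 1e-9) - 1L
    if (mode == "DELTRAN") {
      states[ch] <- if (ps %in% cand) ps else min(cand)
    } else {
      other <- setdiff(cand, ps)
      states[ch] <- if (length(other) > 0L) min(other) else ps
    }
  }
  chg <- po[states[po[, 1L]] != states[po[, 2L]], , drop = FALSE]
  changes <- data.frame(
    parent = chg[, 1L], child = chg[, 2L],
    from = states[chg[, 1L]], to = states[chg[, 2L]]
  )
  nT <- length(tree$tip.label)
  names(states) <- c(tree$tip.label, paste0("node", (nT + 1L):nN))
  structure(
    list(mode = mode, states = states, changes = changes,
         steps = as.integer(round(total)), tree = tree),
    class = "reconstruction"
  )
}

#' @export
print.reconstruction <- function(x, ...) {
  cat(sprintf("%s reconstruction: %d change(s)\n", x$mode, x$steps))
  if (nrow(x$changes) > 0L) print(x$changes, row.names = FALSE)
  invisible(x)
}

mrca_node <- function(tree, taxa) {
  tips <- match(taxa, tree$tip.label)
  if (anyNA(tips)) stop("unknown taxa: ", paste(taxa[is.na(tips)], collapse = ", "))
  if (length(tips) == 1L) return(tips)
  ape::getMRCA(tree, tips)
}

#' Synapomorphies on the stem branch of a clade
#'
#' Lists every (character, derived state) change assigned to the branch
#' subtending the clade, under ACCTRAN, DELTRAN, or both.  Character indices
#' are 1-based matrix indices throughout.
#'
#' @param tree A rooted `phylo` over the matrix taxa.
#' @param x A [char_matrix()].
#' @param clade Internal node id, or a character vector of taxon names whose
#'   MRCA defines the clade.  A single tip is refused.
#' @return Data frame: `character`, `from`, `to`, `support_mode`
#'   (`"both"`, `"ACCTRAN-only"`, `"DELTRAN-only"`), plus `description`
#'   when the matrix carries definitions.
#' @export
synapomorphy_list <- function(tree, x, clade) {
  stopifnot(inherits(x, "char_matrix"))
  tree <- prep_tree(tree, x$taxa)
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  node <- if (is.character(clade)) mrca_node(tree, clade) else as.integer(clade)
  nT <- length(tree$tip.label)
  if (node <= nT) stop("clade must be an internal node, not a leaf")
  tipmask <- x$cells[match(tree$tip.label, x$taxa), , drop = FALSE]
  rows <- list()
  for (j in seq_len(x$n_char)) {
    col <- stats::setNames(lapply(seq_len(nT), function(i) {
      if (x$flags[match(tree$tip.label[i], x$taxa), j] != FLAG_NORMAL) NA
      else mask_to_states(tipmask[i, j], x$n_state)
    }), tree$tip.label)
    acc <- optimize_states(tree, col, "ACCTRAN", x$ordered[j])
    del <- optimize_states(tree, col, "DELTRAN", x$ordered[j])
    on_stem <- function(rec) {
      hit <- rec$changes[rec$changes$child == node, , drop = FALSE]
      if (nrow(hit) == 0L) NULL else hit
    }
    a <- on_stem(acc)
    dl <- on_stem(del)
    if (is.null(a) && is.null(dl)) next
    key_a <- if (is.null(a)) character(0) else paste(a$to)
    key_d <- if (is.null(dl)) character(0) else paste(dl$to)
    for (st in union(key_a, key_d)) {
      support <- if (st %in% key_a && st %in% key_d) "both"
      else if (st %in% key_a) "ACCTRAN-only" else "DELTRAN-only"
      from <- if (st %in% key_a) a$from[match(st, key_a)] else dl$from[match(st, key_d)]
      rows[[length(rows) + 1L]] <- data.frame(
        character = j, from = from, to = as.integer(st),
        support_mode = support
      )
    }
  }
  out <- if (length(rows) == 0L) {
    data.frame(character = integer(0), from = integer(0), to = integer(0),
               support_mode = character(0))
  } else {
    do.call(rbind, rows)
  }
  if (!is.null(x$definitions) && nrow(out) > 0L) {
    out$description <- x$definitions$description[out$character]
  }
  out
}
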