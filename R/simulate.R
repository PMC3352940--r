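# Seeded simulation of trees and discrete (Mk-style) characters with known
# ground truth: random topologies, symmetric multistate change along
# branches, and fossil-style degradation (uniform missingness plus
# taxon-concentrated missingness for fragmentary terminals, and polymorphic
# cells).  Every stage is deterministic given its seed.

#' Simulation configuration
#'
#' Defaults emulate a morphological matrix for fossil terminals: a few
#' hundred unordered multistate characters, moderate per-branch change, and
#' heavy missing data concentrated on a handful of fragmentary taxa.
#'
#' @param n_taxa Number of terminals (>= 4).
#' @param n_char Number of characters.
#' @param states_per_char States per character (2-5).
#' @param rate Per-branch probability that a character changes state.
#' @param fraction_ordered Fraction of characters treated as additive.
#' @param missing_fraction Fraction of cells masked to `?` uniformly.
#' @param fragmentary_count Taxa receiving concentrated missingness.
#' @param fragmentary_missing Per-cell missing probability for those taxa.
#' @param polymorphism_fraction Fraction of cells turned into two-state sets.
#' @param seed Integer seed.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(n_taxa = 24L, n_char = 300L,
                              states_per_char = 3L, rate = 0.08,
                              fraction_ordered = 0, missing_fraction = 0.2,
                              fragmentary_count = 4L,
                              fragmentary_missing = 0.8,
                              polymorphism_fraction = 0.01, seed = 1L) {
  stopifnot(n_taxa >= 4L, n_char >= 1L,
            states_per_char >= 2L, states_per_char <= 5L,
            rate >= 0, rate <= 1,
            fraction_ordered >= 0, fraction_ordered <= 1,
            missing_fraction >= 0, missing_fraction <= 1,
            fragmentary_missing >= 0, fragmentary_missing <= 1,
            polymorphism_fraction >= 0, polymorphism_fraction <= 1,
            fragmentary_count >= 0L, fragmentary_count <= n_taxa)
  structure(
    list(n_taxa = as.integer(n_taxa), n_char = as.integer(n_char),
         states_per_char = as.integer(states_per_char), rate = rate,
         fraction_ordered = fraction_ordered,
         missing_fraction = missing_fraction,
         fragmentary_count = as.integer(fragmentary_count),
         fragmentary_missing = fragmentary_missing,
         polymorphism_fraction = polymorphism_fraction,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Simulate a random binary tree
#'
#' `"uniform"` draws uniformly over unrooted binary topologies (sequential
#' random insertion); `"yule"` grows a rooted tree by random leaf splitting.
#' Leaves are labelled `t1..tn`; deterministic per seed.
#'
#' @param n_taxa Number of leaves (>= 3).
#' @param seed Integer seed.
#' @param method `"uniform"` or `"yule"`.
#' @return A binary `phylo`.
#' @export
simulate_tree <- function(n_taxa, seed = 1L, method = c("uniform", "yule")) {
  method <- match.arg(method)
  stopifnot(n_taxa >= 3L)
  set.seed(seed)
  taxa <- paste0("t", seq_len(n_taxa))
  if (method == "uniform") {
    nst <- list(2L, 3L)
    if (n_taxa > 3L) {
      for (t in 4:n_taxa) {
        cands <- nst_insert_everywhere(nst, t)
        nst <- cands[[sample.int(length(cands), 1L)]]
      }
    }
    return(ape::unroot(nst_to_phylo(nst, taxa)))
  }
  # Yule growth: bifurcate a uniformly chosen current leaf at each step
  rep_tip <- function(node, pick, t) {
    if (!is.list(node)) {
      return(if (node == pick) list(node, t) else node)
    }
    list(rep_tip(node[[1]], pick, t), rep_tip(node[[2]], pick, t))
  }
  x <- list(1L, 2L)
  for (t in 3:n_taxa) {
    x <- rep_tip(x, sample.int(t - 1L, 1L), t)
  }
  # rooted binary phylo from the nested structure
  n <- n_taxa
  edges <- matrix(0L, 2L * n - 2L, 2L)
  nextn <- n + 1L
  rowi <- 0L
  rec <- function(node, parent) {
    if (!is.list(node)) {
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
  rec(x[[1]], root)
  rec(x[[2]], root)
  tr <- list(edge = edges, tip.label = taxa, Nnode = n - 1L)
  class(tr) <- "phylo"
  attr(tr, "order") <- "cladewise"
  tr
}

#' Evolve discrete characters on a tree
#'
#' Each character starts from a uniform root state and, along every branch,
#' changes with probability `config$rate` to a uniformly chosen different
#' state (symmetric Mk-style change; ordered characters step +/-1).  With
#' `clean = TRUE` the matrix instead carries one binary character per
#' internal edge marking that split exactly (repeated to `n_char`), so the
#' generating tree is the unique most-parsimonious tree and CI = 1.
#'
#' The generating tree and the per-branch change list are attached as
#' attributes `"true_tree"` and `"true_changes"`.
#'
#' @param tree A binary `phylo` (rooted trees are used as given; unrooted
#'   trees are rooted internally at the first tip).
#' @param config A [simulation_config()].
#' @param clean Engineer one clean change per internal edge.
#' @return A [char_matrix()] with ground-truth attributes.
#' @export
evolve_characters <- function(tree, config = simulation_config(),
                              clean = FALSE) {
  set.seed(config$seed)
  work <- if (ape::is.rooted(tree)) tree else
    ape::root(tree, outgroup = tree$tip.label[1L], resolve.root = TRUE)
  nT <- length(work$tip.label)
  po <- ape::reorder.phylo(work, "postorder")$edge
  pre <- po[rev(seq_len(nrow(po))), , drop = FALSE]
  root <- pre[1L, 1L]
  nN <- nT + work$Nnode
  k <- config$states_per_char

  if (clean) {
    keys <- phylo_split_keys(ape::unroot(tree))
    cols <- lapply(keys, function(kk) {
      side <- strsplit(kk, "|", fixed = TRUE)[[1L]]
      ifelse(work$tip.label %in% side, "1", "0")
    })
    idx <- rep_len(seq_along(cols), config$n_char)
    mat <- do.call(cbind, cols[idx])
    rownames(mat) <- work$tip.label
    out <- char_matrix(mat, taxa = work$tip.label, symbols = c("0", "1"))
    attr(out, "true_tree") <- tree
    return(out)
  }

  n_ord <- round(config$fraction_ordered * config$n_char)
  ordered <- c(rep(TRUE, n_ord), rep(FALSE, config$n_char - n_ord))
  states <- matrix(0L, nN, config$n_char)
  changes <- list()
  states[root, ] <- sample.int(k, config$n_char, replace = TRUE) - 1L
  for (e in seq_len(nrow(pre))) {
    p <- pre[e, 1L]
    ch <- pre[e, 2L]
    st <- states[p, ]
    flip <- stats::runif(config$n_char) < config$rate
    if (any(flip)) {
      for (j in which(flip)) {
        st[j] <- if (ordered[j]) {
          if (st[j] == 0L) 1L
          else if (st[j] == k - 1L) k - 2L
          else st[j] + sample(c(-1L, 1L), 1L)
        } else {
          sample(setdiff(0:(k - 1L), st[j]), 1L)
        }
      }
      changes[[length(changes) + 1L]] <- data.frame(
        parent = p, child = ch, character = which(flip),
        from = states[p, which(flip)], to = st[which(flip)]
      )
    }
    states[ch, ] <- st
  }
  mat <- matrix(as.character(states[seq_len(nT), , drop = FALSE]),
                nT, config$n_char)
  rownames(mat) <- work$tip.label
  out <- char_matrix(mat, taxa = work$tip.label,
                     symbols = as.character(0:(k - 1L)), ordered = ordered)
  attr(out, "true_tree") <- tree
  attr(out, "true_changes") <- if (length(changes) > 0L) {
    do.call(rbind, changes)
  } else {
    data.frame(parent = integer(0), child = integer(0),
               character = integer(0), from = integer(0), to = integer(0))
  }
  out
}

#' Degrade a matrix with missing data and polymorphism
#'
#' Masks cells to missing uniformly at `missing_fraction`, masks cells of
#' the last `fragmentary_count` taxa at `fragmentary_missing` (emulating
#' fragmentary fossil terminals), and turns a fraction of the remaining
#' cells into two-state polymorphisms.  The mask is recorded in the
#' `"degradation_mask"` attribute; a taxon losing every cell triggers a
#' warning and is flagged.
#'
#' @param x A [char_matrix()].
#' @param config A [simulation_config()].
#' @return A degraded [char_matrix()].
#' @export
degrade_matrix <- function(x, config = simulation_config()) {
  stopifnot(inherits(x, "char_matrix"))
  set.seed(config$seed + 1L)
  nT <- length(x$taxa)
  out <- x
  mask <- matrix(stats::runif(nT * x$n_char) < config$missing_fraction,
                 nT, x$n_char)
  frag <- integer(0)
  if (config$fragmentary_count > 0L) {
    frag <- seq.int(nT - config$fragmentary_count + 1L, nT)
    mask[frag, ] <- mask[frag, , drop = FALSE] |
      matrix(stats::runif(length(frag) * x$n_char) < config$fragmentary_missing,
             length(frag), x$n_char)
  }
  out$cells[mask] <- out$full_mask
  out$flags[mask] <- FLAG_MISSING
  if (config$polymorphism_fraction > 0) {
    elig <- which(!mask)
    npoly <- round(config$polymorphism_fraction * length(elig))
    if (npoly > 0L) {
      pick <- sample(elig, npoly)
      for (cell in pick) {
        st <- mask_to_states(out$cells[cell], out$n_state)[1L]
        other <- (st + 1L) %% x$n_state
        out$cells[cell] <- bitwOr(bitwShiftL(1L, st), bitwShiftL(1L, other))
      }
    }
  }
  lost <- which(vapply(seq_len(nT), function(i) {
    all(out$flags[i, ] != FLAG_NORMAL)
  }, TRUE))
  if (length(lost) > 0L) {
    warning("taxa with no remaining data: ",
            paste(x$taxa[lost], collapse = ", "))
  }
  attr(out, "degradation_mask") <- mask
  attr(out, "fragmentary_taxa") <- x$taxa[frag]
  attr(out, "data_free_taxa") <- x$taxa[lost]
  attr(out, "true_tree") <- attr(x, "true_tree")
  out
}
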