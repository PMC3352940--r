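# Parsimony scoring: Fitch bitmask kernel for unordered characters on binary
# trees, Sankoff dynamic programming for ordered characters, polytomies and
# ancestral-state work, per-character step bounds, and the ensemble homoplasy
# indices CI / HI / RI / RC.

INF_COST <- 1e9

cost_matrix <- function(n_state, ordered) {
  if (ordered) {
    abs(outer(0:(n_state - 1L), 0:(n_state - 1L), "-"))
  } else {
    1 - diag(n_state)
  }
}

# Accept a per-taxon column in several convenient forms and return bitmasks
# aligned to `taxa` plus a missing flag.  Tokens follow the TSV dialect.
column_masks <- function(column, taxa, n_state = NULL) {
  dialect <- matrix_dialect("tsv")
  if (is.list(column)) {
    sets <- column
  } else if (is.numeric(column)) {
    sets <- as.list(as.integer(column))
  } else {
    sets <- lapply(as.character(column), function(tok) {
      if (tok %in% c("?", "-")) return(NA)
      as.integer(strsplit(gsub("[{}()]", "", tok), "", fixed = TRUE)[[1L]])
    })
  }
  nm <- names(column)
  if (!is.null(nm)) {
    idx <- match(taxa, nm)
    if (anyNA(idx)) {
      stop("column lacks data for leaf: ",
           paste(taxa[is.na(idx)], collapse = ", "))
    }
    sets <- sets[idx]
  } else if (length(sets) != length(taxa)) {
    stop("column length does not match number of leaves")
  }
  missing <- vapply(sets, function(s) length(s) == 0L || anyNA(s), TRUE)
  if (is.null(n_state)) {
    mx <- suppressWarnings(max(unlist(sets[!missing]), -1L))
    n_state <- max(mx + 1L, 2L)
  }
  if (any(unlist(sets[!missing]) >= n_state)) {
    stop("state outside declared range (0..", n_state - 1L, ")")
  }
  full <- bitwShiftL(1L, n_state) - 1L
  masks <- vapply(seq_along(sets), function(i) {
    if (missing[i]) return(full)
    m <- 0L
    for (k in sets[[i]]) m <- bitwOr(m, bitwShiftL(1L, k))
    m
  }, 0L)
  list(masks = masks, missing = missing, n_state = n_state)
}

# Sankoff down-pass; returns per-node cost rows (nodes x states) plus the
# postorder edge matrix and root id.  Handles polytomies and any cost matrix.
sankoff_down <- function(tree, masks, n_state, ordered) {
  nT <- length(tree$tip.label)
  nN <- nT + tree$Nnode
  cm <- cost_matrix(n_state, ordered)
  S <- matrix(0, nN, n_state)
  bits <- bitwShiftL(1L, 0:(n_state - 1L))
  for (i in seq_len(nT)) {
    S[i, ] <- ifelse(bitwAnd(masks[i], bits) != 0L, 0, INF_COST)
  }
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(po))) {
    p <- po[e, 1L]
    ch <- po[e, 2L]
    S[p, ] <- S[p, ] + apply(cm + S[ch, ], 2L, min)
  }
  list(S = S, edge_po = po, root = po[nrow(po), 1L], cost = cm)
}

sankoff_length <- function(tree, masks, n_state, ordered) {
  d <- sankoff_down(tree, masks, n_state, ordered)
  as.integer(round(min(d$S[d$root, ])))
}

# Down + up pass: per-node "rest of tree" costs U, per-edge child summaries D,
# and the per-edge minimum optimized length over all most-parsimonious
# reconstructions (used by the zero-length collapse rule and MPR sets).
sankoff_updown <- function(tree, masks, n_state, ordered) {
  d <- sankoff_down(tree, masks, n_state, ordered)
  S <- d$S
  cm <- d$cost
  po <- d$edge_po
  nN <- nrow(S)
  nE <- nrow(po)
  # D[e, j] = min_k cost(j, k) + S[child_e, k]
  D <- matrix(0, nE, n_state)
  for (e in seq_len(nE)) D[e, ] <- apply(cm + S[po[e, 2L], ], 2L, min)
  sumD <- matrix(0, nN, n_state)
  for (e in seq_len(nE)) sumD[po[e, 1L], ] <- sumD[po[e, 1L], ] + D[e, ]
  # U[v, i]: cost of everything outside v's subtree given v has state i;
  # reverse postorder visits parents before their children's edges
  U <- matrix(0, nN, n_state)
  for (e in rev(seq_len(nE))) {
    p <- po[e, 1L]
    ch <- po[e, 2L]
    Tp <- U[p, ] + sumD[p, ] - D[e, ]
    U[ch, ] <- apply(cm + Tp, 2L, min)
  }
  total <- min(S[d$root, ])
  edge_min <- numeric(nE)
  for (e in seq_len(nE)) {
    p <- po[e, 1L]
    ch <- po[e, 2L]
    Tp <- U[p, ] + sumD[p, ] - D[e, ]
    # minimum cost assigned to this edge among optimal joint states
    tot_ji <- outer(Tp, S[ch, ], "+") + cm
    edge_min[e] <- min(cm[tot_ji <= total + 1e-9])
  }
  list(S = S, U = U, edge_po = po, root = d$root, total = total,
       edge_min = edge_min, cost = cm)
}

# MPR state sets: states attainable at each node in some most-parsimonious
# reconstruction.
mpr_state_sets <- function(tree, masks, n_state, ordered) {
  ud <- sankoff_updown(tree, masks, n_state, ordered)
  lapply(seq_len(nrow(ud$S)), function(v) {
    which(abs(ud$S[v, ] + ud$U[v, ] - ud$total) < 0.5) - 1L
  })
}

prep_tree <- function(tree, taxa) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  if (!setequal(tree$tip.label, taxa)) {
    extra <- setdiff(tree$tip.label, taxa)
    lack <- setdiff(taxa, tree$tip.label)
    stop("leaf labels do not match matrix taxa",
         if (length(extra)) paste0("; not in matrix: ", paste(extra, collapse = ", ")),
         if (length(lack)) paste0("; missing from tree: ", paste(lack, collapse = ", ")))
  }
  tree
}

tree_is_binary_unrooted <- function(tree) {
  nT <- length(tree$tip.label)
  deg <- tabulate(c(tree$edge), nbins = nT + tree$Nnode)
  internal <- deg[(nT + 1L):(nT + tree$Nnode)]
  # rooted binary (one degree-2 root) or unrooted binary both qualify
  sum(internal == 2L) <= 1L && all(internal <= 3L)
}

#' Parsimony length of one character on a tree
#'
#' Minimum number of state changes over all internal-node assignments, with
#' unit costs for unordered characters and linear (Manhattan) costs for
#' ordered ones.  Missing cells constrain nothing; polymorphic cells are
#' uncertainty sets (any member may be assigned).
#'
#' @param tree A `phylo` tree (rooted or unrooted; polytomies allowed).
#' @param column Per-taxon states: a named character vector of tokens
#'   (`"0"`, `"{01}"`, `"?"`), a named list of integer state vectors, or a
#'   bare vector ordered like the tip labels.
#' @param ordered Additive character?
#' @param method `"auto"` uses the Fitch bitmask kernel where it applies
#'   (binary tree, unordered) and Sankoff otherwise; `"fitch"` / `"sankoff"`
#'   force a route.
#' @return Non-negative integer step count.
#' @export
character_length <- function(tree, column, ordered = FALSE,
                             method = c("auto", "fitch", "sankoff")) {
  method <- match.arg(method)
  if (length(tree$tip.label) < 2L) stop("tree must have at least 2 leaves")
  cm <- column_masks(column, tree$tip.label)
  use_fitch <- switch(method,
    auto = !ordered && tree_is_binary_unrooted(tree),
    fitch = TRUE,
    sankoff = FALSE
  )
  if (use_fitch) {
    if (ordered) stop("the Fitch route applies to unordered characters only")
    if (!tree_is_binary_unrooted(tree)) {
      stop("the Fitch route requires a binary tree")
    }
    nst <- phylo_to_nst(tree, tree$tip.label)
    post <- nst_postorder(nst, length(tree$tip.label))
    tm <- matrix(cm$masks, ncol = 1L)
    return(as.integer(fitch_counts(tm, post$child1, post$child2)))
  }
  sankoff_length(tree, cm$masks, cm$n_state, ordered)
}

#' Parsimony length of a tree for a whole matrix
#'
#' Sum of [character_length()] over all characters; invariant to rerooting
#' and to child order.
#'
#' @param tree A `phylo` whose tips equal the matrix taxa (set equality).
#' @param x A [char_matrix()].
#' @param per_character Return the per-character step vector instead of the
#'   total.
#' @return Integer total length S (or an integer vector of length `n_char`).
#' @export
tree_length <- function(tree, x, per_character = FALSE) {
  stopifnot(inherits(x, "char_matrix"))
  tree <- prep_tree(tree, x$taxa)
  ord_idx <- which(x$ordered)
  steps <- integer(x$n_char)
  tipmask <- x$cells[match(tree$tip.label, x$taxa), , drop = FALSE]
  unord <- setdiff(seq_len(x$n_char), ord_idx)
  if (length(unord) > 0L) {
    if (tree_is_binary_unrooted(tree)) {
      nst <- phylo_to_nst(tree, tree$tip.label)
      post <- nst_postorder(nst, length(tree$tip.label))
      steps[unord] <- fitch_counts(tipmask[, unord, drop = FALSE],
                                   post$child1, post$child2)
    } else {
      for (j in unord) {
        steps[j] <- sankoff_length(tree, tipmask[, j], x$n_state, FALSE)
      }
    }
  }
  for (j in ord_idx) {
    steps[j] <- sankoff_length(tree, tipmask[, j], x$n_state, TRUE)
  }
  if (per_character) steps else sum(steps)
}

# Bounds from bitmasks of the scored (non-missing) cells only.
char_bounds_masks <- function(masks, n_state, ordered) {
  if (length(masks) == 0L) return(c(m = 0L, g = 0L))
  sets <- lapply(masks, mask_to_states, n_state = n_state)
  observed <- sort(unique(unlist(sets)))
  if (length(observed) == 0L) return(c(m = 0L, g = 0L))
  if (!ordered) {
    # m: minimum hitting set over the cell state sets, minus one
    m <- NA_integer_
    for (size in seq_along(observed)) {
      combs <- utils::combn(observed, size, simplify = FALSE)
      hit <- vapply(combs, function(T) {
        all(vapply(sets, function(s) any(s %in% T), TRUE))
      }, TRUE)
      if (any(hit)) {
        m <- size - 1L
        break
      }
    }
    # g: scored cells minus the maximum attainable modal-state frequency
    freq <- vapply(observed, function(s) {
      sum(vapply(sets, function(x) s %in% x, TRUE))
    }, 0L)
    g <- length(sets) - max(freq)
  } else {
    # m: narrowest state window intersecting every cell set
    m <- NA_integer_
    for (width in 0:(max(observed) - min(observed))) {
      ok <- FALSE
      for (a in min(observed):(max(observed) - width)) {
        win <- a:(a + width)
        if (all(vapply(sets, function(s) any(s %in% win), TRUE))) {
          ok <- TRUE
          break
        }
      }
      if (ok) {
        m <- width
        break
      }
    }
    # g: best star-tree (median-state) length, ambiguity resolved cheapest
    g <- min(vapply(0:(n_state - 1L), function(ctr) {
      sum(vapply(sets, function(s) min(abs(s - ctr)), 0L))
    }, 0L))
  }
  c(m = as.integer(m), g = as.integer(g))
}

#' Minimum and maximum conceivable steps for a character
#'
#' `m` is the minimum length attainable on any tree; `g` the maximum (the
#' length on the completely unresolved star tree).  Ambiguous cells are
#' resolved to minimize each bound's defining quantity; missing and
#' inapplicable cells are excluded.  An all-missing column returns
#' `c(m = 0, g = 0)` with attribute `uninformative = TRUE`.
#'
#' @param column As in [character_length()]; unnamed input is taken as given.
#' @param ordered Additive character?
#' @param n_state Number of declared states (defaults to observed).
#' @return Named integer vector `c(m, g)`; attribute `uninformative` is TRUE
#'   when `g == m`.
#' @export
char_bounds <- function(column, ordered = FALSE, n_state = NULL) {
  nm <- names(column)
  taxa <- if (is.null(nm)) paste0("t", seq_along(column)) else nm
  cm <- column_masks(column, taxa, n_state)
  b <- char_bounds_masks(cm$masks[!cm$missing], cm$n_state, ordered)
  attr(b, "uninformative") <- b[["g"]] == b[["m"]]
  b
}

#' Ensemble homoplasy statistics on a tree
#'
#' Computes per-character minimum m, observed s and maximum g steps, and the
#' ensemble consistency index CI = M/S, homoplasy index HI = 1 - CI,
#' retention index RI = (G - S)/(G - M) and rescaled consistency index
#' RC = CI * RI, where M, S, G sum m, s, g over the included characters.
#' Parsimony-uninformative characters are included by default (the
#' convention under which CI + HI = 1 holds for the printed ensemble pair);
#' set `include_uninformative = FALSE` for the alternative convention.
#'
#' @param x A [char_matrix()].
#' @param tree A `phylo` scoring the matrix.
#' @param include_uninformative Include constant/autapomorphic characters in
#'   the ensemble sums.
#' @return A `homoplasy_stats` object: `$per_character` data frame (index, m,
#'   s, g, ci, ri) and `$ensemble` list (S, M, G, CI, HI, RI, RC).
#' @export
homoplasy_stats <- function(x, tree, include_uninformative = TRUE) {
  stopifnot(inherits(x, "char_matrix"))
  tree <- prep_tree(tree, x$taxa)
  s <- tree_length(tree, x, per_character = TRUE)
  mg <- t(vapply(seq_len(x$n_char), function(j) {
    char_bounds_masks(x$cells[x$flags[, j] == FLAG_NORMAL, j], x$n_state,
                      x$ordered[j])
  }, c(m = 0L, g = 0L)))
  informative <- mg[, "g"] > mg[, "m"]
  per <- data.frame(
    index = seq_len(x$n_char), m = mg[, "m"], s = s, g = mg[, "g"],
    ci = ifelse(s > 0, mg[, "m"] / s, NA_real_),
    ri = ifelse(mg[, "g"] > mg[, "m"],
                (mg[, "g"] - s) / (mg[, "g"] - mg[, "m"]), NA_real_),
    informative = informative
  )
  keep <- if (include_uninformative) rep(TRUE, x$n_char) else informative
  S <- sum(s[keep])
  M <- sum(mg[keep, "m"])
  G <- sum(mg[keep, "g"])
  if (S == 0) {
    ens <- list(S = 0L, M = M, G = G, CI = NA_real_, HI = NA_real_,
                RI = NA_real_, RC = NA_real_, no_variation = TRUE)
  } else {
    CI <- M / S
    RI <- if (G > M) (G - S) / (G - M) else NA_real_
    ens <- list(S = as.integer(S), M = as.integer(M), G = as.integer(G),
                CI = CI, HI = 1 - CI, RI = RI,
                RC = if (is.na(RI)) NA_real_ else CI * RI,
                no_variation = FALSE)
  }
  structure(
    list(per_character = per, ensemble = ens,
         include_uninformative = include_uninformative),
    class = "homoplasy_stats"
  )
}

#' @export
print.homoplasy_stats <- function(x, ...) {
  e <- x$ensemble
  if (isTRUE(e$no_variation)) {
    cat("homoplasy_stats: no variation (S = 0); indices undefined\n")
    return(invisible(x))
  }
  cat(sprintf("homoplasy_stats over %d characters (%s uninformative)\n",
              nrow(x$per_character),
              if (x$include_uninformative) "including" else "excluding"))
  cat(sprintf("  S = %d, M = %d, G = %d\n", e$S, e$M, e$G))
  cat(sprintf("  CI = %.4f  HI = %.4f  RI = %.4f  RC = %.4f\n",
              e$CI, e$HI, e$RI, e$RC))
  invisible(x)
}

#' Serialize a homoplasy report
#'
#' Writes the per-character table as TSV with the ensemble values in
#' commented footer lines, or the whole object as JSON.
#' @param x A `homoplasy_stats` object.
#' @param file Output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_homoplasy_stats <- function(x, file, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(list(per_character = x$per_character,
                              ensemble = x$ensemble[c("S", "M", "G", "CI",
                                                      "HI", "RI", "RC")]),
                         file, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    con <- file(file, "w")
    on.exit(close(con))
    utils::write.table(x$per_character, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    e <- x$ensemble
    writeLines(sprintf("# S=%d M=%d G=%d CI=%.6f HI=%.6f RI=%.6f RC=%.6f",
                       e$S, e$M, e$G, e$CI, e$HI, e$RI, e$RC), con)
  }
  invisible(file)
}
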