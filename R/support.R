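# Bremer decay indices by converse-constraint search: for each clade, find
# the shortest tree NOT containing it; the decay index is that length minus
# the unconstrained optimum.

#' Bremer decay index of one clade
#'
#' `L(not clade) - best_length`, where `L(not clade)` is the minimum length
#' over trees lacking the clade, found by a heuristic search in which every
#' candidate containing the clade is rejected.  Returns 0 immediately when
#' some most-parsimonious tree in `result` already lacks the clade.
#'
#' @param x A [char_matrix()].
#' @param clade Character vector of taxon names (a non-trivial bipartition:
#'   2..n-2 taxa).
#' @param config A [search_config()] for the constrained search.
#' @param best_length Unconstrained optimum; computed by a search when
#'   missing.
#' @param result Optional `search_result` holding the MPT set.
#' @param exact Use [exhaustive_search()] for the constrained optimum (small
#'   instances only).
#' @return Non-negative integer decay value.
#' @export
decay_index <- function(x, clade, config = search_config(),
                        best_length = NULL, result = NULL, exact = FALSE) {
  stopifnot(inherits(x, "char_matrix"))
  n <- length(x$taxa)
  clade <- as.character(clade)
  if (!all(clade %in% x$taxa)) {
    stop("clade contains unknown taxa: ",
         paste(setdiff(clade, x$taxa), collapse = ", "))
  }
  if (length(clade) < 2L || length(clade) > n - 2L) {
    stop("trivial bipartition: a clade must contain 2..n-2 taxa")
  }
  if (is.null(result) && is.null(best_length)) {
    result <- heuristic_search(x, config)
  }
  if (is.null(best_length)) best_length <- result$best_length
  if (!is.null(result)) {
    key <- split_key_from_taxa(clade, x$taxa)
    in_all <- all(vapply(result$trees, function(tr) {
      key %in% phylo_split_keys(tr)
    }, TRUE))
    if (!in_all) return(0L)
  }
  constrained <- if (exact) {
    exhaustive_search(x, config = config, forbidden_clade = clade)
  } else {
    heuristic_search(x, config, forbidden_clade = clade)
  }
  as.integer(constrained$best_length - best_length)
}

#' Decay indices for every clade of the strict consensus
#'
#' One record per internal bipartition of the strict consensus of the MPT
#' set; every consensus clade is present in all MPTs, so each decay value is
#' at least 1.
#'
#' @param x A [char_matrix()].
#' @param result A `search_result` with a non-empty tree set.
#' @param config A [search_config()] for the constrained searches.
#' @param exact Use exhaustive enumeration per clade (small instances).
#' @return A data frame with columns `clade` (comma-joined taxon names),
#'   `size` and `decay`, ordered by clade size.
#' @export
decay_table <- function(x, result, config = search_config(), exact = FALSE) {
  stopifnot(inherits(result, "search_result"), length(result$trees) >= 1L)
  cons <- strict_consensus(result$trees)
  keys <- phylo_split_keys(cons)
  records <- lapply(keys, function(k) {
    side <- strsplit(k, "|", fixed = TRUE)[[1L]]
    # report the side that forms the clade away from the first taxon
    d <- decay_index(x, side, config, best_length = result$best_length,
                     result = result, exact = exact)
    data.frame(clade = paste(sort(side), collapse = ","),
               size = length(side), decay = d)
  })
  out <- do.call(rbind, records)
  if (is.null(out)) {
    return(data.frame(clade = character(0), size = integer(0),
                      decay = integer(0)))
  }
  out[order(out$size, out$clade), , drop = FALSE]
}
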