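# Orchestration: full analysis (search -> homoplasy statistics -> strict
# consensus -> decay indices -> synapomorphies), the reduced rerun after
# taxon deletion, and the tail-evolution stage, with a provenance block so
# every reported number is recomputable from the logged seeds and inputs.

text_checksum <- function(txt) {
  v <- utf8ToInt(txt)
  sprintf("%d:%d:%d", length(v), sum(v),
          sum(v * (seq_along(v) %% 97L)) %% 2147483647L)
}

#' Read a flat key=value analysis configuration file
#'
#' Recognized keys: `matrix` (path), `format` (nexus/plain/tsv),
#' `replicates`, `seed`, `swap`, `maxtrees`, `collapse`, `steepest`,
#' `drop` (comma-separated taxa for the reduced rerun), `outgroup`,
#' `tail_table` (path), `decay` (true/false).  Lines starting with `#` are
#' comments.
#'
#' @param file Path to the configuration file.
#' @return A named list.
#' @export
read_analysis_config <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- list()
  for (p in kv) {
    if (length(p) < 2L) stop("malformed config line: ", paste(p, collapse = "="))
    out[[trimws(p[1L])]] <- trimws(paste(p[-1L], collapse = "="))
  }
  out
}

#' Run the full analysis pipeline
#'
#' Executes heuristic search, homoplasy statistics (on the first
#' most-parsimonious tree), strict consensus, the decay-index table and,
#' when an outgroup is given, synapomorphy lists for every consensus clade;
#' then repeats the search stages on the matrix with `drop` taxa deleted
#' (the reduced analysis); finally encodes and maps tail characters when
#' tail records are supplied.  Identical configuration and seed give an
#' identical report.
#'
#' @param x A [char_matrix()], or the path to a key=value configuration
#'   file (see [read_analysis_config()]) naming the matrix file.
#' @param search A [search_config()].
#' @param drop Taxa to delete for the reduced rerun (NULL = skip).
#' @param outgroup Outgroup taxon for rooting and synapomorphy mapping.
#' @param tail_records A `tail_records` data frame (or TRUE for the bundled
#'   table) to run the tail-evolution stage.
#' @param tail_tree Rooted `phylo` for tail mapping (default
#'   [coelurosaur_tree()]).
#' @param decay Compute the decay-index table (can be slow on large
#'   matrices).
#' @param exact_decay Use exhaustive enumeration in decay computations.
#' @return An `analysis_report`.
#' @export
run_analysis <- function(x, search = search_config(), drop = NULL,
                         outgroup = NULL, tail_records = NULL,
                         tail_tree = coelurosaur_tree(), decay = TRUE,
                         exact_decay = FALSE) {
  if (is.character(x) && length(x) == 1L) {
    cfg <- read_analysis_config(x)
    if (is.null(cfg$matrix)) stop("config must name a matrix file")
    dial <- matrix_dialect(cfg$format %||% "nexus")
    x <- parse_matrix(file = cfg$matrix, dialect = dial)
    num <- function(k, d) if (is.null(cfg[[k]])) d else as.numeric(cfg[[k]])
    search <- search_config(
      replicates = num("replicates", search$replicates),
      seed = num("seed", search$seed),
      swap = cfg$swap %||% search$swap,
      maxtrees = num("maxtrees", search$maxtrees),
      collapse = cfg$collapse %||% search$collapse,
      steepest = isTRUE(as.logical(cfg$steepest %||% search$steepest))
    )
    if (!is.null(cfg$drop)) drop <- trimws(strsplit(cfg$drop, ",")[[1L]])
    outgroup <- cfg$outgroup %||% outgroup
    if (!is.null(cfg$tail_table)) {
      tail_records <- parse_tail_table(file = cfg$tail_table)
    }
    if (!is.null(cfg$decay)) decay <- isTRUE(as.logical(cfg$decay))
  }
  stopifnot(inherits(x, "char_matrix"))
  if (isTRUE(tail_records)) tail_records <- tail_table()

  report <- list(provenance = list(
    seed = search$seed, config = search,
    matrix_checksum = text_checksum(write_matrix(x, matrix_dialect("tsv"))),
    drop = drop, outgroup = outgroup
  ))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(errorCondition(
        sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
        class = "caudotheca_stage_error", partial = report
      ))
    })
  }

  one_run <- function(mat) {
    res <- stage("search", heuristic_search(mat, search))
    stats <- stage("stats", homoplasy_stats(mat, res$trees[[1L]]))
    cons <- stage("consensus", strict_consensus(res$trees))
    dtab <- if (decay) {
      stage("decay", decay_table(mat, res, search, exact = exact_decay))
    } else NULL
    syn <- NULL
    if (!is.null(outgroup) && outgroup %in% mat$taxa) {
      syn <- stage("synapomorphies", {
        first <- res$trees[[1L]]
        rooted <- root_at_outgroup(first, outgroup)
        nT <- length(rooted$tip.label)
        keys <- phylo_split_keys(root_at_outgroup(cons, outgroup))
        clades <- lapply(keys, function(k) strsplit(k, "|", fixed = TRUE)[[1L]])
        clades <- Filter(function(cl) !(outgroup %in% cl), clades)
        out <- lapply(clades, function(cl) {
          tab <- synapomorphy_list(rooted, mat, cl)
          if (nrow(tab) > 0L) tab$clade <- paste(sort(cl), collapse = ",")
          tab
        })
        do.call(rbind, Filter(function(d) nrow(d) > 0L, out))
      })
    }
    list(best_length = res$best_length, n_mpt = res$n_mpt,
         n_binary = res$n_binary, result = res, stats = stats,
         consensus = cons, decay = dtab, synapomorphies = syn)
  }

  report$full <- one_run(x)
  if (!is.null(drop) && length(drop) > 0L) {
    reduced_matrix <- stage("prune", prune_taxa(x, drop))
    report$reduced <- one_run(reduced_matrix)
  }
  if (!is.null(tail_records) && !isFALSE(tail_records)) {
    report$tail <- stage("tail", {
      tm <- encode_tail_characters(tail_records)
      list(matrix = tm,
           changes = map_tail_changes(tail_tree, tm),
           classification = stats::setNames(
             classify_tail_condition(tail_records), tail_records$taxon
           ))
    })
  }
  structure(report, class = "analysis_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.analysis_report <- function(x, ...) {
  show_run <- function(run, label) {
    e <- run$stats$ensemble
    cat(sprintf("%s analysis: length %d, %d tree(s)\n", label,
                run$best_length, run$n_mpt))
    if (!isTRUE(e$no_variation)) {
      cat(sprintf("  CI = %.4f  HI = %.4f  RI = %.4f  RC = %.4f\n",
                  e$CI, e$HI, e$RI, e$RC))
    }
    if (!is.null(run$decay)) {
      cat(sprintf("  decay indices: %s\n",
                  paste(run$decay$decay, collapse = " ")))
    }
  }
  show_run(x$full, "Full")
  if (!is.null(x$reduced)) show_run(x$reduced, "Reduced")
  if (!is.null(x$tail)) {
    cat(sprintf("Tail mapping: %d branch change(s) across %d character(s)\n",
                nrow(x$tail$changes),
                length(unique(x$tail$changes$character))))
  }
  cat(sprintf("seed %d, %d replicates, %s swapping\n",
              x$provenance$seed, x$provenance$config$replicates,
              x$provenance$config$swap))
  invisible(x)
}
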