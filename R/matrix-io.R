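# Character-matrix container and I/O for discrete morphological data.
#
# Cells are state SETS stored as integer bitmasks (bit k <=> state k, states
# are 0-based integers matching single-character symbols).  Missing ("?") and
# inapplicable ("-") cells carry the full mask plus a flag, so scoring treats
# them as unconstrained while writers can reproduce the original token.

FLAG_NORMAL <- 0L
FLAG_MISSING <- 1L
FLAG_GAP <- 2L

#' Describe a character-matrix file dialect
#'
#' @param format One of `"nexus"` (DATA block), `"plain"`
#'   (PHYLIP-style header line, sequential or interleaved) or `"tsv"`
#'   (taxon name plus one tab-separated token per character).
#' @param missing_symbol Symbol for missing data (default `"?"`).
#' @param gap_symbol Symbol for gap/inapplicable cells (default `"-"`).
#' @param poly_open,poly_close Delimiters for polymorphic/uncertain cells.
#' @return A `matrix_dialect` object.
#' @export
matrix_dialect <- function(format = c("nexus", "plain", "tsv"),
                           missing_symbol = "?", gap_symbol = "-",
                           poly_open = "{", poly_close = "}") {
  format <- match.arg(format)
  if (identical(missing_symbol, gap_symbol)) {
    stop("missing_symbol and gap_symbol must differ")
  }
  structure(
    list(format = format, missing_symbol = missing_symbol,
         gap_symbol = gap_symbol, poly_open = poly_open,
         poly_close = poly_close),
    class = "matrix_dialect"
  )
}

#' Construct a character matrix
#'
#' @param tokens Character matrix of cell tokens (rows = taxa), e.g. `"0"`,
#'   `"{01}"`, `"?"`, `"-"`; or an integer matrix of single states.
#' @param taxa Taxon names (defaults to rownames).
#' @param symbols Declared state symbols, single characters in state order
#'   (state k is `symbols[k + 1]`).  Defaults to the digits observed.
#' @param ordered Logical scalar or vector: additive (ordered) characters.
#' @param definitions Optional data frame of character definitions with
#'   columns `index`, `description` (and optionally `ordered`).
#' @param gap_as_state Treat `"-"` as an extra state rather than as missing.
#' @param dialect A [matrix_dialect()] controlling token syntax.
#' @return A `char_matrix` object.
#' @export
char_matrix <- function(tokens, taxa = rownames(tokens), symbols = NULL,
                        ordered = FALSE, definitions = NULL,
                        gap_as_state = FALSE,
                        dialect = matrix_dialect("tsv")) {
  if (is.numeric(tokens)) {
    mode(tokens) <- "integer"
    tokens <- matrix(as.character(tokens), nrow(tokens), ncol(tokens),
                     dimnames = dimnames(tokens))
  }
  if (is.null(taxa)) stop("taxon names are required")
  taxa <- as.character(taxa)
  if (any(!nzchar(taxa)) || anyNA(taxa)) stop("taxon names must be non-empty")
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon name: ", taxa[duplicated(taxa)][1L])
  }
  if (nrow(tokens) != length(taxa)) stop("one row of cells per taxon required")
  n_char <- ncol(tokens)
  if (n_char < 1L) stop("matrix must have at least one character")
  if (is.null(symbols)) {
    used <- unique(unlist(strsplit(as.vector(tokens), "", fixed = TRUE)))
    used <- setdiff(used, c(dialect$missing_symbol, dialect$gap_symbol,
                            dialect$poly_open, dialect$poly_close, "(", ")"))
    symbols <- intersect(as.character(0:9), used)
    if (length(symbols) == 0L) symbols <- "0"
  }
  if (any(nchar(symbols) != 1L)) stop("state symbols must be single characters")
  if (gap_as_state) symbols <- c(symbols, dialect$gap_symbol)
  n_state <- length(symbols)
  if (n_state > 30L) stop("at most 30 states are supported")
  full <- bitwShiftL(1L, n_state) - 1L

  cells <- matrix(0L, length(taxa), n_char)
  flags <- matrix(FLAG_NORMAL, length(taxa), n_char)
  for (i in seq_along(taxa)) {
    for (j in seq_len(n_char)) {
      tok <- tokens[i, j]
      parsed <- parse_cell_token(tok, symbols, dialect, gap_as_state,
                                 taxon = taxa[i], char_index = j)
      cells[i, j] <- parsed$mask
      flags[i, j] <- parsed$flag
    }
  }
  ordered <- rep_len(as.logical(ordered), n_char)
  if (!is.null(definitions)) {
    stopifnot(is.data.frame(definitions), "index" %in% names(definitions))
    if (anyDuplicated(definitions$index) ||
        !identical(sort(as.integer(definitions$index)), seq_len(nrow(definitions)))) {
      stop("definition indices must be unique and contiguous from 1")
    }
    if ("ordered" %in% names(definitions)) {
      ordered[definitions$index] <- as.logical(definitions$ordered)
    }
  }
  structure(
    list(taxa = taxa, cells = cells, flags = flags, symbols = symbols,
         n_state = n_state, n_char = n_char, ordered = ordered,
         definitions = definitions, gap_as_state = gap_as_state,
         full_mask = full),
    class = "char_matrix"
  )
}

parse_cell_token <- function(tok, symbols, dialect, gap_as_state,
                             taxon = NA, char_index = NA) {
  n_state <- length(symbols)
  full <- bitwShiftL(1L, n_state) - 1L
  if (is.na(tok) || tok == dialect$missing_symbol) {
    return(list(mask = full, flag = FLAG_MISSING))
  }
  if (tok == dialect$gap_symbol) {
    if (gap_as_state) {
      return(list(mask = bitwShiftL(1L, n_state - 1L), flag = FLAG_NORMAL))
    }
    return(list(mask = full, flag = FLAG_GAP))
  }
  body <- tok
  for (d in c(dialect$poly_open, dialect$poly_close, "(", ")")) {
    body <- gsub(d, "", body, fixed = TRUE)
  }
  chars <- strsplit(body, "", fixed = TRUE)[[1L]]
  idx <- match(chars, symbols)
  if (anyNA(idx) || length(idx) == 0L) {
    stop(sprintf("undeclared state symbol '%s' (taxon %s, character %d)",
                 tok, taxon, char_index), call. = FALSE)
  }
  mask <- 0L
  for (k in idx) mask <- bitwOr(mask, bitwShiftL(1L, k - 1L))
  list(mask = mask, flag = FLAG_NORMAL)
}

mask_to_states <- function(mask, n_state) {
  k <- 0:(n_state - 1L)
  k[bitwAnd(mask, bitwShiftL(1L, k)) != 0L]
}

#' States present in one cell
#'
#' Returns the cell's state set as 0-based integers; missing and inapplicable
#' cells return the full declared state set.
#' @param x A `char_matrix`.
#' @param taxon Taxon name or row index.
#' @param char Character index (1-based).
#' @export
cell_states <- function(x, taxon, char) {
  i <- if (is.character(taxon)) match(taxon, x$taxa) else as.integer(taxon)
  if (is.na(i)) stop("unknown taxon: ", taxon)
  mask_to_states(x$cells[i, char], x$n_state)
}

#' @export
print.char_matrix <- function(x, ...) {
  cat(sprintf("char_matrix: %d taxa x %d characters, %d declared states (%s)\n",
              length(x$taxa), x$n_char, x$n_state,
              paste(x$symbols, collapse = "")))
  n_ord <- sum(x$ordered)
  if (n_ord > 0L) cat(sprintf("  %d ordered (additive) characters\n", n_ord))
  n_mis <- sum(x$flags != FLAG_NORMAL)
  cat(sprintf("  %d missing/inapplicable cells (%.1f%%)\n", n_mis,
              100 * n_mis / length(x$flags)))
  invisible(x)
}

#' @export
dim.char_matrix <- function(x) c(length(x$taxa), x$n_char)

# Tokens for writing -------------------------------------------------------

cell_token <- function(mask, flag, symbols, dialect) {
  if (flag == FLAG_MISSING) return(dialect$missing_symbol)
  if (flag == FLAG_GAP) return(dialect$gap_symbol)
  st <- mask_to_states(mask, length(symbols))
  if (length(st) == 1L) return(symbols[st + 1L])
  paste0(dialect$poly_open, paste(symbols[st + 1L], collapse = ""),
         dialect$poly_close)
}

#' Parse a character matrix from text
#'
#' Reads NEXUS DATA/CHARACTERS blocks (DIMENSIONS, FORMAT with
#' SYMBOLS/MISSING/GAP, MATRIX, optional ASSUMPTIONS TYPESET with `ord:`
#' ranges), PHYLIP-style plain text (sequential or interleaved), or TSV rows
#' of tokens.  Polymorphic cells may use `{..}` or `(..)`; `?` parses to the
#' full state set and `-` to inapplicable (scored as missing unless
#' `gap_as_state`).
#'
#' @param text The file content as a single string or character vector of
#'   lines; alternatively use `file`.
#' @param dialect A [matrix_dialect()]; the format field selects the parser.
#' @param file Path to read instead of `text`.
#' @param gap_as_state Treat `-` as an extra state.
#' @return A [char_matrix()].
#' @export
parse_matrix <- function(text = NULL, dialect = matrix_dialect("nexus"),
                         file = NULL, gap_as_state = FALSE) {
  if (!is.null(file)) text <- readLines(file, warn = FALSE)
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  }
  switch(dialect$format,
    nexus = parse_matrix_nexus(text, dialect, gap_as_state),
    plain = parse_matrix_plain(text, dialect, gap_as_state),
    tsv = parse_matrix_tsv(text, dialect, gap_as_state)
  )
}

tokenize_row <- function(s, dialect, taxon, n_expected = NULL) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  toks <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t")) {
      i <- i + 1L
    } else if (ch %in% c(dialect$poly_open, "(")) {
      close <- if (ch == "(") ")" else dialect$poly_close
      j <- i + 1L
      while (j <= length(chars) && chars[j] != close) j <- j + 1L
      if (j > length(chars)) {
        stop(sprintf("unterminated polymorphism token (taxon %s)", taxon),
             call. = FALSE)
      }
      toks <- c(toks, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else {
      toks <- c(toks, ch)
      i <- i + 1L
    }
  }
  toks
}

check_dims <- function(tok_list, taxa, n_char = NULL) {
  lens <- lengths(tok_list)
  if (is.null(n_char)) n_char <- lens[1L]
  bad <- which(lens != n_char)
  if (length(bad) > 0L) {
    stop(sprintf("row for taxon '%s' has %d cells, expected %d",
                 taxa[bad[1L]], lens[bad[1L]], n_char), call. = FALSE)
  }
  n_char
}

parse_matrix_tsv <- function(lines, dialect, gap_as_state) {
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty matrix text")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  taxa <- vapply(parts, `[[`, "", 1L)
  toks <- lapply(parts, function(p) {
    unlist(lapply(p[-1L], tokenize_row, dialect = dialect, taxon = p[1L]),
           use.names = FALSE)
  })
  n_char <- check_dims(toks, taxa)
  mat <- do.call(rbind, toks)
  char_matrix(mat, taxa = taxa, dialect = dialect, gap_as_state = gap_as_state)
}

parse_matrix_plain <- function(lines, dialect, gap_as_state) {
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1L]), "[[:space:]]+")[[1L]]
  if (length(hdr) < 2L || anyNA(suppressWarnings(as.integer(hdr[1:2])))) {
    stop("plain format requires a 'ntax nchar' header line")
  }
  ntax <- as.integer(hdr[1L])
  nchr <- as.integer(hdr[2L])
  body <- lines[-1L]
  taxa <- character(0)
  toks <- list()
  for (ln in body) {
    m <- regmatches(ln, regexpr("^[[:space:]]*[^[:space:]]+", ln))
    name <- trimws(m)
    rest <- sub("^[[:space:]]*[^[:space:]]+", "", ln)
    row <- tokenize_row(rest, dialect, name)
    at <- match(name, taxa)
    if (is.na(at)) {
      if (length(taxa) == ntax) {
        stop("more taxa than declared in header: ", name)
      }
      taxa <- c(taxa, name)
      toks[[length(toks) + 1L]] <- row
    } else {
      toks[[at]] <- c(toks[[at]], row)   # interleaved continuation
    }
  }
  if (length(taxa) != ntax) {
    stop(sprintf("declared %d taxa but found %d", ntax, length(taxa)))
  }
  check_dims(toks, taxa, nchr)
  mat <- do.call(rbind, toks)
  char_matrix(mat, taxa = taxa, dialect = dialect, gap_as_state = gap_as_state)
}

strip_nexus_comments <- function(txt) gsub("\\[[^]]*\\]", "", txt)

parse_matrix_nexus <- function(lines, dialect, gap_as_state) {
  txt <- strip_nexus_comments(paste(lines, collapse = "\n"))
  up <- toupper(txt)
  beg <- regexpr("BEGIN\\s+(DATA|CHARACTERS)\\s*;", up)
  if (beg < 0L) stop("no DATA or CHARACTERS block found")
  endm <- regexpr("\\bEND\\s*;", substring(up, beg))
  block <- substring(txt, beg, beg + endm + attr(endm, "match.length"))
  upb <- toupper(block)

  grab <- function(pattern) {
    m <- regexpr(pattern, upb, perl = TRUE)
    if (m < 0L) return(NULL)
    regmatches(block, m)
  }
  dims <- grab("DIMENSIONS[^;]*;")
  if (is.null(dims)) stop("missing DIMENSIONS command")
  ntax <- as.integer(sub(".*NTAX\\s*=\\s*(\\d+).*", "\\1", toupper(dims)))
  nchr <- as.integer(sub(".*NCHAR\\s*=\\s*(\\d+).*", "\\1", toupper(dims)))

  fmt <- grab("FORMAT[^;]*;")
  symbols <- NULL
  missing_symbol <- dialect$missing_symbol
  gap_symbol <- dialect$gap_symbol
  if (!is.null(fmt)) {
    sm <- regmatches(fmt, regexpr('SYMBOLS\\s*=\\s*"[^"]*"', toupper(fmt)))
    if (length(sm) > 0L) {
      raw <- sub('.*"([^"]*)".*', "\\1",
                 regmatches(fmt, regexpr('[Ss][Yy][Mm][Bb][Oo][Ll][Ss]\\s*=\\s*"[^"]*"', fmt)))
      symbols <- setdiff(strsplit(raw, "")[[1L]], " ")
    }
    mm <- regmatches(fmt, regexpr("[Mm][Ii][Ss][Ss][Ii][Nn][Gg]\\s*=\\s*\\S", fmt))
    if (length(mm) > 0L) missing_symbol <- substring(mm, nchar(mm))
    gm <- regmatches(fmt, regexpr("[Gg][Aa][Pp]\\s*=\\s*\\S", fmt))
    if (length(gm) > 0L) gap_symbol <- substring(gm, nchar(gm))
  }
  dialect2 <- matrix_dialect("nexus", missing_symbol, gap_symbol,
                             dialect$poly_open, dialect$poly_close)

  mstart <- regexpr("MATRIX", upb)
  if (mstart < 0L) stop("missing MATRIX command")
  rest <- substring(block, mstart + 6L)
  msemi <- regexpr(";", rest, fixed = TRUE)
  body <- substring(rest, 1L, msemi - 1L)
  rows <- strsplit(body, "\n", fixed = TRUE)[[1L]]
  rows <- rows[nzchar(trimws(rows))]
  taxa <- character(0)
  toks <- list()
  for (ln in rows) {
    ln <- trimws(ln)
    if (startsWith(ln, "'")) {
      close <- regexpr("'", substring(ln, 2L), fixed = TRUE)
      name <- substring(ln, 2L, close)
      rest_ln <- substring(ln, close + 2L)
    } else {
      name <- sub("[[:space:]].*$", "", ln)
      rest_ln <- sub("^[^[:space:]]+", "", ln)
    }
    row <- tokenize_row(rest_ln, dialect2, name)
    at <- match(name, taxa)
    if (is.na(at)) {
      taxa <- c(taxa, name)
      toks[[length(toks) + 1L]] <- row
    } else {
      toks[[at]] <- c(toks[[at]], row)
    }
  }
  if (!is.na(ntax) && length(taxa) != ntax) {
    stop(sprintf("declared NTAX=%d but found %d taxa", ntax, length(taxa)))
  }
  check_dims(toks, taxa, if (is.na(nchr)) NULL else nchr)
  mat <- do.call(rbind, toks)

  # ordered (additive) characters from an ASSUMPTIONS TYPESET, if present
  ordered <- FALSE
  am <- regexpr("(?s)BEGIN\\s+ASSUMPTIONS\\s*;.*?END\\s*;", up, perl = TRUE)
  if (am > 0L) {
    ab <- regmatches(txt, am)
    ts <- regmatches(ab, regexpr("[Tt][Yy][Pp][Ee][Ss][Ee][Tt][^;]*;", ab))
    if (length(ts) > 0L) {
      om <- regmatches(ts, regexpr("[Oo][Rr][Dd]\\s*:[^,;]*", ts))
      if (length(om) > 0L) {
        spec <- sub(".*:", "", om)
        ordered <- rep(FALSE, ncol(mat))
        ordered[parse_index_ranges(spec)] <- TRUE
      }
    }
  }
  char_matrix(mat, taxa = taxa, symbols = symbols, ordered = ordered,
              dialect = dialect2, gap_as_state = gap_as_state)
}

parse_index_ranges <- function(spec) {
  parts <- strsplit(trimws(spec), "[[:space:]]+")[[1L]]
  out <- integer(0)
  for (p in parts) {
    if (grepl("-", p, fixed = TRUE)) {
      ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1L]])
      out <- c(out, ab[1L]:ab[2L])
    } else {
      out <- c(out, as.integer(p))
    }
  }
  out
}

#' Write a character matrix to text
#'
#' The emitted text re-parses to a cell-identical matrix: taxa in stored
#' order, characters 1..n, `?`/`-` and polymorphism tokens preserved.
#'
#' @param x A [char_matrix()].
#' @param dialect Output [matrix_dialect()].
#' @param file Optional path; when given the text is also written there.
#' @return The text, invisibly when `file` is given.
#' @export
write_matrix <- function(x, dialect = matrix_dialect("nexus"), file = NULL) {
  stopifnot(inherits(x, "char_matrix"))
  if (length(x$taxa) == 0L) stop("refusing to write a matrix with no taxa")
  if (any(nchar(x$symbols) != 1L)) {
    stop("state labels not representable in a single-symbol alphabet")
  }
  tok <- matrix("", length(x$taxa), x$n_char)
  for (i in seq_along(x$taxa)) {
    for (j in seq_len(x$n_char)) {
      tok[i, j] <- cell_token(x$cells[i, j], x$flags[i, j], x$symbols, dialect)
    }
  }
  name_w <- max(nchar(x$taxa))
  out <- switch(dialect$format,
    tsv = vapply(seq_along(x$taxa), function(i) {
      paste(c(x$taxa[i], tok[i, ]), collapse = "\t")
    }, ""),
    plain = c(
      paste(length(x$taxa), x$n_char),
      vapply(seq_along(x$taxa), function(i) {
        sprintf("%-*s  %s", name_w, x$taxa[i], paste(tok[i, ], collapse = ""))
      }, "")
    ),
    nexus = {
      body <- vapply(seq_along(x$taxa), function(i) {
        sprintf("    %-*s  %s", name_w, x$taxa[i], paste(tok[i, ], collapse = ""))
      }, "")
      hdr <- c(
        "#NEXUS", "",
        "BEGIN DATA;",
        sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(x$taxa), x$n_char),
        sprintf('  FORMAT SYMBOLS="%s" MISSING=%s GAP=%s;',
                paste(x$symbols, collapse = " "), dialect$missing_symbol,
                dialect$gap_symbol),
        "  MATRIX"
      )
      tail <- c("  ;", "END;")
      ord <- which(x$ordered)
      assum <- if (length(ord) > 0L) {
        c("", "BEGIN ASSUMPTIONS;",
          sprintf("  TYPESET * default = ord: %s;", paste(ord, collapse = " ")),
          "END;")
      } else character(0)
      c(hdr, body, tail, assum)
    }
  )
  text <- paste(out, collapse = "\n")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(text))
  }
  text
}

#' Drop taxa from a matrix
#'
#' Removes the named rows and keeps all characters, as in a reduced analysis
#' after deletion of fragmentary terminals.  Characters rendered constant or
#' otherwise parsimony-uninformative by the deletion are retained and flagged
#' in the `"pruned_uninformative"` attribute.
#'
#' @param x A [char_matrix()].
#' @param drop Character vector of taxon names to remove (may be empty).
#' @return A [char_matrix()] with `length(drop)` fewer rows.
#' @export
prune_taxa <- function(x, drop) {
  stopifnot(inherits(x, "char_matrix"))
  if (length(drop) == 0L) return(x)
  miss <- setdiff(drop, x$taxa)
  if (length(miss) > 0L) {
    stop("unknown taxon name: ", paste(miss, collapse = ", "))
  }
  keep <- !(x$taxa %in% drop)
  out <- x
  out$taxa <- x$taxa[keep]
  out$cells <- x$cells[keep, , drop = FALSE]
  out$flags <- x$flags[keep, , drop = FALSE]
  newly <- which(vapply(seq_len(out$n_char), function(j) {
    !char_is_informative(out, j) && char_is_informative(x, j)
  }, TRUE))
  attr(out, "pruned_uninformative") <- newly
  out
}

# A character is parsimony-informative iff its maximum conceivable length
# exceeds its minimum (constant and autapomorphic characters fail this).
char_is_informative <- function(x, j) {
  b <- char_bounds_masks(x$cells[x$flags[, j] == FLAG_NORMAL, j, drop = TRUE],
                         x$n_state, x$ordered[j])
  b[2L] > b[1L]
}
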