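# NEXUS CHARACTERS/DATA block reader and writer for standard (discrete
# morphological) data.  Character metadata round-trips through an ASSUMPTIONS
# block (TYPESET for additivity, EXSET for excluded characters, WTSET for
# weights), all with 1-based indices as is conventional in NEXUS.

nexus_strip_comments <- function(text) gsub("\\[[^]]*\\]", " ", text)

nexus_index_list <- function(s) {
  # "1 3-5 8" -> c(1,3,4,5,8)
  tokens <- strsplit(trimws(s), "[[:space:],]+")[[1]]
  out <- integer(0)
  for (tk in tokens) {
    if (grepl("^[0-9]+-[0-9]+$", tk)) {
      ab <- as.integer(strsplit(tk, "-")[[1]])
      out <- c(out, seq(ab[1], ab[2]))
    } else if (nzchar(tk)) {
      out <- c(out, as.integer(tk))
    }
  }
  out
}

#' Parse a NEXUS character matrix
#'
#' Reads the first CHARACTERS or DATA block.  Cell semantics match
#' [parse_tnt]: the FORMAT line's MISSING symbol maps to missing, GAP to
#' inapplicable, and parenthesised or bracketed groups to polymorphisms.
#' An ASSUMPTIONS block, if present, sets character ordering (TYPESET
#' `ord`/`unord`), exclusion (EXSET), and weights (WTSET).
#'
#' @param text NEXUS file content as a string or vector of lines.
#' @return a [character_matrix].
#' @export
parse_nexus <- function(text) {
  text <- paste(text, collapse = "\n")
  text <- nexus_strip_comments(text)
  if (!grepl("#NEXUS", text, ignore.case = TRUE))
    stop("not a NEXUS file (missing #NEXUS header)", call. = FALSE)
  block_re <- "(?is)BEGIN[[:space:]]+(CHARACTERS|DATA)[[:space:]]*;(.*?)END[[:space:]]*;"
  bm <- regmatches(text, regexpr(block_re, text, perl = TRUE))
  if (!length(bm)) stop("no CHARACTERS or DATA block", call. = FALSE)
  block <- bm

  dim_m <- regmatches(block, regexpr("(?i)DIMENSIONS[^;]*;", block, perl = TRUE))
  if (!length(dim_m)) stop("missing DIMENSIONS command", call. = FALSE)
  ntax_m <- regmatches(dim_m, regexpr("(?i)NTAX[[:space:]]*=[[:space:]]*[0-9]+",
                                      dim_m, perl = TRUE))
  nchar_m <- regmatches(dim_m, regexpr("(?i)NCHAR[[:space:]]*=[[:space:]]*[0-9]+",
                                       dim_m, perl = TRUE))
  if (!length(ntax_m) || !length(nchar_m))
    stop("DIMENSIONS must declare NTAX and NCHAR", call. = FALSE)
  n_tax <- as.integer(sub(".*=", "", ntax_m))
  n_char <- as.integer(sub(".*=", "", nchar_m))

  missing_sym <- "?"; gap_sym <- "-"; symbols <- NULL
  fmt_m <- regmatches(block, regexpr("(?i)FORMAT[^;]*;", block, perl = TRUE))
  if (length(fmt_m)) {
    ms <- regmatches(fmt_m, regexpr("(?i)MISSING[[:space:]]*=[[:space:]]*\\S",
                                    fmt_m, perl = TRUE))
    if (length(ms)) missing_sym <- substring(ms, nchar(ms))
    gs <- regmatches(fmt_m, regexpr("(?i)GAP[[:space:]]*=[[:space:]]*\\S",
                                    fmt_m, perl = TRUE))
    if (length(gs)) gap_sym <- substring(gs, nchar(gs))
    sy <- regmatches(fmt_m, regexpr('(?i)SYMBOLS[[:space:]]*=[[:space:]]*"[^"]*"',
                                    fmt_m, perl = TRUE))
    if (length(sy)) {
      inner <- sub('"$', "", sub('^[^"]*"', "", sy))
      symbols <- strsplit(gsub("[[:space:]]", "", inner), "")[[1]]
    }
  }

  mat_m <- regexpr("(?is)MATRIX(.*?);", block, perl = TRUE)
  if (mat_m < 0) stop("missing MATRIX command", call. = FALSE)
  mat_txt <- substring(block, mat_m + 6, mat_m + attr(mat_m, "match.length") - 2)
  lines <- trimws(strsplit(mat_txt, "\n")[[1]])
  lines <- lines[nzchar(lines)]

  sym_state <- function(ch, where) {
    if (!is.null(symbols)) {
      i <- match(ch, symbols)
      if (is.na(i))
        stop(sprintf("symbol '%s' outside declared SYMBOLS in %s", ch, where),
             call. = FALSE)
      return(i - 1L)
    }
    st <- tnt_symbol_to_state(ch)
    if (is.na(st))
      stop(sprintf("unknown state symbol '%s' in %s", ch, where), call. = FALSE)
    st
  }

  parse_row <- function(s, where) {
    chars <- strsplit(gsub("[[:space:]]", "", s), "")[[1]]
    out <- integer(0)
    i <- 1L
    while (i <= length(chars)) {
      ch <- chars[i]
      if (ch == missing_sym) {
        out <- c(out, NA_integer_)
      } else if (ch == gap_sym) {
        out <- c(out, CM_INAPPLICABLE)
      } else if (ch %in% c("(", "{")) {
        close <- if (ch == "(") ")" else "}"
        j <- i + 1L; sts <- integer(0)
        while (j <= length(chars) && chars[j] != close) {
          sts <- c(sts, sym_state(chars[j], where)); j <- j + 1L
        }
        if (j > length(chars) || !length(sts))
          stop("malformed polymorphism in ", where, call. = FALSE)
        out <- c(out, mask_from_states(unique(sts)))
        i <- j
      } else {
        out <- c(out, mask_from_states(sym_state(ch, where)))
      }
      i <- i + 1L
    }
    out
  }

  taxa <- character(0); rows <- list()
  for (ln in lines) {
    nm <- regmatches(ln, regexpr("^'[^']+'|^[^[:space:]]+", ln))
    states_text <- sub("^'[^']+'|^[^[:space:]]+", "", ln)
    nm <- gsub("^'|'$", "", nm)
    cells <- parse_row(states_text, sprintf("row '%s'", nm))
    if (nm %in% taxa) {
      i <- match(nm, taxa)
      rows[[i]] <- c(rows[[i]], cells)
    } else {
      taxa <- c(taxa, nm)
      rows[[length(rows) + 1L]] <- cells
    }
  }
  if (length(taxa) != n_tax)
    stop(sprintf("declared NTAX=%d but found %d taxa", n_tax, length(taxa)),
         call. = FALSE)
  lens <- vapply(rows, length, integer(1))
  if (any(lens != n_char))
    stop(sprintf("taxon '%s': declared NCHAR=%d but row has %d",
                 taxa[which(lens != n_char)[1]], n_char,
                 lens[lens != n_char][1]), call. = FALSE)
  meta <- default_char_meta(n_char, source_label = "nexus")

  asm <- regmatches(text, regexpr(
    "(?is)BEGIN[[:space:]]+ASSUMPTIONS[[:space:]]*;(.*?)END[[:space:]]*;",
    text, perl = TRUE))
  if (length(asm)) {
    ts <- regmatches(asm, regexpr("(?i)TYPESET[^;]*;", asm, perl = TRUE))
    if (length(ts)) {
      body <- sub(".*=", "", sub(";$", "", ts))
      for (part in strsplit(body, ",")[[1]]) {
        kv <- strsplit(part, ":")[[1]]
        if (length(kv) == 2) {
          idx <- nexus_index_list(kv[2])
          if (grepl("(?i)^\\s*ord\\s*$", kv[1], perl = TRUE))
            meta$ordered[idx] <- TRUE
        }
      }
    }
    ex <- regmatches(asm, regexpr("(?i)EXSET[^;]*;", asm, perl = TRUE))
    if (length(ex))
      meta$active[nexus_index_list(sub(".*=", "", sub(";$", "", ex)))] <- FALSE
    ws <- regmatches(asm, regexpr("(?i)WTSET[^;]*;", asm, perl = TRUE))
    if (length(ws)) {
      body <- sub(".*=", "", sub(";$", "", ws))
      for (part in strsplit(body, ",")[[1]]) {
        kv <- strsplit(part, ":")[[1]]
        if (length(kv) == 2)
          meta$weight[nexus_index_list(kv[2])] <- as.numeric(trimws(kv[1]))
      }
    }
  }
  character_matrix(taxa, do.call(rbind, rows), meta)
}

#' Write a character matrix in NEXUS format
#'
#' Emits a DATA block (standard datatype, `MISSING=?`, `GAP=-`) plus an
#' ASSUMPTIONS block when any character metadata departs from the default, so
#' that `parse_nexus(write_nexus(m))` reproduces `m`.
#'
#' @param m a [character_matrix].
#' @return a single NEXUS-format string.
#' @export
write_nexus <- function(m) {
  max_state <- 0L
  for (mask in m$cells) {
    if (!is.na(mask) && mask != CM_INAPPLICABLE)
      max_state <- max(max_state, max(states_from_mask(mask)))
  }
  symbols <- as.character(TNT_SYMBOLS[seq_len(max_state + 1L)])
  cell_txt <- function(mask) {
    if (is.na(mask)) return("?")
    if (mask == CM_INAPPLICABLE) return("-")
    sts <- states_from_mask(mask)
    syms <- as.character(TNT_SYMBOLS[sts + 1L])
    if (length(sts) == 1L) syms else paste0("(", paste(syms, collapse = ""), ")")
  }
  rows <- vapply(seq_along(m$taxa), function(i) {
    paste0("    ", gsub("[[:space:]]", "_", m$taxa[i]), "  ",
           paste(vapply(m$cells[i, ], cell_txt, character(1)), collapse = ""))
  }, character(1))
  out <- c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(m$taxa), m$n_char),
    sprintf('  FORMAT DATATYPE=STANDARD MISSING=? GAP=- SYMBOLS="%s";',
            paste(symbols, collapse = " ")),
    "  MATRIX", rows, "  ;", "END;"
  )
  meta <- m$char_meta
  asm <- character(0)
  if (any(meta$ordered))
    asm <- c(asm, sprintf("  TYPESET * default = ord: %s;",
                          paste(which(meta$ordered), collapse = " ")))
  if (any(!meta$active))
    asm <- c(asm, sprintf("  EXSET * default = %s;",
                          paste(which(!meta$active), collapse = " ")))
  if (any(meta$weight != 1)) {
    parts <- vapply(unique(meta$weight[meta$weight != 1]), function(w) {
      sprintf("%s: %s", format(w), paste(which(meta$weight == w), collapse = " "))
    }, character(1))
    asm <- c(asm, sprintf("  WTSET * default = %s;", paste(parts, collapse = ", ")))
  }
  if (length(asm))
    out <- c(out, "BEGIN ASSUMPTIONS;", asm, "END;")
  paste(out, collapse = "\n")
}
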