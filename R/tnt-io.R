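# TNT xread dialect.  Dimensions line is "nchar ntax" (TNT order); state
# tokens are 0-9 and A-U (states 10..30), '?' missing, '-' inapplicable,
# bracketed groups for polymorphism.  ccode commands use TNT's 0-based
# character indices; everything user-facing in this package is 1-based.

TNT_SYMBOLS <- c(0:9, LETTERS[1:21]) # state s printed as TNT_SYMBOLS[s+1]

tnt_symbol_to_state <- function(ch) {
  i <- match(ch, as.character(TNT_SYMBOLS))
  if (is.na(i)) NA_integer_ else i - 1L
}

parse_state_tokens <- function(s, where) {
  s <- gsub("[[:space:]]", "", s)
  chars <- strsplit(s, "")[[1]]
  out <- integer(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "?") {
      out <- c(out, NA_integer_)
    } else if (ch == "-") {
      out <- c(out, CM_INAPPLICABLE)
    } else if (ch == "[" || ch == "{") {
      close <- if (ch == "[") "]" else "}"
      j <- i + 1L
      states <- integer(0)
      while (j <= length(chars) && chars[j] != close) {
        st <- tnt_symbol_to_state(chars[j])
        if (is.na(st))
          stop(sprintf("unknown state token '%s' in %s", chars[j], where),
               call. = FALSE)
        states <- c(states, st)
        j <- j + 1L
      }
      if (j > length(chars))
        stop(sprintf("unclosed polymorphism bracket in %s", where),
             call. = FALSE)
      if (!length(states))
        stop(sprintf("empty polymorphism in %s", where), call. = FALSE)
      out <- c(out, mask_from_states(unique(states)))
      i <- j
    } else {
      st <- tnt_symbol_to_state(ch)
      if (is.na(st))
        stop(sprintf("unknown state token '%s' in %s", ch, where),
             call. = FALSE)
      out <- c(out, mask_from_states(st))
    }
    i <- i + 1L
  }
  out
}

# Expand TNT index tokens ("3", "0.5" meaning the range 0..5) to 0-based ints.
tnt_expand_indices <- function(tokens, n_char) {
  out <- integer(0)
  for (tk in tokens) {
    if (grepl("^[0-9]+\\.[0-9]+$", tk)) {
      ab <- as.integer(strsplit(tk, ".", fixed = TRUE)[[1]])
      out <- c(out, seq(ab[1], ab[2]))
    } else if (tk == ".") {
      out <- c(out, 0:(n_char - 1L))
    } else {
      out <- c(out, as.integer(tk))
    }
  }
  out
}

apply_ccode <- function(meta, body, n_char) {
  # body: ccode command body, e.g. "+ 3 5 ] 0.2 /2 7"
  tokens <- regmatches(body, gregexpr("[][+*/-]|[0-9.]+", body))[[1]]
  mode <- NULL
  weight <- 1
  pending_weight <- FALSE
  for (tk in tokens) {
    if (tk %in% c("+", "-", "[", "]", "*", "/")) {
      mode <- tk
      pending_weight <- tk == "/"
    } else if (pending_weight) {
      weight <- as.numeric(tk)
      pending_weight <- FALSE
    } else {
      idx <- tnt_expand_indices(tk, n_char) + 1L
      if (any(idx < 1L | idx > n_char))
        stop("ccode index out of range: ", tk, call. = FALSE)
      if (is.null(mode)) stop("ccode index before mode flag", call. = FALSE)
      switch(mode,
        "+" = { meta$ordered[idx] <- TRUE },
        "-" = { meta$ordered[idx] <- FALSE },
        "[" = { meta$active[idx] <- TRUE },
        "]" = { meta$active[idx] <- FALSE },
        "/" = { meta$weight[idx] <- weight },
        "*" = {
          meta$ordered[idx] <- FALSE
          meta$active[idx] <- TRUE
          meta$weight[idx] <- 1
        })
    }
  }
  meta
}

#' Parse a TNT-format character matrix
#'
#' Reads an `xread` data block.  `'?'` maps to missing, `'-'` to inapplicable,
#' and bracketed tokens such as `[01]` to polymorphic state sets.  `ccode`
#' commands following the block are honoured for character ordering
#' (additivity), activation, and weights; in their absence every character is
#' unordered, active, with weight 1.
#'
#' @param text a single string (or character vector of lines) in TNT format.
#' @return a [character_matrix].
#' @export
parse_tnt <- function(text) {
  text <- paste(text, collapse = "\n")
  # remove quoted titles/comments
  body <- text
  m <- regexpr("xread", body)
  if (m < 0) stop("no xread block found", call. = FALSE)
  rest <- substring(body, m + attr(m, "match.length"))
  rest <- gsub("'[^']*'", " ", rest)
  # header: nchar ntax
  hdr <- regmatches(rest, regexpr("[0-9]+[[:space:]]+[0-9]+", rest))
  if (!length(hdr)) stop("missing dimensions line after xread", call. = FALSE)
  dims <- as.integer(strsplit(hdr, "[[:space:]]+")[[1]])
  n_char <- dims[1]; n_tax <- dims[2]
  after_hdr <- substring(rest, regexpr("[0-9]+[[:space:]]+[0-9]+", rest) +
                           attr(regexpr("[0-9]+[[:space:]]+[0-9]+", rest),
                                "match.length"))
  semi <- regexpr(";", after_hdr)
  if (semi < 0) stop("xread block not terminated by ';'", call. = FALSE)
  block <- substring(after_hdr, 1, semi - 1)
  tail_text <- substring(after_hdr, semi + 1)

  lines <- strsplit(block, "\n")[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^&", lines)]
  taxa <- character(0)
  rows <- list()
  for (ln in lines) {
    sp <- regmatches(ln, regexpr("^[^[:space:]]+", ln))
    states_text <- sub("^[^[:space:]]+", "", ln)
    name <- sp
    cells <- parse_state_tokens(states_text, sprintf("row '%s'", sp))
    if (name %in% taxa) {
      # interleaved continuation row
      i <- match(name, taxa)
      rows[[i]] <- c(rows[[i]], cells)
    } else {
      taxa <- c(taxa, name)
      rows[[length(rows) + 1L]] <- cells
    }
  }
  if (length(taxa) != n_tax)
    stop(sprintf("declared %d taxa but found %d", n_tax, length(taxa)),
         call. = FALSE)
  bad <- which(vapply(rows, length, integer(1)) != n_char)
  if (length(bad))
    stop(sprintf("taxon '%s': declared %d characters but row has %d",
                 taxa[bad[1]], n_char, length(rows[[bad[1]]])), call. = FALSE)
  mask <- do.call(rbind, rows)
  meta <- default_char_meta(n_char, source_label = "tnt")
  # ccode commands in the trailing text
  cc <- regmatches(tail_text,
                   gregexpr("ccode[^;]*;", tail_text, ignore.case = TRUE))[[1]]
  for (cmd in cc) {
    body_cc <- sub(";$", "", sub("^[Cc][Cc][Oo][Dd][Ee]", "", cmd))
    meta <- apply_ccode(meta, body_cc, n_char)
  }
  character_matrix(taxa, mask, meta)
}

#' Write a character matrix in TNT format
#'
#' Emits an `xread` block (dimensions "nchar ntax") followed by `ccode`
#' commands for any non-default character metadata, so that
#' `parse_tnt(write_tnt(m))` reproduces `m`.
#'
#' @param m a [character_matrix].
#' @return a single TNT-format string.
#' @export
write_tnt <- function(m) {
  cell_txt <- function(mask) {
    if (is.na(mask)) return("?")
    if (mask == CM_INAPPLICABLE) return("-")
    sts <- states_from_mask(mask)
    syms <- as.character(TNT_SYMBOLS[sts + 1L])
    if (length(sts) == 1L) syms else paste0("[", paste(syms, collapse = ""), "]")
  }
  rows <- vapply(seq_along(m$taxa), function(i) {
    paste0(gsub("[[:space:]]", "_", m$taxa[i]), " ",
           paste(vapply(m$cells[i, ], cell_txt, character(1)), collapse = ""))
  }, character(1))
  out <- c("xread", sprintf("%d %d", m$n_char, length(m$taxa)), rows, ";")
  meta <- m$char_meta
  cc <- character(0)
  if (any(meta$ordered))
    cc <- c(cc, sprintf("ccode + %s;",
                        paste(which(meta$ordered) - 1L, collapse = " ")))
  if (any(!meta$active))
    cc <- c(cc, sprintf("ccode ] %s;",
                        paste(which(!meta$active) - 1L, collapse = " ")))
  for (w in unique(meta$weight[meta$weight != 1])) {
    cc <- c(cc, sprintf("ccode /%s %s;", format(w),
                        paste(which(meta$weight == w) - 1L, collapse = " ")))
  }
  paste(c(out, cc, "proc /;"), collapse = "\n")
}
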