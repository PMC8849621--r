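# Cell encoding: each cell of the `cells` integer matrix is a bitmask over
# states 0..30 (state s -> bit 2^s); NA encodes MISSING ('?'), -1L encodes
# INAPPLICABLE ('-').  Both special codes behave as "any state" during
# parsimony scoring but are kept distinct for round-trip fidelity.
CM_INAPPLICABLE <- -1L

mask_from_states <- function(states) {
  if (length(states) == 0L) stop("empty state set", call. = FALSE)
  if (any(states < 0L | states > 30L))
    stop("states must be integers in 0..30", call. = FALSE)
  sum(bitwShiftL(1L, as.integer(states)))
}

states_from_mask <- function(mask) {
  if (is.na(mask)) return(NA_integer_)
  if (mask == CM_INAPPLICABLE) return(CM_INAPPLICABLE)
  which(bitwAnd(mask, bitwShiftL(1L, 0:30)) != 0L) - 1L
}

default_char_meta <- function(n, source_label = "") {
  data.frame(
    ordered = rep(FALSE, n),
    active = rep(TRUE, n),
    weight = rep(1, n),
    source = rep(source_label, n),
    stringsAsFactors = FALSE
  )
}

#' Construct a discrete morphological character matrix
#'
#' The central container for taxon-by-character data.  Cells hold sets of
#' integer states (a set of size > 1 is a polymorphism), or one of two special
#' values: missing (`"?"`) and inapplicable (`"-"`).  The two are stored
#' distinctly but both are scored as "any state" by the parsimony engine,
#' matching the default treatment in mainstream parsimony software.
#'
#' @param taxa character vector of unique, non-empty taxon names.
#' @param cells either an integer bitmask matrix (internal form) or a list of
#'   rows, one per taxon, each a list with one element per character: an
#'   integer vector of states, `NA` for missing, or `"-"` for inapplicable.
#' @param char_meta optional data frame with columns `ordered`, `active`,
#'   `weight`, `source`, one row per character.
#' @return an object of class `character_matrix` with fields `taxa`, `cells`
#'   (bitmask matrix), `n_char`, and `char_meta`.
#' @examples
#' m <- character_matrix(c("A", "B"), list(list(0L, 1L), list(0L, c(0L, 1L))))
#' m$n_char
#' @export
character_matrix <- function(taxa, cells, char_meta = NULL) {
  taxa <- as.character(taxa)
  if (anyDuplicated(taxa)) stop("duplicate taxon names", call. = FALSE)
  if (any(!nzchar(taxa))) stop("empty taxon name", call. = FALSE)
  if (is.matrix(cells)) {
    mask <- cells
    storage.mode(mask) <- "integer"
  } else {
    if (length(cells) != length(taxa))
      stop("one cell row required per taxon", call. = FALSE)
    nc <- if (length(cells)) length(cells[[1]]) else 0L
    mask <- matrix(NA_integer_, nrow = length(taxa), ncol = nc)
    for (i in seq_along(cells)) {
      row <- cells[[i]]
      if (length(row) != nc)
        stop(sprintf("taxon '%s': expected %d cells, got %d",
                     taxa[i], nc, length(row)), call. = FALSE)
      for (j in seq_len(nc)) {
        cell <- row[[j]]
        mask[i, j] <- if (length(cell) == 1L && is.na(cell)) {
          NA_integer_
        } else if (identical(cell, "-") || identical(cell, CM_INAPPLICABLE)) {
          CM_INAPPLICABLE
        } else {
          mask_from_states(as.integer(cell))
        }
      }
    }
  }
  if (nrow(mask) != length(taxa))
    stop("cell matrix row count does not match taxa", call. = FALSE)
  n_char <- ncol(mask)
  if (is.null(char_meta)) char_meta <- default_char_meta(n_char)
  stopifnot(nrow(char_meta) == n_char, all(char_meta$weight >= 0))
  rownames(mask) <- taxa
  structure(
    list(taxa = taxa, cells = mask, n_char = n_char, char_meta = char_meta),
    class = "character_matrix"
  )
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("character_matrix: %d taxa x %d characters\n",
              length(x$taxa), x$n_char))
  cat(sprintf("  active: %d  ordered: %d  missing cells: %d\n",
              sum(x$char_meta$active), sum(x$char_meta$ordered),
              sum(is.na(x$cells))))
  invisible(x)
}

#' @export
`==.character_matrix` <- function(e1, e2) {
  identical(e1$taxa, e2$taxa) &&
    identical(unname(e1$cells), unname(e2$cells)) &&
    isTRUE(all.equal(e1$char_meta[c("ordered", "active", "weight")],
                     e2$char_meta[c("ordered", "active", "weight")],
                     check.attributes = FALSE))
}

# State sets of one character across taxa, as a list of integer vectors.
char_state_sets <- function(m, j) lapply(m$cells[, j], states_from_mask)

#' Drop characters from a matrix
#'
#' @param m a `character_matrix`.
#' @param indices 1-based character indices to remove (duplicates rejected).
#'   Indexing is 1-based to match the character numbering used in published
#'   matrices ("Character 180" and so on).
#' @return the reduced `character_matrix`; remaining characters keep their
#'   original relative order and metadata.
#' @export
drop_characters <- function(m, indices) {
  indices <- as.integer(indices)
  if (length(indices) == 0L) return(m)
  if (anyDuplicated(indices)) stop("duplicate character indices", call. = FALSE)
  if (any(indices < 1L | indices > m$n_char))
    stop(sprintf("character index out of range 1..%d", m$n_char), call. = FALSE)
  keep <- setdiff(seq_len(m$n_char), indices)
  character_matrix(m$taxa, m$cells[, keep, drop = FALSE],
                   m$char_meta[keep, , drop = FALSE])
}

#' Drop taxa from a matrix
#'
#' @param m a `character_matrix`.
#' @param names taxon names to remove; all must be present.
#' @return the reduced `character_matrix` (character count unchanged).
#' @export
drop_taxa <- function(m, names) {
  if (length(names) == 0L) return(m)
  missing <- setdiff(names, m$taxa)
  if (length(missing))
    stop("unknown taxa: ", paste(missing, collapse = ", "), call. = FALSE)
  keep <- !(m$taxa %in% names)
  character_matrix(m$taxa[keep], m$cells[keep, , drop = FALSE], m$char_meta)
}

#' Merge two character matrices over an identical taxon set
#'
#' Concatenates character blocks (`a`'s characters first) for taxa shared by
#' both matrices.  Taxon sets must already agree exactly: harmonization
#' (dropping taxa absent from either source) is a deliberate, separate step so
#' that matrix-merging protocols stay auditable.
#'
#' @param a,b `character_matrix` objects with equal taxon sets.
#' @return merged `character_matrix` with `a`'s taxon order and concatenated
#'   character metadata.
#' @export
merge_matrices <- function(a, b) {
  only_a <- setdiff(a$taxa, b$taxa)
  only_b <- setdiff(b$taxa, a$taxa)
  if (length(only_a) || length(only_b))
    stop("taxon sets differ; only in first: [",
         paste(only_a, collapse = ", "), "]; only in second: [",
         paste(only_b, collapse = ", "), "]", call. = FALSE)
  b_cells <- b$cells[match(a$taxa, b$taxa), , drop = FALSE]
  character_matrix(a$taxa, cbind(a$cells, b_cells),
                   rbind(a$char_meta, b$char_meta))
}

# Parsimony-informative character: at least two states each observed (counting
# polymorphisms toward every member state) in at least two taxa.
is_informative <- function(m) {
  vapply(seq_len(m$n_char), function(j) {
    masks <- m$cells[, j]
    masks <- masks[!is.na(masks) & masks != CM_INAPPLICABLE]
    if (!length(masks)) return(FALSE)
    counts <- vapply(0:30, function(s)
      sum(bitwAnd(masks, bitwShiftL(1L, s)) != 0L), integer(1))
    sum(counts >= 2L) >= 2L
  }, logical(1))
}
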