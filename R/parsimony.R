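# Parsimony scoring.  Tree length is computed with Hartigan's generalisation
# of Fitch optimization, which is exact for unordered multistate characters on
# trees with polytomies.  Missing and inapplicable cells are scored as the
# union of the states observed in that character ("any state"), the default
# treatment in mainstream parsimony software.  Characters flagged as ordered
# are nevertheless scored as unordered (documented limitation; no step
# matrices).

# Scoring context: per-taxon bitmask matrix restricted to active characters,
# with missing cells replaced by the per-character full mask, identical
# columns pooled, and pooled weights.
score_context <- function(m) {
  act <- which(m$char_meta$active & m$char_meta$weight > 0)
  if (!length(act))
    return(list(masks = matrix(integer(0), nrow = length(m$taxa), ncol = 0),
                w = numeric(0), bits = integer(0)))
  masks <- m$cells[, act, drop = FALSE]
  w <- m$char_meta$weight[act]
  full <- integer(ncol(masks))
  for (j in seq_len(ncol(masks))) {
    col <- masks[, j]
    obs <- col[!is.na(col) & col != CM_INAPPLICABLE]
    full[j] <- if (length(obs)) Reduce(bitwOr, obs) else 0L
    col[is.na(col) | col == CM_INAPPLICABLE] <- full[j]
    masks[, j] <- col
  }
  keep <- full != 0L
  masks <- masks[, keep, drop = FALSE]
  w <- w[keep]; full <- full[keep]
  if (ncol(masks)) {
    key <- apply(masks, 2, paste, collapse = ",")
    grp <- match(key, unique(key))
    wpool <- vapply(split(w, grp), sum, numeric(1))
    masks <- masks[, !duplicated(grp), drop = FALSE]
    w <- as.numeric(wpool)
    full <- full[!duplicated(grp)]
  }
  max_bit <- if (length(full)) max(full) else 0L
  nbits <- if (max_bit > 0L) 1L + floor(log2(max_bit)) else 0L
  list(masks = masks, w = w, bits = bitwShiftL(1L, seq_len(nbits) - 1L))
}

# Hartigan downward pass over a nested-list tree; returns weighted length.
nl_score <- function(root, ctx) {
  nc <- ncol(ctx$masks)
  if (nc == 0L) return(0)
  bits <- ctx$bits
  total <- 0
  rec <- function(node) {
    if (!is.list(node)) return(ctx$masks[node, ])
    ms <- lapply(node, rec)
    k <- length(ms)
    M <- do.call(rbind, ms)
    counts <- vector("list", length(bits))
    kmax <- integer(nc)
    for (b in seq_along(bits)) {
      counts[[b]] <- .colSums(bitwAnd(M, bits[b]) != 0L, k, nc)
      kmax <- pmax(kmax, counts[[b]])
    }
    nm <- integer(nc)
    for (b in seq_along(bits)) nm <- nm + bits[b] * (counts[[b]] == kmax)
    total <<- total + sum(ctx$w * (k - kmax))
    as.integer(nm)
  }
  rec(root)
  total
}

check_tree_matrix <- function(tree, m) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo'", call. = FALSE)
  if (!setequal(tree$tip.label, m$taxa))
    stop("tree leaves and matrix taxa differ; only in tree: [",
         paste(setdiff(tree$tip.label, m$taxa), collapse = ", "),
         "]; only in matrix: [",
         paste(setdiff(m$taxa, tree$tip.label), collapse = ", "), "]",
         call. = FALSE)
}

#' Parsimony length of a tree (Fitch/Hartigan optimization)
#'
#' Minimum number of state changes, over all internal-node state assignments,
#' needed to explain the matrix on the given topology, summed over active
#' characters and multiplied by character weights.  Polytomies are scored as
#' given (not resolved).  Missing and inapplicable cells contribute the union
#' of states observed in that character.
#'
#' @param tree an `ape::phylo`; leaves must match the matrix taxa.
#' @param m a [character_matrix].
#' @return non-negative numeric tree length (integer-valued under unit
#'   weights).
#' @export
fitch_length <- function(tree, m) {
  check_tree_matrix(tree, m)
  nl <- phylo_to_nl(tree, m$taxa)
  if (!is.list(nl)) return(0)
  nl_score(nl, score_context(m))
}

#' Minimum conceivable steps, summed over characters
#'
#' For each active character, the smallest number of changes any tree could
#' require, ignoring missing and inapplicable cells.  With fixed (single-
#' state) cells only, this is the number of distinct observed states minus
#' one.  A polymorphic cell is satisfied by any state it contains, so the
#' exact minimum is the size of the smallest state set hitting every scored
#' cell, minus one (found by subset enumeration over the few observed
#' states); this keeps the invariant `M <= L` on every tree.  `M` is the
#' numerator of the ensemble consistency index.
#'
#' @param m a [character_matrix].
#' @return non-negative number (weighted sum).
#' @export
min_steps <- function(m) {
  act <- which(m$char_meta$active & m$char_meta$weight > 0)
  total <- 0
  for (j in act) {
    col <- m$cells[, j]
    obs <- col[!is.na(col) & col != CM_INAPPLICABLE]
    if (!length(obs)) next
    states <- states_from_mask(Reduce(bitwOr, obs))
    k <- length(states)
    if (k > 1L && any(vapply(obs, function(x)
      length(states_from_mask(x)), integer(1)) > 1L)) {
      # minimum hitting set over the cell state-sets
      found <- k
      for (size in seq_len(k)) {
        combos <- utils::combn(states, size)
        hit <- FALSE
        for (ci in seq_len(ncol(combos))) {
          mask <- mask_from_states(combos[, ci])
          if (all(bitwAnd(obs, mask) != 0L)) { hit <- TRUE; break }
        }
        if (hit) { found <- size; break }
      }
      k <- found
    }
    total <- total + m$char_meta$weight[j] * max(0L, k - 1L)
  }
  total
}

#' Maximum conceivable steps (star-tree length), summed over characters
#'
#' For each active character, its parsimony length on the completely
#' unresolved (star) tree: the number of scored cells minus the frequency of
#' the most common state, a polymorphic cell counting toward every state it
#' contains.  This is the `G` term of the retention index.
#'
#' @param m a [character_matrix].
#' @return non-negative number (weighted sum).
#' @export
max_steps <- function(m) {
  act <- which(m$char_meta$active & m$char_meta$weight > 0)
  total <- 0
  for (j in act) {
    col <- m$cells[, j]
    obs <- col[!is.na(col) & col != CM_INAPPLICABLE]
    if (!length(obs)) next
    counts <- vapply(0:30, function(s)
      sum(bitwAnd(obs, bitwShiftL(1L, s)) != 0L), integer(1))
    total <- total + m$char_meta$weight[j] * (length(obs) - max(counts))
  }
  total
}

#' Ensemble consistency and retention indices
#'
#' `CI = M/L` and `RI = (G - L)/(G - M)` where `L` is the observed tree
#' length, `M` the summed per-character minima ([min_steps]) and `G` the
#' summed star-tree lengths ([max_steps]).  When the indices are undefined
#' (`L == 0` or `G == M`) they are reported as `NA` with an explanatory note.
#'
#' @param L observed length (steps).
#' @param M minimum conceivable steps.
#' @param G maximum conceivable steps.
#' @return a list of class `parsimony_stats` with fields `L`, `M`, `G`, `CI`,
#'   `RI`, rounded 3-decimal `CI_3`/`RI_3`, and `note`.
#' @export
ensemble_indices <- function(L, M, G) {
  note <- character(0)
  if (L == 0) {
    CI <- NA_real_; RI <- NA_real_
    note <- "L == 0: all characters constant; indices undefined"
  } else {
    if (!(M <= L && L <= G))
      stop(sprintf("expected M <= L <= G, got M=%s L=%s G=%s", M, L, G),
           call. = FALSE)
    CI <- M / L
    if (G == M) {
      RI <- NA_real_
      note <- "G == M: no potential homoplasy; RI undefined"
    } else {
      RI <- (G - L) / (G - M)
    }
  }
  structure(list(L = L, M = M, G = G, CI = CI, RI = RI,
                 CI_3 = round(CI, 3), RI_3 = round(RI, 3), note = note),
            class = "parsimony_stats")
}

#' @export
print.parsimony_stats <- function(x, ...) {
  cat(sprintf("L = %s  M = %s  G = %s  CI = %s  RI = %s\n",
              format(x$L), format(x$M), format(x$G),
              format(x$CI_3), format(x$RI_3)))
  if (length(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Parsimony statistics of a tree on a matrix
#'
#' Convenience wrapper computing `L` via [fitch_length] and assembling
#' [ensemble_indices].  With `informative_only = TRUE` all three terms are
#' recomputed on the parsimony-informative characters alone (the alternative
#' reporting convention of some programs).
#'
#' @param tree an `ape::phylo`.
#' @param m a [character_matrix].
#' @param informative_only drop parsimony-uninformative characters first?
#' @return a `parsimony_stats` object.
#' @export
parsimony_stats <- function(tree, m, informative_only = FALSE) {
  if (informative_only) {
    keep <- is_informative(m)
    m <- drop_characters(m, which(!keep))
  }
  ensemble_indices(fitch_length(tree, m), min_steps(m), max_steps(m))
}
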