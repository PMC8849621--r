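# Heuristic maximum-parsimony search: random-addition-sequence replicates
# followed by branch swapping (NNI, SPR, or TBR) to a local optimum, holding
# up to `hold` equally parsimonious trees per replicate and pooling the best
# across replicates.  All randomness flows from a single seed.

ras_start <- function(ctx, ord, score_fn) {
  cur <- list(ord[1], ord[2], ord[3])
  for (t in ord[-(1:3)]) {
    cands <- nl_insert_all(cur, t)
    sc <- vapply(cands, score_fn, numeric(1))
    cur <- cands[[which.min(sc)]]
  }
  cur
}

swap_to_optimum <- function(start, swapper, hold, score_fn) {
  best <- score_fn(start)
  pool <- stats::setNames(list(start), nl_canon_key(start))
  queue <- list(start)
  qi <- 1L
  swapped <- character(0)
  repeat {
    if (qi > length(queue)) break
    t <- queue[[qi]]; qi <- qi + 1L
    kt <- nl_canon_key(t)
    if (kt %in% swapped) next
    swapped <- c(swapped, kt)
    improved <- FALSE
    for (nb in nl_neighbors(t, swapper)) {
      len <- score_fn(nb)
      if (len < best - 1e-9) {
        best <- len
        pool <- stats::setNames(list(nb), nl_canon_key(nb))
        queue <- list(nb); qi <- 1L
        swapped <- character(0)
        improved <- TRUE
        break
      }
      if (abs(len - best) <= 1e-9 && length(pool) < hold) {
        k <- nl_canon_key(nb)
        if (!(k %in% names(pool))) {
          pool[[k]] <- nb
          queue[[length(queue) + 1L]] <- nb
        }
      }
    }
    if (improved) next
  }
  list(trees = pool, len = best)
}

search_core <- function(ctx, n_leaves, n_replicates, swapper, hold, score_fn) {
  best <- Inf
  pool <- list()
  for (r in seq_len(n_replicates)) {
    ord <- sample.int(n_leaves)
    res <- swap_to_optimum(ras_start(ctx, ord, score_fn), swapper, hold,
                           score_fn)
    if (res$len < best - 1e-9) {
      best <- res$len
      pool <- res$trees
    } else if (abs(res$len - best) <= 1e-9) {
      for (k in names(res$trees))
        if (!(k %in% names(pool)) && length(pool) < hold)
          pool[[k]] <- res$trees[[k]]
    }
  }
  list(trees = pool, len = best)
}

new_tree_set <- function(nls, length, labels) {
  structure(list(
    trees = lapply(nls, nl_to_phylo, labels = labels),
    length = length,
    labels = labels,
    nl = nls
  ), class = "tree_set")
}

#' @export
print.tree_set <- function(x, ...) {
  cat(sprintf("tree_set: %d tree(s) on %d taxa, length %s\n",
              length(x$trees), length(x$labels), format(x$length)))
  invisible(x)
}

#' Heuristic maximum-parsimony search
#'
#' Random-addition-sequence replicates, each followed by branch swapping to a
#' local optimum.  Every returned tree rescores exactly to the reported
#' length; results are deterministic given `seed`.
#'
#' @param m a [character_matrix] with at least 3 taxa.
#' @param n_replicates number of random addition sequences (>= 1).
#' @param swapper branch-swapping neighbourhood: `"NNI"`, `"SPR"` or `"TBR"`.
#' @param hold maximum number of equally parsimonious trees retained.
#' @param seed integer seed controlling all randomness.
#' @return a `tree_set`: list with `trees` (unrooted `ape::phylo`s),
#'   `length` (best length found) and `labels`.
#' @export
heuristic_search <- function(m, n_replicates = 10, swapper = c("TBR", "SPR", "NNI"),
                             hold = 20, seed = 1L) {
  swapper <- match.arg(swapper)
  if (length(m$taxa) < 3L) stop("need at least 3 taxa", call. = FALSE)
  if (hold < 1L) stop("hold must be >= 1", call. = FALSE)
  if (n_replicates < 1L) stop("n_replicates must be >= 1", call. = FALSE)
  set.seed(seed)
  ctx <- score_context(m)
  score_fn <- function(nl) nl_score(nl, ctx)
  n <- length(m$taxa)
  if (n == 3L) {
    nl <- list(1L, 2L, 3L)
    return(new_tree_set(list(nl), score_fn(nl), m$taxa))
  }
  res <- search_core(ctx, n, n_replicates, swapper, hold, score_fn)
  # admissibility: every returned tree scores exactly the reported length
  stopifnot(all(vapply(res$trees, score_fn, numeric(1)) == res$len))
  new_tree_set(unname(res$trees), res$len, m$taxa)
}

as_nl_trees <- function(trees) {
  # Accept a tree_set, a list of phylo, or a multiPhylo; return list(nl=,
  # labels=) over a common leaf index space.
  if (inherits(trees, "tree_set"))
    return(list(nl = trees$nl, labels = trees$labels))
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (!length(trees)) stop("empty tree set", call. = FALSE)
  labels <- sort(trees[[1]]$tip.label)
  for (t in trees) {
    if (!setequal(t$tip.label, labels))
      stop("trees have different leaf sets", call. = FALSE)
  }
  list(nl = lapply(trees, phylo_to_nl, labels = labels), labels = labels)
}

#' Strict consensus tree
#'
#' The tree whose internal edges are exactly the bipartitions shared by every
#' input tree; everything else collapses into polytomies.
#'
#' @param trees a `tree_set` (from [heuristic_search]), a list of
#'   `ape::phylo`, or a `multiPhylo`; all on the same leaf set.
#' @return an unrooted `ape::phylo`.
#' @export
strict_consensus <- function(trees) {
  tr <- as_nl_trees(trees)
  splits <- lapply(tr$nl, nl_splits)
  common <- Reduce(intersect, splits)
  nl <- nl_from_splits(common, length(tr$labels))
  nl_to_phylo(nl, tr$labels)
}

#' Maximum agreement subtree
#'
#' Largest leaf subset on which all input trees induce the same unrooted
#' topology.  Exact (subset enumeration, largest first) for 12 or fewer
#' leaves; beyond that a deterministic greedy leaf-elimination heuristic is
#' used.  The method actually used is recorded in the `"method"` attribute.
#'
#' @param trees a `tree_set`, list of `ape::phylo`, or `multiPhylo` (>= 2
#'   trees recommended; a single tree returns itself).
#' @param exact_max leaf count up to which the exact search runs (default 12).
#' @return an `ape::phylo` on the retained leaves, with attribute `"method"`
#'   equal to `"exact"` or `"greedy"`.
#' @export
agreement_subtree <- function(trees, exact_max = 12L) {
  tr <- as_nl_trees(trees)
  n <- length(tr$labels)
  agree_on <- function(keep) {
    keys <- vapply(tr$nl, function(x) {
      r <- nl_restrict(x, keep)
      if (is.list(r)) nl_canon_key(r) else paste0("leaf:", r)
    }, character(1))
    all(keys == keys[1])
  }
  if (length(tr$nl) == 1L || agree_on(seq_len(n))) {
    out <- nl_to_phylo(nl_norm_top(tr$nl[[1]]), tr$labels)
    attr(out, "method") <- "exact"
    return(out)
  }
  if (n <= exact_max) {
    for (size in seq(n - 1L, 3L)) {
      subsets <- utils::combn(n, size)
      for (ci in seq_len(ncol(subsets))) {
        keep <- subsets[, ci]
        if (agree_on(keep)) {
          out <- nl_to_phylo(nl_restrict(tr$nl[[1]], keep), tr$labels)
          attr(out, "method") <- "exact"
          return(out)
        }
      }
    }
    stop("no agreement subtree with >= 3 leaves", call. = FALSE)
  }
  # greedy leaf elimination: repeatedly drop the leaf whose removal leaves
  # the most bipartitions common to all restricted trees
  keep <- seq_len(n)
  while (length(keep) > 3L && !agree_on(keep)) {
    score <- vapply(seq_along(keep), function(i) {
      kp <- keep[-i]
      length(Reduce(intersect,
                    lapply(tr$nl, function(x) nl_splits(nl_restrict(x, kp)))))
    }, numeric(1))
    keep <- keep[-which.max(score)]
  }
  if (!agree_on(keep)) stop("greedy agreement search failed", call. = FALSE)
  out <- nl_to_phylo(nl_restrict(tr$nl[[1]], keep), tr$labels)
  attr(out, "method") <- "greedy"
  out
}

default_search_config <- function() list(replicates = 10, swapper = "SPR", hold = 10)

#' Nonparametric bootstrap support
#'
#' Characters are resampled with replacement (same count) and each replicate
#' is searched.  A bipartition's support is the mean, over replicates, of the
#' fraction of that replicate's equally parsimonious trees containing it
#' (the standard frequency convention: a replicate whose trees are split
#' between two resolutions contributes fractionally to each, so two equally
#' supported conflicting resolutions each approach 50%).
#'
#' @param m a [character_matrix].
#' @param n_reps number of bootstrap replicates (default 1000).
#' @param search_config list with `replicates`, `swapper`, `hold` controlling
#'   the per-replicate search effort (reduced by default).
#' @param seed integer seed.
#' @param splits optional character vector of split keys to score; defaults
#'   to the nontrivial splits of the full-data strict consensus.
#' @return a data frame with columns `split` (key), `taxa` (comma-joined
#'   smaller side), and `support` (percent, `NA` when the matrix has no
#'   parsimony-informative characters).
#' @export
bootstrap_support <- function(m, n_reps = 1000, search_config = default_search_config(),
                              seed = 1L, splits = NULL) {
  set.seed(seed)
  run <- function(mat, sd) heuristic_search(
    mat, n_replicates = search_config$replicates,
    swapper = search_config$swapper, hold = search_config$hold, seed = sd)
  if (is.null(splits)) {
    full <- run(m, seed)
    splits <- phylo_splits(strict_consensus(full), m$taxa)
  }
  taxa_txt <- vapply(splits, function(k)
    paste(split_key_to_taxa(k, m$taxa), collapse = ","), character(1))
  if (!any(is_informative(m))) {
    return(data.frame(split = splits, taxa = taxa_txt, support = NA_real_,
                      stringsAsFactors = FALSE))
  }
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  hits <- numeric(length(splits))
  for (r in seq_len(n_reps)) {
    idx <- sample.int(m$n_char, m$n_char, replace = TRUE)
    mb <- character_matrix(m$taxa, m$cells[, idx, drop = FALSE],
                           m$char_meta[idx, , drop = FALSE])
    ts <- run(mb, rep_seeds[r])
    per_tree <- lapply(ts$nl, nl_splits)
    member <- matrix(vapply(per_tree, function(sp) splits %in% sp,
                            logical(length(splits))),
                     nrow = length(splits))
    hits <- hits + rowMeans(member)
  }
  data.frame(split = splits, taxa = taxa_txt,
             support = 100 * hits / n_reps, stringsAsFactors = FALSE)
}

#' Bremer (decay) support
#'
#' For each nontrivial bipartition of the strict consensus of the most
#' parsimonious trees, the decay index is the length of the best tree lacking
#' that bipartition minus the optimal length, found by reverse-constraint
#' searches (trees containing the bipartition are inadmissible).
#'
#' @param m a [character_matrix].
#' @param mpts a `tree_set` of most parsimonious trees (length `L`).
#' @param max_decay cap on the reported decay; capped values are flagged.
#' @param search_config per-constraint search effort (see
#'   [bootstrap_support]).
#' @param seed integer seed.
#' @return data frame with columns `split`, `taxa`, `decay`, `capped`.
#' @export
bremer_support <- function(m, mpts, max_decay = 10,
                           search_config = default_search_config(), seed = 1L) {
  stopifnot(inherits(mpts, "tree_set"), length(mpts$trees) >= 1)
  L <- mpts$length
  cons_splits <- phylo_splits(strict_consensus(mpts), m$taxa)
  ctx <- score_context(m)
  n <- length(m$taxa)
  big <- sum(ctx$w) * n + max_decay + 1
  out <- data.frame(split = character(0), taxa = character(0),
                    decay = numeric(0), capped = logical(0),
                    stringsAsFactors = FALSE)
  set.seed(seed)
  for (k in cons_splits) {
    score_fn <- function(nl) {
      nl_score(nl, ctx) + if (k %in% nl_splits(nl)) big else 0
    }
    res <- search_core(ctx, n, search_config$replicates,
                       search_config$swapper, search_config$hold, score_fn)
    decay <- res$len - L
    capped <- decay > max_decay
    out <- rbind(out, data.frame(
      split = k,
      taxa = paste(split_key_to_taxa(k, m$taxa), collapse = ","),
      decay = min(decay, max_decay), capped = capped,
      stringsAsFactors = FALSE))
  }
  out
}

#' Prune taxa and re-run the parsimony analysis
#'
#' Drops the given taxa, repeats the heuristic search, and returns both the
#' new tree set and its strict consensus — the standard "pruned reanalysis"
#' used to test whether an unstable taxon is masking resolution.
#'
#' @param m a [character_matrix].
#' @param taxa_to_prune taxa to remove (at least 3 must remain).
#' @param ... passed to [heuristic_search] (`n_replicates`, `swapper`,
#'   `hold`, `seed`).
#' @return list with `trees` (a `tree_set`) and `consensus` (`ape::phylo`).
#' @export
prune_and_reanalyze <- function(m, taxa_to_prune, ...) {
  m2 <- drop_taxa(m, taxa_to_prune)
  if (length(m2$taxa) < 3L)
    stop("fewer than 3 taxa would remain", call. = FALSE)
  ts <- heuristic_search(m2, ...)
  list(trees = ts, consensus = strict_consensus(ts))
}
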