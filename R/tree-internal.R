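# Internal tree representation for the parsimony engine.
#
# An unrooted tree on leaf indices 1..n is stored as a nested list whose top
# node has >= 3 children (trifurcating "root" = arbitrary internal vertex);
# every other internal node has >= 2 children; a leaf is a bare integer.
# Rearrangements (NNI/SPR/TBR) are pure functions returning new nested lists.
# Topological identity is tested through canonical bipartition keys, which
# makes all operations rooting-invariant.

nl_leaves <- function(node) {
  if (!is.list(node)) return(node)
  unlist(lapply(node, nl_leaves), use.names = FALSE)
}

# Paths (vectors of child indices) to every non-top node, preorder.
nl_paths <- function(node) {
  if (!is.list(node)) return(list())
  out <- vector("list", 0L)
  for (i in seq_along(node)) {
    out <- c(out, list(i))
    for (p in nl_paths(node[[i]])) out[[length(out) + 1L]] <- c(i, p)
  }
  out
}

# Collapse unary internal nodes below the top.
nl_norm_node <- function(node) {
  if (!is.list(node)) return(node)
  node <- lapply(node, nl_norm_node)
  if (length(node) == 1L) node[[1]] else node
}

# Restore the trifurcating-top invariant after surgery (merge one internal
# child into a binary top when possible).
nl_norm_top <- function(node) {
  node <- nl_norm_node(node)
  if (!is.list(node)) return(node)
  while (length(node) == 2L) {
    int <- which(vapply(node, is.list, logical(1)))
    if (!length(int)) break
    i <- int[1]
    node <- c(node[-i], node[[i]])
  }
  node
}

# Remainder of `root` when the edge above root[[p]] is cut, rooted at the cut.
nl_hang <- function(root, p) {
  if (length(p) == 1L) {
    rem <- root[-p[1]]
    if (length(rem) == 1L) rem[[1]] else rem
  } else {
    parent <- root[[p[-length(p)]]]
    sibs <- parent[-p[length(p)]]
    up <- nl_hang(root, p[-length(p)])
    node <- c(sibs, list(up))
    if (length(node) == 1L) node[[1]] else node
  }
}

# All trees obtained by attaching `sub` onto every edge of `node`.
nl_insert_all <- function(node, sub) {
  if (!is.list(node)) return(list())
  out <- list()
  for (i in seq_along(node)) {
    nn <- node
    nn[[i]] <- list(node[[i]], sub)
    out[[length(out) + 1L]] <- nn
    for (v in nl_insert_all(node[[i]], sub)) {
      nn2 <- node
      nn2[[i]] <- v
      out[[length(out) + 1L]] <- nn2
    }
  }
  out
}

# Bipartitions as canonical keys.  Each nontrivial split is the sorted leaf
# vector of the side not containing the smallest leaf overall.
nl_splits <- function(root) {
  all_leaves <- sort(nl_leaves(root))
  n <- length(all_leaves)
  anchor <- all_leaves[1]
  keys <- character(0)
  rec <- function(node) {
    if (!is.list(node)) return(node)
    below <- unlist(lapply(node, rec), use.names = FALSE)
    if (length(below) >= 2L && length(below) <= n - 2L) {
      side <- if (anchor %in% below) setdiff(all_leaves, below) else below
      keys[[length(keys) + 1L]] <<- paste(sort(side), collapse = ",")
    }
    below
  }
  if (is.list(root)) for (ch in root) rec(ch)
  unique(keys)
}

nl_canon_key <- function(root) {
  paste(c(paste(sort(nl_leaves(root)), collapse = ","),
          sort(nl_splits(root))), collapse = "|")
}

# Detach the subtree at path `p`; returns list(sub=, rest=) with the rest
# renormalised to the trifurcating-top form (or a 2-leaf cherry).
nl_detach <- function(root, p) {
  sub <- root[[p]]
  rest <- root
  rest[[p]] <- NULL
  list(sub = sub, rest = nl_norm_top(rest))
}

# Attachment variants of a pruned subtree (for TBR): re-hang on each edge.
nl_rehang_all <- function(sub) {
  if (!is.list(sub)) return(list(sub))
  out <- list(sub)
  for (p in nl_paths(sub)) {
    out[[length(out) + 1L]] <- list(sub[[p]], nl_hang(sub, p))
  }
  out
}

nl_neighbors <- function(root, swapper = c("SPR", "NNI", "TBR")) {
  swapper <- match.arg(swapper)
  out <- list()
  if (swapper == "NNI") {
    for (p in nl_paths(root)) {
      x <- root[[p]]
      if (!is.list(x)) next
      ctx <- nl_hang(root, p)
      if (!is.list(ctx)) next
      # binary case: exchange one child of x with one child of ctx
      for (i in seq_along(x)) for (j in seq_along(ctx)) {
        a <- x[-i]; a <- if (length(a) == 1L) a[[1]] else a
        b <- ctx[-j]; b <- if (length(b) == 1L) b[[1]] else b
        nb <- nl_norm_top(list(list(x[[i]], ctx[[j]]), list(a, b)))
        out[[length(out) + 1L]] <- nb
      }
    }
    return(out)
  }
  n_leaves <- length(nl_leaves(root))
  for (p in nl_paths(root)) {
    d <- nl_detach(root, p)
    if (length(nl_leaves(d$rest)) < 2L) next
    subs <- if (swapper == "TBR") nl_rehang_all(d$sub) else list(d$sub)
    for (s in subs) {
      if (!is.list(d$rest)) next
      for (nb in nl_insert_all(d$rest, s)) {
        out[[length(out) + 1L]] <- nl_norm_top(nb)
      }
    }
  }
  out
}

# Random unrooted binary topology by sequential insertion (uses the current
# RNG stream; callers are responsible for seeding).
nl_random_tree <- function(n) {
  stopifnot(n >= 3L)
  ord <- sample.int(n)
  cur <- list(ord[1], ord[2], ord[3])
  for (t in ord[-(1:3)]) {
    cands <- nl_insert_all(cur, t)
    cur <- cands[[sample.int(length(cands), 1L)]]
  }
  cur
}

# All unrooted binary topologies on leaves 1..n (1, 3, 15, 105, 945, 10395...).
nl_all_topologies <- function(n) {
  stopifnot(n >= 3L)
  trees <- list(list(1L, 2L, 3L))
  if (n == 3L) return(trees)
  for (t in 4:n) {
    nxt <- list()
    for (tr in trees) for (v in nl_insert_all(tr, t))
      nxt[[length(nxt) + 1L]] <- v
    trees <- nxt
  }
  trees
}

# Induced (restricted) unrooted tree on a leaf subset.
nl_restrict <- function(root, keep) {
  rec <- function(node) {
    if (!is.list(node)) {
      return(if (node %in% keep) node else NULL)
    }
    kids <- Filter(Negate(is.null), lapply(node, rec))
    if (!length(kids)) return(NULL)
    if (length(kids) == 1L) return(kids[[1]])
    kids
  }
  r <- rec(root)
  if (is.list(r)) nl_norm_top(r) else r
}

# Build an unrooted nested-list tree from a set of pairwise-compatible
# splits (character keys "i,j,k" of leaf indices, all excluding the smallest
# leaf).  Used by the strict consensus.
nl_from_splits <- function(split_keys, n) {
  clusters <- lapply(split_keys, function(k)
    as.integer(strsplit(k, ",", fixed = TRUE)[[1]]))
  # normalise every cluster to exclude leaf 1
  clusters <- lapply(clusters, function(cl)
    if (1L %in% cl) setdiff(seq_len(n), cl) else cl)
  clusters <- unique(clusters)
  build <- function(members, cls) {
    # cls: clusters strictly inside `members`
    maximal <- Filter(function(a)
      !any(vapply(cls, function(b)
        length(b) > length(a) && all(a %in% b), logical(1))), cls)
    # deduplicate identical maximal clusters
    maximal <- unique(maximal)
    covered <- unique(unlist(maximal))
    kids <- list()
    for (cl in maximal) {
      inner <- Filter(function(b) length(b) < length(cl) && all(b %in% cl), cls)
      kids[[length(kids) + 1L]] <- build(cl, inner)
    }
    for (lf in setdiff(members, covered)) kids[[length(kids) + 1L]] <- lf
    if (length(kids) == 1L) kids[[1]] else kids
  }
  nl_norm_top(build(seq_len(n), clusters))
}

# --- conversions to/from ape ------------------------------------------------

nl_to_newick <- function(root, labels) {
  rec <- function(node) {
    if (!is.list(node)) return(gsub("[ ,():;]", "_", labels[node]))
    paste0("(", paste(vapply(node, rec, character(1)), collapse = ","), ")")
  }
  paste0(rec(root), ";")
}

nl_to_phylo <- function(root, labels) {
  ape::read.tree(text = nl_to_newick(root, labels))
}

phylo_to_nl <- function(phy, labels) {
  idx <- match(phy$tip.label, labels)
  if (anyNA(idx))
    stop("tree tips not found among matrix taxa: ",
         paste(phy$tip.label[is.na(idx)], collapse = ", "), call. = FALSE)
  n <- length(phy$tip.label)
  kids <- vector("list", n + phy$Nnode)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]; c <- phy$edge[e, 2]
    kids[[p]] <- c(kids[[p]], c)
  }
  rec <- function(v) {
    if (v <= n) return(idx[v])
    lapply(kids[[v]], rec)
  }
  nl_norm_node(rec(n + 1L))
}

# Splits of an ape phylo in the same canonical key space (taxon indices are
# positions in `labels`).
phylo_splits <- function(phy, labels) {
  nl <- phylo_to_nl(phy, labels)
  if (!is.list(nl)) return(character(0))
  nl_splits(nl)
}

split_key_to_taxa <- function(key, labels) {
  labels[as.integer(strsplit(key, ",", fixed = TRUE)[[1]])]
}
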