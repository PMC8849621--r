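# Synapomorphy mapping.  Per character, a unit-cost Sankoff dynamic program
# gives the subtree cost of every (node, state) pair; a mirrored "outside"
# pass gives the cost of the rest of the tree.  From these two tables we read
# off, exactly:
#   * the set of states a node takes across ALL most-parsimonious
#     reconstructions (MPR set), and
#   * whether a state change is forced on an edge (the minimum length with
#     both endpoints constrained equal exceeds the character's optimum) —
#     such a change is "unambiguous": it occurs in every MPR.
# ACCTRAN/DELTRAN produce one concrete reconstruction by resolving ties in a
# preorder walk (accelerate = change as close to the root as allowed; delay =
# keep the parental state whenever optimal).

phylo_children <- function(phy) {
  n <- length(phy$tip.label)
  kids <- vector("list", n + phy$Nnode)
  for (e in seq_len(nrow(phy$edge)))
    kids[[phy$edge[e, 1]]] <- c(kids[[phy$edge[e, 1]]], phy$edge[e, 2])
  kids
}

phylo_postorder <- function(phy) {
  n <- length(phy$tip.label)
  kids <- phylo_children(phy)
  order <- integer(0)
  rec <- function(v) {
    for (w in kids[[v]]) rec(w)
    order <<- c(order, v)
  }
  rec(n + 1L)
  order
}

#' Map character-state changes (synapomorphies) onto a tree
#'
#' Lists the state changes implied by most-parsimonious reconstructions of
#' each active character on a rooted tree.  A change is *unambiguous* when it
#' occurs on that edge in every most-parsimonious reconstruction; `mode`
#' selects which changes are reported and how ambiguity is resolved:
#' `"unambiguous"` reports forced changes only (ancestral/derived columns
#' give the full MPR state sets); `"ACCTRAN"` and `"DELTRAN"` report the
#' changes of one concrete reconstruction, resolved by accelerating
#' (changes pulled toward the root) or delaying (parental state kept when
#' optimal) transformations.
#'
#' @param tree a rooted `ape::phylo` (polytomies allowed); node numbers in
#'   the output follow `tree`'s internal numbering, and tip-set columns name
#'   the clade below the edge.
#' @param m a [character_matrix]; taxa must match the tree's leaves.
#' @param mode `"unambiguous"`, `"ACCTRAN"`, or `"DELTRAN"`.
#' @return data frame with columns `node` (child end of the edge), `clade`
#'   (comma-joined tips below), `character` (1-based index), `from`, `to`
#'   (state labels; MPR sets joined with `/` in unambiguous mode), and
#'   `unambiguous` (logical).
#' @export
map_synapomorphies <- function(tree, m,
                               mode = c("unambiguous", "ACCTRAN", "DELTRAN")) {
  mode <- match.arg(mode)
  check_tree_matrix(tree, m)
  n <- length(tree$tip.label)
  kids <- phylo_children(tree)
  post <- phylo_postorder(tree)
  root <- n + 1L
  tip_idx <- match(tree$tip.label, m$taxa)
  below <- vector("list", n + tree$Nnode)
  for (v in post)
    below[[v]] <- if (v <= n) tree$tip.label[v] else
      sort(unlist(below[kids[[v]]]))
  act <- which(m$char_meta$active & m$char_meta$weight > 0)
  INF <- 1e9
  res <- list()
  for (j in act) {
    col <- m$cells[tip_idx, j]
    obs <- col[!is.na(col) & col != CM_INAPPLICABLE]
    if (!length(obs)) next
    states <- states_from_mask(Reduce(bitwOr, obs))
    S <- length(states)
    if (S < 2L) next
    nnode <- n + tree$Nnode
    C <- matrix(INF, nnode, S) # inside cost given node state
    for (v in post) {
      if (v <= n) {
        mask <- col[v]
        allowed <- if (is.na(mask) || mask == CM_INAPPLICABLE) rep(TRUE, S)
                   else bitwAnd(mask, bitwShiftL(1L, states)) != 0L
        C[v, allowed] <- 0
      } else {
        acc <- numeric(S)
        for (w in kids[[v]]) {
          mn <- min(C[w, ])
          acc <- acc + pmin(C[w, ], mn + 1)
        }
        C[v, ] <- acc
      }
    }
    Lc <- min(C[root, ])
    O <- matrix(INF, nnode, S) # outside cost given node state
    O[root, ] <- 0
    pre <- rev(post)
    for (v in pre) {
      if (v <= n || !length(kids[[v]])) next
      for (w in kids[[v]]) {
        # contribution of v's other children given v-state a
        other <- numeric(S)
        for (u in setdiff(kids[[v]], w)) {
          mn <- min(C[u, ])
          other <- other + pmin(C[u, ], mn + 1)
        }
        base <- O[v, ] + other # cost above edge (v,w) given v-state a
        O[w, ] <- vapply(seq_len(S), function(b)
          min(base + (seq_len(S) != b)), numeric(1))
      }
    }
    mpr <- lapply(seq_len(nnode), function(v)
      states[which(C[v, ] + O[v, ] <= Lc + 1e-9)])
    if (mode == "unambiguous") {
      for (e in seq_len(nrow(tree$edge))) {
        v <- tree$edge[e, 1]; w <- tree$edge[e, 2]
        other <- numeric(S)
        for (u in setdiff(kids[[v]], w)) {
          mn <- min(C[u, ])
          other <- other + pmin(C[u, ], mn + 1)
        }
        equal_cost <- min(O[v, ] + other + C[w, ]) # both ends share a state
        if (equal_cost > Lc + 1e-9) {
          res[[length(res) + 1L]] <- data.frame(
            node = w, clade = paste(below[[w]], collapse = ","),
            character = j,
            from = paste(mpr[[v]], collapse = "/"),
            to = paste(mpr[[w]], collapse = "/"),
            unambiguous = TRUE, stringsAsFactors = FALSE)
        }
      }
    } else {
      accelerate <- mode == "ACCTRAN"
      assign_state <- integer(nnode)
      rs <- states[which(C[root, ] == Lc)]
      assign_state[root] <- rs[1]
      for (v in pre) {
        if (v <= n || !length(kids[[v]])) next
        a_idx <- match(assign_state[v], states)
        for (w in kids[[v]]) {
          costs <- C[w, ] + (seq_len(S) != a_idx)
          cand <- which(costs == min(costs))
          pick <- if (a_idx %in% cand) {
            if (accelerate && length(cand) > 1L)
              cand[cand != a_idx][1] else a_idx
          } else cand[1]
          assign_state[w] <- states[pick]
          if (assign_state[w] != assign_state[v]) {
            forced_other <- numeric(S)
            for (u in setdiff(kids[[v]], w)) {
              mn <- min(C[u, ])
              forced_other <- forced_other + pmin(C[u, ], mn + 1)
            }
            forced <- min(O[v, ] + forced_other + C[w, ]) > Lc + 1e-9
            res[[length(res) + 1L]] <- data.frame(
              node = w, clade = paste(below[[w]], collapse = ","),
              character = j,
              from = as.character(assign_state[v]),
              to = as.character(assign_state[w]),
              unambiguous = forced, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(res))
    return(data.frame(node = integer(0), clade = character(0),
                      character = integer(0), from = character(0),
                      to = character(0), unambiguous = logical(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out[order(out$node, out$character), , drop = FALSE]
}
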