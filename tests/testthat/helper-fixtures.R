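# Shared fixtures and independent oracles, all generated in code.

# random character matrix with optional polymorphism/missing/inapplicable and
# occasionally non-default character metadata
random_matrix <- function(n_taxa, n_char, n_states = 3, p_missing = 0.1,
                          p_poly = 0.05, p_inapp = 0.03, random_meta = FALSE) {
  cells <- matrix(NA_integer_, n_taxa, n_char)
  for (i in seq_len(n_taxa)) for (j in seq_len(n_char)) {
    u <- runif(1)
    cells[i, j] <- if (u < p_missing) {
      NA_integer_
    } else if (u < p_missing + p_inapp) {
      -1L
    } else if (u < p_missing + p_inapp + p_poly) {
      sum(bitwShiftL(1L, sample.int(n_states, 2) - 1L))
    } else {
      bitwShiftL(1L, sample.int(n_states, 1) - 1L)
    }
  }
  meta <- NULL
  if (random_meta) {
    meta <- data.frame(
      ordered = runif(n_char) < 0.2,
      active = runif(n_char) < 0.9,
      weight = sample(c(1, 1, 1, 2, 3), n_char, replace = TRUE),
      source = "",
      stringsAsFactors = FALSE
    )
  }
  character_matrix(paste0("tax", seq_len(n_taxa)), cells, meta)
}

# exhaustive-assignment parsimony oracle: minimise changes over every internal
# state assignment of a nested-list tree (independent of the Hartigan pass)
brute_fitch <- function(nl, m) {
  ctx <- cladomorph:::score_context(m)
  if (ncol(ctx$masks) == 0) return(0)
  n_internal <- function(node) {
    if (!is.list(node)) return(0L)
    1L + sum(vapply(node, n_internal, integer(1)))
  }
  ni <- n_internal(nl)
  total <- 0
  for (j in seq_len(ncol(ctx$masks))) {
    sts <- cladomorph:::states_from_mask(Reduce(bitwOr, ctx$masks[, j]))
    grid <- as.matrix(expand.grid(rep(list(sts), ni)))
    best <- Inf
    for (g in seq_len(nrow(grid))) {
      asg <- grid[g, ]
      idx <- 0L
      rec <- function(node, ps) {
        if (!is.list(node)) {
          mask <- ctx$masks[node, j]
          return(if (bitwAnd(mask, bitwShiftL(1L, ps)) != 0L) 0 else 1)
        }
        idx <<- idx + 1L
        s <- asg[idx]
        edge <- if (is.na(ps)) 0 else as.numeric(s != ps)
        edge + sum(vapply(node, rec, numeric(1), ps = s))
      }
      best <- min(best, rec(nl, NA))
    }
    total <- total + ctx$w[j] * best
  }
  total
}

# exhaustive-topology oracle: best length and the set of optimal topologies
exhaustive_search <- function(m) {
  ctx <- cladomorph:::score_context(m)
  tops <- cladomorph:::nl_all_topologies(length(m$taxa))
  lens <- vapply(tops, function(t) cladomorph:::nl_score(t, ctx), numeric(1))
  best <- min(lens)
  list(length = best,
       keys = vapply(tops[lens == best], cladomorph:::nl_canon_key,
                     character(1)))
}

tree_key <- function(phy, taxa) {
  cladomorph:::nl_canon_key(cladomorph:::phylo_to_nl(phy, taxa))
}

# monotone-alignment oracle for assign_positions: enumerate all strictly
# increasing assignments of m vertebrae to template rows
brute_assign <- function(pct_asi, template, flags, dia_max) {
  tpl <- template[!is.na(template$pct_asi), , drop = FALSE]
  m <- length(pct_asi); P <- nrow(tpl)
  best <- Inf; best_pick <- NULL
  combos <- utils::combn(P, m)
  for (k in seq_len(ncol(combos))) {
    pick <- combos[, k]
    if (any(flags & tpl$position[pick] > dia_max)) next
    err <- sum(abs(pct_asi - tpl$pct_asi[pick]))
    if (err < best - 1e-12) {
      best <- err; best_pick <- tpl$position[pick]
    }
  }
  list(total = best, positions = best_pick)
}

# triangle-decomposition point-in-convex-hull oracle (Caratheodory)
brute_in_hull <- function(px, py, hx, hy, tol = 1e-9) {
  n <- length(hx)
  same_side <- function(ax, ay, bx, by, cx, cy) {
    (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  }
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    d1 <- same_side(hx[i], hy[i], hx[j], hy[j], px, py)
    d2 <- same_side(hx[j], hy[j], hx[k], hy[k], px, py)
    d3 <- same_side(hx[k], hy[k], hx[i], hy[i], px, py)
    neg <- (d1 < -tol) || (d2 < -tol) || (d3 < -tol)
    pos <- (d1 > tol) || (d2 > tol) || (d3 > tol)
    if (!(neg && pos)) return(TRUE)
  }
  FALSE
}

caterpillar_tree <- function(labels) {
  # ((..((l1,l2),l3)..,ln-1),ln); convenient fixed topology
  txt <- paste0("(", labels[1], ",", labels[2], ")")
  for (i in 3:length(labels)) txt <- paste0("(", txt, ",", labels[i], ")")
  ape::read.tree(text = paste0(txt, ";"))
}
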