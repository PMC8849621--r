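# Deterministic synthetic-data generators.  Each generator emulates the
# statistical structure one analysis stage assumes, so the whole pipeline is
# testable without external files:
#   * discrete character matrices evolved on a known tree (homoplasy-free
#     single-change characters give the analytic anchor CI = 1 on the true
#     tree; a Poisson change process introduces controllable homoplasy);
#   * caudal series with geometrically decaying ASI plus lognormal
#     multiplicative noise and a diapophysis cutoff;
#   * multi-group measurement tables with a shared lognormal size factor
#     driving the size-dominated PC1 typical of tooth/ungual data.

#' Simulate a discrete character matrix on a known tree
#'
#' In `"homoplasy-free"` mode each character experiences exactly one change,
#' on a branch drawn proportionally to branch length, from ancestral state 0
#' to derived state 1 — so on the generating tree every character fits
#' perfectly (CI = 1).  In `"poisson"` mode the number of changes per branch
#' is Poisson(rate x branch length) and each change picks a new state
#' uniformly among the other `n_states`, allowing homoplasy.
#'
#' @param tree `ape::phylo` with branch lengths (expected change counts for
#'   the Poisson mode); at least 3 leaves.
#' @param n_characters number of characters (>= 1).
#' @param process `"homoplasy-free"` or `"poisson"`.
#' @param rate per-unit-branch-length change rate (Poisson mode).
#' @param n_states state-space size for the Poisson mode (>= 2).
#' @param missing_fraction fraction of cells masked as missing, in [0, 1).
#' @param seed integer seed; outputs are byte-identical across runs.
#' @return list with `matrix` (a [character_matrix]) and `tree` (the
#'   generating tree, unchanged).
#' @export
simulate_matrix <- function(tree, n_characters = 100,
                            process = c("homoplasy-free", "poisson"),
                            rate = 1, n_states = 2, missing_fraction = 0,
                            seed = 1L) {
  process <- match.arg(process)
  stopifnot(inherits(tree, "phylo"), n_characters >= 1,
            missing_fraction >= 0, missing_fraction < 1)
  if (length(tree$tip.label) < 3L) stop("tree needs >= 3 leaves", call. = FALSE)
  set.seed(seed)
  n <- length(tree$tip.label)
  kids <- phylo_children(tree)
  root <- n + 1L
  bl <- tree$edge.length
  if (is.null(bl)) bl <- rep(1, nrow(tree$edge))
  cells <- matrix(0L, n, n_characters)
  for (ch in seq_len(n_characters)) {
    state <- integer(n + tree$Nnode)
    state[root] <- 0L
    if (process == "homoplasy-free") {
      e_star <- sample.int(nrow(tree$edge), 1L, prob = bl / sum(bl))
      walk <- function(v, s) {
        state[v] <<- s
        for (w in kids[[v]]) {
          e <- which(tree$edge[, 1] == v & tree$edge[, 2] == w)
          walk(w, if (e == e_star) 1L else s)
        }
      }
      walk(root, 0L)
    } else {
      walk <- function(v, s) {
        state[v] <<- s
        for (w in kids[[v]]) {
          e <- which(tree$edge[, 1] == v & tree$edge[, 2] == w)
          k <- stats::rpois(1L, rate * bl[e])
          sw <- s
          if (k > 0) for (z in seq_len(k))
            sw <- sample(setdiff(0:(n_states - 1L), sw), 1L)
          walk(w, sw)
        }
      }
      walk(root, 0L)
    }
    cells[, ch] <- vapply(state[seq_len(n)], mask_from_states, integer(1))
  }
  if (missing_fraction > 0) {
    mask <- stats::runif(length(cells)) < missing_fraction
    cells[mask] <- NA_integer_
  }
  list(matrix = character_matrix(tree$tip.label, cells), tree = tree)
}

#' Simulate an associated caudal-vertebra series
#'
#' ASI at position p is `anchor_asi * asi_decay^(p-1)` times lognormal noise
#' (`sdlog = noise_sd`); centrum length decays by `length_decay` per
#' position; facet diameters are back-computed from the ASI under the
#' ellipse model with a fixed dorsoventral:mediolateral aspect ratio; a
#' diapophysis is present exactly at positions `<= diapophysis_cutoff`.
#' The rows are returned in a shuffled order with the true order alongside.
#'
#' @param n number of vertebrae (>= 2).
#' @param anchor_asi ASI of position 1 (default 0.9, an anterior-caudal
#'   value for a stout-tailed theropod).
#' @param asi_decay per-position multiplicative ASI decay in (0, 1).
#' @param length_decay per-position centrum-length decay in (0, 1].
#' @param anchor_length centrum length (mm) at position 1.
#' @param noise_sd sdlog of the lognormal multiplicative ASI noise (>= 0).
#' @param diapophysis_cutoff last position bearing a diapophysis.
#' @param seed integer seed.
#' @return list with `series` (shuffled data frame usable by [asi_profile],
#'   [order_series], ...) and `true_order` (vertebra ids, anterior first).
#' @export
simulate_caudal_series <- function(n = 15, anchor_asi = 0.9, asi_decay = 0.92,
                                   length_decay = 0.97, anchor_length = 90,
                                   noise_sd = 0, diapophysis_cutoff = 9,
                                   seed = 1L) {
  stopifnot(n >= 2, asi_decay > 0, asi_decay < 1,
            length_decay > 0, length_decay <= 1, noise_sd >= 0)
  set.seed(seed)
  p <- seq_len(n)
  asi_true <- anchor_asi * asi_decay^(p - 1)
  noise <- if (noise_sd > 0) stats::rlnorm(n, 0, noise_sd) else rep(1, n)
  noise[1] <- 1 # the anchor is the reference point
  asi_obs <- asi_true * noise
  len <- anchor_length * length_decay^(p - 1)
  area <- asi_obs * len^2
  aspect <- 1.15 # dv slightly exceeds ml, as in theropod anterior caudals
  ml <- sqrt(4 * area / (pi * aspect))
  dv <- aspect * ml
  ids <- sprintf("V%02d", p)
  series <- data.frame(
    vertebra_id = ids,
    position_true = p,
    length = len,
    dv_diameter = dv,
    ml_diameter = ml,
    has_diapophysis = p <= diapophysis_cutoff,
    anchor = p == 1L,
    stringsAsFactors = FALSE
  )
  shuffle <- c(1L, 1L + sample.int(n - 1L)) # anchor row stays first
  series <- series[shuffle, , drop = FALSE]
  rownames(series) <- NULL
  list(series = series, true_order = ids)
}

#' Simulate grouped specimen measurement tables
#'
#' Per group, draws rows from a multivariate normal with the given mean and
#' covariance, then multiplies every variable by a shared lognormal size
#' factor (`sdlog = size_sd`).  The shared factor produces the
#' size-dominated covariance structure in which PC1 carries most of the
#' variance, as in real tooth and ungual tables.  Non-positive draws are
#' rejected and resampled.
#'
#' @param groups list of specs: each a list with `label`, `mean` (named
#'   numeric vector over variables), `cov` (covariance matrix, symmetric
#'   PSD), `n` (>= 1).
#' @param size_sd sdlog of the shared size factor (0 disables it).
#' @param seed integer seed.
#' @return data frame with `specimen_id`, `group`, and one column per
#'   variable.
#' @export
simulate_measurements <- function(groups, size_sd = 0, seed = 1L) {
  set.seed(seed)
  out <- list()
  counter <- 0L
  for (g in groups) {
    stopifnot(g$n >= 1)
    vars <- names(g$mean)
    cv <- as.matrix(g$cov)
    if (any(abs(cv - t(cv)) > 1e-8) || min(eigen(cv, symmetric = TRUE,
                                                 only.values = TRUE)$values) < -1e-8)
      stop("covariance for group ", g$label,
           " is not symmetric positive semi-definite", call. = FALSE)
    ch <- chol(cv + diag(1e-12, nrow(cv)))
    draw_row <- function() {
      for (try in 1:1000) {
        x <- as.numeric(g$mean + drop(stats::rnorm(length(vars)) %*% ch))
        sz <- if (size_sd > 0) stats::rlnorm(1, 0, size_sd) else 1
        x <- x * sz
        if (all(x > 0)) return(x)
      }
      stop("rejection sampling failed to produce positive measurements",
           call. = FALSE)
    }
    rows <- t(vapply(seq_len(g$n), function(i) draw_row(), numeric(length(vars))))
    colnames(rows) <- vars
    df <- data.frame(
      specimen_id = sprintf("%s-%02d", g$label, seq_len(g$n)),
      group = g$label, rows, stringsAsFactors = FALSE, check.names = FALSE
    )
    out[[length(out) + 1L]] <- df
    counter <- counter + g$n
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
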