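# Tooth, dentary-alveolus, and pedal-ungual morphometrics.
#
# Tooth measurement tables use the standard theropod crown variables:
# CBL (crown base length), CBW (crown base width), CH (crown height), AL
# (apical length), with the derived ratios CBR = CBW/CBL and CHR = CH/CBL.
# Tables are plain data frames with a `specimen_id` column, a `group` column
# (taxon or morphotype), and one numeric column per measurement (mm).

#' Derive crown ratios from basal tooth measurements
#'
#' `CBR = CBW/CBL` (basal compression) and `CHR = CH/CBL` (relative crown
#' height).  Both are dimensionless, so measuring in mm or cm gives identical
#' values.
#'
#' @param CBL,CBW,CH crown base length, crown base width, crown height; all
#'   positive, same unit.
#' @return list with `CBR`, `CHR` (full precision) and `CBR_2`, `CHR_2`
#'   rounded to 2 decimals, the conventional reporting precision.
#' @export
derive_tooth_ratios <- function(CBL, CBW, CH) {
  vals <- c(CBL = CBL, CBW = CBW, CH = CH)
  if (anyNA(vals) || any(vals <= 0))
    stop("CBL, CBW and CH must all be present and > 0", call. = FALSE)
  CBR <- CBW / CBL
  CHR <- CH / CBL
  list(CBR = CBR, CHR = CHR, CBR_2 = round(CBR, 2), CHR_2 = round(CHR, 2))
}

#' Drop records with missing required measurements
#'
#' Standard completeness filter applied before a PCA: specimens missing any
#' of the required variables are removed, and the number of removals per
#' field is attached as the `"removed"` attribute.
#'
#' @param records a data frame.
#' @param required_fields column names that must be non-`NA`.
#' @return the filtered data frame (idempotent).
#' @export
drop_incomplete <- function(records, required_fields) {
  missing_cols <- setdiff(required_fields, names(records))
  if (length(missing_cols))
    stop("unknown fields: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  keep <- rep(TRUE, nrow(records))
  removed <- integer(length(required_fields))
  names(removed) <- required_fields
  for (f in required_fields) {
    bad <- is.na(records[[f]])
    removed[f] <- sum(bad & keep)
    keep <- keep & !bad
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Principal component analysis of a measurement table
#'
#' Eigendecomposition of the covariance matrix of the centred data
#' (`"covariance-raw"`, the default for size-dominated morphometric data),
#' of log-transformed data (`"covariance-log"`), or of the correlation
#' matrix (`"correlation"`).  Loadings are signed so that the
#' largest-magnitude loading of each component is positive.
#'
#' @param records data frame of specimens.
#' @param variables character vector (>= 2) of numeric columns to use; rows
#'   with missing values in these columns are rejected — filter first with
#'   [drop_incomplete].
#' @param scaling one of `"covariance-raw"`, `"covariance-log"`,
#'   `"correlation"`.
#' @param id_col column holding specimen identifiers (rownames of scores).
#' @return object of class `pca_result`: `eigenvalues` (descending),
#'   `variance_fraction`, `loadings` (variables x components), `scores`
#'   (specimens x components), `scaling`.
#' @export
run_pca <- function(records, variables,
                    scaling = c("covariance-raw", "covariance-log", "correlation"),
                    id_col = "specimen_id") {
  scaling <- match.arg(scaling)
  if (length(variables) < 2L) stop("need >= 2 variables", call. = FALSE)
  x <- as.matrix(records[, variables, drop = FALSE])
  if (nrow(x) < 2L) stop("need >= 2 complete records", call. = FALSE)
  if (anyNA(x))
    stop("missing values among PCA variables; apply drop_incomplete() first",
         call. = FALSE)
  if (scaling == "covariance-log") {
    if (any(x <= 0)) stop("log scaling requires positive values", call. = FALSE)
    x <- log(x)
  }
  if (scaling == "correlation") {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0))
      stop("zero-variance variable under correlation scaling: ",
           paste(variables[sds == 0], collapse = ", "), call. = FALSE)
    x <- scale(x, center = TRUE, scale = sds)
  } else {
    x <- scale(x, center = TRUE, scale = FALSE)
  }
  cv <- stats::cov(x)
  eig <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  load <- eig$vectors
  # sign convention: largest |loading| per component is positive
  for (k in seq_len(ncol(load))) {
    i <- which.max(abs(load[, k]))
    if (load[i, k] < 0) load[, k] <- -load[, k]
  }
  scores <- x %*% load
  comp <- paste0("PC", seq_along(ev))
  dimnames(load) <- list(variables, comp)
  rn <- if (id_col %in% names(records)) as.character(records[[id_col]])
        else as.character(seq_len(nrow(x)))
  dimnames(scores) <- list(rn, comp)
  structure(list(
    eigenvalues = ev,
    variance_fraction = if (sum(ev) > 0) ev / sum(ev) else ev,
    loadings = load,
    scores = scores,
    scaling = scaling
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result (%s): %d specimens, %d variables\n", x$scaling,
              nrow(x$scores), nrow(x$loadings)))
  vf <- round(100 * x$variance_fraction, 1)
  cat("  variance explained (%):", paste(vf, collapse = ", "), "\n")
  invisible(x)
}

#' Loading sign and strength report for one component
#'
#' Classifies each variable's loading on a component as positive or negative,
#' and as strong or weak relative to a fixed fraction of that component's
#' largest absolute loading.
#'
#' @param pca a `pca_result`.
#' @param component 1-based component index.
#' @param strong_frac threshold fraction of the maximum absolute loading
#'   (default 0.3) above which a loading counts as strong.
#' @return data frame with columns `variable`, `loading`, `sign`, `strength`.
#' @export
loading_sign_report <- function(pca, component = 1L, strong_frac = 0.3) {
  if (component < 1L || component > ncol(pca$loadings))
    stop("component out of range", call. = FALSE)
  ld <- pca$loadings[, component]
  thr <- strong_frac * max(abs(ld))
  data.frame(
    variable = rownames(pca$loadings),
    loading = unname(ld),
    sign = ifelse(ld >= 0, "positive", "negative"),
    strength = ifelse(abs(ld) >= thr, "strong", "weak"),
    stringsAsFactors = FALSE
  )
}

# convex hull membership with boundary counted inside
point_in_hull <- function(px, py, hx, hy, tol = 1e-9) {
  h <- grDevices::chull(hx, hy)
  hx <- hx[h]; hy <- hy[h] # counter-clockwise
  k <- length(h)
  if (k < 3L) return(NA)
  crosses <- vapply(seq_len(k), function(i) {
    j <- if (i == k) 1L else i + 1L
    (hx[j] - hx[i]) * (py - hy[i]) - (hy[j] - hy[i]) * (px - hx[i])
  }, numeric(1))
  # orientation-agnostic: inside iff on one side of (or on) every hull edge
  all(crosses >= -tol) || all(crosses <= tol)
}

#' Is a specimen inside a group's PC1-PC2 range of variability?
#'
#' Operationalizes "within the range of variability of taxon X" as membership
#' in the convex hull of the group's (PC1, PC2) scores, boundary included.
#' With fewer than 3 non-collinear group points the hull is degenerate and
#' the test falls back to a PC1 interval check, flagged in the result.
#'
#' @param scores score matrix (e.g. `pca$scores`) with at least 2 columns and
#'   specimen ids as rownames.
#' @param groups vector of group labels, one per score row.
#' @param group_label the group whose variability defines the hull.
#' @param query_id rowname of the specimen to test (it is excluded from the
#'   hull if it belongs to the group).
#' @return list with `inside` (logical) and `method` (`"hull"` or
#'   `"pc1-interval"`).
#' @export
hull_membership <- function(scores, groups, group_label, query_id) {
  stopifnot(ncol(scores) >= 2L, length(groups) == nrow(scores))
  qi <- match(query_id, rownames(scores))
  if (is.na(qi)) stop("query_id not found in scores", call. = FALSE)
  sel <- which(groups == group_label & seq_len(nrow(scores)) != qi)
  if (!length(sel)) stop("no group points for ", group_label, call. = FALSE)
  hx <- scores[sel, 1]; hy <- scores[sel, 2]
  px <- scores[qi, 1]; py <- scores[qi, 2]
  degenerate <- length(sel) < 3L ||
    length(unique(grDevices::chull(hx, hy))) < 3L
  if (degenerate) {
    inside <- px >= min(hx) - 1e-9 && px <= max(hx) + 1e-9
    return(list(inside = inside, method = "pc1-interval"))
  }
  list(inside = point_in_hull(px, py, hx, hy), method = "hull")
}

#' Dentary alveolus compression and height profiles
#'
#' For each tooth socket (alveolus) of one specimen: the compression ratio
#' (labiolingual / mesiodistal diameter; < 1 means mesiodistally long,
#' > 1 mesiodistally compressed) and the mean of the labial and lingual
#' dentary heights at that position.
#'
#' @param records data frame with columns `specimen_id`, `position` (1-based
#'   from the mesial end), `mesiodistal`, `labiolingual`, `height_labial`,
#'   `height_lingual`.
#' @param specimen_id specimen to profile.
#' @return data frame sorted by position with columns `position`,
#'   `compression_ratio`, `mean_height`.
#' @export
alveolus_profiles <- function(records, specimen_id) {
  r <- records[records$specimen_id == specimen_id, , drop = FALSE]
  if (!nrow(r)) stop("no alveoli for specimen ", specimen_id, call. = FALSE)
  if (anyDuplicated(r$position))
    stop("duplicate alveolus positions for ", specimen_id, call. = FALSE)
  r <- r[order(r$position), , drop = FALSE]
  data.frame(
    position = r$position,
    compression_ratio = r$labiolingual / r$mesiodistal,
    mean_height = (r$height_labial + r$height_lingual) / 2
  )
}

#' Nearest specimen in curvature-length space
#'
#' Finds the closest specimen to a query point under Euclidean distance after
#' per-axis z-score standardization (curvature in degrees and length in mm
#' are incommensurable).  Ties break toward the smaller row index.
#'
#' @param dataset data frame with columns `specimen_id`, `curvature`
#'   (degrees), `length` (mm).
#' @param query list or vector with `curvature` and `length`.
#' @param standardize z-score both axes over the dataset first (default
#'   TRUE).
#' @return list with `specimen_id`, `distance`, and `index`.
#' @export
nearest_specimen <- function(dataset, query, standardize = TRUE) {
  if (!nrow(dataset)) stop("empty dataset", call. = FALSE)
  query <- as.list(query)
  qc <- query[["curvature"]]; ql <- query[["length"]]
  if (is.null(qc) || is.null(ql) || is.na(qc) || is.na(ql))
    stop("query needs both curvature and length", call. = FALSE)
  cx <- dataset$curvature; lx <- dataset$length
  if (standardize) {
    mc <- mean(cx); sc <- stats::sd(cx)
    ml <- mean(lx); sl <- stats::sd(lx)
    if (sc == 0) sc <- 1
    if (sl == 0) sl <- 1
    cx <- (cx - mc) / sc; qc <- (qc - mc) / sc
    lx <- (lx - ml) / sl; ql <- (ql - ml) / sl
  }
  d <- sqrt((cx - qc)^2 + (lx - ql)^2)
  i <- which.min(d) # which.min takes the first (smallest index) on ties
  list(specimen_id = dataset$specimen_id[i], distance = d[i], index = i)
}
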