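# One-config orchestration of the full workflow: matrix protocol -> parsimony
# search and supports -> morphometric PCAs -> caudal seriation.  The report
# echoes the config and seed so every number is reproducible.

#' Validate a pipeline configuration
#'
#' Problems are returned as data, not raised: an empty character vector means
#' the config is runnable by [run_pipeline].
#'
#' @param config a nested list (see [run_pipeline] for the recognised
#'   fields), typically from `jsonlite::read_json(..., simplifyVector =
#'   TRUE)`.
#' @return character vector of problem descriptions (field path + remedy).
#' @export
validate_config <- function(config) {
  problems <- character(0)
  add <- function(msg) problems <<- c(problems, msg)
  stages <- config$stages
  enabled <- vapply(c("matrix", "phylo", "morpho", "caudal"),
                    function(s) isTRUE(stages[[s]]), logical(1))
  if (!any(enabled))
    add("stages: enable at least one of matrix, phylo, morpho, caudal")
  need_file <- function(path, field) {
    if (is.null(path)) add(sprintf("%s: required path is missing", field))
    else if (!file.exists(path)) add(sprintf("%s: file '%s' not found", field, path))
  }
  if (isTRUE(stages$matrix) || isTRUE(stages$phylo))
    need_file(config$matrix$path, "matrix.path")
  if (isTRUE(stages$phylo)) {
    reps <- config$phylo$replicates
    if (!is.null(reps) && reps < 1)
      add("phylo.replicates: must be >= 1")
    sw <- config$phylo$swapper
    if (!is.null(sw) && !sw %in% c("NNI", "SPR", "TBR"))
      add("phylo.swapper: must be one of NNI, SPR, TBR")
  }
  if (isTRUE(stages$morpho)) {
    need_file(config$morpho$table, "morpho.table")
    if (is.null(config$morpho$variables) || length(config$morpho$variables) < 2)
      add("morpho.variables: need at least 2 variable names")
  }
  if (isTRUE(stages$caudal)) {
    need_file(config$caudal$series, "caudal.series")
    need_file(config$caudal$template, "caudal.template")
  }
  problems
}

#' Run the full analysis pipeline from one configuration
#'
#' Recognised config fields (all stages optional, toggled under `stages`):
#' \describe{
#'   \item{`stages`}{list of logicals: `matrix`, `phylo`, `morpho`, `caudal`.}
#'   \item{`matrix`}{`path` (TNT or NEXUS file; format sniffed), optional
#'     `drop_characters` (1-based), `drop_taxa`, `merge_with` (second file
#'     merged after harmonising taxa to the intersection).}
#'   \item{`phylo`}{`replicates`, `swapper`, `hold`, plus logicals
#'     `consensus`, `agreement`.}
#'   \item{`morpho`}{`table` (CSV), `variables`, `scaling`.}
#'   \item{`caudal`}{`series` (CSV), `template` (CSV with `position`,
#'     `pct_asi` columns), `template_taxon` (for [diapophysis_bounds]),
#'     `area_model`.}
#'   \item{`seed`}{integer used for every stochastic step.}
#'   \item{`outdir`}{artifact directory (created); omit to skip writing.}
#' }
#'
#' @param config nested list as above.
#' @return a `run_report` list: per-stage results, `config` echo, `seed`,
#'   and `artifacts` (paths written).  Deterministic given config + inputs.
#' @export
run_pipeline <- function(config) {
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid config:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  outdir <- config$outdir
  artifacts <- character(0)
  emit <- function(name, writer) {
    if (is.null(outdir)) return(invisible(NULL))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(outdir, name)
    writer(path)
    artifacts <<- c(artifacts, path)
  }
  report <- list(config = config, seed = seed, stages = list())
  fail <- function(stage, e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)

  read_any_matrix <- function(path) {
    txt <- readLines(path, warn = FALSE)
    if (any(grepl("#NEXUS", txt, ignore.case = TRUE))) parse_nexus(txt)
    else parse_tnt(txt)
  }

  m <- NULL
  if (isTRUE(config$stages$matrix) || isTRUE(config$stages$phylo)) {
    m <- tryCatch({
      mm <- read_any_matrix(config$matrix$path)
      if (!is.null(config$matrix$drop_characters))
        mm <- drop_characters(mm, unlist(config$matrix$drop_characters))
      if (!is.null(config$matrix$drop_taxa))
        mm <- drop_taxa(mm, unlist(config$matrix$drop_taxa))
      if (!is.null(config$matrix$merge_with)) {
        b <- read_any_matrix(config$matrix$merge_with)
        shared <- intersect(mm$taxa, b$taxa)
        mm <- drop_taxa(mm, setdiff(mm$taxa, shared))
        b <- drop_taxa(b, setdiff(b$taxa, shared))
        mm <- merge_matrices(mm, b)
      }
      mm
    }, error = function(e) fail("matrix", e))
    report$stages$matrix <- list(
      status = "ok", n_taxa = length(m$taxa), n_characters = m$n_char,
      taxa = m$taxa)
    emit("matrix.tnt", function(p) writeLines(write_tnt(m), p))
  }

  if (isTRUE(config$stages$phylo)) {
    ph <- config$phylo
    res <- tryCatch({
      ts <- heuristic_search(
        m,
        n_replicates = if (is.null(ph$replicates)) 10 else ph$replicates,
        swapper = if (is.null(ph$swapper)) "TBR" else ph$swapper,
        hold = if (is.null(ph$hold)) 20 else ph$hold,
        seed = seed)
      cons <- strict_consensus(ts)
      stats <- ensemble_indices(ts$length, min_steps(m), max_steps(m))
      ag <- if (isTRUE(ph$agreement) && length(ts$trees) > 1)
        agreement_subtree(ts) else NULL
      list(ts = ts, cons = cons, stats = stats, ag = ag)
    }, error = function(e) fail("phylo", e))
    report$stages$phylo <- list(
      status = "ok",
      length = res$ts$length,
      n_mpts = length(res$ts$trees),
      CI = res$stats$CI_3, RI = res$stats$RI_3,
      consensus_newick = ape::write.tree(res$cons),
      agreement_newick = if (!is.null(res$ag)) ape::write.tree(res$ag) else NULL,
      agreement_method = if (!is.null(res$ag)) attr(res$ag, "method") else NULL)
    emit("consensus.nwk", function(p)
      ape::write.tree(res$cons, file = p))
    emit("mpts.nwk", function(p) {
      writeLines(vapply(res$ts$trees, ape::write.tree, character(1)), p)
    })
  }

  if (isTRUE(config$stages$morpho)) {
    mo <- config$morpho
    res <- tryCatch({
      tab <- utils::read.csv(mo$table, stringsAsFactors = FALSE)
      vars <- unlist(mo$variables)
      complete <- drop_incomplete(tab, vars)
      pca <- run_pca(complete, vars,
                     scaling = if (is.null(mo$scaling)) "covariance-raw"
                               else mo$scaling)
      list(tab = complete, pca = pca)
    }, error = function(e) fail("morpho", e))
    report$stages$morpho <- list(
      status = "ok",
      n_specimens = nrow(res$tab),
      removed = as.list(attr(res$tab, "removed")),
      variance_fraction = as.numeric(res$pca$variance_fraction),
      pc1_signs = loading_sign_report(res$pca, 1)$sign)
    emit("pca_scores.csv", function(p)
      utils::write.csv(data.frame(specimen_id = rownames(res$pca$scores),
                                  res$pca$scores), p, row.names = FALSE))
    emit("pca_loadings.csv", function(p)
      utils::write.csv(data.frame(variable = rownames(res$pca$loadings),
                                  res$pca$loadings), p, row.names = FALSE))
  }

  if (isTRUE(config$stages$caudal)) {
    ca <- config$caudal
    res <- tryCatch({
      series <- utils::read.csv(ca$series, stringsAsFactors = FALSE)
      template <- utils::read.csv(ca$template, stringsAsFactors = FALSE)
      model <- if (is.null(ca$area_model)) "ellipse" else ca$area_model
      ord <- order_series(series, model = model)
      series_o <- series[match(ord, series$vertebra_id), , drop = FALSE]
      prof <- asi_profile(series_o, model = model)
      lenp <- length_profile(series_o)
      bound <- if (!is.null(ca$template_taxon))
        diapophysis_bounds(ca$template_taxon) else Inf
      assign <- assign_positions(prof$pct_asi, template,
                                 series_o$has_diapophysis, bound)
      list(ord = ord, prof = prof, lenp = lenp, assign = assign,
           model = model)
    }, error = function(e) fail("caudal", e))
    report$stages$caudal <- list(
      status = "ok",
      order = as.character(res$ord),
      area_model = res$model,
      pct_asi = res$prof$pct_asi_int,
      positions = res$assign$position,
      total_error = attr(res$assign, "total_error"))
    emit("series_assignment.csv", function(p)
      utils::write.csv(cbind(vertebra_id = res$ord, res$assign), p,
                       row.names = FALSE))
  }

  report$artifacts <- artifacts
  if (!is.null(outdir))
    emit("report.json", function(p)
      jsonlite::write_json(report[setdiff(names(report), "artifacts")], p,
                           auto_unbox = TRUE, pretty = TRUE, digits = NA,
                           null = "null"))
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report — stages:", paste(names(x$stages), collapse = ", "), "\n")
  for (s in names(x$stages)) {
    st <- x$stages[[s]]
    cat(sprintf("  %s: %s\n", s, st$status))
  }
  invisible(x)
}
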