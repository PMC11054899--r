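#' Pipeline configuration
#'
#' Configures one end-to-end platform-fidelity analysis. Exactly one of
#' `sim` (a [sim_config()]; the pipeline generates its own data) or
#' `paths` (named list with elements `expression`, `samples`, `tf_sets`,
#' `pathway_sets` pointing at TSV / GMT files) must be supplied.
#'
#' @param sim A [sim_config()], or `NULL`.
#' @param paths Named list of input paths, or `NULL`.
#' @param q_threshold Strict marker q-value cutoff (default `1e-15`).
#' @param deviation_mode Deviation reading, see [platform_deviation()].
#' @param gsva A [gsva_params()].
#' @param stemness,invasiveness Gene panels for the two focused levels.
#' @param normalize Quantile-normalize each analysis matrix before use
#'   (default `TRUE`).
#' @param log2_offset If non-`NULL`, apply [log2_stabilize()] with this
#'   offset first (for raw-scale inputs; simulated data are already on the
#'   log2 scale).
#' @param cluster Build per-patient dendrograms (default `TRUE`).
#' @param out_dir If non-`NULL`, write report artifacts there.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, paths = NULL,
                            q_threshold = 1e-15,
                            deviation_mode = c("pergene-sd", "diff-sd", "rms"),
                            gsva = gsva_params(),
                            stemness = stemness_genes(),
                            invasiveness = invasiveness_genes(),
                            normalize = TRUE,
                            log2_offset = NULL,
                            cluster = TRUE,
                            out_dir = NULL) {
  if (is.null(sim) == is.null(paths)) {
    abort("supply exactly one of `sim` (simulation config) or `paths` (input files)")
  }
  if (!is.null(sim)) sim <- validate_sim_config(unclass(sim))
  if (!is.null(paths)) {
    need <- c("expression", "samples", "tf_sets", "pathway_sets")
    missing_el <- setdiff(need, names(paths))
    if (length(missing_el)) {
      abort(sprintf("paths must name: %s (missing: %s)",
                    paste(need, collapse = ", "), paste(missing_el, collapse = ", ")))
    }
    absent <- !vapply(paths[need], file.exists, logical(1L))
    if (any(absent)) {
      abort(sprintf("input file(s) not found: %s",
                    paste(unlist(paths[need][absent]), collapse = ", ")))
    }
  }
  structure(list(sim = sim, paths = paths, q_threshold = q_threshold,
                 deviation_mode = match.arg(deviation_mode),
                 gsva = gsva, stemness = as.character(stemness),
                 invasiveness = as.character(invasiveness),
                 normalize = isTRUE(normalize), log2_offset = log2_offset,
                 cluster = isTRUE(cluster), out_dir = out_dir),
            class = "pipeline_config")
}

#' Consensus platform ranking
#'
#' Combines per-level rankings into one ordering by mean rank position
#' (ties broken by platform name). The consensus is a package-level
#' summary across the per-level results, which remain the primary output.
#'
#' @param per_level_ranks Named list: level -> character vector of
#'   platforms, most tissue-faithful first. All levels must rank the same
#'   platform set.
#' @return Character vector: consensus ordering, best first.
#' @export
consensus_rank <- function(per_level_ranks) {
  if (length(per_level_ranks) == 0L || is.null(names(per_level_ranks)) ||
      any(names(per_level_ranks) == "")) {
    abort("per_level_ranks must be a non-empty named list of rankings")
  }
  if (any(vapply(per_level_ranks, is.null, logical(1L)))) {
    abort(sprintf("missing ranking for level(s): %s",
                  paste(names(per_level_ranks)[vapply(per_level_ranks, is.null, logical(1L))],
                        collapse = ", ")))
  }
  plats <- sort(per_level_ranks[[1L]])
  ok <- vapply(per_level_ranks, function(r) identical(sort(r), plats), logical(1L))
  if (!all(ok)) abort("every level must rank the same platform set")
  mean_rank <- rowMeans(vapply(per_level_ranks,
                               function(r) match(plats, r), numeric(length(plats))))
  plats[order(mean_rank, plats)]
}

#' Run the platform-fidelity pipeline
#'
#' Executes the full analysis: acquire data (simulate or load), normalize,
#' select tumor marker genes from the reference cohorts, compute
#' platform-versus-tissue deviations at five levels (marker genes,
#' stemness panel, invasiveness panel, TF activity and pathway activity via
#' sample-wise enrichment), normalize deviations per sample, summarize
#' (mean +/- SEM over patients), rank platforms per level and by
#' consensus, and cluster each patient's samples. With `out_dir` set, the
#' report JSON, result tables and per-patient Newick trees are written to
#' disk. Identical configuration (and seed, in simulation mode) yields an
#' identical report.
#'
#' @param config A [pipeline_config()].
#' @return A `fidelity_report` object; see [tidy.fidelity_report()].
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  truth <- NULL
  if (!is.null(config$sim)) {
    study <- stage("simulate", simulate_study(config$sim))
    ref_expr <- study$reference$expression
    ref_samples <- study$reference$samples
    panel_expr <- study$panel$expression
    panel_samples <- study$panel$samples
    tf_sets <- study$collections$tf
    pw_sets <- study$collections$pathways
    truth <- study$truth
    digests <- NULL
    seed <- config$sim$seed
  } else {
    expr <- stage("load", read_expression_matrix(config$paths$expression))
    samples <- stage("load", read_sample_table(config$paths$samples))
    tf_sets <- stage("load", read_gmt(config$paths$tf_sets))
    pw_sets <- stage("load", read_gmt(config$paths$pathway_sets))
    is_ref <- samples$condition %in% c("normal_ref", "tumor_ref")
    ref_samples <- samples[is_ref, , drop = FALSE]
    panel_samples <- samples[!is_ref, , drop = FALSE]
    ref_expr <- expr[, intersect(colnames(expr), ref_samples$sample_id), drop = FALSE]
    panel_expr <- expr[, intersect(colnames(expr), panel_samples$sample_id), drop = FALSE]
    digests <- as.list(tools::md5sum(unlist(config$paths[c(
      "expression", "samples", "tf_sets", "pathway_sets")])))
    seed <- NA_integer_
  }
  if (!is.null(config$log2_offset)) {
    ref_expr <- stage("preprocess", log2_stabilize(ref_expr, config$log2_offset))
    panel_expr <- stage("preprocess", log2_stabilize(panel_expr, config$log2_offset))
  }
  if (config$normalize) {
    ref_expr <- stage("preprocess", quantile_normalize(ref_expr))
    panel_expr <- stage("preprocess", quantile_normalize(panel_expr))
  }
  markers <- stage("select_markers",
                   select_markers(ref_expr, ref_samples, config$q_threshold))
  gbm_panel <- marker_genes(markers)
  dev_gene <- stage("deviation", dplyr::bind_rows(
    platform_deviation(panel_expr, panel_samples, gbm_panel,
                       mode = config$deviation_mode, level = "gbm_genes"),
    platform_deviation(panel_expr, panel_samples, config$stemness,
                       mode = config$deviation_mode, level = "stemness"),
    platform_deviation(panel_expr, panel_samples, config$invasiveness,
                       mode = config$deviation_mode, level = "invasiveness")))
  es_both <- stage("enrichment", gsva_scores_multi(
    panel_expr, list(tf = tf_sets, pathways = pw_sets), config$gsva))
  es_tf <- es_both$tf
  es_pw <- es_both$pathways
  dev_es <- stage("deviation", dplyr::bind_rows(
    deviation_on_enrichment(es_tf, panel_samples, level = "tf_activity",
                            mode = config$deviation_mode),
    deviation_on_enrichment(es_pw, panel_samples, level = "pathways",
                            mode = config$deviation_mode)))
  deviations <- stage("normalize",
                      normalize_per_sample(dplyr::bind_rows(dev_gene, dev_es)))
  summary <- stage("summarize", summarize_deviation(deviations))
  rankings <- lapply(setNames(nm = deviation_levels()),
                     function(lv) platform_ranking(summary, lv))
  consensus <- stage("consensus", consensus_rank(rankings))
  dendrograms <- newick <- NULL
  if (config$cluster) {
    dendrograms <- stage("cluster",
                         cluster_samples(panel_expr, panel_samples, gbm_panel))
    newick <- vapply(dendrograms, export_newick, character(1L))
  }
  report <- structure(list(
    deviations = deviations,
    summary = summary,
    rankings = rankings,
    consensus = consensus,
    markers = markers,
    enrichment = list(tf_activity = es_tf, pathways = es_pw),
    dendrograms = dendrograms,
    newick = newick,
    truth = truth,
    provenance = list(
      package = "platfid",
      version = as.character(utils::packageVersion("platfid")),
      mode = if (is.null(config$sim)) "paths" else "simulation",
      seed = seed,
      q_threshold = config$q_threshold,
      deviation_mode = config$deviation_mode,
      gsva = unclass(config$gsva),
      input_digests = digests)),
    class = "fidelity_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# Serializable body of a report (everything but R-only objects); this is
# what the JSON artifact contains and what the schema describes.
report_body <- function(report) {
  list(
    provenance = report$provenance,
    summary = as.list(as_tibble(report$summary)),
    deviations = as.list(as_tibble(report$deviations)),
    rankings = report$rankings,
    consensus = report$consensus,
    markers = as.list(glance(report$markers)),
    dendrograms = as.list(report$newick))
}

#' Write report artifacts
#'
#' Writes `report.json` (the machine-readable report), `summary.tsv`,
#' `deviations.tsv`, `markers.tsv` and one Newick file per patient
#' dendrogram into `dir`.
#'
#' @param report A `fidelity_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "fidelity_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_body(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  utils::write.table(as_tibble(report$summary), file.path(dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as_tibble(report$deviations), file.path(dir, "deviations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tidy(report$markers), file.path(dir, "markers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(report$newick)) {
    writeLines(report$newick[[nm]], file.path(dir, sprintf("dendrogram_%s.nwk", nm)))
  }
  invisible(dir)
}

#' Structurally validate a fidelity report
#'
#' Checks a report (or a parsed `report.json`) against the shipped schema's
#' structure: required blocks present, per-level rankings and the consensus
#' are permutations of one platform set, and the summary table carries the
#' expected columns. The JSON Schema document itself is installed at
#' `system.file("schema", "fidelity-report.schema.json", package = "platfid")`.
#'
#' @param x A `fidelity_report`, a parsed JSON list, or a path to a
#'   `report.json`.
#' @return `TRUE`, invisibly; otherwise an error describing the violation.
#' @export
validate_report <- function(x) {
  if (inherits(x, "fidelity_report")) x <- report_body(x)
  if (is.character(x) && length(x) == 1L) {
    x <- jsonlite::read_json(x, simplifyVector = TRUE)
  }
  need <- c("provenance", "summary", "deviations", "rankings", "consensus", "markers")
  missing_el <- setdiff(need, names(x))
  if (length(missing_el)) {
    abort(sprintf("report is missing block(s): %s", paste(missing_el, collapse = ", ")))
  }
  scols <- c("level", "platform", "mean_deviation", "sem", "n_patients", "rank")
  if (!all(scols %in% names(x$summary))) {
    abort(sprintf("report summary must have columns: %s", paste(scols, collapse = ", ")))
  }
  plats <- sort(unique(unlist(x$summary$platform)))
  ranks <- lapply(x$rankings, unlist)
  bad <- names(ranks)[!vapply(ranks, function(r) identical(sort(r), plats), logical(1L))]
  if (length(bad)) {
    abort(sprintf("ranking for level(s) %s is not a permutation of the platform set",
                  paste(bad, collapse = ", ")))
  }
  if (!identical(sort(unlist(x$consensus)), plats)) {
    abort("consensus is not a permutation of the platform set")
  }
  if (!all(c("package", "version", "mode") %in% names(x$provenance))) {
    abort("provenance must record package, version and mode")
  }
  invisible(TRUE)
}

#' @export
print.fidelity_report <- function(x, ...) {
  cat("<fidelity_report>\n")
  cat(sprintf("  markers: %d selected of %d tested (q < %g)\n",
              sum(x$markers$selected), nrow(x$markers),
              attr(x$markers, "threshold")))
  cat(sprintf("  levels: %s\n", paste(unique(x$summary$level), collapse = ", ")))
  cat(sprintf("  consensus ranking: %s\n", paste(x$consensus, collapse = " < ")))
  invisible(x)
}

#' Tidy a fidelity report
#'
#' @param x A `fidelity_report`.
#' @param ... Unused.
#' @return `tidy()`: the per-(patient, platform, level) deviation tibble.
#'   `glance()`: a one-row overview (marker count, consensus winner, sizes).
#' @export
tidy.fidelity_report <- function(x, ...) {
  as_tibble(x$deviations)
}

#' @rdname tidy.fidelity_report
#' @export
glance.fidelity_report <- function(x, ...) {
  tibble(n_markers = sum(x$markers$selected),
         n_patients = length(unique(x$deviations$patient_id)),
         n_levels = length(unique(x$deviations$level)),
         best_platform = x$consensus[1L],
         worst_platform = x$consensus[length(x$consensus)])
}
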