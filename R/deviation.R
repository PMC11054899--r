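#' Two-value paired standard deviation
#'
#' The sample standard deviation of the pair `{x, y}`, which reduces to
#' `|x - y| / sqrt(2)`. This is the elementary deviation between a platform
#' value and its paired tissue value; vectorized.
#'
#' @param x,y Finite numeric vectors (recycled to a common length).
#' @return Non-negative numeric vector.
#' @examples
#' paired_sd(1, 2) # 0.7071
#' @export
paired_sd <- function(x, y) {
  abs(x - y) / sqrt(2)
}

# Shared engine for gene-level and enrichment-level deviations.
# `features` plays the role of the gene panel (or the full set list).
deviation_core <- function(x, samples, features, mode, level, min_features) {
  validate_expression_matrix(x, what = "feature matrix")
  samples <- validate_sample_table(samples)
  mode <- match.arg(mode, c("pergene-sd", "diff-sd", "rms"))
  features <- unique(as.character(features))
  present <- intersect(features, rownames(x))
  dropped <- length(features) - length(present)
  if (dropped > 0L) {
    inform(sprintf("deviation: %d panel feature(s) absent from the matrix, dropped",
                   dropped))
  }
  if (length(present) < min_features) {
    abort(sprintf("deviation: only %d panel feature(s) present; need >= %d",
                  length(present), min_features))
  }
  if (mode == "diff-sd" && length(present) < 2L) {
    abort("deviation mode 'diff-sd' needs >= 2 panel features")
  }
  samples <- samples[samples$sample_id %in% colnames(x), , drop = FALSE]
  plat <- samples[samples$condition %in% platform_conditions(), , drop = FALSE]
  if (nrow(plat) == 0L) abort("no platform samples found")
  patients <- unique(plat$patient_id)
  tissue_of <- setNames(samples$sample_id[samples$condition == "tissue"],
                        samples$patient_id[samples$condition == "tissue"])
  no_tissue <- setdiff(patients, names(tissue_of))
  if (length(no_tissue)) {
    abort(sprintf("patient(s) without a paired tissue sample in the matrix: %s",
                  paste(no_tissue, collapse = ", ")))
  }
  xm <- x[present, , drop = FALSE]
  rows <- purrr::pmap(
    list(plat$sample_id, plat$patient_id, plat$condition),
    function(sid, pid, cond) {
      d <- xm[, sid] - xm[, tissue_of[[pid]]]
      raw <- switch(mode,
                    "pergene-sd" = mean(abs(d) / sqrt(2)),
                    "diff-sd" = sd(d),
                    "rms" = sqrt(mean(d^2)))
      tibble(patient_id = pid, platform = cond, raw_deviation = raw)
    })
  out <- dplyr::bind_rows(rows)
  # replicate samples of one (patient, platform) average to a single row
  out <- dplyr::summarise(dplyr::group_by(out, .data$patient_id, .data$platform),
                          raw_deviation = mean(.data$raw_deviation), .groups = "drop")
  out <- dplyr::mutate(out, level = level, .before = "raw_deviation")
  attr(out, "n_dropped") <- dropped
  attr(out, "mode") <- mode
  out
}

#' Platform-versus-tissue deviation over a gene panel
#'
#' For each (patient, platform) pair, quantifies the transcriptional
#' deviation of the platform sample from the patient's paired tissue over a
#' gene panel. The default reading (`mode = "pergene-sd"`) is the mean over
#' panel genes of the two-value standard deviation [paired_sd()] between
#' the platform and tissue values; `"diff-sd"` instead takes the standard
#' deviation across genes of the platform-minus-tissue differences, and
#' `"rms"` the root-mean-square difference.
#'
#' Panel genes absent from the matrix are dropped with a message; fewer
#' than 2 remaining is an error.
#'
#' @param x Expression matrix covering the paired samples.
#' @param samples Sample table defining the tissue-platform pairing.
#' @param panel Character vector of panel gene ids.
#' @param mode Deviation reading; see Description.
#' @param level Label stored in the `level` column (default `"gbm_genes"`).
#' @return A tibble with columns `patient_id`, `platform`, `level`,
#'   `raw_deviation`.
#' @seealso [normalize_per_sample()], [summarize_deviation()]
#' @export
platform_deviation <- function(x, samples, panel,
                               mode = c("pergene-sd", "diff-sd", "rms"),
                               level = "gbm_genes") {
  deviation_core(x, samples, panel, match.arg(mode), level, min_features = 2L)
}

#' Deviation of enrichment profiles from tissue
#'
#' Identical computation to [platform_deviation()] with gene sets playing
#' the role of genes: the input is a set-by-sample enrichment matrix (see
#' [gsva_scores()]) and the panel is all of its sets.
#'
#' @param es Enrichment matrix (sets x samples) covering the paired samples.
#' @param samples Sample table defining the tissue-platform pairing.
#' @param level Label stored in the `level` column, conventionally
#'   `"tf_activity"` or `"pathways"`.
#' @inheritParams platform_deviation
#' @return A tibble with columns `patient_id`, `platform`, `level`,
#'   `raw_deviation`.
#' @export
deviation_on_enrichment <- function(es, samples, level = "tf_activity",
                                    mode = c("pergene-sd", "diff-sd", "rms")) {
  deviation_core(es, samples, rownames(es), match.arg(mode), level,
                 min_features = 1L)
}

#' Normalize deviations per sample
#'
#' Rescales raw deviations so that, for every patient (and level), the
#' average deviation from tissue across platforms is exactly 1:
#' `normalized = raw / mean(raw across that patient's platforms)`.
#'
#' @param x A tibble from [platform_deviation()] /
#'   [deviation_on_enrichment()] (columns `patient_id`, `platform`,
#'   `level`, `raw_deviation`).
#' @return The input with a `normalized_deviation` column appended.
#' @export
normalize_per_sample <- function(x) {
  need <- c("patient_id", "platform", "level", "raw_deviation")
  if (!all(need %in% names(x))) {
    abort(sprintf("expected columns: %s", paste(need, collapse = ", ")))
  }
  if (any(x$raw_deviation < 0)) abort("raw deviations must be >= 0")
  grp <- dplyr::group_by(as_tibble(x), .data$patient_id, .data$level)
  grp <- dplyr::mutate(grp, .mean_raw = mean(.data$raw_deviation))
  bad <- dplyr::filter(grp, .data$.mean_raw <= 0)
  if (nrow(bad) > 0L) {
    abort(sprintf(
      "all-zero deviations for patient(s) %s: per-sample normalization undefined",
      paste(unique(bad$patient_id), collapse = ", ")))
  }
  out <- dplyr::mutate(grp,
                       normalized_deviation = .data$raw_deviation / .data$.mean_raw)
  out <- dplyr::ungroup(out)
  dplyr::select(out, -".mean_raw")
}

#' Summarize and rank platforms
#'
#' Per (level, platform): mean and standard error of the mean (sample sd
#' with `n - 1` denominator over patients, divided by `sqrt(n)`) of the
#' normalized deviations, plus the platform rank (ascending by mean; ties
#' broken by platform name). Rank 1 is the most tissue-faithful platform.
#'
#' @param x A tibble from [normalize_per_sample()].
#' @param value Column to summarize (default `normalized_deviation`).
#' @return A `deviation_summary` tibble with columns `level`, `platform`,
#'   `mean_deviation`, `sem`, `n_patients`, `rank`.
#' @export
summarize_deviation <- function(x, value = "normalized_deviation") {
  if (!value %in% names(x)) abort(sprintf("column '%s' not found", value))
  grp <- dplyr::group_by(as_tibble(x), .data$level, .data$platform)
  out <- dplyr::summarise(grp,
                          mean_deviation = mean(.data[[value]]),
                          sem = sd(.data[[value]]) / sqrt(dplyr::n()),
                          n_patients = dplyr::n(),
                          .groups = "drop")
  if (any(out$n_patients < 2L)) {
    abort("SEM needs >= 2 patients per (level, platform)")
  }
  out <- dplyr::group_by(out, .data$level)
  out <- dplyr::mutate(out, rank = order(order(.data$mean_deviation, .data$platform)))
  out <- dplyr::arrange(dplyr::ungroup(out), .data$level, .data$rank)
  class(out) <- c("deviation_summary", class(out))
  out
}

#' Platform ranking from a deviation summary
#'
#' @param x A `deviation_summary` tibble (one level).
#' @param level Which level to extract (defaults to the only one present).
#' @return Character vector of platforms, most tissue-faithful first.
#' @export
platform_ranking <- function(x, level = NULL) {
  if (is.null(level)) {
    lv <- unique(x$level)
    if (length(lv) != 1L) abort("multiple levels present; pick one with `level`")
    level <- lv
  }
  sub <- x[x$level == level, , drop = FALSE]
  if (nrow(sub) == 0L) abort(sprintf("level '%s' not found", level))
  sub$platform[order(sub$rank)]
}
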