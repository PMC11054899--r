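#' Validate a gene-by-sample expression matrix
#'
#' An expression matrix is a numeric matrix on the log2-intensity scale with
#' unique, non-empty gene ids as row names and unique sample ids as column
#' names; every value must be finite.
#'
#' @param x A numeric matrix.
#' @param what Label used in error messages.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_expression_matrix <- function(x, what = "expression matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("%s must be a numeric matrix", what))
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    abort(sprintf("%s must have at least one gene and one sample", what))
  }
  gid <- rownames(x)
  sid <- colnames(x)
  if (is.null(gid) || anyNA(gid) || any(gid == "")) {
    abort(sprintf("%s must have non-empty gene ids as row names", what))
  }
  if (is.null(sid) || anyNA(sid) || any(sid == "")) {
    abort(sprintf("%s must have non-empty sample ids as column names", what))
  }
  if (anyDuplicated(gid)) {
    abort(sprintf("duplicate gene id(s) in %s: %s", what,
                  paste(unique(gid[duplicated(gid)]), collapse = ", ")))
  }
  if (anyDuplicated(sid)) {
    abort(sprintf("duplicate sample id(s) in %s: %s", what,
                  paste(unique(sid[duplicated(sid)]), collapse = ", ")))
  }
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    abort(sprintf("non-finite value in %s at gene '%s', sample '%s'",
                  what, gid[bad[1L]], sid[bad[2L]]))
  }
  invisible(x)
}

#' Read a tab-delimited expression matrix
#'
#' The file must be tab-delimited with a header row whose first field is
#' `gene_id` followed by the sample ids, and one row per gene. All
#' expression cells must parse as finite numbers; duplicated gene or sample
#' ids are rejected with the offending id named.
#'
#' @param path Path to a TSV file.
#' @return A validated numeric matrix (genes x samples) preserving the
#'   file's row and column order.
#' @seealso [write_expression_matrix()]
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) < 2L) {
    abort(sprintf("%s: expected a header row and at least one gene row", path))
  }
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L) {
    abort(sprintf("%s: header must contain 'gene_id' and at least one sample id", path))
  }
  if (header[1L] != "gene_id") {
    abort(sprintf("%s: first header field must be 'gene_id', found '%s'",
                  path, header[1L]))
  }
  sample_ids <- header[-1L]
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nfield <- lengths(body)
  if (any(nfield != length(header))) {
    bad <- which(nfield != length(header))[1L]
    abort(sprintf("%s: row %d has %d fields, expected %d",
                  path, bad + 1L, nfield[bad], length(header)))
  }
  gene_ids <- vapply(body, `[[`, character(1L), 1L)
  cells <- matrix(unlist(lapply(body, `[`, -1L), use.names = FALSE),
                  nrow = length(body), byrow = TRUE)
  values <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  if (anyNA(values) || !all(is.finite(values))) {
    bad <- which(is.na(values) | !is.finite(values), arr.ind = TRUE)[1L, ]
    abort(sprintf(
      "%s: cell '%s' at gene '%s' (row %d), sample '%s' (column %d) is not a finite number",
      path, cells[bad[1L], bad[2L]], gene_ids[bad[1L]], bad[1L] + 1L,
      sample_ids[bad[2L]], bad[2L] + 1L))
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  validate_expression_matrix(values, what = sprintf("expression matrix '%s'", path))
  values
}

#' Write an expression matrix to a tab-delimited file
#'
#' Values are written with full double precision (`%.17g`) so that
#' [read_expression_matrix()] reproduces the matrix exactly.
#'
#' @param x A validated expression matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  validate_expression_matrix(x)
  header <- paste(c("gene_id", colnames(x)), collapse = "\t")
  rows <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], sprintf("%.17g", x[i, ])), collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a sample table
#'
#' A sample table maps each sample to a patient and a condition. The file
#' must be tab-delimited with columns `sample_id`, `patient_id`,
#' `condition`; the condition vocabulary is closed (see
#' [sample_conditions()]).
#'
#' @param path Path to a TSV file.
#' @return A validated tibble with character columns `sample_id`,
#'   `patient_id`, `condition`.
#' @seealso [validate_sample_table()], [write_sample_table()]
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  validate_sample_table(as_tibble(df))
}

#' @rdname read_sample_table
#' @param x A data frame with columns `sample_id`, `patient_id`, `condition`.
#' @export
validate_sample_table <- function(x) {
  need <- c("sample_id", "patient_id", "condition")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    abort(sprintf("sample table is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  x <- as_tibble(x)[need]
  x[] <- lapply(x, as.character)
  if (anyNA(x) || any(unlist(x) == "")) {
    abort("sample table contains empty or missing fields")
  }
  if (anyDuplicated(x$sample_id)) {
    abort(sprintf("duplicate sample id(s): %s",
                  paste(unique(x$sample_id[duplicated(x$sample_id)]), collapse = ", ")))
  }
  bad_cond <- setdiff(unique(x$condition), sample_conditions())
  if (length(bad_cond)) {
    abort(sprintf("unknown condition(s) %s; allowed values: %s",
                  paste(sQuote(bad_cond), collapse = ", "),
                  paste(sample_conditions(), collapse = ", ")))
  }
  # tissue pairing: a patient appearing with a platform condition must have
  # exactly one tissue sample
  is_platform <- x$condition %in% platform_conditions()
  tissue_count <- table(x$patient_id[x$condition == "tissue"])
  if (any(tissue_count > 1L)) {
    abort(sprintf("patient(s) with more than one tissue sample: %s",
                  paste(names(tissue_count)[tissue_count > 1L], collapse = ", ")))
  }
  plat_patients <- unique(x$patient_id[is_platform])
  no_tissue <- setdiff(plat_patients, names(tissue_count))
  if (length(no_tissue)) {
    abort(sprintf("patient(s) with platform samples but no tissue sample: %s",
                  paste(no_tissue, collapse = ", ")))
  }
  # reference cohorts live in their own patient-id namespace
  is_ref <- x$condition %in% c("normal_ref", "tumor_ref")
  clash <- intersect(unique(x$patient_id[is_ref]), unique(x$patient_id[!is_ref]))
  if (length(clash)) {
    abort(sprintf(
      "patient id(s) used by both reference and paired samples: %s",
      paste(clash, collapse = ", ")))
  }
  x
}

#' @rdname read_sample_table
#' @export
write_sample_table <- function(x, path) {
  x <- validate_sample_table(x)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
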