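#' Log2 variance stabilization
#'
#' Elementwise `log2(x + offset)`. This is the package's stand-in for
#' bead-array variance stabilization: the original transform is
#' parameterized by probe-level variance estimates that do not exist at
#' gene level, so a shifted log is used instead (and the synthetic
#' generator emits already-stabilized values, making this step optional in
#' simulated pipelines).
#'
#' @param x An expression matrix (see [validate_expression_matrix()]).
#' @param offset Non-negative shift added before the log (default 1).
#' @return The transformed matrix, ids unchanged.
#' @export
log2_stabilize <- function(x, offset = 1) {
  validate_expression_matrix(x)
  if (!is.finite(offset) || offset < 0) abort("offset must be finite and >= 0")
  shifted <- x + offset
  if (any(shifted <= 0)) {
    bad <- which(shifted <= 0, arr.ind = TRUE)[1L, ]
    abort(sprintf(
      "log2_stabilize: value + offset <= 0 at gene '%s', sample '%s' (value %g, offset %g)",
      rownames(x)[bad[1L]], colnames(x)[bad[2L]], x[bad[1L], bad[2L]], offset))
  }
  out <- log2(shifted)
  dimnames(out) <- dimnames(x)
  out
}

#' Quantile normalization
#'
#' Forces every sample (column) onto a common distribution: the reference
#' is the per-rank mean of the column-sorted values, each value is replaced
#' by the reference value at its rank, and ties within a column receive the
#' mean of the reference values over the tied rank range (a k-way tie maps
#' to the plain average of the k reference values it spans,
#' deterministically).
#'
#' @param x An expression matrix with at least 2 samples.
#' @return The normalized matrix, ids unchanged.
#' @export
quantile_normalize <- function(x) {
  validate_expression_matrix(x)
  if (ncol(x) < 2L) {
    abort("quantile normalization needs >= 2 samples")
  }
  ref <- rowMeans(apply(x, 2L, sort))
  cref <- cumsum(ref)
  out <- x
  for (j in seq_len(ncol(x))) {
    lo <- rank(x[, j], ties.method = "min")
    hi <- rank(x[, j], ties.method = "max")
    out[, j] <- (cref[hi] - c(0, cref)[lo]) / (hi - lo + 1)
  }
  dimnames(out) <- dimnames(x)
  out
}
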