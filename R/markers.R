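#' Two-sample Student's t-test (pooled variance)
#'
#' Classical two-sample t with pooled variance,
#' `df = n_a + n_b - 2`, and a two-tailed p-value from the t distribution.
#' A Welch (unpooled) variant is available via `var_equal = FALSE`.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param var_equal Pool the variances (default `TRUE`, classical Student).
#' @return A one-row tibble with `statistic`, `df`, `p.value`.
#' @examples
#' student_t_two_tailed(c(1, 2, 3), c(4, 5, 6))
#' @export
student_t_two_tailed <- function(a, b, var_equal = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) abort("each group needs >= 2 values")
  if (anyNA(a) || anyNA(b)) abort("missing values are not allowed")
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    if (sp2 <= 0) abort("zero pooled variance: t statistic undefined")
    df <- na + nb - 2
    se <- sqrt(sp2 * (1 / na + 1 / nb))
  } else {
    if (va <= 0 && vb <= 0) abort("zero variance in both groups: t statistic undefined")
    se <- sqrt(va / na + vb / nb)
    df <- se^4 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (mean(a) - mean(b)) / se
  tibble(statistic = t, df = df, p.value = 2 * pt(-abs(t), df))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: with order statistics `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min over j >= i of m * p_(j) / j`, capped at 1, returned in the
#' input order. Delegates to `stats::p.adjust(method = "BH")`, which is
#' this definition.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values in input order.
#' @export
bh_fdr <- function(p) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

# Vectorized per-gene pooled-variance t-test of two column groups.
# Genes constant across ALL reference samples get t = 0, p = 1; genes with
# zero pooled variance but distinct group means separate perfectly
# (t = +/-Inf, p = 0) -- the noise-free limit.
row_t_pooled <- function(x, idx_a, idx_b) {
  na <- length(idx_a); nb <- length(idx_b)
  xa <- x[, idx_a, drop = FALSE]
  xb <- x[, idx_b, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  df <- na + nb - 2
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  diff <- ma - mb
  t <- diff / se
  zero_var <- sp2 <= 0
  t[zero_var & diff == 0] <- 0
  t[zero_var & diff != 0] <- sign(diff[zero_var & diff != 0]) * Inf
  p <- 2 * pt(-abs(t), df)
  list(statistic = unname(t), p.value = unname(p), df = df,
       n_constant = sum(zero_var & diff == 0))
}

#' Select tumor marker genes by differential expression
#'
#' Runs a per-gene two-tailed pooled-variance t-test between the
#' `normal_ref` and `tumor_ref` samples, adjusts all p-values with
#' Benjamini-Hochberg, and selects genes with `q < threshold` (strict).
#' Genes constant across all reference samples are assigned `p = 1` (their
#' count is reported) rather than aborting the run.
#'
#' @param x Expression matrix containing the reference samples.
#' @param samples Sample table; needs >= 2 `normal_ref` and >= 2
#'   `tumor_ref` rows matching columns of `x`.
#' @param threshold Strict q-value cutoff (default `1e-15`).
#' @param var_equal Pool the variances (default `TRUE`); `FALSE` gives the
#'   Welch variant.
#' @return A `marker_selection` object: a tibble with columns `gene_id`,
#'   `statistic`, `p.value`, `q.value`, `selected`, carrying the threshold,
#'   group sizes and constant-gene count as attributes.
#' @seealso [marker_genes()], [tidy.marker_selection()],
#'   [glance.marker_selection()]
#' @export
select_markers <- function(x, samples, threshold = 1e-15, var_equal = TRUE) {
  validate_expression_matrix(x)
  samples <- validate_sample_table(samples)
  ids_n <- samples$sample_id[samples$condition == "normal_ref"]
  ids_t <- samples$sample_id[samples$condition == "tumor_ref"]
  ids_n <- intersect(ids_n, colnames(x))
  ids_t <- intersect(ids_t, colnames(x))
  if (length(ids_n) < 2L || length(ids_t) < 2L) {
    abort("need >= 2 normal_ref and >= 2 tumor_ref samples present in the matrix")
  }
  if (!is.finite(threshold) || threshold < 0) abort("threshold must be >= 0")
  if (var_equal) {
    res <- row_t_pooled(x, match(ids_n, colnames(x)), match(ids_t, colnames(x)))
  } else {
    res_rows <- lapply(seq_len(nrow(x)), function(i) {
      a <- x[i, ids_n]; b <- x[i, ids_t]
      if (stats::var(a) <= 0 && stats::var(b) <= 0) {
        tibble(statistic = if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf,
               df = NA_real_,
               p.value = if (mean(a) == mean(b)) 1 else 0)
      } else {
        student_t_two_tailed(a, b, var_equal = FALSE)
      }
    })
    joined <- dplyr::bind_rows(res_rows)
    res <- list(statistic = joined$statistic, p.value = joined$p.value,
                df = joined$df,
                n_constant = sum(joined$statistic == 0 & joined$p.value == 1))
  }
  if (res$n_constant > 0L) {
    inform(sprintf("select_markers: %d constant gene(s) assigned p = 1", res$n_constant))
  }
  q <- bh_fdr(res$p.value)
  out <- tibble(gene_id = rownames(x),
                statistic = res$statistic,
                p.value = res$p.value,
                q.value = q,
                selected = q < threshold)
  structure(out,
            class = c("marker_selection", class(out)),
            threshold = threshold,
            n_normal = length(ids_n), n_tumor = length(ids_t),
            n_constant = res$n_constant, var_equal = var_equal)
}

#' Selected marker gene ids
#'
#' @param x A `marker_selection` object.
#' @return Character vector of gene ids with `q < threshold`.
#' @export
marker_genes <- function(x) {
  stopifnot(inherits(x, "marker_selection"))
  x$gene_id[x$selected]
}

#' @export
print.marker_selection <- function(x, ...) {
  cat(sprintf(
    "<marker_selection> %d genes tested (%d normal vs %d tumor), %d selected at q < %g\n",
    nrow(x), attr(x, "n_normal"), attr(x, "n_tumor"),
    sum(x$selected), attr(x, "threshold")))
  print(as_tibble(x), ...)
  invisible(x)
}

#' Tidy a marker selection
#'
#' @param x A `marker_selection` object.
#' @param ... Unused.
#' @return `tidy()`: the per-gene result tibble. `glance()`: a one-row
#'   summary (counts, threshold, group sizes).
#' @export
tidy.marker_selection <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @rdname tidy.marker_selection
#' @export
glance.marker_selection <- function(x, ...) {
  tibble(n_genes = nrow(x),
         n_selected = sum(x$selected),
         n_constant = attr(x, "n_constant"),
         threshold = attr(x, "threshold"),
         n_normal = attr(x, "n_normal"),
         n_tumor = attr(x, "n_tumor"),
         var_equal = attr(x, "var_equal"))
}
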