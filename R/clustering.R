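#' Pearson correlation distance between samples
#'
#' `d(a, b) = 1 - r(a, b)` over a gene panel, where `r` is the Pearson
#' correlation of the two sample columns restricted to the panel. Distances
#' lie in \[0, 2\] with a zero diagonal.
#'
#' @param x Expression matrix.
#' @param gene_subset Optional panel of gene ids (default: all genes); at
#'   least 2 must be present.
#' @return A symmetric samples-by-samples dissimilarity matrix.
#' @export
pearson_distance <- function(x, gene_subset = NULL) {
  validate_expression_matrix(x)
  if (is.null(gene_subset)) gene_subset <- rownames(x)
  present <- intersect(unique(as.character(gene_subset)), rownames(x))
  if (length(present) < 2L) abort("need >= 2 panel genes present for correlation")
  sub <- x[present, , drop = FALSE]
  v <- apply(sub, 2L, stats::var)
  if (any(v == 0)) {
    abort(sprintf("zero variance over the panel for sample(s): %s",
                  paste(colnames(sub)[v == 0], collapse = ", ")))
  }
  d <- 1 - cor(sub)
  diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerates the pair of clusters with minimal dissimilarity; the
#' distance from a merged cluster to any other is the size-weighted mean of
#' its members' distances. Items are pre-sorted lexicographically by label
#' so that tied merges resolve deterministically. Merge heights are checked
#' to be non-decreasing (average linkage admits no inversions).
#'
#' @param d A symmetric dissimilarity matrix with zero diagonal and >= 2
#'   labeled items.
#' @return An object of class `hclust`.
#' @export
average_linkage <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) abort("d must be a square matrix")
  if (nrow(d) < 2L) abort("need >= 2 items to cluster")
  labs <- rownames(d)
  if (is.null(labs) || anyDuplicated(labs)) {
    abort("d must have unique row/column labels")
  }
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12, check.attributes = FALSE))) {
    abort("d must be symmetric")
  }
  if (any(abs(diag(d)) > 1e-12)) abort("d must have a zero diagonal")
  o <- order(labs)
  d <- d[o, o, drop = FALSE]
  h <- hclust(as.dist(d), method = "average")
  if (is.unsorted(h$height)) {
    abort("average linkage produced decreasing merge heights; input is not a dissimilarity")
  }
  h
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths are derived from merge heights: each leaf branch spans
#' its parent's merge height, each internal branch the difference between
#' its parent's and its own height (the root carries the top height, so
#' leaf-to-root path lengths equal the root merge height). Sibling order
#' follows the `hclust` merge table.
#'
#' @param tree An `hclust` object (e.g. from [average_linkage()]).
#' @param digits Significant digits for branch lengths.
#' @return A single Newick string, terminated with `;`.
#' @export
export_newick <- function(tree, digits = 10L) {
  stopifnot(inherits(tree, "hclust"))
  fmt <- function(x) format(x, digits = digits, trim = TRUE, scientific = FALSE)
  node_str <- function(i, parent_height) {
    # i < 0: leaf -i; i > 0: internal node i of the merge table
    if (i < 0L) {
      sprintf("%s:%s", tree$labels[-i], fmt(parent_height))
    } else {
      h <- tree$height[i]
      sprintf("(%s,%s):%s",
              node_str(tree$merge[i, 1L], h),
              node_str(tree$merge[i, 2L], h),
              fmt(parent_height - h))
    }
  }
  n <- nrow(tree$merge)
  top <- tree$height[n]
  inner <- sprintf("(%s,%s)",
                   node_str(tree$merge[n, 1L], top),
                   node_str(tree$merge[n, 2L], top))
  paste0(inner, ";")
}

#' Per-patient sample clustering over a gene panel
#'
#' Mirrors the study's per-patient dendrograms: for each patient, that
#' patient's tissue + platform samples are clustered with
#' [pearson_distance()] + [average_linkage()] restricted to the panel
#' genes. A pooled mode clusters all samples together.
#'
#' @param x Expression matrix covering the paired samples.
#' @param samples Sample table.
#' @param panel Gene panel (ids) used for the correlation.
#' @param per_patient If `FALSE`, one pooled tree over all samples.
#' @return A named list of `hclust` objects (one per patient, or
#'   `"pooled"`).
#' @export
cluster_samples <- function(x, samples, panel, per_patient = TRUE) {
  validate_expression_matrix(x)
  samples <- validate_sample_table(samples)
  samples <- samples[samples$sample_id %in% colnames(x), , drop = FALSE]
  paired <- samples[samples$condition %in% c("tissue", platform_conditions()), ,
                    drop = FALSE]
  if (nrow(paired) < 2L) abort("need >= 2 paired samples to cluster")
  if (!per_patient) {
    d <- pearson_distance(x[, paired$sample_id, drop = FALSE], panel)
    return(list(pooled = average_linkage(d)))
  }
  patients <- unique(paired$patient_id)
  out <- lapply(patients, function(pid) {
    ids <- paired$sample_id[paired$patient_id == pid]
    if (length(ids) < 2L) {
      abort(sprintf("patient '%s' has fewer than 2 samples to cluster", pid))
    }
    average_linkage(pearson_distance(x[, ids, drop = FALSE], panel))
  })
  setNames(out, patients)
}
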