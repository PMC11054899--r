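#' Parameters for sample-wise enrichment scoring
#'
#' Defaults follow the published description of sample-wise gene-set
#' variation analysis for continuous (microarray-scale) data: Gaussian
#' kernel CDF with per-gene bandwidth `sd / 4`, rank-weight exponent
#' `tau = 1`, and the two-sided `max_diff` enrichment statistic.
#'
#' @param tau Non-negative weight exponent applied to the rank statistic in
#'   the random walk (0 gives the unweighted Kolmogorov-Smirnov statistic).
#' @param kernel_bandwidth_factor Per-gene kernel bandwidth as a multiple
#'   of the gene's expression standard deviation.
#' @param es_mode `"max_diff"` (sum of the walk's positive maximum and
#'   negative minimum) or `"max_dev"` (the signed walk value of largest
#'   magnitude).
#' @param min_set_size,max_set_size Size filters applied after intersecting
#'   each set with the matrix genes.
#' @return A list of class `gsva_params`.
#' @export
gsva_params <- function(tau = 1,
                        kernel_bandwidth_factor = 1 / 4,
                        es_mode = c("max_diff", "max_dev"),
                        min_set_size = 2L,
                        max_set_size = Inf) {
  es_mode <- match.arg(es_mode)
  if (!is.finite(tau) || tau < 0) abort("tau must be finite and >= 0")
  if (!is.finite(kernel_bandwidth_factor) || kernel_bandwidth_factor <= 0) {
    abort("kernel_bandwidth_factor must be > 0")
  }
  min_set_size <- as.integer(min_set_size)
  if (min_set_size < 1L) abort("min_set_size must be >= 1")
  if (max_set_size < min_set_size) abort("max_set_size must be >= min_set_size")
  structure(list(tau = tau, kernel_bandwidth_factor = kernel_bandwidth_factor,
                 es_mode = es_mode, min_set_size = min_set_size,
                 max_set_size = max_set_size),
            class = "gsva_params")
}

#' Kernel-CDF expression statistic
#'
#' For gene `i` in sample `j`, estimates the within-gene cumulative
#' position of `x_ij` against the gene's empirical distribution across
#' samples with a Gaussian kernel:
#' `z_ij = (1/n) * sum_k Phi((x_ij - x_ik) / h_i)`, `h_i = sd_i * factor`.
#' Genes with zero variance get the uninformative middle value 0.5 in
#' every sample.
#'
#' @param x Expression matrix with >= 2 samples.
#' @param bandwidth_factor Bandwidth multiple of the per-gene sd.
#' @return A genes-by-samples matrix of values in (0, 1).
#' @export
kernel_cdf_statistic <- function(x, bandwidth_factor = 1 / 4) {
  validate_expression_matrix(x, what = "feature matrix")
  n <- ncol(x)
  if (n < 2L) abort("kernel CDF statistic needs >= 2 samples")
  if (!is.finite(bandwidth_factor) || bandwidth_factor <= 0) {
    abort("bandwidth_factor must be > 0")
  }
  sds <- sqrt(rowSums((x - rowMeans(x))^2) / (n - 1))
  const <- sds == 0
  h <- sds * bandwidth_factor
  h[const] <- 1 # placeholder; constant rows are overwritten below
  z <- matrix(0, nrow(x), n, dimnames = dimnames(x))
  for (j in seq_len(n)) {
    z[, j] <- rowMeans(pnorm((x[, j] - x) / h))
  }
  z[const, ] <- 0.5
  z
}

#' Symmetric rank statistic
#'
#' Per sample, genes are ranked by the kernel-CDF statistic in decreasing
#' order (ties broken by gene id, lexicographically, for determinism) and
#' each gene receives `r_ij = |p/2 - rank_ij|`, so extreme ranks in either
#' direction weigh most.
#'
#' @param z A genes-by-samples statistic matrix (from
#'   [kernel_cdf_statistic()]).
#' @return A matrix of the same shape; attribute `rank_order` holds, per
#'   sample, the gene indices in walk (rank) order.
#' @export
rank_statistic <- function(z) {
  p <- nrow(z)
  if (p < 2L) abort("rank statistic needs >= 2 genes")
  ids <- rownames(z)
  r <- z
  ord <- matrix(0L, p, ncol(z), dimnames = list(NULL, colnames(z)))
  for (j in seq_len(ncol(z))) {
    o <- order(-z[, j], ids)
    rk <- integer(p)
    rk[o] <- seq_len(p)
    r[, j] <- abs(p / 2 - rk)
    ord[, j] <- o
  }
  attr(r, "rank_order") <- ord
  r
}

#' Enrichment-score random walk for one sample
#'
#' Walks down the rank-ordered gene list accumulating the weighted in-set
#' fraction minus the uniform out-of-set fraction:
#' `nu(l) = sum_{i<=l, in} r_i^tau / sum_{in} r_i^tau -
#'  #\{i<=l, out\} / (p - k)`.
#' `max_diff` returns `max(0, max nu) + min(0, min nu)`; `max_dev` returns
#' the signed `nu` at the (first) position of maximum `|nu|`. If every
#' in-set weight is zero (possible when `tau > 0` and all members sit at
#' the exact middle rank), the in-set term falls back to the unweighted
#' indicator CDF so the walk stays defined.
#'
#' @param r Rank statistic values in walk (rank) order.
#' @param in_set Logical vector, same order: membership of the set.
#' @param tau Weight exponent.
#' @param es_mode `"max_diff"` or `"max_dev"`.
#' @return A single enrichment score in \[-1, 1\].
#' @export
random_walk_es <- function(r, in_set, tau = 1, es_mode = c("max_diff", "max_dev")) {
  es_mode <- match.arg(es_mode)
  p <- length(r)
  in_set <- as.logical(in_set)
  if (length(in_set) != p) abort("r and in_set must have equal length")
  k <- sum(in_set)
  if (k == 0L || k == p) abort("the set must be non-empty and a proper subset of the genes")
  w <- (r^tau) * in_set
  tot <- sum(w)
  if (tot == 0) {
    w <- as.numeric(in_set)
    tot <- k
  }
  nu <- cumsum(w) / tot - cumsum(!in_set) / (p - k)
  switch(es_mode,
         max_diff = max(0, max(nu)) + min(0, min(nu)),
         max_dev = nu[which.max(abs(nu))])
}

# Enrichment score from the member rank positions alone. Between member
# hits the walk drifts down linearly, so its extrema (and the positions of
# maximal |nu|) occur only immediately before or after a member; this
# evaluates the same statistic as the full walk in O(k) per set.
walk_es_members <- function(pos, w, p, mode) {
  k <- length(pos)
  tot <- sum(w)
  if (tot == 0) {
    w <- rep(1, k)
    tot <- k
  }
  cw <- cumsum(w)
  out_frac <- (pos - seq_len(k)) / (p - k)
  nu_after <- cw / tot - out_frac
  nu_before <- c(0, cw[-k]) / tot - out_frac
  if (mode == "max_diff") {
    max(0, max(nu_after)) + min(0, min(nu_before))
  } else {
    cand <- as.numeric(rbind(nu_before, nu_after)) # walk order
    cand[which.max(abs(cand))]
  }
}

# Shared core: score several collections against one matrix, computing the
# kernel-CDF / rank statistics once.
gsva_scores_multi <- function(x, collections, params = gsva_params()) {
  validate_expression_matrix(x)
  stopifnot(inherits(params, "gsva_params"))
  ids <- rownames(x)
  p <- nrow(x)
  prepared <- lapply(collections, function(sets) {
    if (!inherits(sets, "gene_set_collection")) sets <- gene_set_collection(sets)
    members <- lapply(unclass(sets), intersect, y = ids)
    sizes <- lengths(members)
    keep <- sizes >= params$min_set_size & sizes <= params$max_set_size
    if (!all(keep)) {
      inform(sprintf("gsva_scores: %d set(s) dropped by size filters: %s",
                     sum(!keep), paste(names(members)[!keep], collapse = ", ")))
    }
    members <- members[keep]
    if (length(members) == 0L) abort("no gene set survives the size filters")
    if (any(lengths(members) >= p)) {
      abort("a gene set covering every matrix gene has no complement; enrichment undefined")
    }
    lapply(members, match, table = ids)
  })
  z <- kernel_cdf_statistic(x, params$kernel_bandwidth_factor)
  r <- rank_statistic(z)
  ord <- attr(r, "rank_order")
  lapply(prepared, function(members) {
    es <- matrix(NA_real_, length(members), ncol(x),
                 dimnames = list(names(members), colnames(x)))
    for (j in seq_len(ncol(x))) {
      rk <- integer(p)
      rk[ord[, j]] <- seq_len(p)
      rj <- r[, j]
      for (s in seq_along(members)) {
        idx <- members[[s]]
        o <- order(rk[idx])
        pos <- rk[idx][o]
        w <- rj[idx][o]^params$tau
        es[s, j] <- walk_es_members(pos, w, p, params$es_mode)
      }
    }
    es
  })
}

#' Sample-wise gene-set enrichment scores
#'
#' Composes [kernel_cdf_statistic()], [rank_statistic()] and the
#' enrichment random walk (see [random_walk_es()]) for every set and
#' sample, converting a gene-by-sample expression matrix into a
#' set-by-sample matrix of enrichment scores in \[-1, 1\]. Set members
#' absent from the matrix are intersected out; sets falling outside the
#' size filters are dropped with a message.
#'
#' @param x Expression matrix (>= 2 samples).
#' @param sets A [gene_set_collection()] (or named list of id vectors).
#' @param params A [gsva_params()].
#' @return A sets-by-samples numeric matrix of enrichment scores.
#' @export
gsva_scores <- function(x, sets, params = gsva_params()) {
  gsva_scores_multi(x, list(sets), params)[[1L]]
}
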