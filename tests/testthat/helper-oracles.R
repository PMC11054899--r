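# Independent brute-force oracles. These re-derive each statistic directly
# from its definition with plain loops, sharing no code with the package.

# Benjamini-Hochberg step-up from the definition:
# q_(i) = min over j >= i of m * p_(j) / j, capped at 1, in input order.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) m * p[o[j]] / j, numeric(1))
    q_sorted[i] <- min(1, min(cand))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Quantile normalization straight from the stated rule.
quantile_brute <- function(x) {
  n <- nrow(x)
  ref <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    for (i in seq_len(n)) {
      lo <- sum(col < col[i]) + 1
      hi <- sum(col <= col[i])
      out[i, j] <- mean(ref[lo:hi])
    }
  }
  out
}

# Naive UPGMA returning the cophenetic matrix (merge height of the first
# cluster joining each leaf pair); equal trees <=> equal cophenetics.
upgma_brute_cophenetic <- function(d) {
  n <- nrow(d)
  labs <- rownames(d)
  members <- as.list(seq_len(n))
  sizes <- rep(1, n)
  D <- d
  alive <- rep(TRUE, n)
  coph <- matrix(0, n, n, dimnames = list(labs, labs))
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA)
    bestd <- Inf
    idx <- which(alive)
    for (a in idx) for (b in idx) {
      if (a < b && D[a, b] < bestd) {
        bestd <- D[a, b]
        best <- c(a, b)
      }
    }
    a <- best[1]; b <- best[2]
    for (la in members[[a]]) for (lb in members[[b]]) {
      coph[la, lb] <- coph[lb, la] <- bestd
    }
    for (k in idx) {
      if (k != a && k != b) {
        D[a, k] <- D[k, a] <-
          (sizes[a] * D[a, k] + sizes[b] * D[b, k]) / (sizes[a] + sizes[b])
      }
    }
    members[[a]] <- c(members[[a]], members[[b]])
    sizes[a] <- sizes[a] + sizes[b]
    alive[b] <- FALSE
  }
  coph
}

# Direct-formula evaluation of the whole enrichment pipeline for one
# matrix and one gene set: kernel CDF, descending rank (ties by gene id),
# symmetric rank statistic, full cumulative walk.
gsva_brute <- function(x, set_members, tau = 1, bw_factor = 1 / 4,
                       mode = "max_diff") {
  p <- nrow(x); n <- ncol(x)
  ids <- rownames(x)
  z <- matrix(0, p, n)
  for (i in seq_len(p)) {
    s <- sqrt(sum((x[i, ] - mean(x[i, ]))^2) / (n - 1))
    if (s == 0) {
      z[i, ] <- 0.5
    } else {
      h <- s * bw_factor
      for (j in seq_len(n)) {
        z[i, j] <- mean(pnorm((x[i, j] - x[i, ]) / h))
      }
    }
  }
  es <- numeric(n)
  for (j in seq_len(n)) {
    o <- order(-z[, j], ids)
    rk <- integer(p); rk[o] <- seq_len(p)
    r <- abs(p / 2 - rk)
    in_set <- ids %in% set_members
    k <- sum(in_set)
    w <- (r^tau) * in_set
    if (sum(w) == 0) w <- as.numeric(in_set)
    nu <- numeric(p)
    cin <- 0; cout <- 0
    for (l in seq_len(p)) {
      g <- o[l]
      if (in_set[g]) cin <- cin + w[g] else cout <- cout + 1
      nu[l] <- cin / sum(w) - cout / (p - k)
    }
    es[j] <- if (mode == "max_diff") {
      max(0, max(nu)) + min(0, min(nu))
    } else {
      nu[which.max(abs(nu))]
    }
  }
  es
}

# Unweighted two-sample KS statistic (signed, two-sided sup) over a ranked
# list split into set / complement -- the tau = 0 limit of the walk.
ks_brute <- function(in_set_in_rank_order) {
  k <- sum(in_set_in_rank_order)
  p <- length(in_set_in_rank_order)
  f_in <- cumsum(in_set_in_rank_order) / k
  f_out <- cumsum(!in_set_in_rank_order) / (p - k)
  nu <- f_in - f_out
  max(0, max(nu)) + min(0, min(nu))
}

# Naive double-loop platform deviation (per-gene pair SD, averaged).
deviation_brute <- function(x, samples, panel) {
  plat <- samples[samples$condition %in% platform_conditions(), ]
  res <- NULL
  for (i in seq_len(nrow(plat))) {
    pid <- plat$patient_id[i]
    tissue_id <- samples$sample_id[samples$patient_id == pid &
                                     samples$condition == "tissue"]
    acc <- 0
    for (g in panel) {
      acc <- acc + sd(c(x[g, plat$sample_id[i]], x[g, tissue_id]))
    }
    res <- rbind(res, data.frame(patient_id = pid, platform = plat$condition[i],
                                 raw = acc / length(panel)))
  }
  res
}
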