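test_that("paired_sd is the two-value sample standard deviation", {
  expect_equal(paired_sd(2, 2), 0)
  expect_equal(paired_sd(1, 2), 0.70711, tolerance = 1e-5)
  expect_equal(paired_sd(0, 4), 2.82843, tolerance = 1e-5)
  # vectorized, and identical to sd() on each pair
  set.seed(2)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(paired_sd(x, y),
               vapply(1:20, function(i) sd(c(x[i], y[i])), numeric(1)))
})

make_paired_fixture <- function(n_genes = 6, seed = 1) {
  set.seed(seed)
  samples <- paired_samples(2)
  x <- matrix(rnorm(n_genes * nrow(samples), 8, 2), n_genes, nrow(samples),
              dimnames = list(sprintf("g%d", seq_len(n_genes)),
                              samples$sample_id))
  list(x = x, samples = samples)
}

test_that("platform deviation matches the hand computation and zero identity", {
  fx <- make_paired_fixture()
  x <- fx$x
  # force the hand-computable configuration for patient P1, platform LM
  x["g1", "P1_LM"] <- x["g1", "P1_tissue"] - 1
  x["g2", "P1_LM"] <- x["g2", "P1_tissue"] + 2
  dev <- platform_deviation(x, fx$samples, c("g1", "g2"))
  got <- dev$raw_deviation[dev$patient_id == "P1" & dev$platform == "LM"]
  expect_equal(got, (0.70711 + 1.41421) / 2, tolerance = 1e-5)

  # platform column identical to tissue -> deviation 0
  x[, "P2_mouse"] <- x[, "P2_tissue"]
  dev <- platform_deviation(x, fx$samples, rownames(x))
  expect_equal(dev$raw_deviation[dev$patient_id == "P2" & dev$platform == "mouse"], 0)
})

test_that("alternative deviation readings are available and correct", {
  fx <- make_paired_fixture()
  x <- fx$x
  x["g1", "P1_LM"] <- x["g1", "P1_tissue"] - 1
  x["g2", "P1_LM"] <- x["g2", "P1_tissue"] + 2
  pick <- function(dev) dev$raw_deviation[dev$patient_id == "P1" & dev$platform == "LM"]
  expect_equal(pick(platform_deviation(x, fx$samples, c("g1", "g2"), mode = "diff-sd")),
               sd(c(-1, 2)))
  expect_equal(pick(platform_deviation(x, fx$samples, c("g1", "g2"), mode = "rms")),
               sqrt(mean(c(1, 4))))
})

test_that("panel genes are intersected, small panels refused, pairing enforced", {
  fx <- make_paired_fixture()
  expect_message(platform_deviation(fx$x, fx$samples, c("g1", "g2", "NOPE")),
                 "absent")
  expect_error(suppressMessages(
    platform_deviation(fx$x, fx$samples, c("g1", "NOPE"))), ">= 2")
  # P1's tissue column missing from the matrix -> pairing error names P1
  err <- expect_error(platform_deviation(fx$x[, -1], fx$samples, c("g1", "g2")))
  expect_match(conditionMessage(err), "P1")
})

test_that("platform deviation equals a naive double-loop recomputation", {
  for (seed in 1:10) {
    set.seed(seed)
    samples <- paired_samples(3)
    x <- matrix(rnorm(20 * nrow(samples), 8, 2), 20, nrow(samples),
                dimnames = list(sprintf("g%d", 1:20), samples$sample_id))
    panel <- sample(rownames(x), 12)
    mine <- platform_deviation(x, samples, panel)
    ref <- deviation_brute(x, samples, panel)
    merged <- merge(as.data.frame(mine), ref, by = c("patient_id", "platform"))
    expect_equal(nrow(merged), nrow(mine))
    expect_lt(max(abs(merged$raw_deviation - merged$raw)), 1e-12)
  }
})

test_that("per-sample normalization matches the worked example and conserves the mean", {
  raw <- tibble::tibble(patient_id = "P1",
                        platform = platform_conditions(),
                        level = "gbm_genes",
                        raw_deviation = c(2, 4, 6, 8, 10))
  norm <- normalize_per_sample(raw)
  expect_equal(norm$normalized_deviation, c(1/3, 2/3, 1, 4/3, 5/3))
  expect_equal(mean(norm$normalized_deviation), 1)

  single <- tibble::tibble(patient_id = "P1", platform = "LM",
                           level = "gbm_genes", raw_deviation = 7)
  expect_equal(normalize_per_sample(single)$normalized_deviation, 1)

  zero <- tibble::tibble(patient_id = "P1", platform = platform_conditions(),
                         level = "gbm_genes", raw_deviation = 0)
  expect_error(normalize_per_sample(zero), "undefined")
})

test_that("normalization conservation holds on random deviation tables", {
  set.seed(41)
  for (i in 1:20) {
    raw <- tidyr::expand_grid(patient_id = sprintf("P%d", 1:4),
                              platform = platform_conditions(),
                              level = c("gbm_genes", "tf_activity"))
    raw$raw_deviation <- rexp(nrow(raw))
    norm <- normalize_per_sample(raw)
    means <- dplyr::summarise(
      dplyr::group_by(norm, patient_id, level),
      m = mean(normalized_deviation), .groups = "drop")
    expect_lt(max(abs(means$m - 1)), 1e-12)
  }
})

test_that("normalized deviations are invariant to a global expression scale factor", {
  fx <- make_paired_fixture(n_genes = 30, seed = 5)
  base <- normalize_per_sample(platform_deviation(fx$x, fx$samples, rownames(fx$x)))
  scaled <- normalize_per_sample(platform_deviation(fx$x * 7.3, fx$samples,
                                                    rownames(fx$x)))
  expect_equal(base$normalized_deviation, scaled$normalized_deviation,
               tolerance = 1e-12)
})

test_that("summaries report mean, SEM and deterministic ranks", {
  tbl <- tibble::tibble(patient_id = rep(sprintf("P%d", 1:3), 2),
                        platform = rep(c("LM", "mouse"), each = 3),
                        level = "gbm_genes",
                        normalized_deviation = c(1, 1, 1, 0.8, 1.2, 1.0))
  s <- summarize_deviation(tbl)
  lm_row <- s[s$platform == "LM", ]
  expect_equal(lm_row$mean_deviation, 1)
  expect_equal(lm_row$sem, 0)
  expect_equal(lm_row$rank, 1L)

  two <- tibble::tibble(patient_id = c("P1", "P2"), platform = "LM",
                        level = "gbm_genes", normalized_deviation = c(0.8, 1.2))
  s2 <- summarize_deviation(two)
  expect_equal(s2$mean_deviation, 1)
  expect_equal(s2$sem, 0.2)

  # exact ties rank alphabetically
  tied <- tibble::tibble(patient_id = rep(c("P1", "P2"), 2),
                         platform = rep(c("nECM", "collagen"), each = 2),
                         level = "gbm_genes",
                         normalized_deviation = c(1, 1, 1, 1))
  st <- summarize_deviation(tied)
  expect_identical(platform_ranking(st), c("collagen", "nECM"))

  one_patient <- tibble::tibble(patient_id = "P1", platform = "LM",
                                level = "gbm_genes", normalized_deviation = 1)
  expect_error(summarize_deviation(one_patient), ">= 2 patients")
})

test_that("enrichment-level deviation mirrors the gene-level computation", {
  samples <- paired_samples(1)
  es <- matrix(0.1, nrow = 1, ncol = nrow(samples),
               dimnames = list("SET1", samples$sample_id))
  # identical scores everywhere -> all deviations 0 (single-set matrices allowed)
  dev0 <- deviation_on_enrichment(es, samples, level = "tf_activity")
  expect_equal(dev0$raw_deviation, rep(0, 5))
  expect_identical(unique(dev0$level), "tf_activity")

  es["SET1", "P1_LM"] <- es["SET1", "P1_tissue"] + 0.2
  dev <- deviation_on_enrichment(es, samples, level = "pathways")
  expect_equal(dev$raw_deviation[dev$platform == "LM"], 0.14142, tolerance = 1e-5)
})
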