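test_that("identical config and seed give bit-identical output", {
  a <- simulate_study(small_sim(seed = 11))
  b <- simulate_study(small_sim(seed = 11))
  expect_identical(a$reference$expression, b$reference$expression)
  expect_identical(a$panel$expression, b$panel$expression)
  expect_identical(a$truth, b$truth)
  c <- simulate_study(small_sim(seed = 12))
  expect_false(identical(a$panel$expression, c$panel$expression))
})

test_that("reference cohorts have the configured shape and planted truth", {
  cfg <- sim_config(seed = 1)
  ref <- simulate_reference_cohorts(cfg)
  expect_equal(ncol(ref$expression), 60L)
  expect_equal(nrow(ref$expression), 10000L)
  expect_length(ref$truth$de_gene_ids, 1000L)
  expect_true(all(ref$truth$de_gene_ids %in% rownames(ref$expression)))
  expect_equal(sum(ref$samples$condition == "normal_ref"), 8L)
  expect_equal(sum(ref$samples$condition == "tumor_ref"), 52L)
  # marker symbols are planted differential genes
  expect_true(all(c(stemness_genes(), invasiveness_genes()) %in%
                    ref$truth$de_gene_ids))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(de_fraction = 0), "open interval")
  expect_error(sim_config(de_fraction = 1), "open interval")
  expect_error(sim_config(n_normal_ref = 1), "n >= 2")
  expect_error(sim_config(patient_ids = character(0)), "non-empty")
  expect_error(sim_config(n_genes = 20, tf_set_size = 30), "exceed n_genes")
  expect_error(sim_config(platform_drift_sd = c(LM = 0.3)), "exactly the platforms")
  expect_error(sim_config(active_conditions = "dish"), "outside the platform set")
})

test_that("noise-free planted genes separate the cohorts with zero overlap", {
  cfg <- small_sim(seed = 3, residual_sd = 0, de_effect = 5)
  ref <- simulate_reference_cohorts(cfg)
  normal <- ref$samples$sample_id[ref$samples$condition == "normal_ref"]
  tumor <- ref$samples$sample_id[ref$samples$condition == "tumor_ref"]
  for (g in ref$truth$de_gene_ids) {
    rng_n <- range(ref$expression[g, normal])
    rng_t <- range(ref$expression[g, tumor])
    expect_true(rng_n[2] < rng_t[1] || rng_t[2] < rng_n[1])
  }
})

test_that("platform panel pairs every patient with tissue and all platforms", {
  cfg <- sim_config(seed = 7)
  panel <- simulate_platform_panel(cfg)
  expect_equal(ncol(panel$expression), 30L)
  tab <- table(panel$samples$patient_id, panel$samples$condition)
  expect_true(all(tab[, c("tissue", platform_conditions())] == 1L))
  expect_identical(panel$truth$drift_rank,
                   c("LM", "collagen", "nECM", "tECM", "mouse"))
})

test_that("zero drift makes every platform column equal its tissue column", {
  cfg <- small_sim(seed = 5,
                   platform_drift_sd = c(LM = 0, collagen = 0, nECM = 0,
                                         tECM = 0, mouse = 0),
                   n_active_sets = 0)
  panel <- simulate_platform_panel(cfg)
  x <- panel$expression
  s <- panel$samples
  for (pid in cfg$patient_ids) {
    tissue <- x[, s$sample_id[s$patient_id == pid & s$condition == "tissue"]]
    for (p in platform_conditions()) {
      col <- x[, s$sample_id[s$patient_id == pid & s$condition == p]]
      expect_identical(unname(col), unname(tissue))
    }
  }
})

test_that("empirical drift is ordered by the generating sds (law of large numbers)", {
  cfg <- sim_config(seed = 9, n_active_sets = 0)
  panel <- simulate_platform_panel(cfg)
  x <- panel$expression
  s <- panel$samples
  for (pid in cfg$patient_ids) {
    tissue <- x[, s$sample_id[s$patient_id == pid & s$condition == "tissue"]]
    sds <- vapply(platform_conditions(), function(p) {
      sd(x[, s$sample_id[s$patient_id == pid & s$condition == p]] - tissue)
    }, numeric(1))
    expect_lt(sds[["LM"]], sds[["mouse"]])
    # full ordering matches the generating sds at n_genes = 10000
    expect_identical(names(sort(sds)), panel$truth$drift_rank)
  }
})

test_that("gene-set collections have the configured shape and active truth", {
  cfg <- sim_config(seed = 3, n_tf_sets = 50, tf_set_size = 30)
  coll <- simulate_geneset_collections(cfg)
  expect_length(coll$tf, 50L)
  expect_true(all(lengths(coll$tf) == 30L))
  expect_length(unique(names(coll$tf)), 50L)

  # zero planted shift -> nothing recorded active
  coll0 <- simulate_geneset_collections(small_sim(seed = 3, active_shift = 0))
  expect_length(coll0$truth$planted_active_sets, 0L)

  # planting restricted to mouse -> truth lists only mouse
  collm <- simulate_geneset_collections(small_sim(seed = 3,
                                                  active_conditions = "mouse"))
  conds <- unique(unlist(lapply(collm$truth$planted_active_sets, `[[`, "conditions")))
  expect_identical(conds, "mouse")
})

test_that("panel applies exactly the planted condition shifts the truth records", {
  cfg <- small_sim(seed = 21, active_shift = 2, active_conditions = "collagen",
                   platform_drift_sd = c(LM = 0, collagen = 0, nECM = 0,
                                         tECM = 0, mouse = 0))
  panel <- simulate_platform_panel(cfg)
  coll <- simulate_geneset_collections(cfg)
  x <- panel$expression
  s <- panel$samples
  all_sets <- c(as.list(unclass(coll$tf)), as.list(unclass(coll$pathways)))
  shift <- setNames(numeric(nrow(x)), rownames(x))
  for (nm in names(coll$truth$planted_active_sets)) {
    info <- coll$truth$planted_active_sets[[nm]]
    shift[all_sets[[nm]]] <- shift[all_sets[[nm]]] + info$direction * 2
  }
  pid <- cfg$patient_ids[1]
  tissue <- x[, s$sample_id[s$patient_id == pid & s$condition == "tissue"]]
  collagen <- x[, s$sample_id[s$patient_id == pid & s$condition == "collagen"]]
  lm <- x[, s$sample_id[s$patient_id == pid & s$condition == "LM"]]
  expect_equal(unname(collagen - tissue), unname(shift))
  expect_identical(unname(lm), unname(tissue))
})
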