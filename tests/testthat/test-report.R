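# A reduced-size but complete study configuration used across these tests.
report_sim <- function(seed = 1) {
  sim_config(n_genes = 800, de_fraction = 0.1, de_effect = 5,
             n_tf_sets = 10, tf_set_size = 15,
             n_pathway_sets = 10, pathway_set_size = 15,
             n_active_sets = 2, seed = seed)
}

cached_report <- local({
  rep <- NULL
  function() {
    if (is.null(rep)) {
      rep <<- suppressMessages(
        run_pipeline(pipeline_config(sim = report_sim(seed = 1))))
    }
    rep
  }
})

test_that("the pipeline config demands exactly one input source", {
  expect_error(pipeline_config(), "exactly one")
  expect_error(pipeline_config(sim = report_sim(),
                               paths = list(expression = "x", samples = "y",
                                            tf_sets = "z", pathway_sets = "w")),
               "exactly one")
  expect_error(pipeline_config(paths = list(expression = "missing.tsv")),
               "paths must name")
})

test_that("a simulated run reports all five levels with unit per-patient means", {
  rep <- cached_report()
  expect_s3_class(rep, "fidelity_report")
  expect_setequal(unique(rep$summary$level),
                  c("gbm_genes", "stemness", "invasiveness",
                    "tf_activity", "pathways"))
  expect_equal(nrow(rep$summary), 25L) # 5 levels x 5 platforms
  means <- dplyr::summarise(
    dplyr::group_by(tidy(rep), patient_id, level),
    m = mean(normalized_deviation), .groups = "drop")
  expect_lt(max(abs(means$m - 1)), 1e-12)
  expect_length(rep$consensus, 5L)
  expect_setequal(rep$consensus, platform_conditions())
  expect_length(rep$newick, 5L)
})

test_that("rerunning the same configuration reproduces the report body exactly", {
  rep1 <- cached_report()
  rep2 <- suppressMessages(run_pipeline(pipeline_config(sim = report_sim(seed = 1))))
  json1 <- jsonlite::toJSON(platfid:::report_body(rep1), auto_unbox = TRUE, digits = NA)
  json2 <- jsonlite::toJSON(platfid:::report_body(rep2), auto_unbox = TRUE, digits = NA)
  expect_identical(json1, json2)
  rep3 <- suppressMessages(run_pipeline(pipeline_config(sim = report_sim(seed = 2))))
  expect_false(identical(
    jsonlite::toJSON(platfid:::report_body(rep3), auto_unbox = TRUE, digits = NA),
    json1))
})

test_that("report artifacts are written and validate against the schema structure", {
  dir <- withr::local_tempdir()
  rep <- cached_report()
  write_report(rep, dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  expect_true(file.exists(file.path(dir, "summary.tsv")))
  expect_true(file.exists(file.path(dir, "deviations.tsv")))
  expect_true(file.exists(file.path(dir, "markers.tsv")))
  expect_length(list.files(dir, pattern = "^dendrogram_.*\\.nwk$"), 5L)
  expect_true(validate_report(file.path(dir, "report.json")))
  expect_true(validate_report(rep))
  expect_true(file.exists(system.file("schema", "fidelity-report.schema.json",
                                      package = "platfid")))
  broken <- platfid:::report_body(rep)
  broken$consensus <- broken$consensus[-1]
  expect_error(validate_report(broken), "permutation")
})

test_that("stage failures propagate with the stage name", {
  cfg <- pipeline_config(sim = report_sim(seed = 1), q_threshold = 0)
  err <- expect_error(suppressMessages(run_pipeline(cfg)))
  expect_match(conditionMessage(err), "stage 'deviation'")
})

test_that("consensus ranking averages level ranks with name tie-breaks", {
  plats <- c("a", "b", "c")
  all_same <- list(x = plats, y = plats)
  expect_identical(consensus_rank(all_same), plats)
  # two levels swap positions 2/3 symmetrically -> tie broken by name
  swapped <- list(x = c("a", "b", "c"), y = c("a", "c", "b"))
  expect_identical(consensus_rank(swapped), c("a", "b", "c"))
  expect_error(consensus_rank(list(x = plats, y = NULL)), "missing ranking")
  expect_error(consensus_rank(list(x = plats, y = c("a", "b", "z"))),
               "same platform set")
})

test_that("tidy, glance and autoplot views are well-formed", {
  rep <- cached_report()
  td <- tidy(rep)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("patient_id", "platform", "level", "raw_deviation",
                    "normalized_deviation") %in% names(td)))
  gl <- glance(rep)
  expect_equal(gl$n_levels, 5L)
  expect_identical(gl$best_platform, rep$consensus[1])
  expect_s3_class(autoplot(rep), "ggplot")
  expect_s3_class(autoplot(rep$summary), "ggplot")
  expect_s3_class(autoplot(rep$markers), "ggplot")
  expect_s3_class(plot_enrichment_heatmap(rep$enrichment$tf_activity), "ggplot")
})

test_that("the pipeline accepts on-disk inputs and records digests", {
  dir <- withr::local_tempdir()
  study <- simulate_study(report_sim(seed = 5))
  expr <- cbind(study$reference$expression, study$panel$expression)
  write_expression_matrix(expr, file.path(dir, "expr.tsv"))
  write_sample_table(dplyr::bind_rows(study$reference$samples,
                                      study$panel$samples),
                     file.path(dir, "samples.tsv"))
  write_gmt(study$collections$tf, file.path(dir, "tf.gmt"))
  write_gmt(study$collections$pathways, file.path(dir, "pw.gmt"))
  cfg <- pipeline_config(paths = list(expression = file.path(dir, "expr.tsv"),
                                      samples = file.path(dir, "samples.tsv"),
                                      tf_sets = file.path(dir, "tf.gmt"),
                                      pathway_sets = file.path(dir, "pw.gmt")))
  rep <- suppressMessages(run_pipeline(cfg))
  expect_identical(rep$provenance$mode, "paths")
  expect_length(rep$provenance$input_digests, 4L)
  expect_setequal(unique(rep$summary$level), platfid:::deviation_levels())
  # same data through the simulation path gives the same deviations
  rep_sim <- suppressMessages(run_pipeline(pipeline_config(sim = report_sim(seed = 5))))
  expect_equal(rep$deviations$normalized_deviation,
               rep_sim$deviations$normalized_deviation, tolerance = 1e-10)
})
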