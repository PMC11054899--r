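#' Simulation configuration for a paired multi-platform study
#'
#' Builds and validates the configuration of the synthetic-data generator.
#' The generator emulates a paired design in which each patient contributes
#' one tumor-tissue sample plus one sample per culture platform, and two
#' independent reference cohorts (normal and tumor tissue) carry planted
#' differentially expressed genes for marker selection. All values are on
#' the log2-intensity scale.
#'
#' Platform infidelity is modeled as per-gene Gaussian drift around the
#' paired tissue profile, with a platform-specific standard deviation
#' (`platform_drift_sd`); a subset of simulated TF-target / pathway sets can
#' additionally carry a coordinated mean shift in selected conditions
#' (`active_shift`, `active_conditions`), giving enrichment-level deviations
#' a planted direction.
#'
#' @param n_genes Number of simulated genes.
#' @param patient_ids Patient labels for the paired panel.
#' @param platform_drift_sd Named numeric: per-platform drift standard
#'   deviation (log2 units). Must cover exactly the five platforms of
#'   [platform_conditions()].
#' @param n_normal_ref,n_tumor_ref Reference cohort sizes (each >= 2).
#' @param de_fraction Fraction of genes planted as tumor-vs-normal
#'   differential, in the open interval (0, 1).
#' @param residual_sd Per-sample residual noise standard deviation.
#' @param de_effect Absolute planted effect size (log2 units); sign is drawn
#'   per gene and recorded.
#' @param patient_effect_sd Standard deviation of the per-patient additive
#'   offset that makes samples cluster by patient.
#' @param n_replicates Platform samples per (patient, platform).
#' @param n_tf_sets,tf_set_size,n_pathway_sets,pathway_set_size Size of the
#'   simulated TF-target and pathway collections.
#' @param n_active_sets Number of sets per collection planted as "active"
#'   (condition-biased).
#' @param active_shift Mean shift (log2 units) added to active-set member
#'   genes in the affected conditions; 0 disables planting.
#' @param active_conditions Platform condition(s) receiving the shift.
#' @param include_marker_symbols If `TRUE`, the stemness / invasiveness
#'   gene symbols are assigned to planted differential genes so the fixed
#'   panels of [stemness_genes()] and [invasiveness_genes()] are present.
#' @param seed Master seed; per-component streams are derived from it (see
#'   Details).
#'
#' @details Each generator component (gene-level parameters, gene sets,
#' reference cohorts, paired panel) seeds its own RNG stream as
#' `(seed %% 1000003) * 2039 + offset (mod 2^31 - 1)` with a fixed
#' per-component offset, so adding a component never perturbs the draws of
#' another.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 10000L,
                       patient_ids = c("13-20", "13-64", "14-08", "14-15", "15-88"),
                       platform_drift_sd = c(LM = 0.3, collagen = 0.6,
                                             nECM = 0.7, tECM = 0.8, mouse = 1.0),
                       n_normal_ref = 8L,
                       n_tumor_ref = 52L,
                       de_fraction = 0.1,
                       residual_sd = 1.0,
                       de_effect = 5 * residual_sd,
                       patient_effect_sd = 0.5,
                       n_replicates = 1L,
                       n_tf_sets = 50L,
                       tf_set_size = 30L,
                       n_pathway_sets = 50L,
                       pathway_set_size = 30L,
                       n_active_sets = 5L,
                       active_shift = 1.0,
                       active_conditions = "mouse",
                       include_marker_symbols = TRUE,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), patient_ids = as.character(patient_ids),
              platform_drift_sd = platform_drift_sd,
              n_normal_ref = as.integer(n_normal_ref),
              n_tumor_ref = as.integer(n_tumor_ref),
              de_fraction = de_fraction, residual_sd = residual_sd,
              de_effect = de_effect, patient_effect_sd = patient_effect_sd,
              n_replicates = as.integer(n_replicates),
              n_tf_sets = as.integer(n_tf_sets), tf_set_size = as.integer(tf_set_size),
              n_pathway_sets = as.integer(n_pathway_sets),
              pathway_set_size = as.integer(pathway_set_size),
              n_active_sets = as.integer(n_active_sets),
              active_shift = active_shift,
              active_conditions = as.character(active_conditions),
              include_marker_symbols = isTRUE(include_marker_symbols),
              seed = as.integer(seed))
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param cfg A `sim_config` list.
#' @export
validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 2L) abort("n_genes must be >= 2")
  if (length(cfg$patient_ids) == 0L) abort("patient_ids must be non-empty")
  if (anyDuplicated(cfg$patient_ids)) abort("patient_ids must be unique")
  drift <- cfg$platform_drift_sd
  if (!setequal(names(drift), platform_conditions()) ||
      length(drift) != length(platform_conditions())) {
    abort(sprintf("platform_drift_sd must name exactly the platforms: %s",
                  paste(platform_conditions(), collapse = ", ")))
  }
  cfg$platform_drift_sd <- drift[platform_conditions()]
  if (any(!is.finite(drift)) || any(drift < 0)) abort("drift sds must be finite and >= 0")
  if (cfg$n_normal_ref < 2L || cfg$n_tumor_ref < 2L) {
    abort("reference cohorts need n >= 2 per group (two-sample t-test)")
  }
  if (!is.finite(cfg$de_fraction) || cfg$de_fraction <= 0 || cfg$de_fraction >= 1) {
    abort("de_fraction must lie in the open interval (0, 1)")
  }
  if (cfg$residual_sd < 0) abort("residual_sd must be >= 0")
  if (cfg$de_effect <= 0) abort("de_effect must be > 0")
  if (cfg$patient_effect_sd < 0) abort("patient_effect_sd must be >= 0")
  if (cfg$n_replicates < 1L) abort("n_replicates must be >= 1")
  if (cfg$tf_set_size > cfg$n_genes || cfg$pathway_set_size > cfg$n_genes) {
    abort("gene-set size cannot exceed n_genes")
  }
  if (cfg$n_tf_sets < 1L || cfg$n_pathway_sets < 1L) abort("need >= 1 set per collection")
  if (cfg$tf_set_size < 1L || cfg$pathway_set_size < 1L) abort("set sizes must be >= 1")
  if (cfg$n_active_sets < 0L ||
      cfg$n_active_sets > min(cfg$n_tf_sets, cfg$n_pathway_sets)) {
    abort("n_active_sets must be between 0 and the smallest collection size")
  }
  if (cfg$active_shift < 0) abort("active_shift must be >= 0")
  bad <- setdiff(cfg$active_conditions, platform_conditions())
  if (length(bad)) {
    abort(sprintf("active_conditions outside the platform set: %s",
                  paste(bad, collapse = ", ")))
  }
  structure(cfg, class = "sim_config")
}

# Deterministic per-component RNG stream (see ?sim_config Details).
component_seed <- function(seed, component) {
  offsets <- c(genes = 101L, sets = 211L, ref = 307L, panel = 401L)
  off <- offsets[[component]]
  as.integer(((as.numeric(seed) %% 1000003) * 2039 + off) %% 2147483647)
}

# Gene-level parameters shared by the reference cohorts and the paired
# panel: baseline means, planted differential genes and their signed
# effects, and the final gene ids (with marker symbols substituted in).
sim_gene_params <- function(cfg) {
  set.seed(component_seed(cfg$seed, "genes"))
  n <- cfg$n_genes
  mu <- rnorm(n, mean = 8, sd = 2)
  n_de <- max(1L, round(cfg$de_fraction * n))
  de_idx <- sort(sample.int(n, n_de))
  signs <- sample(c(-1, 1), n_de, replace = TRUE)
  delta <- numeric(n)
  delta[de_idx] <- signs * cfg$de_effect
  gene_ids <- sprintf("G%05d", seq_len(n))
  if (cfg$include_marker_symbols) {
    symbols <- c(stemness_genes(), invasiveness_genes())
    take <- head(de_idx, length(symbols))
    gene_ids[take] <- symbols[seq_along(take)]
  }
  list(gene_ids = gene_ids, mu = mu, delta = delta,
       de_gene_ids = gene_ids[de_idx], de_signs = setNames(signs, gene_ids[de_idx]))
}

# Gene-set memberships and planted activity, drawn on their own stream.
sim_gene_sets <- function(cfg) {
  params <- sim_gene_params(cfg)
  set.seed(component_seed(cfg$seed, "sets"))
  draw <- function(prefix, k, size) {
    sets <- lapply(seq_len(k), function(i) sample(params$gene_ids, size))
    setNames(sets, sprintf("%s%03d", prefix, seq_len(k)))
  }
  tf <- draw("TF", cfg$n_tf_sets, cfg$tf_set_size)
  pw <- draw("PATHWAY", cfg$n_pathway_sets, cfg$pathway_set_size)
  active <- list()
  if (cfg$n_active_sets > 0L && cfg$active_shift > 0 &&
      length(cfg$active_conditions) > 0L) {
    act_tf <- sample(names(tf), cfg$n_active_sets)
    act_pw <- sample(names(pw), cfg$n_active_sets)
    dir_tf <- sample(c(-1, 1), cfg$n_active_sets, replace = TRUE)
    dir_pw <- sample(c(-1, 1), cfg$n_active_sets, replace = TRUE)
    active <- c(
      setNames(lapply(seq_len(cfg$n_active_sets), function(i) {
        list(direction = dir_tf[i], conditions = cfg$active_conditions)
      }), act_tf),
      setNames(lapply(seq_len(cfg$n_active_sets), function(i) {
        list(direction = dir_pw[i], conditions = cfg$active_conditions)
      }), act_pw))
  }
  list(tf = gene_set_collection(tf, rep("simulated TF target set", length(tf))),
       pathways = gene_set_collection(pw, rep("simulated pathway", length(pw))),
       active = active, gene_ids = params$gene_ids)
}

# Per-condition mean-shift matrix (genes x platforms) implied by the
# planted active sets.
sim_shift_matrix <- function(cfg, sets) {
  shift <- matrix(0, nrow = cfg$n_genes, ncol = length(platform_conditions()),
                  dimnames = list(sets$gene_ids, platform_conditions()))
  all_sets <- c(unclass(sets$tf), unclass(sets$pathways))
  for (nm in names(sets$active)) {
    info <- sets$active[[nm]]
    members <- all_sets[[nm]]
    shift[members, info$conditions] <-
      shift[members, info$conditions] + info$direction * cfg$active_shift
  }
  shift
}

#' Simulate the normal / tumor reference cohorts
#'
#' Generates the two reference cohorts used for marker selection. Gene `g`
#' in sample `s` is `mu_g + delta_g * 1[tumor] + eps`, with `mu_g ~ N(8, 2)`
#' (log2 scale), `delta_g = +/- de_effect` for the planted fraction of genes
#' (sign random, recorded in the truth) and 0 otherwise, and
#' `eps ~ N(0, residual_sd)` i.i.d.
#'
#' @param cfg A [sim_config()].
#' @return A list with `expression` (matrix), `samples` (tibble) and
#'   `truth` (list with `de_gene_ids`, `de_signs`).
#' @export
simulate_reference_cohorts <- function(cfg) {
  cfg <- validate_sim_config(unclass(cfg))
  params <- sim_gene_params(cfg)
  set.seed(component_seed(cfg$seed, "ref"))
  n_n <- cfg$n_normal_ref
  n_t <- cfg$n_tumor_ref
  n <- cfg$n_genes
  eps <- matrix(rnorm(n * (n_n + n_t), sd = cfg$residual_sd), nrow = n)
  values <- params$mu + eps
  tumor_cols <- seq.int(n_n + 1L, n_n + n_t)
  values[, tumor_cols] <- values[, tumor_cols] + params$delta
  sample_ids <- c(sprintf("NREF%02d", seq_len(n_n)), sprintf("TREF%02d", seq_len(n_t)))
  dimnames(values) <- list(params$gene_ids, sample_ids)
  samples <- tibble(
    sample_id = sample_ids,
    patient_id = paste0("REF-", sample_ids),
    condition = rep(c("normal_ref", "tumor_ref"), c(n_n, n_t)))
  list(expression = validate_expression_matrix(values),
       samples = validate_sample_table(samples),
       truth = list(de_gene_ids = params$de_gene_ids, de_signs = params$de_signs))
}

#' Simulate the paired tissue / platform panel
#'
#' For each patient, one tumor-tissue profile is drawn as
#' `baseline + planted tumor effects + patient offset + residual noise`, and
#' each platform sample is that patient's tissue profile plus i.i.d.
#' per-gene drift `N(0, platform_drift_sd[p])`, plus any planted
#' condition-biased gene-set shift (see [sim_config()]).
#'
#' @param cfg A [sim_config()].
#' @return A list with `expression` (matrix; columns
#'   `<patient>_<condition>`), `samples` (tibble) and `truth` (list with
#'   `drift_rank`, `de_gene_ids`, `planted_active_sets`).
#' @export
simulate_platform_panel <- function(cfg) {
  cfg <- validate_sim_config(unclass(cfg))
  params <- sim_gene_params(cfg)
  sets <- sim_gene_sets(cfg)
  shift <- sim_shift_matrix(cfg, sets)
  set.seed(component_seed(cfg$seed, "panel"))
  n <- cfg$n_genes
  platforms <- platform_conditions()
  reps <- cfg$n_replicates
  cols_per_patient <- 1L + length(platforms) * reps
  values <- matrix(NA_real_, nrow = n,
                   ncol = length(cfg$patient_ids) * cols_per_patient)
  sample_ids <- character(ncol(values))
  patient_col <- character(ncol(values))
  condition_col <- character(ncol(values))
  j <- 0L
  for (pat in cfg$patient_ids) {
    pe <- rnorm(n, sd = cfg$patient_effect_sd)
    tissue <- params$mu + params$delta + pe + rnorm(n, sd = cfg$residual_sd)
    j <- j + 1L
    values[, j] <- tissue
    sample_ids[j] <- paste0(pat, "_tissue")
    patient_col[j] <- pat
    condition_col[j] <- "tissue"
    for (p in platforms) {
      for (r in seq_len(reps)) {
        j <- j + 1L
        drift <- rnorm(n, sd = cfg$platform_drift_sd[[p]])
        values[, j] <- tissue + drift + shift[, p]
        sample_ids[j] <- if (reps == 1L) paste0(pat, "_", p) else
          sprintf("%s_%s_rep%d", pat, p, r)
        patient_col[j] <- pat
        condition_col[j] <- p
      }
    }
  }
  dimnames(values) <- list(params$gene_ids, sample_ids)
  drift_rank <- platforms[order(cfg$platform_drift_sd, platforms)]
  samples <- tibble(sample_id = sample_ids, patient_id = patient_col,
                    condition = condition_col)
  list(expression = validate_expression_matrix(values),
       samples = validate_sample_table(samples),
       truth = list(drift_rank = drift_rank,
                    de_gene_ids = params$de_gene_ids,
                    planted_active_sets = sets$active))
}

#' Simulate TF-target and pathway gene-set collections
#'
#' Draws two collections of gene sets over the simulated gene universe.
#' When `active_shift > 0`, `n_active_sets` sets per collection are planted
#' as "active": their member genes receive a coordinated mean shift in the
#' `active_conditions` platform sample(s) of [simulate_platform_panel()]
#' (the two generators share a deterministic stream, so the collections
#' returned here are exactly those whose members are shifted in the panel).
#'
#' @param cfg A [sim_config()].
#' @return A list with `tf` and `pathways` ([gene_set_collection()]s) and
#'   `truth` (list with `planted_active_sets`: per active set, its shift
#'   direction and affected conditions).
#' @export
simulate_geneset_collections <- function(cfg) {
  cfg <- validate_sim_config(unclass(cfg))
  sets <- sim_gene_sets(cfg)
  list(tf = sets$tf, pathways = sets$pathways,
       truth = list(planted_active_sets = sets$active))
}

#' Simulate a complete study
#'
#' Convenience wrapper running [simulate_reference_cohorts()],
#' [simulate_platform_panel()] and [simulate_geneset_collections()] under
#' one configuration, with mutually consistent planted truth.
#'
#' @param cfg A [sim_config()].
#' @return A list with `reference`, `panel`, `collections` and a merged
#'   `truth`.
#' @export
simulate_study <- function(cfg) {
  cfg <- validate_sim_config(unclass(cfg))
  ref <- simulate_reference_cohorts(cfg)
  panel <- simulate_platform_panel(cfg)
  coll <- simulate_geneset_collections(cfg)
  list(reference = ref, panel = panel, collections = coll,
       truth = c(ref$truth,
                 panel$truth[c("drift_rank", "planted_active_sets")]),
       config = cfg)
}
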