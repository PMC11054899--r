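# Fixture builders shared across test files.

random_expression <- function(n_genes, n_samples, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(n_genes * n_samples, mean = 8, sd = 2), n_genes, n_samples,
         dimnames = list(sprintf("G%04d", seq_len(n_genes)),
                         sprintf("S%02d", seq_len(n_samples))))
}

# A small paired design: `n_patients` patients x (tissue + 5 platforms).
paired_samples <- function(n_patients = 2) {
  pats <- sprintf("P%d", seq_len(n_patients))
  conds <- c("tissue", platform_conditions())
  tibble::tibble(
    sample_id = as.vector(outer(pats, conds, paste, sep = "_")),
    patient_id = rep(pats, times = length(conds)),
    condition = rep(conds, each = n_patients))
}

# Small simulation configuration keeping unit tests fast; any field can be
# overridden through `...`.
small_sim <- function(seed = 1, ...) {
  args <- list(n_genes = 400, de_fraction = 0.1, n_tf_sets = 8,
               tf_set_size = 12, n_pathway_sets = 8, pathway_set_size = 12,
               n_active_sets = 2, seed = seed)
  args <- utils::modifyList(args, list(...))
  do.call(sim_config, args)
}
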