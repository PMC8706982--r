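# Small cohort configurations used by several test files; tiny dimensions
# keep random-forest imputation and SGCCA fits fast.

small_config <- function(seed = 3, n_subjects = 47, ...) {
  cohort_config(n_subjects = n_subjects, n_genera_raw = 40, n_fecal_raw = 30,
                n_plasma_raw = 34, n_rare_genera = 5,
                n_fecal_high_missing = 3, n_plasma_high_missing = 2,
                n_factors = 3, loading_sparsity = 0.1, seed = seed, ...)
}

recovery_config <- function(seed = 11, n_subjects = 200) {
  cohort_config(n_subjects = n_subjects, seed = seed)
}

# run generator -> preprocess -> sgcca -> network -> clusters on a planted
# cohort, with per-block keep-counts matching the planted per-factor counts
run_recovery_pipeline <- function(cfg, cutoff = 0.6) {
  cohort <- simulate_cohort(cfg, with_missingness = FALSE)
  prep <- preprocess_blocks(cohort$blocks)
  tr <- cohort$truth
  keep <- vapply(c("genus", "fecal", "plasma"),
                 function(b) sum(tr$block == b & tr$factor == 1), integer(1))
  model <- fit_sgcca(prep$blocks, n_components = cfg$n_factors,
                     sparsity = as.list(keep))
  pairs <- utils::combn(names(prep$blocks), 2)
  sims <- list()
  for (j in seq_len(ncol(pairs))) {
    sims[[paste(pairs[, j], collapse = "|")]] <-
      compute_similarity_matrix(model, pairs[, j])
  }
  net <- extract_clusters(build_network(sims, cutoff))
  list(cohort = cohort, prep = prep, model = model, network = net)
}

# cluster assignment joined with planted factor labels
cluster_truth_table <- function(net, truth) {
  cl <- net$clusters
  cl$factor <- truth$factor[match(paste(cl$block, cl$feature),
                                  paste(truth$block, truth$feature))]
  cl
}

scale01 <- function(x) (x - mean(x)) / sd(x)
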