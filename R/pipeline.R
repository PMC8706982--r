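#' Assemble and validate a pipeline configuration
#'
#' @param input_dir Directory with `genus.tsv`, `fecal.tsv`, `plasma.tsv`,
#'   `subjects.tsv` (as written by [write_cohort()] or user data of the same
#'   shape).
#' @param output_dir Directory the run writes into.
#' @param max_missing_frac,min_prevalence,pseudocount,int_offset
#'   Preprocessing parameters, see [preprocess_blocks()].
#' @param n_components,sparsity,scheme SGCCA parameters, see [fit_sgcca()].
#' @param cutoff Network similarity threshold.
#' @param damping,orientation Score parameters, see
#'   [compute_cluster_scores()].
#' @param fdr_family Association FDR family, see
#'   [fit_score_associations()].
#' @param seed Seed used for imputation.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, output_dir,
                            max_missing_frac = 0.20, min_prevalence = 0.10,
                            pseudocount = 1, int_offset = 3 / 8,
                            n_components = 2, sparsity = NULL,
                            scheme = "centroid", cutoff = 0.6,
                            damping = 0.85, orientation = "propagate",
                            fdr_family = "per_score", seed = 1) {
  for (f in c("genus.tsv", "fecal.tsv", "plasma.tsv", "subjects.tsv")) {
    path <- file.path(input_dir, f)
    if (!file.exists(path)) {
      stop("input file not found: ", path, call. = FALSE)
    }
  }
  stopifnot_fraction(max_missing_frac, "max_missing_frac")
  stopifnot_fraction(min_prevalence, "min_prevalence")
  structure(
    list(input_dir = input_dir, output_dir = output_dir,
         max_missing_frac = max_missing_frac,
         min_prevalence = min_prevalence, pseudocount = pseudocount,
         int_offset = int_offset, n_components = n_components,
         sparsity = sparsity, scheme = scheme, cutoff = cutoff,
         damping = damping, orientation = orientation,
         fdr_family = fdr_family, seed = seed),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' All [pipeline_config()] arguments are accepted as top-level keys;
#' unknown keys fail loudly.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
  writeLines(msg, con)
}

#' Run the full multi-omics pipeline
#'
#' Executes preprocess, SGCCA, network, score and association stages on the
#' cohort under `config$input_dir`, writing every artifact (processed
#' blocks, model JSON and weight TSVs, edge list and GraphML, cluster
#' membership, scores, associations, partial correlations), a `run.log`
#' with per-stage parameters and counts, and a `manifest.json` with input
#' checksums. A stage failure aborts with a stage-named message and leaves
#' a `FAILED` marker next to any partial outputs.
#'
#' @param config A [pipeline_config()].
#' @return The output directory, invisibly; the full result list is
#'   attached as attribute `"results"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(out, "run.log"), "w")
  on.exit(close(logf), add = TRUE)
  stage <- function(name, expr) {
    log_line(logf, "stage ", name, ": start")
    tryCatch(expr, error = function(e) {
      log_line(logf, "stage ", name, ": FAILED: ", conditionMessage(e))
      writeLines(paste0("stage ", name, ": ", conditionMessage(e)),
                 file.path(out, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  inputs <- file.path(config$input_dir,
                      c("genus.tsv", "fecal.tsv", "plasma.tsv", "subjects.tsv"))
  manifest <- list(
    inputs = stats::setNames(as.list(unname(tools::md5sum(inputs))),
                             basename(inputs)),
    config = unclass(config))

  cohort <- stage("read", read_cohort(config$input_dir))

  prep <- stage("preprocess", {
    p <- preprocess_blocks(
      cohort$blocks, max_missing_frac = config$max_missing_frac,
      min_prevalence = config$min_prevalence,
      pseudocount = config$pseudocount, int_offset = config$int_offset,
      impute_seed = config$seed)
    for (b in names(p$blocks)) {
      write_block_tsv(p$blocks[[b]], file.path(out, paste0("processed_", b, ".tsv")))
      log_line(logf, "preprocess ", b, ": ",
               p$report[[b]]$n_features_raw, " -> ",
               p$report[[b]]$n_features_retained, " features (",
               length(p$report[[b]]$removed), " removed)")
    }
    jsonlite::write_json(p$report, file.path(out, "preprocess_report.json"),
                         auto_unbox = TRUE, digits = NA)
    p
  })

  model <- stage("sgcca", {
    m <- fit_sgcca(prep$blocks, n_components = config$n_components,
                   sparsity = config$sparsity, scheme = config$scheme)
    write_sgcca_model(m, out)
    log_line(logf, "sgcca: ", m$n_components, " components, converged: ",
             paste(m$converged, collapse = ","))
    m
  })

  network <- stage("network", {
    pairs <- utils::combn(names(prep$blocks), 2)
    sims <- list()
    for (j in seq_len(ncol(pairs))) {
      nm <- paste(pairs[, j], collapse = "|")
      sims[[nm]] <- compute_similarity_matrix(model, pairs[, j])
    }
    net <- build_network(sims, cutoff = config$cutoff)
    net <- extract_clusters(net)
    write_network(net, out)
    log_line(logf, "network: ", nrow(net$nodes), " nodes, ",
             nrow(net$edges), " edges, ",
             length(unique(net$clusters$cluster)), " clusters at cutoff ",
             config$cutoff)
    net
  })

  score_set <- stage("score", {
    if (nrow(network$nodes) == 0) {
      log_line(logf, "score: empty network, no scores")
      NULL
    } else {
      s <- compute_cluster_scores(network, prep$blocks,
                                  damping = config$damping,
                                  orientation = config$orientation)
      write_scores(s, out)
      s
    }
  })

  assoc <- stage("associate", {
    if (is.null(score_set)) {
      NULL
    } else {
      a <- fit_score_associations(score_set$scores, cohort$outcomes,
                                  cohort$covariates,
                                  fdr_family = config$fdr_family)
      node_vals <- vapply(seq_len(nrow(network$clusters)), function(i) {
        blk <- prep$blocks[[network$clusters$block[i]]]
        blk$values[, network$clusters$feature[i]]
      }, numeric(nrow(score_set$scores)))
      colnames(node_vals) <- network$clusters$feature
      rownames(node_vals) <- rownames(score_set$scores)
      pc <- partial_correlations(node_vals, cohort$outcomes,
                                 cohort$covariates)
      write_associations(a, pc, out)
      log_line(logf, "associate: ", sum(!is.na(a$p)), " models fitted")
      list(associations = a, partial_correlations = pc)
    }
  })

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  log_line(logf, "pipeline complete")
  res <- list(preprocess = prep, model = model, network = network,
              scores = score_set, associations = assoc)
  structure(invisible(out), results = res)
}
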