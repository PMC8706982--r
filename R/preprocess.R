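#' Remove features with too many missing values
#'
#' Drops every feature whose missing fraction exceeds `max_frac` (strictly),
#' the usual exclusion applied to metabolite panels before imputation.
#'
#' @param block An [omics_block()].
#' @param max_frac Maximum tolerated missing fraction, default 0.20.
#' @return A list with `block` (features removed, order preserved, filter
#'   logged) and `removed` (character vector of removed feature names).
#' @export
filter_by_missingness <- function(block, max_frac = 0.20) {
  stopifnot(inherits(block, "omics_block"))
  assert_not_applied(block, "filter_by_missingness")
  stopifnot_fraction(max_frac, "max_frac")
  if (nrow(block$values) < 1L) stop("block has no samples", call. = FALSE)
  frac <- colMeans(is.na(block$values))
  drop <- frac > max_frac
  removed <- feature_names(block)[drop]
  block$values <- block$values[, !drop, drop = FALSE]
  block <- log_transform(block, "filter_by_missingness")
  list(block = block, removed = removed)
}

#' Impute missing cells by iterative random forests
#'
#' Each feature with missing values is regressed on all other features of
#' the block with a random forest; missing cells start at feature means and
#' the fit/predict cycle is repeated until the imputed values stabilize
#' (relative change below `tol`) or `max_iter` passes. Observed cells are
#' never altered, and the result is deterministic given `seed`.
#'
#' @param block An [omics_block()]; no feature may be entirely missing.
#' @param seed Integer seed.
#' @param ntree Trees per forest.
#' @param tol Relative-change stopping tolerance.
#' @param max_iter Maximum number of passes over the features.
#' @return The imputed block (imputation logged).
#' @export
impute_missing <- function(block, seed = 1, ntree = 100, tol = 1e-3,
                           max_iter = 10) {
  stopifnot(inherits(block, "omics_block"))
  assert_not_applied(block, "impute_missing")
  x <- block$values
  miss <- is.na(x)
  if (!any(miss)) return(log_transform(block, "impute_missing"))
  all_missing <- colSums(!miss) == 0
  if (any(all_missing)) {
    stop("feature(s) entirely missing (should have been filtered): ",
         paste(feature_names(block)[all_missing], collapse = ", "),
         call. = FALSE)
  }
  # mean initialization, then refine features in order of increasing
  # missingness so better-observed features inform worse ones first
  mu <- colMeans(x, na.rm = TRUE)
  for (j in which(colSums(miss) > 0)) x[miss[, j], j] <- mu[j]
  targets <- which(colSums(miss) > 0)
  targets <- targets[order(colSums(miss)[targets])]
  withr::with_seed(seed, {
    for (iter in seq_len(max_iter)) {
      x_prev <- x
      for (j in targets) {
        obs <- !miss[, j]
        fit <- randomForest::randomForest(
          x = x[obs, -j, drop = FALSE], y = x[obs, j], ntree = ntree)
        x[!obs, j] <- stats::predict(fit, x[!obs, -j, drop = FALSE])
      }
      delta <- sqrt(sum((x[miss] - x_prev[miss])^2)) /
        max(sqrt(sum(x[miss]^2)), .Machine$double.eps)
      if (delta < tol) break
    }
  })
  block$values <- x
  log_transform(block, "impute_missing")
}

#' Rank-based inverse normal transformation
#'
#' Maps each feature to normal quantiles of its offset-adjusted ranks,
#' `qnorm((rank - c) / (n - 2c + 1))`, with average ranks for ties and the
#' Blom offset `c = 3/8` by default. The result is approximately standard
#' normal per feature and monotone in the original values. Intended for the
#' metabolite blocks; the genus block goes through [clr_transform()] instead.
#'
#' @param block An [omics_block()] with no missing cells.
#' @param offset Rank offset constant `c`.
#' @return The transformed block (transform logged). Constant features map
#'   to all zeros with a warning.
#' @export
rank_inverse_normal <- function(block, offset = 3 / 8) {
  stopifnot(inherits(block, "omics_block"))
  assert_not_applied(block, "rank_inverse_normal")
  if (anyNA(block$values)) {
    stop("missing cells present; impute before transforming", call. = FALSE)
  }
  n <- nrow(block$values)
  const <- apply(block$values, 2, function(v) length(unique(v)) == 1L)
  if (any(const)) {
    warning("constant feature(s) map to all zeros: ",
            paste(feature_names(block)[const], collapse = ", "),
            call. = FALSE)
  }
  block$values <- apply(block$values, 2, function(v) {
    r <- rank(v, ties.method = "average")
    qnorm((r - offset) / (n - 2 * offset + 1))
  })
  log_transform(block, "rank_inverse_normal")
}

#' Remove low-prevalence genera
#'
#' Drops genera with a nonzero count in fewer than `min_prevalence * n`
#' samples.
#'
#' @param block A genus [omics_block()] of nonnegative counts, no missing
#'   cells.
#' @param min_prevalence Minimum fraction of samples with a nonzero count,
#'   default 0.10.
#' @return A list with `block` (filter logged) and `removed`.
#' @export
prevalence_filter <- function(block, min_prevalence = 0.10) {
  stopifnot(inherits(block, "omics_block"))
  assert_not_applied(block, "prevalence_filter")
  stopifnot_fraction(min_prevalence, "min_prevalence")
  if (anyNA(block$values)) stop("genus block has missing cells", call. = FALSE)
  if (any(block$values < 0)) stop("negative counts in genus block", call. = FALSE)
  n <- nrow(block$values)
  prev <- colSums(block$values > 0)
  drop <- prev < min_prevalence * n
  removed <- feature_names(block)[drop]
  block$values <- block$values[, !drop, drop = FALSE]
  block <- log_transform(block, "prevalence_filter")
  list(block = block, removed = removed)
}

#' Centered log-ratio transform
#'
#' Per sample, adds `pseudocount` to the counts and maps each value to its
#' natural log minus the sample's mean log, so every output row sums to
#' zero. The standard map from compositional count data to unconstrained
#' space.
#'
#' @param block A genus [omics_block()] of nonnegative counts.
#' @param pseudocount Added to every count before the log; must leave all
#'   values strictly positive.
#' @return The transformed block (transform logged).
#' @export
clr_transform <- function(block, pseudocount = 1) {
  stopifnot(inherits(block, "omics_block"))
  assert_not_applied(block, "clr_transform")
  if (anyNA(block$values)) stop("genus block has missing cells", call. = FALSE)
  if (any(block$values < 0)) {
    stop("negative counts in genus block", call. = FALSE)
  }
  x <- block$values + pseudocount
  if (any(x <= 0)) {
    stop("zero counts with pseudocount ", pseudocount,
         "; use a positive pseudocount", call. = FALSE)
  }
  lx <- log(x)
  block$values <- lx - rowMeans(lx)
  log_transform(block, "clr_transform")
}

#' Preprocess the three omics blocks
#'
#' Metabolite blocks: missingness filter, iterative random-forest
#' imputation, rank-based inverse normal transformation. Genus block:
#' prevalence filter, centered log-ratio transform. Each step is recorded in
#' the block's `transform_log`, and re-running preprocessing on an
#' already-processed block is an error.
#'
#' @param blocks Named list with `genus`, `fecal`, `plasma`
#'   [omics_block()]s.
#' @param max_missing_frac Missingness exclusion threshold for metabolites.
#' @param min_prevalence Genus prevalence threshold.
#' @param pseudocount CLR pseudocount.
#' @param int_offset Rank offset for the inverse normal transformation.
#' @param impute_seed,impute_ntree Imputation controls, see
#'   [impute_missing()].
#' @return A list with `blocks` (processed) and `report` (removed features,
#'   missing fractions and parameters per block).
#' @export
preprocess_blocks <- function(blocks, max_missing_frac = 0.20,
                              min_prevalence = 0.10, pseudocount = 1,
                              int_offset = 3 / 8, impute_seed = 1,
                              impute_ntree = 100) {
  stopifnot(all(c("genus", "fecal", "plasma") %in% names(blocks)))
  report <- list(parameters = list(
    max_missing_frac = max_missing_frac, min_prevalence = min_prevalence,
    pseudocount = pseudocount, int_offset = int_offset,
    impute_seed = impute_seed, impute_ntree = impute_ntree))
  out <- list()
  for (b in c("fecal", "plasma")) {
    blk <- blocks[[b]]
    report[[b]] <- list(
      n_features_raw = ncol(blk$values),
      missing_fraction = unname(round(mean(is.na(blk$values)), 4)))
    flt <- filter_by_missingness(blk, max_missing_frac)
    report[[b]]$removed <- flt$removed
    report[[b]]$n_features_retained <- ncol(flt$block$values)
    blk <- impute_missing(flt$block, seed = impute_seed, ntree = impute_ntree)
    out[[b]] <- rank_inverse_normal(blk, offset = int_offset)
  }
  gen <- blocks$genus
  report$genus <- list(n_features_raw = ncol(gen$values))
  flt <- prevalence_filter(gen, min_prevalence)
  report$genus$removed <- flt$removed
  report$genus$n_features_retained <- ncol(flt$block$values)
  out$genus <- clr_transform(flt$block, pseudocount = pseudocount)
  list(blocks = out[c("genus", "fecal", "plasma")], report = report)
}
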