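#' Construct an omics block
#'
#' The unit every pipeline stage passes along: one sample-by-feature numeric
#' matrix tagged with a block label, plus an ordered log of the transforms
#' already applied to it.
#'
#' @param values Numeric matrix, samples in rows and features in columns.
#'   Counts for the genus block; concentrations (arbitrary units) for the
#'   metabolite blocks. `NA` marks a missing cell.
#' @param block_label One of `"genus"`, `"fecal"`, `"plasma"`.
#' @param feature_names Unique feature names; defaults to `colnames(values)`.
#' @param sample_ids Unique sample identifiers; defaults to
#'   `rownames(values)`.
#' @param transform_log Character vector of transforms already applied, in
#'   application order. Usually left empty at construction.
#'
#' @return An object of class `omics_block`.
#' @export
omics_block <- function(values, block_label,
                        feature_names = colnames(values),
                        sample_ids = rownames(values),
                        transform_log = character()) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  block_label <- match.arg(block_label, c("genus", "fecal", "plasma"))
  if (is.null(feature_names)) {
    feature_names <- paste0(substr(block_label, 1, 1), seq_len(ncol(values)))
  }
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (anyDuplicated(feature_names)) {
    stop("duplicate feature names in ", block_label, " block", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids in ", block_label, " block", call. = FALSE)
  }
  if (length(feature_names) != ncol(values)) {
    stop("feature_names length does not match ncol(values)", call. = FALSE)
  }
  if (length(sample_ids) != nrow(values)) {
    stop("sample_ids length does not match nrow(values)", call. = FALSE)
  }
  dimnames(values) <- list(sample_ids, feature_names)
  structure(
    list(values = values, block_label = block_label,
         transform_log = transform_log),
    class = "omics_block"
  )
}

#' @export
print.omics_block <- function(x, ...) {
  cat(sprintf("<omics_block '%s'> %d samples x %d features\n",
              x$block_label, nrow(x$values), ncol(x$values)))
  n_miss <- sum(is.na(x$values))
  if (n_miss > 0) {
    cat(sprintf("  missing cells: %d (%.1f%%)\n", n_miss,
                100 * n_miss / length(x$values)))
  }
  if (length(x$transform_log)) {
    cat("  transforms:", paste(x$transform_log, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' @export
dim.omics_block <- function(x) dim(x$values)

feature_names <- function(block) colnames(block$values)
sample_ids <- function(block) rownames(block$values)

# Applying the same transform twice is a pipeline-order error; checked on
# entry to each preprocessing operation.
assert_not_applied <- function(block, name) {
  if (name %in% block$transform_log) {
    stop("transform '", name, "' already applied to ", block$block_label,
         " block (transform_log: ",
         paste(block$transform_log, collapse = ", "), ")", call. = FALSE)
  }
  invisible(block)
}

# Record a transform exactly once, in application order.
log_transform <- function(block, name) {
  assert_not_applied(block, name)
  block$transform_log <- c(block$transform_log, name)
  block
}

stopifnot_fraction <- function(x, name, allow_one = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 &&
    (if (allow_one) x <= 1 else x < 1)
  if (!ok) {
    stop("`", name, "` must be a fraction in [0,", if (allow_one) "1]" else "1)",
         call. = FALSE)
  }
  invisible(x)
}
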