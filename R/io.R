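#' Write an omics block as TSV
#'
#' Samples as rows (first column `subject`), one header row of feature
#' names, missing cells empty.
#'
#' @param block An [omics_block()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_block_tsv <- function(block, path) {
  df <- data.frame(subject = sample_ids(block), block$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read an omics block from TSV
#'
#' @param path File written by [write_block_tsv()] (or user data of the same
#'   shape: `subject` column, then one numeric column per feature, empty
#'   cells missing).
#' @param block_label One of `"genus"`, `"fecal"`, `"plasma"`.
#' @return An [omics_block()].
#' @export
read_block_tsv <- function(path, block_label) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, na.strings = "",
                          stringsAsFactors = FALSE)
  if (!"subject" %in% names(df)) {
    stop("`", path, "` must have a `subject` column", call. = FALSE)
  }
  m <- as.matrix(df[setdiff(names(df), "subject")])
  storage.mode(m) <- "double"
  rownames(m) <- df$subject
  omics_block(m, block_label)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `genus.tsv`, `fecal.tsv`, `plasma.tsv`
#'   and `subjects.tsv` (and optionally `truth.json`).
#' @return A list with `blocks`, `covariates`, `outcomes` and `truth`
#'   (`NULL` when absent).
#' @export
read_cohort <- function(dir) {
  blocks <- list(
    genus = read_block_tsv(file.path(dir, "genus.tsv"), "genus"),
    fecal = read_block_tsv(file.path(dir, "fecal.tsv"), "fecal"),
    plasma = read_block_tsv(file.path(dir, "plasma.tsv"), "plasma")
  )
  subj_path <- file.path(dir, "subjects.tsv")
  if (!file.exists(subj_path)) {
    stop("subjects file not found: ", subj_path, call. = FALSE)
  }
  subjects <- utils::read.delim(subj_path, check.names = FALSE,
                                na.strings = "", stringsAsFactors = FALSE)
  covars <- subjects[c("subject", "age", "sex", "bmi")]
  outcomes <- subjects[c("subject", intersect(.outcome_names, names(subjects)))]
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    as.data.frame(jsonlite::read_json(truth_path, simplifyVector = TRUE))
  }
  list(blocks = blocks, covariates = covars, outcomes = outcomes,
       truth = truth)
}
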