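#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over [stats::p.adjust()] with input validation; adjusted
#' `p_(i) = min_{j>=i} min(1, p_(j) * m / j)` mapped back to input order.
#'
#' @param p Numeric vector of p-values in \[0,1\].
#' @param m Family size; defaults to `length(p)`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0,1]", call. = FALSE)
  }
  p.adjust(p, method = "BH", n = m)
}

#' Associate multi-omics scores with outcomes by adjusted linear regression
#'
#' Fits `outcome ~ score + age + sex + bmi` by OLS per (score, outcome) on
#' complete cases, reporting the score coefficient (effect per 1-SD score,
#' since scores are standardized), its SE, raw p, and BH-adjusted p. The
#' FDR family is, by default, each score's set of outcomes.
#'
#' @param scores Subject x score matrix (e.g. `$scores` of a
#'   `cluster_score_set`), subjects in rownames.
#' @param outcomes Data frame with `subject` plus outcome columns.
#' @param covariates Data frame with `subject`, `age`, `sex`, `bmi`.
#' @param fdr_family `"per_score"` (default) adjusts within each score
#'   across its outcomes; `"global"` adjusts across every row at once.
#' @return An `association_table` data frame: score, outcome, n, beta, se,
#'   p, p_adj, flag (`"constant_outcome"` rows are not fitted).
#' @export
fit_score_associations <- function(scores, outcomes, covariates,
                                   fdr_family = c("per_score", "global")) {
  fdr_family <- match.arg(fdr_family)
  scores <- as.matrix(scores)
  outcome_names <- setdiff(names(outcomes), "subject")
  rows <- NULL
  for (sc in colnames(scores)) {
    df0 <- merge(
      data.frame(subject = rownames(scores), score = scores[, sc],
                 stringsAsFactors = FALSE),
      covariates, by = "subject")
    for (oc in outcome_names) {
      df <- merge(df0, outcomes[c("subject", oc)], by = "subject")
      names(df)[names(df) == oc] <- "y"
      df <- df[complete.cases(df[c("y", "score", "age", "sex", "bmi")]), ]
      n <- nrow(df)
      if (n < 6 || sd(df$y) == 0) {
        rows <- rbind(rows, data.frame(
          score = sc, outcome = oc, n = n, beta = NA_real_, se = NA_real_,
          p = NA_real_, p_adj = NA_real_,
          flag = if (n >= 6) "constant_outcome" else "insufficient_n",
          stringsAsFactors = FALSE))
        next
      }
      fit <- lm(y ~ score + age + sex + bmi, data = df)
      cf <- summary(fit)$coefficients
      flag <- ""
      if (!"score" %in% rownames(cf)) {
        beta <- se <- p <- NA_real_
        flag <- "degenerate_fit"
      } else {
        beta <- cf["score", "Estimate"]
        se <- cf["score", "Std. Error"]
        p <- cf["score", "Pr(>|t|)"]
        if (!is.finite(se) || se == 0 || is.nan(p)) flag <- "degenerate_fit"
      }
      rows <- rbind(rows, data.frame(
        score = sc, outcome = oc, n = n, beta = beta, se = se, p = p,
        p_adj = NA_real_, flag = flag, stringsAsFactors = FALSE))
    }
  }
  fitted <- !is.na(rows$p)
  if (fdr_family == "per_score") {
    for (sc in unique(rows$score)) {
      idx <- which(rows$score == sc & fitted)
      if (length(idx)) rows$p_adj[idx] <- bh_adjust(rows$p[idx])
    }
  } else if (any(fitted)) {
    rows$p_adj[fitted] <- bh_adjust(rows$p[fitted])
  }
  rows$covariates <- "age,sex,bmi"
  class(rows) <- c("association_table", "data.frame")
  rows
}

residualize <- function(v, covar_mat) {
  stats::resid(stats::lm.fit(covar_mat, v))
}

#' Covariate-adjusted Pearson partial correlations
#'
#' Residualizes every variable and outcome on the covariates (with
#' intercept) by OLS and correlates the residuals; p-values come from
#' `t = r * sqrt((n - 2 - k) / (1 - r^2))` with `k` covariates, BH-adjusted
#' across the whole matrix.
#'
#' @param values Subject x variable matrix (cluster member values),
#'   subjects in rownames.
#' @param outcomes Data frame with `subject` plus outcome columns.
#' @param covariates Data frame with `subject`, `age`, `sex`, `bmi`.
#' @return A `partial_correlation_matrix`: list with `r`, `p`, `p_adj`
#'   (variable x outcome matrices), `n`, `covariates`.
#' @export
partial_correlations <- function(values, outcomes, covariates) {
  values <- as.matrix(values)
  outcome_names <- setdiff(names(outcomes), "subject")
  merged <- merge(merge(
    data.frame(subject = rownames(values), stringsAsFactors = FALSE),
    covariates, by = "subject"), outcomes, by = "subject")
  keep <- complete.cases(merged[c("age", "sex", "bmi", outcome_names)])
  merged <- merged[keep, ]
  v <- values[merged$subject, , drop = FALSE]
  n <- nrow(merged)
  k <- 3L
  if (n <= k + 2) stop("too few complete cases", call. = FALSE)
  cm <- cbind(1, merged$age, merged$sex, merged$bmi)
  rv <- apply(v, 2, residualize, covar_mat = cm)
  ro <- apply(as.matrix(merged[outcome_names]), 2, residualize,
              covar_mat = cm)
  # a variable fully explained by the covariates has a (numerically) zero
  # residual; its partial correlations are 0 by convention
  degen_v <- apply(rv, 2, sd) < 1e-10 * pmax(apply(v, 2, sd), 1)
  degen_o <- apply(ro, 2, sd) < 1e-10 *
    pmax(apply(as.matrix(merged[outcome_names]), 2, sd), 1)
  rv[, degen_v] <- 0
  ro[, degen_o] <- 0
  r <- suppressWarnings(cor(rv, ro))
  r[degen_v, ] <- 0
  r[, degen_o] <- 0
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2 - k) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2 - k)
  p[abs(r) >= 1] <- 0
  p_adj <- matrix(bh_adjust(as.vector(p)), nrow(p), ncol(p),
                  dimnames = dimnames(p))
  structure(list(r = r, p = p, p_adj = p_adj, n = n,
                 covariates = c("age", "sex", "bmi")),
            class = "partial_correlation_matrix")
}

#' @export
print.partial_correlation_matrix <- function(x, ...) {
  cat(sprintf("<partial_correlation_matrix> %d variables x %d outcomes, n = %d\n",
              nrow(x$r), ncol(x$r), x$n))
  invisible(x)
}

#' Write association artifacts (associations.tsv, partial_correlations.tsv)
#'
#' @param assoc An `association_table`.
#' @param pcor Optional `partial_correlation_matrix`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_associations <- function(assoc, pcor = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(assoc, file.path(dir, "associations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(pcor)) {
    long <- data.frame(
      variable = rep(rownames(pcor$r), ncol(pcor$r)),
      outcome = rep(colnames(pcor$r), each = nrow(pcor$r)),
      r = as.vector(pcor$r), p = as.vector(pcor$p),
      p_adj = as.vector(pcor$p_adj), stringsAsFactors = FALSE)
    utils::write.table(long, file.path(dir, "partial_correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
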