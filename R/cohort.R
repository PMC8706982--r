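#' @importFrom stats rnorm rbinom rmultinom runif cor qnorm sd lm coef
#'   complete.cases p.adjust pt cov quantile
NULL

.outcome_names <- c("Cholesterol", "LDLc", "HDLc", "VLDLc", "Triglycerides",
                    "Glucose", "Insulin", "HOMA-IR", "SBP", "DBP")

# Cohort means and cross-sectional SDs for the ten cardiometabolic outcomes
# (mg/dL for lipids and glucose, mcUI/mL insulin, mmHg pressures), typical of
# an adult overweight/obese population with metabolic syndrome.
.outcome_means <- c(Cholesterol = 215.3, LDLc = 135.8, HDLc = 50.5,
                    VLDLc = 28.1, Triglycerides = 147.7, Glucose = 100.2,
                    Insulin = 13.4, `HOMA-IR` = 3.3, SBP = 135.1, DBP = 85.0)
.outcome_sds <- c(Cholesterol = 32.2, LDLc = 27.1, HDLc = 10.3, VLDLc = 11.9,
                  Triglycerides = 75.0, Glucose = 12.9, Insulin = 7.3,
                  `HOMA-IR` = 1.9, SBP = 12.1, DBP = 9.4)

# Deterministic per-stage substream of a user seed; stays below 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 262139) * 7919 + k)
}

#' Configuration of a synthetic tri-omics cohort
#'
#' Defines the dimensions, planted latent structure, noise and missingness of
#' a generated cohort. Defaults emulate a cross-sectional metabolic-syndrome
#' cohort: 47 subjects, 226 fecal and 378 plasma metabolites of which 23 and
#' 5 respectively carry heavy missingness, and a genus count panel in which
#' 151 of 180 genera are prevalent in at least 10% of subjects.
#'
#' @param n_subjects Number of subjects.
#' @param n_genera_raw Number of genera in the raw count table (common plus
#'   rare; see `n_rare_genera`).
#' @param n_fecal_raw,n_plasma_raw Numbers of measured fecal and plasma
#'   metabolites before missingness filtering.
#' @param n_factors Number of planted cross-block latent factors.
#' @param loading_sparsity Fraction of each block's features loading on each
#'   factor (disjoint feature sets across factors).
#' @param noise_sd Residual SD of the feature-level noise around the factor
#'   signal, on the latent (log/logit) scale.
#' @param library_size Sequencing depth per subject for the genus counts.
#' @param n_rare_genera Number of genera constructed to be present in fewer
#'   than 10% of subjects (removed by the default prevalence filter).
#' @param n_fecal_high_missing,n_plasma_high_missing Numbers of metabolites
#'   assigned the heavy missingness rate (removed by the default >20% filter).
#' @param high_missing_rate,low_missing_rate Per-cell missingness
#'   probabilities for the heavy and light groups; must lie in \[0,1) with
#'   `high_missing_rate` > 0.25 and `low_missing_rate` < 0.15 so the two
#'   groups fall on opposite sides of the 20% exclusion threshold.
#' @param missing_profile Optional list with numeric vectors `fecal` and
#'   `plasma` of per-feature missingness rates, overriding the two-rate
#'   default profile.
#' @param outcome_effects `n_factors` x 10 matrix of factor effects on the
#'   outcomes, in raw outcome units per 1-SD factor; columns named after the
#'   outcomes. Default plants lipid effects on the first and last factors.
#' @param covariate_effects 3 x 10 matrix (rows `age`, `sex`, `bmi`) of
#'   covariate effects in raw outcome units.
#' @param outcome_means,outcome_noise_sd Named numeric vectors of outcome
#'   intercepts and residual SDs.
#' @param seed Integer seed; a fixed seed makes the whole cohort
#'   reproducible byte-for-byte.
#'
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 47,
                          n_genera_raw = 180,
                          n_fecal_raw = 226,
                          n_plasma_raw = 378,
                          n_factors = 5,
                          loading_sparsity = 0.05,
                          noise_sd = 0.3,
                          library_size = 50000,
                          n_rare_genera = 29,
                          n_fecal_high_missing = 23,
                          n_plasma_high_missing = 5,
                          high_missing_rate = 0.35,
                          low_missing_rate = 0.05,
                          missing_profile = NULL,
                          outcome_effects = NULL,
                          covariate_effects = NULL,
                          outcome_means = .outcome_means,
                          outcome_noise_sd = .outcome_sds,
                          seed = 1) {
  chk_count <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 ||
        x != round(x)) {
      stop("configuration error: `", name, "` must be a positive integer",
           call. = FALSE)
    }
    as.integer(x)
  }
  n_subjects <- chk_count(n_subjects, "n_subjects")
  n_genera_raw <- chk_count(n_genera_raw, "n_genera_raw")
  n_fecal_raw <- chk_count(n_fecal_raw, "n_fecal_raw")
  n_plasma_raw <- chk_count(n_plasma_raw, "n_plasma_raw")
  n_factors <- chk_count(n_factors, "n_factors")
  library_size <- chk_count(library_size, "library_size")
  if (n_rare_genera < 0 || n_rare_genera >= n_genera_raw) {
    stop("configuration error: `n_rare_genera` must be in [0, n_genera_raw)",
         call. = FALSE)
  }
  for (nm in c("n_fecal_high_missing", "n_plasma_high_missing")) {
    v <- get(nm)
    if (v < 0 || v > get(sub("_high_missing", "_raw", nm))) {
      stop("configuration error: `", nm, "` out of range", call. = FALSE)
    }
  }
  for (nm in c("high_missing_rate", "low_missing_rate")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || v >= 1) {
      stop("configuration error: `", nm, "` must lie in [0,1)", call. = FALSE)
    }
  }
  if (loading_sparsity <= 0 || loading_sparsity > 1 / n_factors) {
    stop("configuration error: `loading_sparsity` must lie in (0, 1/n_factors]",
         call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("configuration error: `noise_sd` must be >= 0", call. = FALSE)
  }
  if (!is.null(missing_profile)) {
    if (!is.list(missing_profile) ||
        !all(c("fecal", "plasma") %in% names(missing_profile))) {
      stop("configuration error: `missing_profile` must list `fecal` and `plasma` rates",
           call. = FALSE)
    }
    for (b in c("fecal", "plasma")) {
      r <- missing_profile[[b]]
      if (length(r) != get(paste0("n_", b, "_raw")) || any(r < 0 | r >= 1)) {
        stop("configuration error: `missing_profile$", b,
             "` must give one rate in [0,1) per raw feature", call. = FALSE)
      }
    }
  }
  if (is.null(outcome_effects)) {
    outcome_effects <- default_outcome_effects(n_factors)
  } else {
    outcome_effects <- as.matrix(outcome_effects)
    if (is.null(colnames(outcome_effects)) ||
        !all(colnames(outcome_effects) %in% .outcome_names)) {
      stop("configuration error: `outcome_effects` columns must be named after outcomes: ",
           paste(.outcome_names, collapse = ", "), call. = FALSE)
    }
    if (nrow(outcome_effects) != n_factors) {
      stop("configuration error: `outcome_effects` must have n_factors rows",
           call. = FALSE)
    }
    full <- matrix(0, n_factors, length(.outcome_names),
                   dimnames = list(NULL, .outcome_names))
    full[, colnames(outcome_effects)] <- outcome_effects
    outcome_effects <- full
  }
  if (is.null(covariate_effects)) {
    covariate_effects <- default_covariate_effects()
  } else {
    covariate_effects <- as.matrix(covariate_effects)
    if (!identical(rownames(covariate_effects), c("age", "sex", "bmi")) ||
        !all(colnames(covariate_effects) %in% .outcome_names)) {
      stop("configuration error: `covariate_effects` must have rows age/sex/bmi and outcome-named columns",
           call. = FALSE)
    }
    full <- matrix(0, 3, length(.outcome_names),
                   dimnames = list(c("age", "sex", "bmi"), .outcome_names))
    full[, colnames(covariate_effects)] <- covariate_effects
    covariate_effects <- full
  }
  for (nm in c("outcome_means", "outcome_noise_sd")) {
    v <- get(nm)
    if (!all(.outcome_names %in% names(v))) {
      stop("configuration error: `", nm, "` must name all ten outcomes",
           call. = FALSE)
    }
    assign(nm, v[.outcome_names])
  }
  if (any(outcome_noise_sd < 0)) {
    stop("configuration error: `outcome_noise_sd` must be >= 0", call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("configuration error: `seed` must be a single integer", call. = FALSE)
  }
  structure(
    list(n_subjects = n_subjects, n_genera_raw = n_genera_raw,
         n_fecal_raw = n_fecal_raw, n_plasma_raw = n_plasma_raw,
         n_factors = n_factors, loading_sparsity = loading_sparsity,
         noise_sd = noise_sd, library_size = library_size,
         n_rare_genera = n_rare_genera,
         n_fecal_high_missing = n_fecal_high_missing,
         n_plasma_high_missing = n_plasma_high_missing,
         high_missing_rate = high_missing_rate,
         low_missing_rate = low_missing_rate,
         missing_profile = missing_profile,
         outcome_effects = outcome_effects,
         covariate_effects = covariate_effects,
         outcome_means = outcome_means,
         outcome_noise_sd = outcome_noise_sd,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# Default factor -> outcome effect pattern: the first factor drives total and
# LDL cholesterol, the last drives the triglyceride-rich lipid axis; effects
# are half an outcome SD per 1-SD factor.
default_outcome_effects <- function(n_factors) {
  g <- matrix(0, n_factors, length(.outcome_names),
              dimnames = list(NULL, .outcome_names))
  g[1, c("Cholesterol", "LDLc")] <- 0.5 * .outcome_sds[c("Cholesterol", "LDLc")]
  if (n_factors >= 2) {
    last <- n_factors
    nm <- c("Cholesterol", "VLDLc", "Triglycerides", "LDLc")
    g[last, nm] <- 0.4 * .outcome_sds[nm]
  }
  g
}

default_covariate_effects <- function() {
  ce <- matrix(0, 3, length(.outcome_names),
               dimnames = list(c("age", "sex", "bmi"), .outcome_names))
  ce["age", ] <- 0.02 * .outcome_sds   # per year, age centered at 50
  ce["sex", ] <- -0.25 * .outcome_sds  # female = 1
  ce["bmi", ] <- 0.05 * .outcome_sds   # per kg/m^2, centered at 30
  ce
}

rnorm_trunc <- function(n, mean, sd, lower, upper) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
  }
  x
}

#' Generate the latent skeleton of a synthetic cohort
#'
#' Draws independent standard-normal latent factors and plausible demographic
#' covariates (age truncated normal 30-65 years around 50.6, BMI truncated
#' normal 25-35 around 30.5, sex Bernoulli with 63.8% women coded 1).
#'
#' @param config A [cohort_config()].
#' @return A `synthetic_cohort` with `latent_factors` (subject x factor
#'   matrix) and `covariates` (age/sex/bmi data frame); omics blocks and
#'   outcomes are filled in by [generate_blocks()] and [generate_outcomes()].
#' @export
generate_latent_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  ids <- sprintf("S%03d", seq_len(n))
  withr::with_seed(derive_seed(config$seed, 1L), {
    f <- matrix(rnorm(n * config$n_factors), n, config$n_factors,
                dimnames = list(ids, paste0("F", seq_len(config$n_factors))))
    covariates <- data.frame(
      subject = ids,
      age = round(rnorm_trunc(n, 50.6, 7.13, 30, 65), 1),
      sex = rbinom(n, 1, 0.638),
      bmi = round(rnorm_trunc(n, 30.5, 2.28, 25, 35), 1),
      stringsAsFactors = FALSE
    )
  })
  structure(
    list(latent_factors = f, covariates = covariates, blocks = NULL,
         outcomes = NULL, truth = NULL, config = config),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, %d latent factors\n",
              nrow(x$latent_factors), ncol(x$latent_factors)))
  for (b in x$blocks) {
    cat("  "); print(b)
  }
  if (!is.null(x$outcomes)) cat("  outcomes:", ncol(x$outcomes) - 1L, "\n")
  invisible(x)
}

# Disjoint per-factor feature assignments for one block; returns a p x L
# loading matrix and the truth table rows.
plant_loadings <- function(p, n_factors, loading_sparsity, feature_names,
                           block_label) {
  per_factor <- max(1L, round(loading_sparsity * p))
  idx <- sample(p, per_factor * n_factors)
  lambda <- matrix(0, p, n_factors)
  truth <- NULL
  for (l in seq_len(n_factors)) {
    feats <- idx[seq.int((l - 1L) * per_factor + 1L, l * per_factor)]
    lam <- runif(per_factor, 0.75, 1.25) * sample(c(-1, 1), per_factor, TRUE)
    lambda[feats, l] <- lam
    truth <- rbind(truth, data.frame(block = block_label,
                                     feature = feature_names[feats],
                                     factor = l, loading = lam,
                                     stringsAsFactors = FALSE))
  }
  list(lambda = lambda, truth = truth)
}

#' Fill in the three omics blocks of a synthetic cohort
#'
#' Metabolite features are affine transforms of `latent signal + noise`
#' (per-feature location/scale so values look like concentrations; monotone
#' linear, so correlation structure is untouched). Genus counts are drawn by
#' a logistic-normal-multinomial model: per-subject softmax of
#' `baseline + loadings x factors + noise` over the genera, multiplied into
#' multinomial counts at the configured library size, so rows are
#' nonnegative integers summing to the library size. A configured number of
#' rare genera are present in fewer than 10% of subjects; count draws are
#' repeated with an incremented seed until every common genus clears and
#' every rare genus fails the 10% prevalence line.
#'
#' @param cohort A `synthetic_cohort` from [generate_latent_cohort()].
#' @param config The same [cohort_config()].
#' @return The cohort with `blocks` (list of genus/fecal/plasma
#'   [omics_block()]s) and `truth` (data frame of planted feature-factor
#'   loadings) filled.
#' @export
generate_blocks <- function(cohort, config) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (is.null(cohort$latent_factors)) stop("latent factors missing", call. = FALSE)
  f <- cohort$latent_factors
  n <- nrow(f)
  L <- ncol(f)
  ids <- rownames(f)

  metab_block <- function(p, label, prefix) {
    pl <- plant_loadings(p, L, config$loading_sparsity,
                         paste0(prefix, seq_len(p)), label)
    z <- f %*% t(pl$lambda) + matrix(rnorm(n * p, 0, config$noise_sd), n, p)
    mu <- exp(rnorm(p, 2, 0.8))
    vals <- sweep(sweep(z, 2, mu / 8, "*"), 2, mu, "+")
    colnames(vals) <- paste0(prefix, seq_len(p))
    rownames(vals) <- ids
    list(block = omics_block(vals, label), truth = pl$truth)
  }

  withr::with_seed(derive_seed(config$seed, 2L), {
    fecal <- metab_block(config$n_fecal_raw, "fecal", "fm")
    plasma <- metab_block(config$n_plasma_raw, "plasma", "pm")

    p_g <- config$n_genera_raw
    genus_names <- paste0("g", seq_len(p_g))
    n_rare <- config$n_rare_genera
    rare_idx <- if (n_rare > 0) sample(p_g, n_rare) else integer()
    common_idx <- setdiff(seq_len(p_g), rare_idx)
    baseline <- rnorm(p_g, 0, 1)
    # prevalence threshold the rare/common split is engineered around
    min_prev_n <- ceiling(0.10 * n)
    presence <- matrix(TRUE, n, p_g)
    for (g in rare_idx) {
      k <- sample(max(1L, min_prev_n - 1L), 1L)
      pres <- rep(FALSE, n)
      pres[sample(n, k)] <- TRUE
      presence[, g] <- pres
    }
    pl <- plant_loadings(length(common_idx), L, config$loading_sparsity,
                         genus_names[common_idx], "genus")
    lambda <- matrix(0, p_g, L)
    lambda[common_idx, ] <- pl$lambda
  })

  for (attempt in seq_len(100L)) {
    counts <- withr::with_seed(derive_seed(config$seed, 20L + attempt), {
      eta <- matrix(rep(baseline, each = n), n, p_g) + f %*% t(lambda) +
        matrix(rnorm(n * p_g, 0, config$noise_sd), n, p_g)
      eta[, rare_idx] <- -3            # low but nonzero share where present
      eta[!presence] <- -Inf
      cnt <- t(vapply(seq_len(n), function(i) {
        p <- exp(eta[i, ] - max(eta[i, is.finite(eta[i, ])]))
        p[!is.finite(p)] <- 0
        as.numeric(rmultinom(1, config$library_size, p / sum(p)))
      }, numeric(p_g)))
      dimnames(cnt) <- list(ids, genus_names)
      cnt
    })
    prev <- colSums(counts > 0)
    min_prev_n <- ceiling(0.10 * n)
    ok_common <- all(prev[common_idx] >= min_prev_n)
    ok_rare <- length(rare_idx) == 0 || all(prev[rare_idx] < min_prev_n)
    if (ok_common && ok_rare) break
    if (attempt == 100L) {
      stop("could not realize the configured genus prevalence pattern",
           call. = FALSE)
    }
  }

  cohort$blocks <- list(genus = omics_block(counts, "genus"),
                        fecal = fecal$block, plasma = plasma$block)
  cohort$truth <- rbind(pl$truth, fecal$truth, plasma$truth)
  rownames(cohort$truth) <- NULL
  cohort
}

#' Set cells of a block missing according to a per-feature rate profile
#'
#' Each cell is set missing independently with its feature's rate (missing
#' completely at random). When `guard_threshold` is given, features with a
#' rate above 0.25 must come out with an empirical missing fraction above the
#' threshold and features with a rate below 0.15 at or below it; a draw that
#' violates this is discarded and repeated with the seed incremented, so the
#' heavy/light split of the default profile survives sampling noise at small
#' n.
#'
#' @param block An [omics_block()].
#' @param profile Numeric vector of per-feature missingness rates in \[0,1),
#'   recycled if length 1; optionally named by feature.
#' @param seed Integer seed.
#' @param guard_threshold Optional missing-fraction threshold (e.g. 0.20)
#'   enforced as described above; `NULL` disables the check.
#' @return The block with `NA`s injected.
#' @export
inject_missingness <- function(block, profile, seed, guard_threshold = NULL) {
  stopifnot(inherits(block, "omics_block"))
  p <- ncol(block$values)
  if (length(profile) == 1L) profile <- rep(profile, p)
  if (!is.null(names(profile))) profile <- profile[feature_names(block)]
  if (length(profile) != p || anyNA(profile)) {
    stop("configuration error: `profile` must give one rate per feature",
         call. = FALSE)
  }
  if (any(profile < 0 | profile >= 1)) {
    stop("configuration error: missingness rates must lie in [0,1)",
         call. = FALSE)
  }
  n <- nrow(block$values)
  for (attempt in seq_len(100L)) {
    vals <- withr::with_seed(seed + attempt - 1L, {
      v <- block$values
      mask <- matrix(runif(n * p), n, p) < rep(profile, each = n)
      v[mask] <- NA_real_
      v
    })
    if (is.null(guard_threshold)) break
    frac <- colMeans(is.na(vals))
    ok <- all(frac[profile > 0.25] > guard_threshold) &&
      all(frac[profile < 0.15] <= guard_threshold)
    if (ok) break
    if (attempt == 100L) {
      stop("could not realize the configured missingness pattern", call. = FALSE)
    }
  }
  block$values <- vals
  block
}

# Build the default two-rate missingness profiles; heavy features are a
# seeded random subset.
default_missing_profile <- function(config) {
  if (!is.null(config$missing_profile)) return(config$missing_profile)
  withr::with_seed(derive_seed(config$seed, 6L), {
    prof <- list()
    for (b in c("fecal", "plasma")) {
      p <- config[[paste0("n_", b, "_raw")]]
      k <- config[[paste0("n_", b, "_high_missing")]]
      r <- rep(config$low_missing_rate, p)
      if (k > 0) r[sample(p, k)] <- config$high_missing_rate
      prof[[b]] <- r
    }
    prof
  })
}

#' Fill in the outcome table of a synthetic cohort
#'
#' Each outcome is `intercept + sum_l gamma_l f_l + covariate effects +
#' noise`, with effects in raw outcome units taken from the configuration.
#'
#' @param cohort A `synthetic_cohort` with latent factors and covariates.
#' @param config The same [cohort_config()].
#' @return The cohort with a 10-column `outcomes` data frame (plus subject
#'   ids) filled.
#' @export
generate_outcomes <- function(cohort, config) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (is.null(cohort$latent_factors) || is.null(cohort$covariates)) {
    stop("latent factors and covariates must be generated first", call. = FALSE)
  }
  f <- cohort$latent_factors
  cv <- cohort$covariates
  n <- nrow(f)
  withr::with_seed(derive_seed(config$seed, 5L), {
    xc <- cbind(age = cv$age - 50, sex = cv$sex, bmi = cv$bmi - 30)
    mu <- matrix(rep(config$outcome_means, each = n), n,
                 length(.outcome_names)) +
      f %*% config$outcome_effects + xc %*% config$covariate_effects
    noise <- matrix(rnorm(n * length(.outcome_names)), n,
                    length(.outcome_names))
    y <- mu + sweep(noise, 2, config$outcome_noise_sd, "*")
  })
  colnames(y) <- .outcome_names
  out <- data.frame(subject = cv$subject, y, check.names = FALSE,
                    stringsAsFactors = FALSE)
  cohort$outcomes <- out
  cohort
}

#' Simulate a complete tri-omics cohort
#'
#' Runs [generate_latent_cohort()], [generate_blocks()],
#' [generate_outcomes()] and injects metabolite missingness with the
#' configured profile (guarded so the heavy/light groups fall on the intended
#' sides of the 20% exclusion threshold).
#'
#' @param config A [cohort_config()].
#' @param with_missingness Inject metabolite missingness? Set `FALSE` for
#'   complete-data experiments.
#' @return A complete `synthetic_cohort`.
#' @export
simulate_cohort <- function(config = cohort_config(), with_missingness = TRUE) {
  cohort <- generate_latent_cohort(config)
  cohort <- generate_blocks(cohort, config)
  cohort <- generate_outcomes(cohort, config)
  if (with_missingness) {
    prof <- default_missing_profile(config)
    cohort$blocks$fecal <- inject_missingness(
      cohort$blocks$fecal, prof$fecal, derive_seed(config$seed, 3L),
      guard_threshold = 0.20)
    cohort$blocks$plasma <- inject_missingness(
      cohort$blocks$plasma, prof$plasma, derive_seed(config$seed, 4L),
      guard_threshold = 0.20)
  }
  cohort
}

#' Write a synthetic cohort as delimited text files
#'
#' Writes `genus.tsv`, `fecal.tsv`, `plasma.tsv` (samples as rows, header row
#' of feature names, missing cells empty), `subjects.tsv` (covariates joined
#' with outcomes) and `truth.json` (planted loadings) into `dir`. These files
#' are the pipeline's canonical input fixtures.
#'
#' @param cohort A complete `synthetic_cohort`.
#' @param dir Output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (b in cohort$blocks) {
    write_block_tsv(b, file.path(dir, paste0(b$block_label, ".tsv")))
  }
  subjects <- merge(cohort$covariates, cohort$outcomes, by = "subject",
                    sort = FALSE)
  utils::write.table(subjects, file.path(dir, "subjects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}
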