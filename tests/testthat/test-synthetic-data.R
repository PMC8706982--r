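test_that("configuration is validated field by field", {
  expect_error(cohort_config(n_factors = 0), "n_factors")
  expect_error(cohort_config(n_subjects = -3), "n_subjects")
  expect_error(cohort_config(high_missing_rate = 1), "high_missing_rate")
  expect_error(cohort_config(loading_sparsity = 0.9), "loading_sparsity")
  expect_error(
    cohort_config(outcome_effects = matrix(1, 5, 1,
                                           dimnames = list(NULL, "NotAnOutcome"))),
    "outcome_effects")
  expect_error(
    cohort_config(missing_profile = list(fecal = rep(0.5, 3),
                                         plasma = rep(0.5, 378))),
    "missing_profile")
})

test_that("latent skeleton has the right shape and plausible covariates", {
  cfg <- cohort_config(n_subjects = 47, seed = 1)
  co <- generate_latent_cohort(cfg)
  expect_identical(dim(co$latent_factors), c(47L, 5L))
  expect_identical(dim(co$covariates), c(47L, 4L))
  expect_true(all(co$covariates$age >= 30 & co$covariates$age <= 65))
  expect_true(all(co$covariates$bmi >= 25 & co$covariates$bmi <= 35))
  expect_true(all(co$covariates$sex %in% c(0, 1)))
})

test_that("identical config and seed reproduce the cohort byte for byte", {
  cfg <- small_config(seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$blocks$genus$values, b$blocks$genus$values)
  expect_identical(a$blocks$fecal$values, b$blocks$fecal$values)
  expect_identical(a$outcomes, b$outcomes)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(a, d1)
  write_cohort(b, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("genus counts are a valid composition at the library size", {
  co <- simulate_cohort(small_config(seed = 4), with_missingness = FALSE)
  cnt <- co$blocks$genus$values
  expect_true(all(cnt >= 0))
  expect_true(all(cnt == round(cnt)))
  expect_true(all(rowSums(cnt) == small_config()$library_size))
})

test_that("planted features correlate with their factor, unplanted do not", {
  co <- simulate_cohort(small_config(seed = 1), with_missingness = FALSE)
  tr <- co$truth[co$truth$block == "fecal", ]
  vals <- co$blocks$fecal$values
  planted_r <- vapply(seq_len(nrow(tr)), function(i) {
    abs(cor(vals[, tr$feature[i]], co$latent_factors[, tr$factor[i]]))
  }, numeric(1))
  unplanted <- setdiff(colnames(vals), tr$feature)
  unplanted_r <- as.vector(abs(cor(vals[, unplanted], co$latent_factors)))
  expect_gt(min(planted_r), max(unplanted_r))
})

test_that("noise-free planted features are exact affine images of their factor", {
  co <- simulate_cohort(small_config(seed = 2, noise_sd = 0),
                        with_missingness = FALSE)
  for (b in c("fecal", "plasma")) {
    tr <- co$truth[co$truth$block == b, ]
    for (i in seq_len(nrow(tr))) {
      r <- cor(co$blocks[[b]]$values[, tr$feature[i]],
               co$latent_factors[, tr$factor[i]])
      expect_equal(abs(r), 1, tolerance = 1e-12)
    }
  }
})

test_that("missingness injection honors rates, guards and boundaries", {
  co <- simulate_cohort(small_config(seed = 5), with_missingness = FALSE)
  blk <- co$blocks$fecal

  # rate 0 leaves the block untouched
  same <- inject_missingness(blk, 0, seed = 1)
  expect_identical(same$values, blk$values)

  # rate >= 1 is a configuration error; 0.99 is allowed
  expect_error(inject_missingness(blk, 1, seed = 1), "\\[0,1\\)")
  heavy <- inject_missingness(blk, 0.99, seed = 1)
  expect_gt(mean(is.na(heavy$values)), 0.9)

  # the default profile lands exactly the heavy features beyond 20% missing
  cfg <- cohort_config(seed = 7)
  full <- simulate_cohort(cfg)
  expect_identical(sum(colMeans(is.na(full$blocks$fecal$values)) > 0.20), 23L)
  expect_identical(sum(colMeans(is.na(full$blocks$plasma$values)) > 0.20), 5L)
})

test_that("outcomes follow the configured linear model", {
  # all effects zero: outcomes independent of factors up to sampling error
  zero <- matrix(0, 3, 10, dimnames = list(NULL, crosstalknet:::.outcome_names))
  cfg <- small_config(seed = 6, outcome_effects = zero)
  co <- simulate_cohort(cfg, with_missingness = FALSE)
  r <- cor(co$outcomes$Cholesterol, co$latent_factors)
  expect_lt(max(abs(r)), 4 / sqrt(47))

  # gamma = 1, no noise, no covariate effects: outcome equals the factor
  eff <- matrix(0, 3, 10, dimnames = list(NULL, crosstalknet:::.outcome_names))
  eff[1, "Glucose"] <- 1
  cfg0 <- small_config(
    seed = 6, outcome_effects = eff,
    covariate_effects = matrix(0, 3, 10,
                               dimnames = list(c("age", "sex", "bmi"),
                                               crosstalknet:::.outcome_names)),
    outcome_means = stats::setNames(rep(0, 10), crosstalknet:::.outcome_names),
    outcome_noise_sd = stats::setNames(rep(0, 10), crosstalknet:::.outcome_names))
  co0 <- simulate_cohort(cfg0, with_missingness = FALSE)
  expect_equal(co0$outcomes$Glucose, unname(co0$latent_factors[, 1]),
               tolerance = 1e-12)

  # gamma = 0.5 at n = 1000: OLS recovers the effect within 3 SE
  eff2 <- eff
  eff2[1, "Glucose"] <- 0.5
  noise1 <- stats::setNames(rep(1, 10), crosstalknet:::.outcome_names)
  cfg2 <- small_config(seed = 3, n_subjects = 1000, outcome_effects = eff2,
                       outcome_noise_sd = noise1)
  co2 <- simulate_cohort(cfg2, with_missingness = FALSE)
  df <- data.frame(y = co2$outcomes$Glucose, f = co2$latent_factors[, 1],
                   co2$covariates[c("age", "sex", "bmi")])
  fit <- summary(lm(y ~ f + age + sex + bmi, data = df))$coefficients
  expect_lt(abs(fit["f", "Estimate"] - 0.5), 3 * fit["f", "Std. Error"])
})

test_that("cohort round-trips through the delimited text files", {
  co <- simulate_cohort(small_config(seed = 8))
  d <- withr::local_tempdir()
  write_cohort(co, d)
  back <- read_cohort(d)
  expect_equal(back$blocks$fecal$values, co$blocks$fecal$values,
               tolerance = 1e-9)
  expect_equal(back$blocks$genus$values, co$blocks$genus$values)
  expect_identical(names(back$outcomes)[-1], crosstalknet:::.outcome_names)
  expect_identical(nrow(back$truth), nrow(co$truth))
})
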