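scaled_random_blocks <- function(seed, n = 30, p = c(3, 3, 3)) {
  set.seed(seed)
  blocks <- lapply(p, function(pk) {
    m <- matrix(rnorm(n * pk), n, pk)
    rownames(m) <- sprintf("S%02d", seq_len(n))
    colnames(m) <- paste0("x", seq_len(pk))
    m
  })
  names(blocks) <- c("a", "b", "c")[seq_along(p)]
  scale_blocks(blocks)
}

test_that("block scaling standardizes features and normalizes block width", {
  set.seed(1)
  blocks <- list(a = matrix(rnorm(40), 10, 4,
                            dimnames = list(sprintf("S%02d", 1:10), paste0("x", 1:4))))
  xs <- scale_blocks(blocks)$a
  std <- scale(blocks$a)
  expect_true(all(abs(colMeans(xs)) < 1e-10))
  # 4 features: Frobenius norm is that of the standardized matrix over 2
  expect_equal(norm(xs, "F"), norm(std, "F") / 2, tolerance = 1e-9)

  # an already-standardized single feature passes through unchanged
  one <- matrix(scale01(rnorm(20)), 20, 1,
                dimnames = list(sprintf("S%02d", 1:20), "x1"))
  expect_equal(scale_blocks(list(a = one))$a, one, tolerance = 1e-9)
})

test_that("sparsification matches the closed forms", {
  w <- c(0.5, -0.2, 0.1)
  # explicit lambda
  expect_equal(soft_threshold_sparsify(w, list(lambda = 0.15)),
               c(0.98995, -0.14142, 0), tolerance = 1e-5)
  # lambda 0: plain normalization
  expect_equal(soft_threshold_sparsify(w, list(lambda = 0)), w / sqrt(sum(w^2)))
  expect_equal(soft_threshold_sparsify(w), w / sqrt(sum(w^2)))
  # keep-count 1: the single survivor normalizes to +/-1
  expect_equal(soft_threshold_sparsify(w, list(keep = 1)), c(1, 0, 0))
  expect_equal(soft_threshold_sparsify(-w, list(keep = 1)), c(-1, 0, 0))
  # exact tie: earlier feature kept
  expect_equal(soft_threshold_sparsify(c(0.5, -0.5, 0.1), list(keep = 1)),
               c(1, 0, 0))
  # L1 bound reached by bisection: result obeys the bound at unit norm
  s <- soft_threshold_sparsify(c(3, 2, 1, -0.5), list(l1 = 1.5))
  expect_equal(sqrt(sum(s^2)), 1, tolerance = 1e-9)
  expect_lte(sum(abs(s)), 1.5 + 1e-6)
  # overtight bounds error
  expect_error(soft_threshold_sparsify(w, list(l1 = 0.5)), "L1 bound")
  expect_error(soft_threshold_sparsify(numeric(3)), "zero norm")
})

test_that("a two-block single-feature problem is solved exactly", {
  set.seed(2)
  n <- 25
  x1 <- matrix(rnorm(n), n, 1, dimnames = list(sprintf("S%02d", 1:n), "u"))
  x2 <- matrix(0.6 * x1 + rnorm(n, 0, 0.5), n, 1,
               dimnames = list(sprintf("S%02d", 1:n), "v"))
  X <- scale_blocks(list(a = x1, b = x2))
  fit <- fit_component(X, design = matrix(c(0, 1, 1, 0), 2), scheme = "centroid")
  expect_equal(utils::tail(fit$objective_trace, 1),
               abs(cov(X$a[, 1], X$b[, 1])), tolerance = 1e-9)
  expect_equal(abs(unname(fit$weights$a)), 1)
  expect_equal(abs(unname(fit$weights$b)), 1)
  expect_equal(unname(sign(fit$weights$a * fit$weights$b)),
               sign(cov(X$a[, 1], X$b[, 1])))
})

test_that("keep-1 fits reach the exhaustive-support optimum", {
  design <- matrix(1, 3, 3) - diag(3)
  for (seed in c(4, 9, 14)) {
    X <- scaled_random_blocks(seed)
    m <- fit_sgcca(X, n_components = 1, sparsity = list(a = 1, b = 1, c = 1))
    fitted <- utils::tail(m$objective_trace[[1]], 1)
    expect_gte(fitted, (1 - 1e-6) * brute_force_keep1(X))
  }
})

test_that("two-block unconstrained fit matches the cross-covariance SVD", {
  set.seed(6)
  n <- 40
  X <- scaled_random_blocks(6, n = n, p = c(4, 5))
  fit <- fit_component(X, design = matrix(c(0, 1, 1, 0), 2), scheme = "horst",
                       tol = 1e-12)
  sv <- svd(crossprod(X$a, X$b) / (n - 1))
  expect_equal(utils::tail(fit$objective_trace, 1), sv$d[1], tolerance = 1e-6)
  expect_equal(abs(sum(fit$weights$a * sv$u[, 1])), 1, tolerance = 1e-4)
  expect_equal(abs(sum(fit$weights$b * sv$v[, 1])), 1, tolerance = 1e-4)
})

test_that("the objective trace is non-decreasing", {
  for (seed in c(5, 8)) {
    X <- scaled_random_blocks(seed, p = c(4, 4, 4))
    m <- fit_sgcca(X, n_components = 2, sparsity = list(a = 2, b = 2, c = 2))
    for (tr in m$objective_trace) {
      expect_true(all(diff(tr) > -1e-10))
    }
  }
})

test_that("canonical deflation is an orthogonal projection", {
  set.seed(7)
  n <- 20
  x <- matrix(rnorm(n * 5), n, 5)
  t1 <- drop(x %*% rnorm(5))
  d1 <- deflate_blocks(list(x), list(t1))[[1]]
  # component orthogonal to every deflated column
  expect_true(all(abs(crossprod(t1, d1)) < 1e-9))
  # idempotent
  d2 <- deflate_blocks(list(d1), list(t1))[[1]]
  expect_lt(norm(d2 - d1, "F"), 1e-10)
  # t in the column space: rank drops by exactly one
  expect_identical(qr(x)$rank - qr(d1)$rank, 1L)
})

test_that("AVE matches squared correlations", {
  set.seed(8)
  n <- 200
  t <- rnorm(n)
  # single feature proportional to t: AVE 1
  expect_equal(compute_ave(matrix(2 * t, n, 1), t), 1)
  # orthogonal feature: AVE ~ 0
  e <- stats::resid(lm(rnorm(n) ~ t))
  expect_lt(compute_ave(matrix(e, n, 1), t), 1e-20)
  # constructed correlations 0.6 and 0.8: AVE exactly 0.5
  th <- scale01(t)
  eh <- scale01(e)
  x <- cbind(0.6 * th + 0.8 * eh, 0.8 * th + 0.6 * eh)
  expect_equal(compute_ave(x, t), (0.36 + 0.64) / 2, tolerance = 1e-9)
})

test_that("fit_sgcca with one component reduces to fit_component", {
  X <- scaled_random_blocks(10)
  design <- matrix(1, 3, 3) - diag(3)
  single <- fit_component(X, design, sparsity = list(list(keep = 2),
                                                    list(keep = 2),
                                                    list(keep = 2)))
  model <- fit_sgcca(X, n_components = 1, sparsity = list(a = 2, b = 2, c = 2))
  for (k in names(X)) {
    expect_equal(abs(unname(model$weights[[k]][, 1])),
                 abs(unname(single$weights[[k]])), tolerance = 1e-9)
  }
  expect_equal(utils::tail(model$objective_trace[[1]], 1),
               utils::tail(single$objective_trace, 1), tolerance = 1e-12)
})

test_that("permuting features permutes the weights identically", {
  co <- simulate_cohort(small_config(seed = 12), with_missingness = FALSE)
  prep <- preprocess_blocks(co$blocks)
  m1 <- fit_sgcca(prep$blocks, n_components = 1,
                  sparsity = list(genus = 3, fecal = 3, plasma = 3))
  perm <- sample(ncol(prep$blocks$fecal$values))
  blocks2 <- prep$blocks
  blocks2$fecal$values <- blocks2$fecal$values[, perm]
  m2 <- fit_sgcca(blocks2, n_components = 1,
                  sparsity = list(genus = 3, fecal = 3, plasma = 3))
  # the component sign is arbitrary; compare up to a global flip
  got <- unname(m2$weights$fecal[, 1])
  want <- unname(m1$weights$fecal[perm, 1])
  expect_true(isTRUE(all.equal(got, want, tolerance = 1e-8)) ||
                isTRUE(all.equal(got, -want, tolerance = 1e-8)))
})

test_that("selected feature sets are stable across initialization seeds", {
  co <- simulate_cohort(small_config(seed = 13), with_missingness = FALSE)
  prep <- preprocess_blocks(co$blocks)
  sel <- lapply(1:5, function(s) {
    fit_sgcca(prep$blocks, n_components = 3,
              sparsity = list(genus = 4, fecal = 3, plasma = 3),
              seed = s)$selected
  })
  for (s in 2:5) expect_identical(sel[[s]], sel[[1]])
})

test_that("sample mismatch across blocks is a data error naming the ids", {
  X <- scaled_random_blocks(11)
  rownames(X$b)[1] <- "OTHER"
  expect_error(fit_sgcca(X, n_components = 1), "sample mismatch.*OTHER")
})
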