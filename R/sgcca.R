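#' Center, scale and block-normalize omics blocks
#'
#' Each feature is centered to mean 0 and scaled to SD 1, then the whole
#' block is divided by the square root of its feature count so blocks of
#' very different widths contribute comparably to the multi-block objective.
#'
#' @param blocks Named list of [omics_block()]s with no missing cells.
#' @return List of numeric matrices (same names), attribute `block_label`
#'   preserved via names.
#' @export
scale_blocks <- function(blocks) {
  lapply(blocks, function(b) {
    x <- if (inherits(b, "omics_block")) b$values else as.matrix(b)
    if (anyNA(x)) stop("missing cells in block; preprocess first", call. = FALSE)
    s <- apply(x, 2, sd)
    s[s == 0] <- 1  # constant features carry no signal; leave them at zero
    x <- sweep(sweep(x, 2, colMeans(x)), 2, s, "/")
    x / sqrt(ncol(x))
  })
}

#' Sparsify a weight vector to a target and renormalize to unit norm
#'
#' Three bounds are understood. `list(lambda = l)` soft-thresholds at the
#' given level, `S_lambda(x) = sign(x) * max(|x| - lambda, 0)`, then
#' rescales to unit L2 norm. `list(l1 = c)` finds by bisection the smallest
#' lambda whose soft-thresholded, renormalized vector has L1 norm at most
#' `c` — the exact maximizer of a linear form over the intersection of the
#' L1 ball and the L2 sphere. `list(keep = m)` keeps the `m` largest
#' magnitudes (ties broken by feature order, earlier kept), zeroes the
#' rest, and renormalizes without shrinkage — the exact maximizer of a
#' linear form over m-sparse unit vectors, which keeps the block-coordinate
#' objective monotone.
#'
#' @param w Numeric weight vector with positive L2 norm.
#' @param bound `list(lambda = level)`, `list(l1 = value)` or
#'   `list(keep = count)`; `NULL` means no thresholding (plain L2
#'   normalization).
#' @return Unit-norm sparse vector.
#' @export
soft_threshold_sparsify <- function(w, bound = NULL) {
  nrm <- sqrt(sum(w^2))
  if (nrm <= 0) stop("weight vector has zero norm", call. = FALSE)
  if (is.null(bound)) return(w / nrm)
  st <- function(lambda) {
    s <- sign(w) * pmax(abs(w) - lambda, 0)
    n2 <- sqrt(sum(s^2))
    if (n2 > 0) s / n2 else s
  }
  if (!is.null(bound$lambda)) {
    s <- st(bound$lambda)
    if (all(s == 0)) stop("sparsity bound removed every weight", call. = FALSE)
    return(s)
  }
  if (!is.null(bound$keep)) {
    m <- as.integer(bound$keep)
    if (m < 1L) stop("keep-count must be >= 1", call. = FALSE)
    if (m >= length(w)) return(w / nrm)
    ord <- order(-abs(w), seq_along(w))
    s <- w
    s[ord[-seq_len(m)]] <- 0
    n2 <- sqrt(sum(s^2))
    if (n2 == 0) stop("sparsity bound removed every weight", call. = FALSE)
    return(s / n2)
  }
  if (!is.null(bound$l1)) {
    t1 <- bound$l1
    if (t1 < 1) stop("L1 bound below 1 removes every weight", call. = FALSE)
    if (sum(abs(w / nrm)) <= t1) return(w / nrm)
    lo <- 0
    hi <- max(abs(w))
    for (i in seq_len(200L)) {
      mid <- (lo + hi) / 2
      s <- st(mid)
      if (sum(abs(s)) > t1) lo <- mid else hi <- mid
    }
    s <- st(hi)
    if (all(s == 0)) stop("sparsity bound removed every weight", call. = FALSE)
    return(s)
  }
  stop("`bound` must supply `l1` or `keep`", call. = FALSE)
}

# g and g' for the two schemes
scheme_fun <- function(scheme) {
  switch(scheme,
         horst = list(g = identity, dg = function(x) rep(1, length(x))),
         centroid = list(g = abs, dg = sign),
         stop("unknown scheme: ", scheme, call. = FALSE))
}

sgcca_objective <- function(ts, design, scheme) {
  sf <- scheme_fun(scheme)
  K <- length(ts)
  obj <- 0
  for (k in seq_len(K - 1)) {
    for (l in seq.int(k + 1, K)) {
      if (design[k, l] != 0) {
        obj <- obj + design[k, l] * sf$g(cov(ts[[k]], ts[[l]]))
      }
    }
  }
  obj
}

#' Fit one sparse generalized canonical component
#'
#' Block-coordinate ascent on
#' `sum_{k<l} c_kl g(cov(X_k a_k, X_l a_l))` under unit-norm and sparsity
#' constraints: the inner gradient for block k is
#' `sum_l c_kl g'(cov) X_k' X_l a_l`, passed through
#' [soft_threshold_sparsify()], cycled until the objective changes by less
#' than `tol` or `max_iter` is reached (non-convergence is recorded as a
#' warning flag in the result, not thrown).
#'
#' @param X List of scaled (and, for later components, deflated) block
#'   matrices sharing rows.
#' @param design Symmetric block-connection matrix with zero diagonal.
#' @param sparsity List (one element per block) of bounds for
#'   [soft_threshold_sparsify()], or `NULL` entries for none.
#' @param scheme `"centroid"` (`g = |x|`, sign-robust; default) or
#'   `"horst"` (`g = x`).
#' @param tol Convergence tolerance on the objective.
#' @param max_iter Iteration cap.
#' @param n_starts Number of initializations: the leading right singular
#'   vector of each block, plus `n_starts - 1` seeded random starts; the
#'   start reaching the highest objective wins. Multistart matters mostly
#'   for tight keep-counts, where coordinate ascent has local optima.
#' @param seed Seed for the random restarts.
#' @return List with `weights` (list of unit-norm vectors), `components`
#'   (list of score vectors `X_k a_k`), `objective_trace` (of the winning
#'   start), `converged`.
#' @export
fit_component <- function(X, design, sparsity = NULL, scheme = "centroid",
                          tol = 1e-8, max_iter = 1000L, n_starts = 8L,
                          seed = 42L) {
  K <- length(X)
  if (is.null(sparsity)) sparsity <- vector("list", K)
  sf <- scheme_fun(scheme)
  n <- nrow(X[[1]])

  run_from <- function(a, first_block = 1L) {
    a <- Map(soft_threshold_sparsify, a, sparsity)
    ts <- Map(function(x, ak) drop(x %*% ak), X, a)
    trace <- sgcca_objective(ts, design, scheme)
    converged <- FALSE
    cycle <- ((first_block - 1L + seq_len(K) - 1L) %% K) + 1L
    for (iter in seq_len(max_iter)) {
      for (k in cycle) {
        grad <- numeric(ncol(X[[k]]))
        for (l in seq_len(K)) {
          if (l != k && design[k, l] != 0) {
            grad <- grad + design[k, l] * sf$dg(cov(ts[[k]], ts[[l]])) *
              drop(crossprod(X[[k]], ts[[l]])) / (n - 1)
          }
        }
        if (sqrt(sum(grad^2)) > 0) {
          a[[k]] <- soft_threshold_sparsify(grad, sparsity[[k]])
          ts[[k]] <- drop(X[[k]] %*% a[[k]])
        }
      }
      obj <- sgcca_objective(ts, design, scheme)
      trace <- c(trace, obj)
      if (abs(obj - trace[length(trace) - 1]) < tol) {
        converged <- TRUE
        break
      }
    }
    names(a) <- names(X)
    names(ts) <- names(X)
    list(weights = a, components = ts, objective_trace = trace,
         converged = converged)
  }

  svd_init <- lapply(X, function(x) {
    tryCatch(svd(x, nu = 0, nv = 1)$v[, 1], error = function(e) {
      rep(1 / sqrt(ncol(x)), ncol(x))
    })
  })
  starts <- list(list(init = svd_init, first_block = 1L))
  if (n_starts > 1L) {
    for (s in seq_len(n_starts - 1L)) {
      init <- withr::with_seed(derive_seed(seed, s), {
        lapply(X, function(x) rnorm(ncol(x)))
      })
      starts[[length(starts) + 1L]] <- list(init = init, first_block = 1L)
    }
  }
  # on narrow sparse blocks, seed each feature axis in turn (updating the
  # other blocks first so they respond to the seeded support): coordinate
  # ascent under tight keep-counts has support-combinatorial local optima,
  # and axis starts sweep them near-exhaustively at negligible cost
  sparse_blocks <- which(!vapply(sparsity, is.null, logical(1)))
  for (k in sparse_blocks) {
    p <- ncol(X[[k]])
    if (p <= 32L) {
      for (j in seq_len(p)) {
        init <- svd_init
        init[[k]] <- replace(numeric(p), j, 1)
        starts[[length(starts) + 1L]] <-
          list(init = init, first_block = (k %% K) + 1L)
      }
    }
  }
  best <- NULL
  for (st in starts) {
    cand <- run_from(st$init, st$first_block)
    if (is.null(best) || utils::tail(cand$objective_trace, 1) >
          utils::tail(best$objective_trace, 1) + 1e-12) {
      best <- cand
    }
  }
  best
}

#' Deflate blocks by their own components (canonical mode)
#'
#' Projects each block onto the orthogonal complement of its own component:
#' `X_k <- X_k - t_k (t_k' t_k)^-1 t_k' X_k`, so subsequent components of
#' the same block are orthogonal to `t_k`.
#'
#' @param X List of block matrices.
#' @param components List of score vectors, one per block.
#' @return The deflated list.
#' @export
deflate_blocks <- function(X, components) {
  Map(function(x, t) {
    tt <- sum(t^2)
    if (tt < .Machine$double.eps) return(x)
    x - t %*% (crossprod(t, x) / tt)
  }, X, components)
}

#' Average variance explained of a block by a component
#'
#' Mean over the block's features of the squared correlation with the
#' component score; in \[0,1\]. Zero-variance features contribute 0.
#'
#' @param block Numeric matrix (features in columns) or [omics_block()].
#' @param component Score vector.
#' @return A fraction.
#' @export
compute_ave <- function(block, component) {
  x <- if (inherits(block, "omics_block")) block$values else as.matrix(block)
  r2 <- apply(x, 2, function(v) {
    if (sd(v) == 0 || sd(component) == 0) return(0)
    cor(v, component)^2
  })
  mean(r2)
}

#' Sparse generalized canonical correlation analysis over omics blocks
#'
#' Unsupervised multi-block decomposition in canonical mode: components are
#' fitted one at a time by [fit_component()] and each block is deflated by
#' its own component ([deflate_blocks()]) before the next. Per-block
#' sparsity is expressed as keep-counts or L1 bounds. AVE (average variance
#' explained) is reported per block and component against the undeflated
#' scaled blocks.
#'
#' @param blocks Named list of preprocessed [omics_block()]s (or plain
#'   matrices) sharing the same samples in the same order.
#' @param n_components Number of components per block.
#' @param sparsity Either `NULL` (no sparsity), a named list of per-block
#'   keep-counts (single number or one per component), or a named list of
#'   lists of [soft_threshold_sparsify()] bounds per component.
#' @param design Symmetric block-connection matrix; default fully connected
#'   (all off-diagonal 1).
#' @param scheme `"centroid"` (default) or `"horst"`.
#' @param tol,max_iter Convergence controls for each component fit.
#' @param n_starts,seed Multistart controls, see [fit_component()].
#' @return An object of class `sgcca_model`: `weights` (per block, features
#'   x components matrix), `components` (per block, subjects x components),
#'   `ave` (blocks x components), `objective_trace` (list per component),
#'   `converged`, `selected` (per block, features with a nonzero weight on
#'   any component), `scaled_blocks`, and the call parameters.
#' @export
fit_sgcca <- function(blocks, n_components = 2, sparsity = NULL,
                      design = NULL, scheme = "centroid", tol = 1e-8,
                      max_iter = 1000L, n_starts = 8L, seed = 42L) {
  K <- length(blocks)
  if (K < 2) stop("need at least two blocks", call. = FALSE)
  if (is.null(names(blocks))) names(blocks) <- paste0("block", seq_len(K))
  ids <- lapply(blocks, function(b) {
    if (inherits(b, "omics_block")) sample_ids(b) else rownames(b)
  })
  ref <- ids[[1]]
  for (k in seq_len(K)) {
    if (!identical(ids[[k]], ref)) {
      bad <- union(setdiff(ids[[k]], ref), setdiff(ref, ids[[k]]))
      stop("sample mismatch across blocks ('", names(blocks)[k],
           "' vs '", names(blocks)[1], "'): ",
           paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(design)) {
    design <- matrix(1, K, K) - diag(K)
  }
  if (!isSymmetric(unname(design)) || any(diag(design) != 0) ||
      any(design < 0 | design > 1)) {
    stop("design must be symmetric with zero diagonal and entries in [0,1]",
         call. = FALSE)
  }
  H <- as.integer(n_components)
  if (H < 1) stop("n_components must be >= 1", call. = FALSE)
  sparsity_h <- normalize_sparsity(sparsity, names(blocks), H,
                                   vapply(blocks, function(b) {
                                     ncol(if (inherits(b, "omics_block")) b$values else b)
                                   }, integer(1)))

  X0 <- scale_blocks(blocks)
  X <- X0
  weights <- lapply(X0, function(x) {
    matrix(0, ncol(x), H, dimnames = list(colnames(x), paste0("comp", 1:H)))
  })
  comps <- lapply(X0, function(x) {
    matrix(0, nrow(x), H, dimnames = list(rownames(x), paste0("comp", 1:H)))
  })
  ave <- matrix(NA_real_, K, H,
                dimnames = list(names(blocks), paste0("comp", 1:H)))
  traces <- vector("list", H)
  converged <- logical(H)
  for (h in seq_len(H)) {
    fit <- fit_component(X, design, sparsity = sparsity_h[[h]],
                         scheme = scheme, tol = tol, max_iter = max_iter,
                         n_starts = n_starts, seed = derive_seed(seed, 997L + h))
    if (!fit$converged) {
      warning("component ", h, " did not converge in ", max_iter,
              " iterations", call. = FALSE)
    }
    converged[h] <- fit$converged
    traces[[h]] <- fit$objective_trace
    if (scheme == "centroid" && K > 1) {
      # per-block sign indeterminacy of the sign-robust objective: align
      # every block's component with block 1 so cross-block variates add
      # rather than cancel
      for (k in seq.int(2, K)) {
        if (cov(fit$components[[k]], fit$components[[1]]) < 0) {
          fit$weights[[k]] <- -fit$weights[[k]]
          fit$components[[k]] <- -fit$components[[k]]
        }
      }
    }
    for (k in seq_len(K)) {
      weights[[k]][, h] <- fit$weights[[k]]
      comps[[k]][, h] <- fit$components[[k]]
      ave[k, h] <- compute_ave(X0[[k]], fit$components[[k]])
    }
    if (h < H) X <- deflate_blocks(X, fit$components)
  }
  selected <- lapply(weights, function(w) rownames(w)[rowSums(w != 0) > 0])
  structure(
    list(weights = weights, components = comps, ave = ave,
         objective_trace = traces, converged = converged,
         selected = selected, scaled_blocks = X0,
         design = design, scheme = scheme, n_components = H,
         sparsity = sparsity),
    class = "sgcca_model"
  )
}

# Expand user sparsity spec to a list (length H) of per-block bound lists.
normalize_sparsity <- function(sparsity, block_names, H, p) {
  empty <- stats::setNames(vector("list", length(block_names)), block_names)
  if (is.null(sparsity)) return(rep(list(empty), H))
  if (!is.list(sparsity) || is.null(names(sparsity))) {
    stop("`sparsity` must be a named list keyed by block", call. = FALSE)
  }
  unknown <- setdiff(names(sparsity), block_names)
  if (length(unknown)) {
    stop("sparsity names unknown block(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- rep(list(empty), H)
  for (b in names(sparsity)) {
    v <- sparsity[[b]]
    if (is.numeric(v)) {
      v <- rep(v, length.out = H)
      for (h in seq_len(H)) out[[h]][[b]] <- list(keep = v[h])
    } else if (is.list(v)) {
      v <- rep(v, length.out = H)
      for (h in seq_len(H)) out[[h]][[b]] <- v[[h]]
    } else {
      stop("sparsity for block '", b, "' must be numeric keep-counts or a ",
           "list of bounds", call. = FALSE)
    }
  }
  out
}

#' @export
print.sgcca_model <- function(x, ...) {
  cat(sprintf("<sgcca_model> %d blocks, %d component(s), scheme '%s'\n",
              length(x$weights), x$n_components, x$scheme))
  cat("  selected features:",
      paste(sprintf("%s=%d", names(x$selected),
                    lengths(x$selected)), collapse = ", "), "\n")
  cat("  AVE:\n")
  print(round(x$ave, 3))
  invisible(x)
}

#' Serialize an SGCCA model to JSON and per-block weight TSVs
#'
#' @param model An `sgcca_model`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_sgcca_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    scheme = model$scheme, n_components = model$n_components,
    design = model$design, ave = model$ave,
    objective_trace = model$objective_trace,
    converged = model$converged, selected = model$selected,
    weights = lapply(model$weights, function(w) {
      as.data.frame(as.table(w), stringsAsFactors = FALSE)
    })
  )
  jsonlite::write_json(meta, file.path(dir, "sgcca_model.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  for (b in names(model$weights)) {
    w <- model$weights[[b]]
    df <- data.frame(feature = rep(rownames(w), ncol(w)),
                     component = rep(colnames(w), each = nrow(w)),
                     weight = as.vector(w), stringsAsFactors = FALSE)
    df <- df[df$weight != 0, ]
    utils::write.table(df, file.path(dir, paste0("weights_", b, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
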