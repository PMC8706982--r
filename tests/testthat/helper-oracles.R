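# Independent oracles used across tests: every one is a direct, brute-force
# or closed-form computation that never calls the code path it checks.

# exhaustive single-feature-support optimum of the centroid objective for
# three blocks under keep-count 1
brute_force_keep1 <- function(X) {
  best <- -Inf
  for (i in seq_len(ncol(X[[1]]))) {
    for (j in seq_len(ncol(X[[2]]))) {
      for (k in seq_len(ncol(X[[3]]))) {
        obj <- abs(cov(X[[1]][, i], X[[2]][, j])) +
          abs(cov(X[[1]][, i], X[[3]][, k])) +
          abs(cov(X[[2]][, j], X[[3]][, k]))
        best <- max(best, obj)
      }
    }
  }
  best
}

# step-up BH computed literally from the definition
brute_force_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in rev(seq_len(m))) {
    running <- min(running, p[ord[i]] * m / i, 1)
    adj[ord[i]] <- running
  }
  adj
}

# connected components by boolean transitive closure (dense; tiny graphs)
brute_force_components <- function(nodes, edges) {
  n <- length(nodes)
  adj <- diag(TRUE, n)
  dimnames(adj) <- list(nodes, nodes)
  for (i in seq_len(nrow(edges))) {
    adj[edges$source[i], edges$target[i]] <- TRUE
    adj[edges$target[i], edges$source[i]] <- TRUE
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  grp <- integer(n)
  g <- 0L
  for (i in seq_len(n)) {
    if (grp[i] == 0L) {
      g <- g + 1L
      grp[adj[i, ]] <- g
    }
  }
  stats::setNames(grp, nodes)
}

# PageRank as the solution of the dense linear system
# (I - d P') pr = (1 - d)/n
pagerank_dense <- function(edges, nodes, damping = 0.85) {
  n <- length(nodes)
  w <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    s <- abs(edges$similarity[i])
    w[edges$source[i], edges$target[i]] <- w[edges$source[i], edges$target[i]] + s
    w[edges$target[i], edges$source[i]] <- w[edges$target[i], edges$source[i]] + s
  }
  deg <- rowSums(w)
  P <- w
  for (i in seq_len(n)) P[i, ] <- if (deg[i] > 0) w[i, ] / deg[i] else 1 / n
  pr <- solve(diag(n) - damping * t(P), rep((1 - damping) / n, n))
  stats::setNames(pr / sum(pr), nodes)
}

# partial correlation by recursive elimination of covariates from the
# marginal correlation matrix
pcor_recursive <- function(data, x, y, covars) {
  rmat <- cor(data)
  elim <- function(r, z) {
    vars <- setdiff(rownames(r), z)
    out <- matrix(NA_real_, length(vars), length(vars),
                  dimnames = list(vars, vars))
    for (a in vars) {
      for (b in vars) {
        out[a, b] <- (r[a, b] - r[a, z] * r[b, z]) /
          sqrt((1 - r[a, z]^2) * (1 - r[b, z]^2))
      }
    }
    out
  }
  for (z in covars) rmat <- elim(rmat, z)
  rmat[x, y]
}

# random connected weighted graph on n nodes (spanning tree plus extras)
random_connected_graph <- function(n, extra = n) {
  nodes <- sprintf("n%02d", seq_len(n))
  src <- tgt <- character(0)
  for (i in seq.int(2, n)) {
    src <- c(src, nodes[sample(i - 1, 1)])
    tgt <- c(tgt, nodes[i])
  }
  for (e in seq_len(extra)) {
    ij <- sample(n, 2)
    src <- c(src, nodes[ij[1]])
    tgt <- c(tgt, nodes[ij[2]])
  }
  ed <- data.frame(source = src, target = tgt,
                   similarity = runif(length(src), -1, 1),
                   stringsAsFactors = FALSE)
  ed[ed$source != ed$target & !duplicated(paste(pmin(ed$source, ed$target),
                                                pmax(ed$source, ed$target))), ]
}
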