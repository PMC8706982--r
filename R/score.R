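# Consistent node orientation: breadth-first from the lexicographically
# smallest node (sign +1); each tree edge copies the neighbor's sign for a
# positive similarity and flips it for a negative one. Non-tree edges are
# ignored, so a frustrated cycle does not loop forever; isolated members
# stay +1.
propagate_signs <- function(edges, members) {
  members <- sort(members)
  sgn <- stats::setNames(rep(NA_real_, length(members)), members)
  adj <- split(
    rbind(data.frame(node = edges$source, nb = edges$target, s = edges$similarity),
          data.frame(node = edges$target, nb = edges$source, s = edges$similarity)),
    c(edges$source, edges$target))
  while (anyNA(sgn)) {
    root <- names(sgn)[which(is.na(sgn))[1]]
    sgn[root] <- 1
    queue <- root
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      nb <- adj[[cur]]
      if (is.null(nb)) next
      for (i in seq_len(nrow(nb))) {
        v <- nb$nb[i]
        if (is.na(sgn[v])) {
          sgn[v] <- sgn[cur] * (if (nb$s[i] < 0) -1 else 1)
          queue <- c(queue, v)
        }
      }
    }
  }
  sgn
}

#' Weighted PageRank centrality on an undirected cluster subgraph
#'
#' Each undirected edge is treated as two directed edges with transition
#' probability proportional to the absolute edge similarity; the damped
#' random-walk stationary distribution is found by power iteration to an L1
#' change below `tol`. Centralities sum to 1.
#'
#' @param edges Data frame with `source`, `target`, `similarity` columns
#'   describing a connected subgraph (may have zero rows for a singleton).
#' @param nodes Character vector of node names (defaults to those appearing
#'   in `edges`; must be supplied for a singleton cluster).
#' @param damping Damping factor, default 0.85.
#' @param tol Power-iteration tolerance.
#' @param max_iter Iteration cap.
#' @return Named numeric vector of centralities summing to 1.
#' @export
pagerank_centrality <- function(edges, nodes = NULL, damping = 0.85,
                                tol = 1e-12, max_iter = 100000L) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$source, edges$target)))
  n <- length(nodes)
  if (n == 0) stop("empty subgraph", call. = FALSE)
  if (n == 1) return(stats::setNames(1, nodes))
  w <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    s <- abs(edges$similarity[i])
    w[edges$source[i], edges$target[i]] <- w[edges$source[i], edges$target[i]] + s
    w[edges$target[i], edges$source[i]] <- w[edges$target[i], edges$source[i]] + s
  }
  deg <- rowSums(w)
  # dangling nodes distribute uniformly
  P <- w
  for (i in seq_len(n)) {
    P[i, ] <- if (deg[i] > 0) w[i, ] / deg[i] else 1 / n
  }
  pr <- rep(1 / n, n)
  for (iter in seq_len(max_iter)) {
    pr_new <- (1 - damping) / n + damping * drop(crossprod(P, pr))
    if (sum(abs(pr_new - pr)) < tol) {
      pr <- pr_new
      break
    }
    pr <- pr_new
  }
  pr <- pr / sum(pr)
  stats::setNames(pr, nodes)
}

#' Per-subject multi-omics scores for each network cluster
#'
#' Every cluster node gets a weight equal to its PageRank centrality within
#' the cluster subgraph (weights sum to 1 in absolute value) carrying an
#' orientation sign: the sign of the sum of the node's incident edge
#' similarities (ties and isolated nodes get +1), so anti-correlated members
#' do not cancel. A subject's raw score is the signed centrality-weighted
#' sum of the node's post-transformation values (CLR for genus, inverse
#' normal for metabolites); scores are then standardized to mean 0 and SD 1
#' across subjects.
#'
#' @param network A clustered `similarity_network` from
#'   [extract_clusters()].
#' @param blocks Named list of processed [omics_block()]s holding every
#'   cluster node.
#' @param damping PageRank damping factor.
#' @param orientation `"propagate"` (default) spreads signs over a
#'   breadth-first tree from the cluster's lexicographically first node
#'   (positive-similarity edges keep the neighbor's sign, negative edges
#'   flip it), giving one consistent orientation per cluster;
#'   `"incident"` uses each node's local sign of the sum of its incident
#'   similarities; `"none"` gives the unsigned centrality-weighted sum.
#' @return An object of class `cluster_score_set`: `weights` (data frame
#'   cluster/feature/block/centrality/sign), `scores` (subject x cluster
#'   matrix of standardized scores), `raw_scores`.
#' @export
compute_cluster_scores <- function(network, blocks, damping = 0.85,
                                   orientation = c("propagate", "incident",
                                                   "none")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(network, "similarity_network"))
  if (is.null(network$clusters)) {
    stop("run extract_clusters() first", call. = FALSE)
  }
  cl <- network$clusters
  ids <- sample_ids(blocks[[1]])
  value_of <- function(feature, block) {
    blk <- blocks[[block]]
    if (is.null(blk) || !feature %in% feature_names(blk)) {
      stop("cluster node '", feature, "' not found in processed '", block,
           "' block", call. = FALSE)
    }
    blk$values[ids, feature]
  }
  ks <- sort(unique(cl$cluster))
  weights <- NULL
  raw <- matrix(NA_real_, length(ids), length(ks),
                dimnames = list(ids, paste0("cluster", ks)))
  for (k in ks) {
    members <- cl$feature[cl$cluster == k]
    sub <- network$edges[network$edges$source %in% members &
                           network$edges$target %in% members, ]
    pr <- pagerank_centrality(sub, nodes = sort(members), damping = damping)
    sgn <- switch(orientation,
                  none = stats::setNames(rep(1, length(members)), members),
                  incident = vapply(members, function(f) {
                    s <- sum(sub$similarity[sub$source == f]) +
                      sum(sub$similarity[sub$target == f])
                    if (s < 0) -1 else 1
                  }, numeric(1)),
                  propagate = propagate_signs(sub, members))
    sgn <- sgn[members]
    blockof <- cl$block[cl$cluster == k][match(members, cl$feature[cl$cluster == k])]
    weights <- rbind(weights, data.frame(
      cluster = k, feature = members, block = blockof,
      centrality = unname(pr[members]), sign = unname(sgn),
      stringsAsFactors = FALSE))
    vals <- vapply(seq_along(members),
                   function(i) value_of(members[i], blockof[i]),
                   numeric(length(ids)))
    raw[, paste0("cluster", k)] <- drop(vals %*% (pr[members] * sgn))
  }
  std <- apply(raw, 2, function(v) {
    s <- sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  })
  rownames(std) <- ids
  structure(list(weights = weights, scores = std, raw_scores = raw),
            class = "cluster_score_set")
}

#' @export
print.cluster_score_set <- function(x, ...) {
  cat(sprintf("<cluster_score_set> %d cluster(s), %d subjects\n",
              ncol(x$scores), nrow(x$scores)))
  invisible(x)
}

#' Write cluster score artifacts (scores.tsv, weights.tsv)
#'
#' @param score_set A `cluster_score_set`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_scores <- function(score_set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scores <- data.frame(subject = rownames(score_set$scores),
                       score_set$scores, check.names = FALSE,
                       stringsAsFactors = FALSE)
  utils::write.table(scores, file.path(dir, "scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(score_set$weights, file.path(dir, "weights.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
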