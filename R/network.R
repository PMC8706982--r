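#' Cross-block similarity matrix from an SGCCA model
#'
#' For a pair of blocks (A, B) and each component h, the shared variate
#' `v_h = t_A + t_B` (normalized to unit SD) gives every feature a
#' coordinate `cor(feature, v_h)`; the similarity between feature i of A
#' and feature j of B is the inner product of their coordinate vectors over
#' components, clipped to \[-1, 1\]. Only features with a nonzero weight on
#' at least one component enter.
#'
#' @param model An `sgcca_model` from [fit_sgcca()].
#' @param block_pair Character vector of two block names.
#' @return Numeric matrix, selected features of the first block in rows,
#'   of the second in columns.
#' @export
compute_similarity_matrix <- function(model, block_pair) {
  stopifnot(inherits(model, "sgcca_model"), length(block_pair) == 2)
  a <- block_pair[1]
  b <- block_pair[2]
  if (!all(block_pair %in% names(model$weights))) {
    stop("unknown block(s): ", paste(block_pair, collapse = ", "),
         call. = FALSE)
  }
  H <- model$n_components
  coords <- function(blk) {
    sel <- model$selected[[blk]]
    x <- model$scaled_blocks[[blk]][, sel, drop = FALSE]
    m <- matrix(0, length(sel), H, dimnames = list(sel, NULL))
    for (h in seq_len(H)) {
      v <- model$components[[a]][, h] + model$components[[b]][, h]
      if (sd(v) == 0) stop("zero-variance shared variate for component ", h,
                           call. = FALSE)
      v <- v / sd(v)
      m[, h] <- apply(x, 2, function(col) {
        if (sd(col) == 0) 0 else cor(col, v)
      })
    }
    m
  }
  s <- coords(a) %*% t(coords(b))
  pmin(pmax(s, -1), 1)
}

#' Build the thresholded cross-block similarity network
#'
#' Keeps edges with `|similarity| >= cutoff`; only between-block edges
#' exist by construction, and features left without any surviving edge are
#' omitted from the node set.
#'
#' @param similarities Named list of matrices from
#'   [compute_similarity_matrix()], names of the form `"blockA|blockB"`.
#' @param cutoff Absolute-similarity threshold, default 0.6.
#' @return An object of class `similarity_network` with `nodes` (data frame
#'   feature/block), `edges` (source, source_block, target, target_block,
#'   similarity), `cutoff`, and `clusters` (`NULL` until
#'   [extract_clusters()]).
#' @export
build_network <- function(similarities, cutoff = 0.6) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 0) {
    stop("`cutoff` must be a single nonnegative number", call. = FALSE)
  }
  edges <- NULL
  for (nm in names(similarities)) {
    pair <- strsplit(nm, "|", fixed = TRUE)[[1]]
    if (length(pair) != 2) {
      stop("similarity names must be 'blockA|blockB'; got: ", nm,
           call. = FALSE)
    }
    s <- similarities[[nm]]
    hit <- which(abs(s) >= cutoff, arr.ind = TRUE)
    if (nrow(hit)) {
      edges <- rbind(edges, data.frame(
        source = rownames(s)[hit[, 1]], source_block = pair[1],
        target = colnames(s)[hit[, 2]], target_block = pair[2],
        similarity = s[hit], stringsAsFactors = FALSE))
    }
  }
  if (is.null(edges)) {
    edges <- data.frame(source = character(), source_block = character(),
                        target = character(), target_block = character(),
                        similarity = numeric(), stringsAsFactors = FALSE)
  }
  edges <- edges[order(edges$source, edges$target), ]
  rownames(edges) <- NULL
  nodes <- unique(rbind(
    data.frame(feature = edges$source, block = edges$source_block,
               stringsAsFactors = FALSE),
    data.frame(feature = edges$target, block = edges$target_block,
               stringsAsFactors = FALSE)))
  nodes <- nodes[order(nodes$feature), ]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, cutoff = cutoff,
                 clusters = NULL),
            class = "similarity_network")
}

#' @export
print.similarity_network <- function(x, ...) {
  cat(sprintf("<similarity_network> %d nodes, %d edges (|s| >= %.2f)\n",
              nrow(x$nodes), nrow(x$edges), x$cutoff))
  if (!is.null(x$clusters)) {
    k <- length(unique(x$clusters$cluster))
    cat("  clusters:", k, "\n")
  }
  invisible(x)
}

network_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges[c("source", "target", "similarity")],
    directed = FALSE,
    vertices = network$nodes[c("feature", "block")])
}

#' Extract connected-component clusters from a similarity network
#'
#' Clusters are the connected components of the thresholded graph, labeled
#' 1..K in decreasing size order with ties broken by the lexicographically
#' smallest member name.
#'
#' @param network A `similarity_network`.
#' @return The network with `clusters` filled: a data frame
#'   feature/block/cluster, plus a `composition` attribute counting
#'   genus/fecal/plasma nodes per cluster.
#' @export
extract_clusters <- function(network) {
  stopifnot(inherits(network, "similarity_network"))
  if (nrow(network$nodes) == 0) {
    network$clusters <- data.frame(feature = character(), block = character(),
                                   cluster = integer(),
                                   stringsAsFactors = FALSE)
    attr(network$clusters, "composition") <-
      data.frame(cluster = integer(), n_nodes = integer())
    return(network)
  }
  g <- network_igraph(network)
  comp <- igraph::components(g)
  member <- comp$membership
  sizes <- comp$csize
  first_name <- vapply(seq_along(sizes), function(k) {
    min(names(member)[member == k])
  }, character(1))
  ord <- order(-sizes, first_name)
  relabel <- integer(length(sizes))
  relabel[ord] <- seq_along(sizes)
  cl <- data.frame(feature = names(member),
                   cluster = relabel[member],
                   stringsAsFactors = FALSE)
  cl <- merge(network$nodes, cl, by = "feature", sort = TRUE)
  cl <- cl[order(cl$cluster, cl$feature), ]
  rownames(cl) <- NULL
  comp_tab <- as.data.frame.matrix(table(cl$cluster, cl$block))
  comp_tab <- data.frame(cluster = as.integer(rownames(comp_tab)),
                         comp_tab, check.names = FALSE)
  comp_tab$n_nodes <- rowSums(comp_tab[-1])
  attr(cl, "composition") <- comp_tab
  network$clusters <- cl
  network
}

#' Write network artifacts (edge list TSV, GraphML, cluster membership TSV)
#'
#' @param network A clustered `similarity_network`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_network <- function(network, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(network$edges, file.path(dir, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (nrow(network$nodes) > 0) {
    igraph::write_graph(network_igraph(network),
                        file.path(dir, "network.graphml"), format = "graphml")
  }
  if (!is.null(network$clusters)) {
    utils::write.table(network$clusters, file.path(dir, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
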