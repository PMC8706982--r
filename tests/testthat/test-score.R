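edge_df <- function(source, target, similarity) {
  data.frame(source = source, target = target, similarity = similarity,
             stringsAsFactors = FALSE)
}

test_that("pagerank matches closed forms on small graphs", {
  # two nodes, one edge: symmetric
  two <- pagerank_centrality(edge_df("a", "b", 0.9))
  expect_equal(unname(two), c(0.5, 0.5), tolerance = 1e-12)
  two2 <- pagerank_centrality(edge_df("a", "b", 0.9), damping = 0.3)
  expect_equal(unname(two2), c(0.5, 0.5), tolerance = 1e-12)

  # path a-b-c at damping 0.85
  path <- pagerank_centrality(edge_df(c("a", "b"), c("b", "c"), c(1, 1)))
  expect_equal(unname(path), c(0.2568, 0.4865, 0.2568), tolerance = 1e-4)

  # singleton
  expect_identical(pagerank_centrality(edge_df(character(), character(),
                                               numeric()), nodes = "only"),
                   c(only = 1))
  expect_error(pagerank_centrality(edge_df(character(), character(),
                                           numeric())), "empty")
})

test_that("power iteration agrees with the dense linear-system oracle", {
  set.seed(5)
  for (n in c(5, 17, 50)) {
    ed <- random_connected_graph(n)
    nodes <- sort(unique(c(ed$source, ed$target)))
    mine <- pagerank_centrality(ed, nodes = nodes)
    oracle <- pagerank_dense(ed, nodes)
    expect_equal(mine, oracle[names(mine)], tolerance = 1e-9)
    expect_equal(sum(mine), 1, tolerance = 1e-12)
  }
})

test_that("power iteration agrees with the graph-library implementation", {
  set.seed(6)
  ed <- random_connected_graph(20)
  nodes <- sort(unique(c(ed$source, ed$target)))
  mine <- pagerank_centrality(ed, nodes = nodes)
  g <- igraph::graph_from_data_frame(ed, directed = FALSE, vertices = nodes)
  ref <- igraph::page_rank(g, damping = 0.85,
                           weights = abs(igraph::E(g)$similarity))$vector
  expect_equal(mine, ref[names(mine)], tolerance = 1e-6)
})

fake_network <- function(edges, nodes) {
  structure(list(nodes = nodes, edges = edges, cutoff = 0.6,
                 clusters = NULL),
            class = "similarity_network")
}

two_cluster_setup <- function(n = 40, seed = 7) {
  set.seed(seed)
  ids <- sprintf("S%02d", seq_len(n))
  vals_f <- matrix(rnorm(n * 2), n, 2, dimnames = list(ids, c("f1", "f2")))
  vals_p <- matrix(rnorm(n * 2), n, 2, dimnames = list(ids, c("p1", "p2")))
  blocks <- list(
    fecal = omics_block(vals_f, "fecal"),
    plasma = omics_block(vals_p, "plasma"))
  edges <- edge_df(c("f1", "f2"), c("p1", "p2"), c(0.8, -0.7))
  edges$source_block <- "fecal"
  edges$target_block <- "plasma"
  nodes <- data.frame(feature = c("f1", "f2", "p1", "p2"),
                      block = c("fecal", "fecal", "plasma", "plasma"),
                      stringsAsFactors = FALSE)
  net <- extract_clusters(fake_network(edges, nodes))
  list(net = net, blocks = blocks)
}

test_that("cluster scores are standardized signed weighted sums", {
  st <- two_cluster_setup()
  ss <- compute_cluster_scores(st$net, st$blocks)
  # standardization invariants
  expect_true(all(abs(colMeans(ss$scores)) < 1e-9))
  expect_true(all(abs(apply(ss$scores, 2, sd) - 1) < 1e-9))
  # centralities within each cluster sum to 1
  tot <- tapply(ss$weights$centrality, ss$weights$cluster, sum)
  expect_true(all(abs(tot - 1) < 1e-9))
  # two-node cluster: equal centralities, negative edge flips one sign,
  # so the raw score is proportional to the difference of the members
  w2 <- ss$weights[ss$weights$cluster == 2, ]
  expect_equal(w2$centrality, c(0.5, 0.5), tolerance = 1e-9)
  expect_identical(sort(w2$sign * c(1, 1)), c(-1, 1))
  f2 <- st$blocks$fecal$values[, "f2"]
  p2 <- st$blocks$plasma$values[, "p2"]
  expected <- scale01(0.5 * f2 - 0.5 * p2)
  got <- ss$scores[, "cluster2"]
  expect_equal(abs(cor(got, expected)), 1, tolerance = 1e-9)
})

test_that("a one-node cluster reproduces the standardized feature", {
  n <- 30
  ids <- sprintf("S%02d", seq_len(n))
  set.seed(8)
  vals <- matrix(rnorm(n), n, 1, dimnames = list(ids, "solo"))
  blocks <- list(fecal = omics_block(vals, "fecal"))
  nodes <- data.frame(feature = "solo", block = "fecal",
                      stringsAsFactors = FALSE)
  net <- extract_clusters(fake_network(
    edge_df(character(), character(), numeric())[, ],
    nodes))
  # components on an edgeless graph: the single node is its own cluster
  ss <- compute_cluster_scores(net, blocks)
  expect_equal(unname(ss$scores[, 1]), unname(scale01(vals[, 1])),
               tolerance = 1e-9)
})

test_that("orientation modes behave as documented", {
  st <- two_cluster_setup()
  signed <- compute_cluster_scores(st$net, st$blocks, orientation = "propagate")
  unsigned <- compute_cluster_scores(st$net, st$blocks, orientation = "none")
  expect_true(all(unsigned$weights$sign == 1))
  # cluster 1 (positive edge): identical either way
  expect_equal(signed$scores[, "cluster1"], unsigned$scores[, "cluster1"],
               tolerance = 1e-9)
  # the local incident rule gives BOTH endpoints of a lone negative edge a
  # negative sign (their contributions cancel rather than contrast; this is
  # why sign propagation is the default)
  incident <- compute_cluster_scores(st$net, st$blocks, orientation = "incident")
  wi <- incident$weights[incident$weights$cluster == 2, ]
  expect_identical(wi$sign, c(-1, -1))
  # propagation contrasts them instead
  wp <- signed$weights[signed$weights$cluster == 2, ]
  expect_identical(sort(wp$sign), c(-1, 1))
})

test_that("flipping all similarities incident to a non-root node flips only it", {
  # path a - m - z; the propagation root is the lexicographically smallest
  # member ("a"), so m is a non-root node
  n <- 25
  ids <- sprintf("S%02d", seq_len(n))
  set.seed(9)
  vals <- matrix(rnorm(n * 3), n, 3, dimnames = list(ids, c("a", "m", "z")))
  blocks <- list(fecal = omics_block(vals[, c(1, 3)], "fecal"),
                 plasma = omics_block(vals[, 2, drop = FALSE], "plasma"))
  nodes <- data.frame(feature = c("a", "m", "z"),
                      block = c("fecal", "plasma", "fecal"),
                      stringsAsFactors = FALSE)
  e1 <- edge_df(c("a", "m"), c("m", "z"), c(0.9, 0.8))
  e2 <- edge_df(c("a", "m"), c("m", "z"), c(-0.9, -0.8))  # flip node m
  s1 <- compute_cluster_scores(extract_clusters(fake_network(e1, nodes)), blocks)
  s2 <- compute_cluster_scores(extract_clusters(fake_network(e2, nodes)), blocks)
  w1 <- s1$weights[order(s1$weights$feature), ]
  w2 <- s2$weights[order(s2$weights$feature), ]
  expect_equal(w1$centrality, w2$centrality, tolerance = 1e-12)
  flip <- w1$sign * w2$sign
  expect_identical(flip[w1$feature == "m"], -1)
  expect_true(all(flip[w1$feature != "m"] == 1))
})

test_that("scores recover the planted factors", {
  res <- run_recovery_pipeline(small_config(seed = 21, n_subjects = 150))
  cl <- cluster_truth_table(res$network, res$cohort$truth)
  ss <- compute_cluster_scores(res$network, res$prep$blocks)
  for (k in sort(unique(cl$cluster))) {
    fk <- as.integer(names(which.max(table(cl$factor[cl$cluster == k]))))
    r <- cor(ss$scores[, paste0("cluster", k)],
             res$cohort$latent_factors[, fk])
    expect_gt(abs(r), 0.8)
  }
})
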