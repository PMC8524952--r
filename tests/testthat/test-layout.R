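test_that("LSH queries never return the query item and rank by similarity", {
  fp <- small_fingerprints()
  forest <- build_lsh_forest(fp, n_trees = 16)
  for (i in c(1, 10, 40)) {
    res <- lsh_query(forest, i, k = 5)
    expect_false(i %in% res$index)
    expect_true(all(diff(res$similarity) <= 0))
    expect_lte(nrow(res), 5)
  }
})

test_that("duplicate fingerprints are each other's top neighbor", {
  fp <- small_fingerprints()[1:20, ]
  fp <- rbind(fp, fp[3, ])  # item 21 duplicates item 3
  forest <- build_lsh_forest(fp, n_trees = 8)
  expect_equal(lsh_query(forest, 21, k = 1)$index, 3)
  expect_equal(lsh_query(forest, 21, k = 1)$similarity, 1)
  expect_equal(lsh_query(forest, 3, k = 1)$index, 21)
})

test_that("LSH recall vs the exact top-10 oracle is high and grows with trees", {
  fp <- small_fingerprints()  # 75 synthetic molecules
  n <- nrow(fp)
  K <- compute_kernel_matrix(fp, spec = kernel_spec("map4_match"))
  diag(K) <- -1
  exact_top <- lapply(seq_len(n), function(i)
    order(-K[i, ], seq_len(n))[1:10])
  recall_at <- function(n_trees) {
    forest <- build_lsh_forest(fp, n_trees = n_trees)
    mean(vapply(seq_len(n), function(i) {
      got <- lsh_query(forest, i, k = 10)$index
      # exact top-10 under ties: count retrieved items whose similarity
      # reaches the 10th-best exact value
      thr <- K[i, exact_top[[i]][10]]
      sum(K[i, got] >= thr) / 10
    }, numeric(1)))
  }
  r <- vapply(c(8, 16, 32), recall_at, numeric(1))
  expect_gte(r[3], 0.7)
  expect_true(all(diff(r) >= 0))  # candidate pools nest, so recall can't drop
})

test_that("knn graph is undirected, bounded and complete when k >= n-1", {
  fp <- small_fingerprints()[1:15, ]
  forest <- build_lsh_forest(fp, n_trees = 32)
  g <- knn_graph(forest, k = 20)  # k >= n-1
  expect_equal(igraph::vcount(g), 15)
  expect_equal(igraph::ecount(g), choose(15, 2))
  w <- igraph::E(g)$weight
  expect_true(all(w >= 0 & w <= 1))
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  expect_equal(A, t(A))
})

test_that("MST matches the unique solution on a worked triangle", {
  g <- igraph::make_graph(c(1, 2, 2, 3, 1, 3), directed = FALSE)
  igraph::E(g)$weight <- c(1, 2, 3)
  mst <- minimum_spanning_tree(g)
  expect_equal(nrow(mst), 2)
  expect_equal(sum(mst$weight), 3)
  expect_equal(mst[, c("i", "j")], data.frame(i = c(1, 2), j = c(2, 3)),
               ignore_attr = TRUE)
  expect_error(minimum_spanning_tree(igraph::make_empty_graph(0)), "degenerate")
})

test_that("MST has n - components edges and matches a Kruskal oracle", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 50
    # random connected-ish graph: random tree plus extra random edges
    edges <- cbind(2:n, vapply(2:n, function(v) sample.int(v - 1, 1), integer(1)))
    extra <- cbind(sample.int(n, 60, TRUE), sample.int(n, 60, TRUE))
    extra <- extra[extra[, 1] != extra[, 2], , drop = FALSE]
    allE <- rbind(edges, extra)
    g <- igraph::graph_from_edgelist(allE, directed = FALSE)
    g <- igraph::simplify(g)
    igraph::E(g)$weight <- round(stats::runif(igraph::ecount(g)), 3)
    mst <- minimum_spanning_tree(g)
    comp <- igraph::count_components(g)
    expect_equal(nrow(mst), n - comp)
    el <- igraph::as_edgelist(g, names = FALSE)
    oracle <- kruskal_mst_weight(data.frame(i = el[, 1], j = el[, 2],
                                            weight = igraph::E(g)$weight))
    expect_equal(sum(mst$weight), oracle, tolerance = 1e-12)
    # acyclic: edge count equals node count minus components of the tree
    tg <- igraph::graph_from_edgelist(as.matrix(mst[, c("i", "j")]),
                                      directed = FALSE)
    expect_equal(igraph::ecount(tg),
                 igraph::vcount(tg) - igraph::count_components(tg))
  }
})

test_that("tree layout gives distinct finite coordinates", {
  # path graph of 3 nodes
  xy <- layout_tree(data.frame(i = c(1, 2), j = c(2, 3)), 3, seed = 1)
  expect_true(all(is.finite(xy)))
  expect_equal(nrow(unique(as.data.frame(xy))), 3)
  # star K_{1,4}: no two leaves coincide
  star <- data.frame(i = rep(1, 4), j = 2:5)
  xy2 <- layout_tree(star, 5, seed = 1)
  expect_equal(nrow(unique(as.data.frame(round(xy2, 9)))), 5)
  # cyclic input is rejected
  expect_error(layout_tree(data.frame(i = c(1, 2, 3), j = c(2, 3, 1)), 3),
               "cycle")
})

test_that("disconnected forests are laid out with non-overlapping components", {
  edges <- data.frame(i = c(1, 2, 4, 5), j = c(2, 3, 5, 6))  # two paths
  xy <- layout_tree(edges, 7, seed = 2)  # node 7 isolated
  expect_true(all(is.finite(xy)))
  ranges <- lapply(list(1:3, 4:6, 7), function(nodes)
    range(xy[nodes, 1]))
  # bounding boxes ordered along x without overlap
  expect_lt(ranges[[1]][2], ranges[[2]][1])
  expect_lt(ranges[[2]][2], ranges[[3]][1])
})

test_that("full layout satisfies the structural contract on synthetic data", {
  ds <- small_dataset()
  fp <- small_fingerprints()
  pr <- small_profile()
  lay <- chemspace_layout(fp, pr, ds$origin, k = 10, n_trees = 16, seed = 1)
  n <- nrow(fp)
  comp <- igraph::count_components(igraph::graph_from_edgelist(
    as.matrix(lay$mst_edges[, c("i", "j")]), directed = FALSE))
  expect_equal(nrow(lay$mst_edges), n - comp)
  # MST edges are a subset of the kNN graph edges
  key <- function(df) paste(df$i, df$j)
  expect_true(all(key(lay$mst_edges) %in% key(lay$knn_edges)))
  # no coincident coordinates
  expect_equal(nrow(unique(as.data.frame(round(lay$coordinates, 9)))), n)
  # tree edges are shorter on average than random node pairs
  d_edge <- sqrt(rowSums((lay$coordinates[lay$mst_edges$i, ] -
                          lay$coordinates[lay$mst_edges$j, ])^2))
  set.seed(8)
  ri <- sample.int(n, 500, TRUE); rj <- sample.int(n, 500, TRUE)
  ok <- ri != rj
  d_rand <- sqrt(rowSums((lay$coordinates[ri[ok], ] -
                          lay$coordinates[rj[ok], ])^2))
  expect_lt(mean(d_edge), mean(d_rand))
  # channels carry the three origins and the curation categories
  expect_setequal(unique(lay$channels$origin), c("plant", "fungi", "bacteria"))
  expect_true(all(lay$channels$category %in%
                  c("glycoside", "peptide", "high_MW", "high_Fsp3",
                    "low_Fsp3", "low_MW", "none")))
})

test_that("layout export and import round-trip", {
  ds <- small_dataset()[1:20, ]
  fp <- small_fingerprints()[1:20, ]
  pr <- small_profile()[1:20, ]
  lay <- chemspace_layout(fp, pr, ds$origin, k = 5, n_trees = 8, seed = 1)
  dir <- file.path(tempdir(), "layout_roundtrip")
  export_layout(lay, dir, images = FALSE)
  back <- import_layout(dir)
  expect_equal(back$coordinates, lay$coordinates, tolerance = 1e-12)
  expect_equal(back$mst_edges, lay$mst_edges, ignore_attr = TRUE)
  expect_equal(back$channels$origin, lay$channels$origin)
  # missing channel values are refused
  lay$channels$mw[3] <- NA
  expect_error(export_layout(lay, dir, images = FALSE), "missing channel")
})
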