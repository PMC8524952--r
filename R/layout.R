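# Chemical-space map: LSH forest over MinHash fingerprints, approximate
# k-nearest-neighbor graph, minimum spanning tree and a 2D tree layout.

#' Build an LSH forest over MinHash fingerprints
#'
#' Each of the `n_trees` prefix trees indexes a fixed 32-position block of
#' the MinHash vector; approximate neighbors are the items sharing the
#' longest hash prefixes with the query across trees.
#'
#' @param fingerprints Integer MinHash matrix, one row per molecule.
#' @param n_trees Number of trees (default 32).
#' @param depth Hash positions per tree (default 32).
#' @return An object of class `lsh_forest`.
#' @export
build_lsh_forest <- function(fingerprints, n_trees = 32L, depth = 32L) {
  stopifnot(is.matrix(fingerprints), nrow(fingerprints) >= 2, n_trees >= 1)
  d <- ncol(fingerprints)
  positions <- lapply(seq_len(n_trees), function(t)
    ((seq_len(depth) - 1L + (t - 1L) * depth) %% d) + 1L)
  keys <- lapply(positions, function(p) fingerprints[, p, drop = FALSE])
  structure(list(
    n_items = nrow(fingerprints),
    n_trees = as.integer(n_trees),
    depth = as.integer(depth),
    positions = positions,
    keys = keys,
    fingerprints = fingerprints
  ), class = "lsh_forest")
}

# candidate pool for query rows: per tree, every item sharing the longest
# available prefix is taken, widening the prefix until the tree has yielded
# at least `per_tree` candidates (or no shared prefix remains); pools from
# all trees are unioned. The per-tree rule is independent of the other
# trees, so pools grow monotonically with n_trees.
lsh_candidates <- function(forest, query_fp, per_tree, exclude = NULL) {
  nq <- nrow(query_fp)
  pools <- vector("list", nq)
  for (t in seq_len(forest$n_trees)) {
    qk <- query_fp[, forest$positions[[t]], drop = FALSE]
    depths <- prefix_depths_cpp(forest$keys[[t]], qk)
    for (q in seq_len(nq)) {
      dq <- depths[q, ]
      if (!is.null(exclude)) dq[exclude[q]] <- -1L
      pos <- which(dq > 0)
      if (!length(pos)) next
      lv <- sort(unique(dq[pos]), decreasing = TRUE)
      picked <- integer(0)
      for (m in lv) {
        picked <- c(picked, pos[dq[pos] == m])
        if (length(picked) >= per_tree) break
      }
      pools[[q]] <- c(pools[[q]], picked)
    }
  }
  lapply(pools, unique)
}

#' Query approximate nearest neighbors from an LSH forest
#'
#' Pools prefix-matched candidates from every tree and ranks them by exact
#' MinHash match fraction. When `query` is an index into the forest, the
#' item itself is never returned.
#'
#' @param forest An [build_lsh_forest()] object.
#' @param query Either an item index or a fingerprint vector/matrix row.
#' @param k Number of neighbors.
#' @return Data frame with columns `index` and `similarity`, at most
#'   `min(k, n_items - 1)` rows, ordered by decreasing similarity.
#' @export
lsh_query <- function(forest, query, k = 10L) {
  if (length(query) == 1 && is.numeric(query) && query == as.integer(query) &&
      query >= 1 && query <= forest$n_items) {
    idx <- as.integer(query)
    qfp <- forest$fingerprints[idx, , drop = FALSE]
    exclude <- idx
  } else {
    qfp <- matrix(as.integer(query), nrow = 1)
    exclude <- NULL
  }
  pool <- lsh_candidates(forest, qfp, per_tree = min(k, forest$n_items - 1L),
                         exclude = exclude)[[1]]
  if (!length(pool))
    return(data.frame(index = integer(0), similarity = numeric(0)))
  sims <- as.numeric(match_fraction_cpp(
    qfp, forest$fingerprints[pool, , drop = FALSE]))
  ord <- order(-sims, pool)
  take <- utils::head(ord, min(k, forest$n_items - 1L))
  data.frame(index = pool[take], similarity = sims[take])
}

#' Approximate k-nearest-neighbor graph
#'
#' Undirected graph with an edge whenever either endpoint lists the other
#' among its k approximate nearest neighbors; edge weight is
#' `1 - map4_similarity`.
#'
#' @param forest An [build_lsh_forest()] object.
#' @param k Neighbors per query (default 20).
#' @return An igraph graph with `n_items` vertices and a `weight` edge
#'   attribute.
#' @export
knn_graph <- function(forest, k = 20L) {
  stopifnot(k >= 1)
  n <- forest$n_items
  pools <- lsh_candidates(forest, forest$fingerprints,
                          per_tree = min(k, n - 1L),
                          exclude = seq_len(n))
  edges <- vector("list", n)
  need <- min(k, n - 1L)
  for (i in seq_len(n)) {
    pool <- pools[[i]]
    if (length(pool) < need)
      pool <- c(pool, setdiff(seq_len(n), c(pool, i)))
    sims <- as.numeric(match_fraction_cpp(
      forest$fingerprints[i, , drop = FALSE],
      forest$fingerprints[pool, , drop = FALSE]))
    ord <- order(-sims, pool)
    take <- utils::head(ord, min(k, n - 1L))
    edges[[i]] <- data.frame(from = i, to = pool[take],
                             similarity = sims[take])
  }
  edf <- do.call(rbind, edges)
  if (is.null(edf) || nrow(edf) == 0)
    stop("degenerate input: no neighbor candidates found")
  a <- pmin(edf$from, edf$to)
  b <- pmax(edf$from, edf$to)
  key <- paste(a, b)
  keep <- !duplicated(key)
  g <- igraph::graph_from_edgelist(cbind(a[keep], b[keep]), directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::E(g)$weight <- 1 - edf$similarity[keep]
  g
}

#' Minimum spanning tree (or forest) of a weighted graph
#'
#' @param graph An igraph graph with a `weight` edge attribute.
#' @return Data frame of tree edges `(i, j, weight)` with `i < j`, sorted by
#'   `(weight, i, j)`; `n_nodes - n_components` rows.
#' @export
minimum_spanning_tree <- function(graph) {
  if (igraph::vcount(graph) == 0) stop("degenerate input: empty graph")
  mst <- igraph::mst(graph, weights = igraph::E(graph)$weight)
  el <- igraph::as_edgelist(mst, names = FALSE)
  w <- igraph::E(mst)$weight
  out <- data.frame(i = pmin(el[, 1], el[, 2]), j = pmax(el[, 1], el[, 2]),
                    weight = w)
  out[order(out$weight, out$i, out$j), , drop = FALSE]
}

#' 2D layout of a spanning tree or forest
#'
#' Kamada-Kawai layout per connected component; components are normalized
#' and placed side by side so their bounding boxes never overlap.
#'
#' @param edges Tree edge data frame (`i`, `j`, optional `weight`).
#' @param n_nodes Total number of nodes (isolated nodes allowed).
#' @param seed Layout seed.
#' @return `n_nodes x 2` matrix of finite coordinates.
#' @export
layout_tree <- function(edges, n_nodes, seed = 1L) {
  g <- igraph::make_empty_graph(n_nodes, directed = FALSE)
  if (nrow(edges) > 0)
    g <- igraph::add_edges(g, rbind(edges$i, edges$j))
  if (any(igraph::which_loop(g)) || igraph::ecount(g) >
      n_nodes - igraph::count_components(g))
    stop("not a tree: input contains cycles")
  comp <- igraph::components(g)
  coords <- matrix(0, n_nodes, 2)
  offset <- 0
  gap <- 0.1
  for (ci in seq_len(comp$no)) {
    nodes <- which(comp$membership == ci)
    if (length(nodes) == 1) {
      xy <- matrix(0, 1, 2)
    } else {
      sub <- igraph::induced_subgraph(g, nodes)
      xy <- with_local_seed(seed + ci, igraph::layout_with_kk(sub))
    }
    xy[, 1] <- xy[, 1] - min(xy[, 1])
    xy[, 2] <- xy[, 2] - min(xy[, 2])
    span <- max(xy[, 1], 1e-9)
    coords[nodes, 1] <- xy[, 1] + offset
    coords[nodes, 2] <- xy[, 2]
    offset <- offset + span + gap + max(span, 1) * 0.05
  }
  coords
}

#' Build the full chemical-space layout
#'
#' LSH forest, approximate kNN graph, minimum spanning tree, 2D tree layout
#' and per-molecule color channels (MW, Fsp3, AlogP, origin, category).
#'
#' @param fingerprints MinHash fingerprint matrix.
#' @param profile Data frame from [compute_profile()] (same row order).
#' @param origin Character vector of origin labels (same order).
#' @param k Approximate neighbors per molecule (default 20).
#' @param n_trees LSH trees (default 32).
#' @param seed Layout seed.
#' @return An object of class `chemspace_layout`.
#' @export
chemspace_layout <- function(fingerprints, profile, origin, k = 20L,
                             n_trees = 32L, seed = 1L) {
  stopifnot(nrow(fingerprints) == nrow(profile),
            nrow(profile) == length(origin))
  forest <- build_lsh_forest(fingerprints, n_trees = n_trees)
  g <- knn_graph(forest, k = k)
  mst_edges <- minimum_spanning_tree(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  knn_edges <- data.frame(i = pmin(el[, 1], el[, 2]),
                          j = pmax(el[, 1], el[, 2]),
                          weight = igraph::E(g)$weight)
  coords <- layout_tree(mst_edges, nrow(fingerprints), seed = seed)
  structure(list(
    coordinates = coords,
    mst_edges = mst_edges,
    knn_edges = knn_edges,
    channels = data.frame(
      mw = profile$mw,
      fsp3 = profile$fsp3,
      alogp = profile$alogp,
      origin = origin,
      category = profile$category,
      stringsAsFactors = FALSE
    )
  ), class = "chemspace_layout")
}

#' Export a chemical-space layout
#'
#' Writes coordinates, kNN and MST edge lists and the channel table as CSV;
#' optionally renders one static scatter plot per channel (requires
#' ggplot2).
#'
#' @param layout A [chemspace_layout()] object.
#' @param dir Output directory (created if absent).
#' @param channels Channels to render (subset of the channel columns).
#' @param images Render PNGs? Default `TRUE` when ggplot2 is installed.
#' @return `dir`, invisibly.
#' @export
export_layout <- function(layout, dir,
                          channels = colnames(layout$channels),
                          images = requireNamespace("ggplot2", quietly = TRUE)) {
  miss <- vapply(channels, function(ch)
    any(is.na(layout$channels[[ch]])), logical(1))
  if (any(miss))
    stop("export error: missing channel values for molecule(s) in channel(s): ",
         paste(channels[miss], collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(x = layout$coordinates[, 1],
                              y = layout$coordinates[, 2]),
                   file.path(dir, "coordinates.csv"), row.names = FALSE)
  utils::write.csv(layout$mst_edges, file.path(dir, "mst_edges.csv"),
                   row.names = FALSE)
  utils::write.csv(layout$knn_edges, file.path(dir, "knn_edges.csv"),
                   row.names = FALSE)
  utils::write.csv(layout$channels, file.path(dir, "channels.csv"),
                   row.names = FALSE)
  if (images) {
    df <- data.frame(x = layout$coordinates[, 1], y = layout$coordinates[, 2])
    seg <- data.frame(
      x = df$x[layout$mst_edges$i], y = df$y[layout$mst_edges$i],
      xend = df$x[layout$mst_edges$j], yend = df$y[layout$mst_edges$j])
    for (ch in channels) {
      df$value <- layout$channels[[ch]]
      p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
        ggplot2::geom_segment(data = seg,
          ggplot2::aes(x = .data$x, y = .data$y,
                       xend = .data$xend, yend = .data$yend),
          inherit.aes = FALSE, linewidth = 0.2, color = "grey70") +
        ggplot2::geom_point(ggplot2::aes(color = .data$value), size = 0.8) +
        ggplot2::labs(title = ch, color = ch) +
        ggplot2::theme_void()
      ggplot2::ggsave(file.path(dir, paste0("map_", ch, ".png")), p,
                      width = 7, height = 6, dpi = 150)
    }
  }
  invisible(dir)
}

#' Re-import a layout written by [export_layout()]
#'
#' @param dir Directory previously written by [export_layout()].
#' @return A `chemspace_layout` object.
#' @export
import_layout <- function(dir) {
  coords <- as.matrix(utils::read.csv(file.path(dir, "coordinates.csv")))
  dimnames(coords) <- NULL
  structure(list(
    coordinates = coords,
    mst_edges = utils::read.csv(file.path(dir, "mst_edges.csv")),
    knn_edges = utils::read.csv(file.path(dir, "knn_edges.csv")),
    channels = utils::read.csv(file.path(dir, "channels.csv"),
                               stringsAsFactors = FALSE)
  ), class = "chemspace_layout")
}
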