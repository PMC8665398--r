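test_that("build_graph collapses duplicate and reciprocal relations", {
  g <- graph_from_edges(c("A", "B", "C"),
                        list(c("A", "B"), c("B", "A"), c("A", "B")))
  expect_equal(length(g$nodes), 3L)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(unname(g$edges[1, ]), c("A", "B"))

  edgeless <- build_graph(concepts_df(c("A", "B")), relations_df(list()))
  expect_equal(nrow(edgeless$edges), 0L)
})

test_that("build_graph edge set matches a pair-normalization oracle", {
  set.seed(101)
  nodes <- sprintf("C%02d", 1:15)
  pairs <- lapply(1:30, function(i) sample(nodes, 2))
  g <- graph_from_edges(nodes, pairs)
  oracle <- unique(t(vapply(pairs, function(p) sort(p), character(2))))
  oracle <- oracle[order(oracle[, 1], oracle[, 2]), , drop = FALSE]
  got <- g$edges[order(g$edges[, 1], g$edges[, 2]), , drop = FALSE]
  expect_equal(unname(got), unname(oracle))
})

test_that("relations with unknown endpoints are skipped with a warning", {
  expect_warning(
    g <- build_graph(concepts_df(c("A", "B")),
                     relations_df(list(c("A", "B"), c("A", "Z")))),
    "not in the concept table")
  expect_equal(nrow(g$edges), 1L)
})

test_that("induction on a path graph recovers the whole path", {
  g <- graph_from_edges(c("A", "B", "C", "D", "E"),
                        list(c("A", "B"), c("B", "C"), c("C", "D"),
                             c("D", "E")))
  ig <- induce_sentence_graph(g, c("A", "E"))
  expect_equal(ig$node_ids, c("A", "B", "C", "D", "E"))
  expect_equal(sum(ig$adjacency) / 2, 4)
  expect_equal(ig$seed_ids, c("A", "E"))
})

test_that("induction on a star passes through the hub", {
  g <- graph_from_edges(c("H", "L1", "L2", "L3", "L4"),
                        list(c("H", "L1"), c("H", "L2"), c("H", "L3"),
                             c("H", "L4")))
  ig <- induce_sentence_graph(g, c("L1", "L2"))
  expect_equal(ig$node_ids, c("H", "L1", "L2"))
  expect_equal(sum(ig$adjacency) / 2, 2)
})

test_that("degenerate inductions behave as stated", {
  g <- graph_from_edges(c("A", "B", "C", "D"),
                        list(c("A", "B"), c("C", "D")))
  # empty seeds
  empty <- induce_sentence_graph(g, character(0))
  expect_equal(length(empty$node_ids), 0L)
  # one seed per component: two isolated nodes, no edges
  ig <- induce_sentence_graph(g, c("A", "C"))
  expect_equal(ig$node_ids, c("A", "C"))
  expect_equal(sum(ig$adjacency), 0L)
  # unknown seeds dropped with a warning
  expect_warning(ig2 <- induce_sentence_graph(g, c("A", "ZZ")),
                 "dropping 1 seed")
  expect_equal(ig2$node_ids, "A")
})

test_that("induction is idempotent and deterministic", {
  set.seed(77)
  g <- random_connected_graph(12)
  seeds <- sample(g$nodes, 4)
  ig1 <- induce_sentence_graph(g, seeds)
  ig2 <- induce_sentence_graph(g, seeds)
  expect_identical(ig1, ig2)
  # re-inducing with the previous seed set over the same graph is identity
  again <- induce_sentence_graph(g, ig1$seed_ids)
  expect_true(all(ig1$node_ids %in% again$node_ids))
  expect_identical(induce_sentence_graph(g, again$seed_ids), again)
})

test_that("induced node sets match the independent BFS oracle on random graphs", {
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(5:20, 1)
    g <- random_connected_graph(n)
    seeds <- sample(g$nodes, sample(1:5, 1))
    ig <- induce_sentence_graph(g, seeds)
    expect_equal(ig$node_ids, oracle_induce_nodes(g, seeds))
  }
})

test_that("seed distances inside the induced graph equal full-graph distances", {
  skip_if_not_installed("igraph")
  set.seed(9)
  for (rep in 1:20) {
    g <- random_connected_graph(sample(6:18, 1))
    seeds <- sample(g$nodes, sample(2:5, 1))
    ig <- induce_sentence_graph(g, seeds)
    full <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
    sub <- if (sum(ig$adjacency) > 0)
      igraph::graph_from_adjacency_matrix(ig$adjacency, mode = "undirected")
    else igraph::make_empty_graph(length(ig$node_ids)) +
      igraph::vertices(name = ig$node_ids)
    for (i in seq_along(ig$seed_ids))
      for (j in seq_along(ig$seed_ids))
        if (i < j) {
          d_full <- igraph::distances(full, ig$seed_ids[i], ig$seed_ids[j])
          d_sub <- igraph::distances(sub, ig$seed_ids[i], ig$seed_ids[j])
          expect_equal(as.numeric(d_sub), as.numeric(d_full))
        }
  }
})

test_that("every induced edge lies on a computed shortest path", {
  skip_if_not_installed("igraph")
  set.seed(13)
  for (rep in 1:20) {
    g <- random_connected_graph(sample(6:15, 1))
    seeds <- sample(g$nodes, sample(2:4, 1))
    ig <- induce_sentence_graph(g, seeds)
    if (sum(ig$adjacency) == 0) next
    full <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
    d <- igraph::distances(full)
    up <- which(upper.tri(ig$adjacency) & ig$adjacency == 1, arr.ind = TRUE)
    for (k in seq_len(nrow(up))) {
      u <- ig$node_ids[up[k, 1]]; v <- ig$node_ids[up[k, 2]]
      on_some_path <- any(vapply(ig$seed_ids, function(s)
        any(vapply(ig$seed_ids, function(t)
          s != t &&
            (d[s, u] + 1 + d[v, t] == d[s, t] ||
             d[s, v] + 1 + d[u, t] == d[s, t]), TRUE)), TRUE))
      expect_true(on_some_path)
    }
  }
})

test_that("induced graphs round-trip through the edge-list serialization", {
  set.seed(3)
  g <- random_connected_graph(10)
  ig <- induce_sentence_graph(g, sample(g$nodes, 3))
  ep <- tempfile()
  write_induced_graph(ig, ep)
  back <- read_induced_graph(ep)
  expect_identical(back$node_ids, ig$node_ids)
  expect_equal(unname(back$adjacency), unname(ig$adjacency))
  expect_identical(back$seed_ids, ig$seed_ids)
  # empty graph round-trips too
  e <- induce_sentence_graph(g, character(0))
  ep2 <- tempfile()
  write_induced_graph(e, ep2)
  expect_equal(length(read_induced_graph(ep2)$node_ids), 0L)
})
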