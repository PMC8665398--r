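path_graph <- function() {
  g <- graph_from_edges(c("A", "B", "C", "D", "E"),
                        list(c("A", "B"), c("B", "C"), c("C", "D"),
                             c("D", "E")))
  induce_sentence_graph(g, c("A", "E"))
}

test_that("node features come from the table when present, seeded noise otherwise", {
  ig <- path_graph()
  vec <- matrix(seq_len(5 * 4) / 10, 5, 4,
                dimnames = list(ig$node_ids, NULL))
  table <- structure(list(dim = 4L, vectors = vec), class = "embedding_table")
  f <- init_node_features(ig, "pretrained", table = table, dim = 4L, seed = 1L)
  expect_equal(unname(f), unname(vec))

  # random mode: deterministic under a fixed seed
  f1 <- init_node_features(ig, "random", dim = 8L, seed = 3L)
  f2 <- init_node_features(ig, "random", dim = 8L, seed = 3L)
  expect_identical(f1, f2)
  expect_false(isTRUE(all.equal(f1,
    init_node_features(ig, "random", dim = 8L, seed = 4L))))

  # half the nodes out of table: exactly those rows vary with the seed
  partial <- structure(list(dim = 4L,
                            vectors = vec[c("A", "C", "E"), , drop = FALSE]),
                       class = "embedding_table")
  expect_message(
    fa <- init_node_features(ig, "pretrained", table = partial, dim = 4L,
                             seed = 1L),
    "not in the embedding table")
  suppressMessages(
    fb <- init_node_features(ig, "pretrained", table = partial, dim = 4L,
                             seed = 2L))
  in_table <- ig$node_ids %in% c("A", "C", "E")
  expect_equal(fa[in_table, ], fb[in_table, ])
  expect_false(any(fa[!in_table, ] == fb[!in_table, ]))

  # dimension mismatch is a configuration error
  expect_error(init_node_features(ig, "pretrained", table = table, dim = 5L),
               class = "graphsts_config_error")
})

test_that("gcn layer equals hand-computed and dense oracles", {
  # edgeless graph: S = I, identity weights -> identity map
  f <- matrix(c(1, 2, 3), 3, 1)
  a0 <- matrix(0L, 3, 3)
  expect_equal(gcn_layer(f, a0, matrix(1), activation = "identity"), f)

  # 2-node single edge, features [1, 3]: S is the all-1/2 matrix -> [2, 2]
  a <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  out <- gcn_layer(matrix(c(1, 3), 2, 1), a, matrix(1),
                   activation = "identity")
  expect_equal(as.numeric(out), c(2, 2))

  # random graphs against the dense normalized-adjacency oracle
  set.seed(8)
  for (rep in 1:30) {
    n <- sample(2:8, 1)
    a <- matrix(0L, n, n)
    for (k in seq_len(n)) {
      uv <- sample.int(n, 2)
      a[uv[1], uv[2]] <- a[uv[2], uv[1]] <- 1L
    }
    d_in <- sample(1:5, 1); d_out <- sample(1:5, 1)
    f <- matrix(rnorm(n * d_in), n, d_in)
    w <- matrix(rnorm(d_in * d_out), d_in, d_out)
    expect_equal(gcn_layer(f, a, w, activation = "relu"),
                 oracle_gcn_layer(f, a, w), tolerance = 1e-6)
  }

  expect_error(gcn_layer(matrix(0, 2, 3), a, matrix(0, 2, 1)),
               class = "graphsts_config_error")
})

test_that("gcn layers are permutation-equivariant", {
  set.seed(15)
  for (rep in 1:20) {
    n <- sample(3:7, 1)
    a <- matrix(0L, n, n)
    for (k in seq_len(n + 2)) {
      uv <- sample.int(n, 2)
      a[uv[1], uv[2]] <- a[uv[2], uv[1]] <- 1L
    }
    f <- matrix(rnorm(n * 3), n, 3)
    w <- matrix(rnorm(3 * 4), 3, 4)
    p <- diag(n)[sample.int(n), , drop = FALSE]
    lhs <- p %*% gcn_layer(f, a, w)
    rhs <- gcn_layer(p %*% f, p %*% a %*% t(p), w)
    expect_equal(lhs, rhs, tolerance = 1e-6)
  }
})

test_that("graph encoding is permutation-invariant and handles degenerates", {
  params <- gcn_params(dims = c(4L, 6L, 5L), seed = 2L)
  ig <- path_graph()
  set.seed(30)
  f <- matrix(rnorm(5 * 4), 5, 4)
  v <- encode_graph(ig, f, params)
  expect_length(v, 5L)
  # permuting node order leaves the encoding unchanged
  perm <- sample.int(5)
  igp <- ig
  igp$node_ids <- ig$node_ids[perm]
  igp$adjacency <- ig$adjacency[perm, perm]
  expect_equal(encode_graph(igp, f[perm, , drop = FALSE], params), v,
               tolerance = 1e-6)

  # empty graph encodes to the zero vector
  g2 <- graph_from_edges(c("A", "B"), list(c("A", "B")))
  empty <- induce_sentence_graph(g2, character(0))
  expect_equal(encode_graph(empty, matrix(0, 0, 4), params), numeric(5))

  # single isolated node: chained linear maps of its feature row
  solo <- induce_sentence_graph(g2, "A")
  f1 <- matrix(rnorm(4), 1, 4)
  manual <- pmax(pmax(f1 %*% params$layer_weights[[1]], 0) %*%
                   params$layer_weights[[2]], 0)
  expect_equal(encode_graph(solo, f1, params), as.numeric(manual),
               tolerance = 1e-10)
})

test_that("complete-graph propagation equalizes rows", {
  for (n in 2:6) {
    a <- matrix(1L, n, n) - diag(n)
    f <- matrix(rnorm(n * 3), n, 3)
    out <- gcn_layer(f, a, diag(3), activation = "identity")
    for (j in 1:3) expect_equal(var(out[, j]), 0, tolerance = 1e-20)
  }
})

test_that("embedding files round-trip in word2vec text format", {
  vec <- matrix(round(rnorm(12), 6), 3, 4,
                dimnames = list(c("C1", "C2", "C3"), NULL))
  path <- tempfile()
  write_embeddings(vec, path)
  back <- read_embeddings(path)
  expect_equal(back$dim, 4L)
  expect_equal(back$vectors, vec, tolerance = 1e-6)
  # headerless files parse too
  path2 <- tempfile()
  write_embeddings(vec, path2, header = FALSE)
  expect_equal(read_embeddings(path2)$dim, 4L)
  # ragged rows are format errors
  path3 <- tempfile()
  writeLines(c("C1 1 2 3", "C2 1 2"), path3)
  expect_error(read_embeddings(path3), class = "graphsts_format_error")
})
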