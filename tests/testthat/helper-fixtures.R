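# Shared fixtures: miniature RRF writers, small graphs, and independent
# oracles used to cross-check the package's algorithms.

# Write an MRCONSO-dialect file from (cui, sab, str) triples using the
# standard 18-column layout.
write_conso_fixture <- function(rows, path = tempfile(fileext = ".RRF")) {
  lines <- vapply(rows, function(r)
    paste(r[1], "ENG", "P", "", "PF", "", "Y", "", "", "", "", r[2], "PT",
          "", r[3], "0", "N", "", sep = "|"), "")
  writeLines(lines, path)
  path
}

# Write an MRREL-dialect file from (cui1, cui2) pairs (16-column layout).
write_rel_fixture <- function(pairs, path = tempfile(fileext = ".RRF")) {
  lines <- vapply(pairs, function(p)
    paste(p[1], "", "CUI", "RO", p[2], "", "CUI", "", "", "", "SRC", "", "",
          "", "N", "", sep = "|"), "")
  writeLines(lines, path)
  path
}

concepts_df <- function(cuis) {
  data.frame(cui = cuis, preferred_name = paste0("name_", cuis),
             source_vocab = "SRC", semantic_types = "",
             stringsAsFactors = FALSE)
}

relations_df <- function(pairs) {
  data.frame(cui1 = vapply(pairs, `[`, "", 1),
             cui2 = vapply(pairs, `[`, "", 2),
             rel_label = rep("RO", length(pairs)), stringsAsFactors = FALSE)
}

# Terminology graph straight from an edge list over the given node names.
graph_from_edges <- function(nodes, pairs) {
  build_graph(concepts_df(nodes), relations_df(pairs))
}

# Random connected graph: random spanning tree plus extra edges.
random_connected_graph <- function(n, extra = n %/% 2) {
  nodes <- sprintf("C%03d", seq_len(n))
  pairs <- list()
  for (i in seq_len(n)[-1])
    pairs[[length(pairs) + 1]] <- c(nodes[sample.int(i - 1L, 1L)], nodes[i])
  for (k in seq_len(extra)) {
    uv <- sample.int(n, 2L)
    pairs[[length(pairs) + 1]] <- nodes[uv]
  }
  graph_from_edges(nodes, pairs)
}

# Independent BFS with lexicographic tie-breaking, written against the
# adjacency implied by the edge matrix only (never the package's neighbor
# lists): returns distances and BFS-tree parents from `src` (node names).
oracle_bfs <- function(graph, src) {
  nodes <- sort(graph$nodes)
  adj <- lapply(stats::setNames(nodes, nodes), function(x) character(0))
  for (k in seq_len(nrow(graph$edges))) {
    a <- graph$edges[k, 1]; b <- graph$edges[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj <- lapply(adj, sort)
  dist <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  parent <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  dist[src] <- 0L
  queue <- src
  while (length(queue) > 0) {
    u <- queue[1]; queue <- queue[-1]
    for (v in adj[[u]]) {
      if (is.na(dist[v])) {
        dist[v] <- dist[u] + 1L
        parent[v] <- u
        queue <- c(queue, v)
      }
    }
  }
  list(dist = dist, parent = parent)
}

# Oracle induction: union over sorted seed pairs of the BFS-tree path.
oracle_induce_nodes <- function(graph, seeds) {
  seeds <- sort(intersect(unique(seeds), graph$nodes))
  nodes <- seeds
  if (length(seeds) >= 2) {
    for (i in seq_len(length(seeds) - 1)) {
      bfs <- oracle_bfs(graph, seeds[i])
      for (j in (i + 1):length(seeds)) {
        t <- seeds[j]
        if (is.na(bfs$dist[t])) next
        v <- t
        while (v != seeds[i]) {
          nodes <- c(nodes, v)
          v <- bfs$parent[v]
        }
      }
    }
  }
  sort(unique(nodes))
}

# Dense normalized-adjacency oracle for the graph-convolution layer.
oracle_gcn_layer <- function(features, adjacency, weights,
                             act = function(x) pmax(x, 0)) {
  n <- nrow(adjacency)
  at <- adjacency + diag(n)
  d <- diag(1 / sqrt(rowSums(at)))
  act(d %*% at %*% d %*% features %*% weights)
}

# Tiny deterministic corpus for end-to-end tests.
tiny_corpus <- function(seed = 5L, n_concepts = 30L, n_pairs = 80L) {
  cfg <- synthetic_config(n_concepts = n_concepts, n_pairs = n_pairs,
                          seed = seed)
  simulate_corpus(cfg, file.path(tempdir(), paste0("tiny_", seed, "_",
                                                   n_concepts, "_", n_pairs)))
}
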