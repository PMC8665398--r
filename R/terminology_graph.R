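#' Build an undirected terminology graph
#'
#' Nodes are the concept identifiers; each relation row contributes one
#' undirected, unweighted edge. Duplicate and reciprocal rows collapse to a
#' single edge; relation labels are carried by the relation table but never
#' affect topology (only connectivity among concepts is represented).
#' Relations with an endpoint absent from the concept table are skipped with
#' a warning.
#'
#' @param concepts data.frame from [read_concept_file()].
#' @param relations data.frame from [read_relation_file()].
#' @return A `terminology_graph`: list with `nodes` (character), `edges`
#'   (2-column character matrix, each row lexicographically sorted),
#'   `concepts` (the concept table, one row per node) and `neighbors`
#'   (adjacency list of integer node indices, each sorted by neighbor CUI).
#' @export
build_graph <- function(concepts, relations) {
  nodes <- concepts$cui
  i1 <- match(relations$cui1, nodes)
  i2 <- match(relations$cui2, nodes)
  missing <- is.na(i1) | is.na(i2)
  if (any(missing)) {
    bad <- unique(c(relations$cui1[is.na(i1)], relations$cui2[is.na(i2)]))
    warning(sprintf("skipping %d relation row(s) with endpoint(s) not in the concept table: %s",
                    sum(missing), paste(utils::head(bad, 5), collapse = ", ")))
    i1 <- i1[!missing]; i2 <- i2[!missing]
  }
  a <- pmin(i1, i2); b <- pmax(i1, i2)
  keep <- !duplicated(cbind(a, b)) & a != b
  a <- a[keep]; b <- b[keep]
  n <- length(nodes)
  nbr <- vector("list", n)
  for (k in seq_along(a)) {
    nbr[[a[k]]] <- c(nbr[[a[k]]], b[k])
    nbr[[b[k]]] <- c(nbr[[b[k]]], a[k])
  }
  # lexicographic neighbor order by CUI gives deterministic BFS tie-breaks
  ord <- order(nodes)
  rank <- integer(n); rank[ord] <- seq_len(n)
  nbr <- lapply(nbr, function(v) if (is.null(v)) integer(0) else v[order(rank[v])])
  edges <- cbind(nodes[a], nodes[b])
  swap <- edges[, 1] > edges[, 2]
  if (any(swap)) edges[swap, ] <- edges[swap, c(2, 1), drop = FALSE]
  structure(list(nodes = nodes, edges = edges, concepts = concepts,
                 neighbors = nbr),
            class = "terminology_graph")
}

#' @export
print.terminology_graph <- function(x, ...) {
  cat(sprintf("terminology_graph: %d concepts, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# BFS from node index `src` with lexicographic neighbor expansion.
# Returns integer distances (NA when unreachable) and BFS-tree parents.
bfs_from <- function(graph, src) {
  n <- length(graph$nodes)
  dist <- rep(NA_integer_, n)
  parent <- rep(NA_integer_, n)
  dist[src] <- 0L
  queue <- integer(n); queue[1] <- src; head <- 1L; tail <- 1L
  while (head <= tail) {
    u <- queue[head]; head <- head + 1L
    for (v in graph$neighbors[[u]]) {
      if (is.na(dist[v])) {
        dist[v] <- dist[u] + 1L
        parent[v] <- u
        tail <- tail + 1L
        queue[tail] <- v
      }
    }
  }
  list(dist = dist, parent = parent)
}

# All shortest-path distances from each of `from` (node indices); rows = from.
bfs_distance_matrix <- function(graph, from) {
  do.call(rbind, lapply(from, function(s) bfs_from(graph, s)$dist))
}

#' Induce a per-sentence concept subgraph
#'
#' For every unordered pair of retained seed concepts lying in the same
#' connected component, one unweighted shortest path is computed by
#' breadth-first search (ties broken deterministically by lexicographic
#' neighbor order); the induced graph is the union of the nodes and
#' consecutive edges of those paths. Seeds absent from the terminology graph
#' are dropped with a warning; seed pairs in different components contribute
#' nothing beyond the isolated seed nodes themselves.
#'
#' @param graph a `terminology_graph`.
#' @param seeds character vector of seed CUIs (duplicates collapse).
#' @return An `induced_graph`: list with `node_ids` (sorted CUIs),
#'   `adjacency` (binary symmetric matrix, zero diagonal, dimnames =
#'   `node_ids`) and `seed_ids` (retained seeds, sorted).
#' @export
induce_sentence_graph <- function(graph, seeds) {
  seeds <- unique(as.character(seeds))
  idx <- match(seeds, graph$nodes)
  if (anyNA(idx)) {
    warning(sprintf("dropping %d seed(s) not in the terminology graph: %s",
                    sum(is.na(idx)), paste(seeds[is.na(idx)], collapse = ", ")))
    idx <- idx[!is.na(idx)]
  }
  idx <- sort(idx)
  if (length(idx) == 0) return(empty_induced_graph())
  node_set <- idx
  edge_a <- integer(0); edge_b <- integer(0)
  if (length(idx) >= 2) {
    # one BFS per seed serves all pairs rooted at that seed
    src_order <- idx[order(graph$nodes[idx])]
    for (si in seq_len(length(src_order) - 1)) {
      s <- src_order[si]
      bfs <- bfs_from(graph, s)
      for (t in src_order[(si + 1):length(src_order)]) {
        if (is.na(bfs$dist[t])) next
        v <- t
        while (v != s) {
          p <- bfs$parent[v]
          node_set <- c(node_set, v, p)
          edge_a <- c(edge_a, min(v, p)); edge_b <- c(edge_b, max(v, p))
          v <- p
        }
      }
    }
  }
  node_set <- sort(unique(node_set))
  ids <- graph$nodes[node_set]
  ord <- order(ids)
  ids <- ids[ord]
  n <- length(ids)
  adj <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (length(edge_a) > 0) {
    ea <- match(graph$nodes[edge_a], ids)
    eb <- match(graph$nodes[edge_b], ids)
    adj[cbind(ea, eb)] <- 1L
    adj[cbind(eb, ea)] <- 1L
  }
  structure(list(node_ids = ids, adjacency = adj,
                 seed_ids = sort(graph$nodes[idx])),
            class = "induced_graph")
}

empty_induced_graph <- function() {
  structure(list(node_ids = character(0),
                 adjacency = matrix(0L, 0, 0),
                 seed_ids = character(0)),
            class = "induced_graph")
}

#' @export
print.induced_graph <- function(x, ...) {
  cat(sprintf("induced_graph: %d nodes (%d seeds), %d edges\n",
              length(x$node_ids), length(x$seed_ids), sum(x$adjacency) / 2))
  invisible(x)
}

#' Serialize / read an induced graph
#'
#' The edge list is written one `cui1 TAB cui2` pair per line; the node
#' manifest (`cui TAB is_seed`) goes to a companion file.
#'
#' @param x an `induced_graph`.
#' @param edge_path path for the edge list.
#' @param node_path path for the node manifest.
#' @return `read_induced_graph()` returns the reconstructed `induced_graph`.
#' @export
write_induced_graph <- function(x, edge_path,
                                node_path = paste0(edge_path, ".nodes")) {
  up <- which(upper.tri(x$adjacency) & x$adjacency == 1L, arr.ind = TRUE)
  edges <- if (nrow(up) > 0)
    paste(x$node_ids[up[, 1]], x$node_ids[up[, 2]], sep = "\t") else character(0)
  writeLines(edges, edge_path)
  writeLines(paste(x$node_ids,
                   as.integer(x$node_ids %in% x$seed_ids), sep = "\t"),
             node_path)
  invisible(x)
}

#' @rdname write_induced_graph
#' @export
read_induced_graph <- function(edge_path,
                               node_path = paste0(edge_path, ".nodes")) {
  nl <- readLines(node_path, warn = FALSE)
  nl <- nl[nzchar(nl)]
  if (length(nl) == 0) return(empty_induced_graph())
  nf <- strsplit(nl, "\t", fixed = TRUE)
  ids <- vapply(nf, `[[`, "", 1)
  is_seed <- vapply(nf, `[[`, "", 2) == "1"
  ord <- order(ids)
  ids <- ids[ord]; is_seed <- is_seed[ord]
  n <- length(ids)
  adj <- matrix(0L, n, n, dimnames = list(ids, ids))
  el <- readLines(edge_path, warn = FALSE)
  el <- el[nzchar(el)]
  if (length(el) > 0) {
    ef <- strsplit(el, "\t", fixed = TRUE)
    a <- match(vapply(ef, `[[`, "", 1), ids)
    b <- match(vapply(ef, `[[`, "", 2), ids)
    if (anyNA(a) || anyNA(b))
      stop_format(sprintf("edge list '%s' references nodes missing from the manifest",
                          edge_path))
    adj[cbind(a, b)] <- 1L
    adj[cbind(b, a)] <- 1L
  }
  structure(list(node_ids = ids, adjacency = adj, seed_ids = ids[is_seed]),
            class = "induced_graph")
}
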