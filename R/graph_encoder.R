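#' Initialize node features for an induced graph
#'
#' `mode = "random"` draws every row from a standard normal scaled by
#' `1/sqrt(dim)`; draws are seeded per CUI (combined with `seed`), so a
#' concept receives the same vector in every graph of a corpus — node
#' identity is preserved even without pretrained embeddings.
#' `mode = "pretrained"` looks each CUI up in a knowledge-graph-embedding
#' table; out-of-table CUIs fall back to the seeded random draw (logged),
#' since pretrained tables never fully cover an ontology.
#'
#' @param graph an `induced_graph`.
#' @param mode `"random"` or `"pretrained"`.
#' @param table an `embedding_table` (required for `"pretrained"`).
#' @param dim feature dimension; for `"pretrained"` it must equal
#'   `table$dim`.
#' @param seed integer base seed for the per-CUI draws.
#' @return Numeric matrix, one row per `graph$node_ids` entry.
#' @export
init_node_features <- function(graph, mode = c("random", "pretrained"),
                               table = NULL, dim = 16L, seed = 1L) {
  mode <- match.arg(mode)
  n <- length(graph$node_ids)
  if (mode == "pretrained") {
    if (is.null(table)) stop_config("pretrained initialization requires an embedding table")
    if (table$dim != dim)
      stop_config(sprintf("embedding table dim (%d) does not match requested dim (%d)",
                          table$dim, dim))
  }
  feats <- matrix(0, n, dim, dimnames = list(graph$node_ids, NULL))
  missing <- character(0)
  for (i in seq_len(n)) {
    cui <- graph$node_ids[i]
    if (mode == "pretrained" && cui %in% rownames(table$vectors)) {
      feats[i, ] <- table$vectors[cui, ]
    } else {
      if (mode == "pretrained") missing <- c(missing, cui)
      feats[i, ] <- with_seed(string_seed(cui, seed),
                              stats::rnorm(dim) / sqrt(dim))
    }
  }
  if (length(missing) > 0)
    message(sprintf("init_node_features: %d node(s) not in the embedding table, using seeded random vectors: %s",
                    length(missing), paste(utils::head(missing, 5), collapse = ", ")))
  feats
}

# Symmetric-normalized propagation operator with self-loops:
# S = D^(-1/2) (A + I) D^(-1/2), D the degree matrix of A + I.
#' @keywords internal
normalized_adjacency <- function(adjacency) {
  n <- nrow(adjacency)
  if (n == 0) return(matrix(0, 0, 0))
  at <- adjacency + diag(n)
  dinv <- 1 / sqrt(rowSums(at))
  at * outer(dinv, dinv)
}

activation_fun <- function(name) {
  switch(name,
         relu = function(x) pmax(x, 0),
         identity = function(x) x,
         tanh = tanh,
         stop_config(sprintf("unknown activation '%s'", name)))
}

#' One graph-convolution layer
#'
#' Computes `activation(S %*% features %*% weights)` with `S` the
#' symmetric-normalized adjacency with self-loops (see
#' [gcn_params()] for the parameter container).
#'
#' @param features n x d_in numeric matrix.
#' @param adjacency n x n binary symmetric matrix with zero diagonal.
#' @param weights d_in x d_out numeric matrix.
#' @param activation activation name (`"relu"`, `"identity"`, `"tanh"`).
#' @return n x d_out matrix.
#' @export
gcn_layer <- function(features, adjacency, weights, activation = "relu") {
  if (nrow(adjacency) != nrow(features) || ncol(adjacency) != nrow(features))
    stop_config("adjacency and feature shapes do not conform")
  if (ncol(features) != nrow(weights))
    stop_config("feature and weight shapes do not conform")
  act <- activation_fun(activation)
  act(normalized_adjacency(adjacency) %*% features %*% weights)
}

#' Construct graph-encoder parameters
#'
#' Layer weights are Glorot-initialized under the given seed. Consecutive
#' layer dimensions chain: `dims = c(d_in, hidden..., d_out)`.
#'
#' @param dims integer vector of layer dimensions (length `n_layers + 1`).
#' @param activation elementwise nonlinearity applied after each layer.
#' @param seed integer seed for weight initialization.
#' @return A `gcn_params` list: `layer_weights`, `n_layers`, `activation`,
#'   `readout` (mean pooling).
#' @export
gcn_params <- function(dims = c(16L, 64L, 64L), activation = "relu",
                       seed = 1L) {
  stopifnot(length(dims) >= 2)
  weights <- with_seed(seed, lapply(seq_len(length(dims) - 1L), function(l) {
    s <- sqrt(6 / (dims[l] + dims[l + 1]))
    matrix(stats::runif(dims[l] * dims[l + 1], -s, s), dims[l], dims[l + 1])
  }))
  structure(list(layer_weights = weights, n_layers = length(dims) - 1L,
                 activation = activation, readout = "mean"),
            class = "gcn_params")
}

#' Encode an induced graph into a fixed-length vector
#'
#' Applies the stacked graph-convolution layers and mean-pools node
#' representations. The empty graph encodes to the zero vector.
#'
#' @param graph an `induced_graph`.
#' @param features node-feature matrix aligned with `graph$node_ids`.
#' @param params a `gcn_params` object.
#' @return Numeric vector of length `ncol(params$layer_weights[[n_layers]])`.
#' @export
encode_graph <- function(graph, features, params) {
  d_out <- ncol(params$layer_weights[[params$n_layers]])
  if (length(graph$node_ids) == 0) return(numeric(d_out))
  if (nrow(features) != length(graph$node_ids))
    stop_config("feature rows do not align with graph nodes")
  h <- features
  for (l in seq_len(params$n_layers))
    h <- gcn_layer(h, graph$adjacency, params$layer_weights[[l]],
                   params$activation)
  colMeans(h)
}
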