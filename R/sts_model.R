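# Fusion model: joint text encoder + shared-weight graph encoder applied to
# each sentence's concept graph, concatenated and scored by a small
# feed-forward head. Trained by Adam with two learning-rate groups (text
# encoder vs graph encoder + head), following the convention of fine-tuning
# a text encoder gently while the graph encoder and head learn faster.

#' Initialize a fusion model
#'
#' One graph encoder with shared weights is applied to each sentence's
#' induced graph; its two readout vectors are concatenated with the
#' pair-level text vector, giving a fused vector of dimension
#' `text output_dim + 2 * graph output dim`. A one-hidden-layer
#' feed-forward head maps this vector — augmented with the elementwise
#' product and absolute difference of the two graph readouts, the standard
#' sentence-pair interaction features — to a real similarity score. The
#' interaction features matter because the two graphs are encoded
#' independently: without them, no pairwise-similarity function of the two
#' graph readouts is reachable by a shallow head.
#'
#' @param text_config a [text_encoder_config()].
#' @param vocab a `token_vocab`.
#' @param feature_mode node-feature initialization, `"random"` or
#'   `"pretrained"` (see [init_node_features()]).
#' @param feature_dim node-feature dimension (must match the embedding table
#'   for `"pretrained"`).
#' @param embedding_table optional `embedding_table` for pretrained features.
#' @param graph_hidden,graph_out graph-encoder layer dimensions.
#' @param head_hidden hidden width of the scoring head.
#' @param use_graph if `FALSE` the graph blocks are identically zero (the
#'   text-only ablation); the architecture is otherwise unchanged.
#' @param seed integer seed for parameter initialization.
#' @return A `fusion_model`.
#' @export
init_fusion_model <- function(text_config = text_encoder_config(), vocab,
                              feature_mode = c("pretrained", "random"),
                              feature_dim = 16L, embedding_table = NULL,
                              graph_hidden = 64L, graph_out = 64L,
                              head_hidden = 64L, use_graph = TRUE,
                              seed = 1L) {
  feature_mode <- match.arg(feature_mode)
  if (feature_mode == "pretrained") {
    if (is.null(embedding_table))
      stop_config("pretrained feature mode requires an embedding table")
    if (embedding_table$dim != feature_dim)
      stop_config("feature_dim must equal the embedding table dimension")
  }
  # head input: [t; g1; g2] plus interactions [g1 * g2; |g1 - g2|]
  d_head <- text_config$output_dim + 4L * graph_out
  head <- with_seed(seed + 1L, list(
    Wh = matrix(stats::rnorm(d_head * head_hidden, sd = sqrt(2 / d_head)),
                d_head, head_hidden),
    bh = numeric(head_hidden),
    wo = stats::rnorm(head_hidden, sd = sqrt(1 / head_hidden)),
    bo = 2.5))
  structure(list(
    text_config = text_config,
    vocab = vocab,
    text = init_text_params(text_config, vocab, seed = seed),
    gcn = gcn_params(dims = c(feature_dim, graph_hidden, graph_out),
                     activation = "relu", seed = seed + 2L),
    head = head,
    feature = list(mode = feature_mode, dim = as.integer(feature_dim),
                   table = embedding_table, seed = seed),
    use_graph = isTRUE(use_graph),
    seed = as.integer(seed)),
    class = "fusion_model")
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf(paste0("fusion_model: text %s (%d-d), graph %s features (%d-d in, %d-d out)%s,\n",
                     "  head %d -> %d -> 1\n"),
              x$text_config$encoder_kind, x$text_config$output_dim,
              x$feature$mode, x$feature$dim,
              ncol(x$gcn$layer_weights[[x$gcn$n_layers]]),
              if (x$use_graph) "" else " [graph blocks zeroed]",
              nrow(x$head$Wh), length(x$head$wo)))
  invisible(x)
}

# ---- internal forward / backward ------------------------------------------

graph_forward_cached <- function(S, feats, gcn, proj = NULL) {
  d_out <- ncol(gcn$layer_weights[[gcn$n_layers]])
  n <- nrow(S)
  if (is.null(n) || n == 0)
    return(list(g = numeric(d_out), cache = NULL))
  h <- feats
  layers <- vector("list", gcn$n_layers)
  for (l in seq_len(gcn$n_layers)) {
    sh <- S %*% h
    pre <- sh %*% gcn$layer_weights[[l]]
    layers[[l]] <- list(sh = sh, pre = pre)
    h <- pmax(pre, 0)
  }
  list(g = colMeans(h), cache = list(layers = layers, S = S, n = n))
}

graph_backward_cached <- function(dg, cache, gcn, grads) {
  if (is.null(cache)) return(grads)
  n <- cache$n
  dh <- matrix(rep(dg / n, each = n), n, length(dg))
  for (l in rev(seq_len(gcn$n_layers))) {
    ly <- cache$layers[[l]]
    dpre <- dh * (ly$pre > 0)
    grads$W[[l]] <- grads$W[[l]] + t(ly$sh) %*% dpre
    if (l > 1)
      dh <- t(cache$S) %*% (dpre %*% t(gcn$layer_weights[[l]]))
  }
  grads
}

head_forward <- function(z, head) {
  pre <- as.numeric(z %*% head$Wh) + head$bh
  h <- pmax(pre, 0)
  list(s = sum(h * head$wo) + head$bo, cache = list(z = z, pre = pre, h = h))
}

head_backward <- function(ds, cache, head, grads) {
  grads$wo <- grads$wo + ds * cache$h
  grads$bo <- grads$bo + ds
  dh <- ds * head$wo
  dpre <- dh * (cache$pre > 0)
  grads$Wh <- grads$Wh + outer(cache$z, dpre)
  grads$bh <- grads$bh + dpre
  list(grads = grads, dz = as.numeric(head$Wh %*% dpre))
}

# One full forward over a prepared item, with caches for training.
fusion_forward_item <- function(model, item, cache = FALSE) {
  tf <- text_forward(item$ids, model$text, cache = cache)
  if (model$use_graph) {
    g1 <- graph_forward_cached(item$S1, item$F1, model$gcn)
    g2 <- graph_forward_cached(item$S2, item$F2, model$gcn)
  } else {
    d_out <- ncol(model$gcn$layer_weights[[model$gcn$n_layers]])
    g1 <- g2 <- list(g = numeric(d_out), cache = NULL)
  }
  z <- c(tf$vec, g1$g, g2$g, g1$g * g2$g, abs(g1$g - g2$g))
  hf <- head_forward(z, model$head)
  out <- list(score = hf$s)
  if (cache)
    out$cache <- list(text = tf$cache, g1 = g1$cache, g2 = g2$cache,
                      gvec1 = g1$g, gvec2 = g2$g, head = hf$cache)
  out
}

# Decompose the head-input gradient into text and graph-readout gradients,
# folding the interaction-feature terms back onto g1 and g2.
split_head_grad <- function(dz, d_text, d_g, g1, g2) {
  dt <- dz[seq_len(d_text)]
  dg1 <- dz[d_text + seq_len(d_g)]
  dg2 <- dz[d_text + d_g + seq_len(d_g)]
  dprod <- dz[d_text + 2L * d_g + seq_len(d_g)]
  dabs <- dz[d_text + 3L * d_g + seq_len(d_g)]
  sgn <- sign(g1 - g2)
  list(dt = dt,
       dg1 = dg1 + dprod * g2 + dabs * sgn,
       dg2 = dg2 + dprod * g1 - dabs * sgn)
}

#' Score one sentence pair with a fusion model
#'
#' Runs the text encoder on the (already augmented, if desired) pair, the
#' shared graph encoder on each sentence's induced graph, and the scoring
#' head on the concatenation. Deterministic given parameters. Empty graphs
#' contribute zero vectors. The returned score is unclamped; clamping to
#' \[0, 5\] happens at prediction/ensembling time.
#'
#' @param model a `fusion_model`.
#' @param text1,text2 sentence pair (augmented upstream if applicable).
#' @param graph1,graph2 `induced_graph`s for the two sentences.
#' @param features1,features2 optional node-feature matrices; computed from
#'   the model's feature settings via [init_node_features()] when `NULL`.
#' @return Real score.
#' @export
fusion_forward <- function(model, text1, text2, graph1, graph2,
                           features1 = NULL, features2 = NULL) {
  feat <- function(g, f) {
    if (!is.null(f)) return(f)
    init_node_features(g, mode = model$feature$mode,
                       table = model$feature$table, dim = model$feature$dim,
                       seed = model$feature$seed)
  }
  item <- list(
    ids = pair_token_ids(text1, text2, model$vocab, model$text_config$max_len),
    S1 = normalized_adjacency(graph1$adjacency),
    S2 = normalized_adjacency(graph2$adjacency),
    F1 = feat(graph1, features1), F2 = feat(graph2, features2))
  fusion_forward_item(model, item)$score
}

# ---- parameter-tree utilities ---------------------------------------------

param_tree <- function(model) {
  list(text = model$text,
       graph = list(W = model$gcn$layer_weights),
       head = model$head)
}

set_params <- function(model, tree) {
  model$text <- tree$text
  model$gcn$layer_weights <- tree$graph$W
  model$head <- tree$head
  model
}

tree_map <- function(f, ...) {
  trees <- list(...)
  if (is.list(trees[[1]])) {
    out <- lapply(seq_along(trees[[1]]), function(i)
      do.call(tree_map, c(list(f), lapply(trees, `[[`, i))))
    names(out) <- names(trees[[1]])
    out
  } else do.call(f, trees)
}

tree_zero <- function(tree) tree_map(function(x) x * 0, tree)

# ---- training --------------------------------------------------------------

#' Training configuration
#'
#' Two parameter groups get separate learning rates: the text encoder
#' (default 1e-4) and the graph encoder plus scoring head (default 1e-3);
#' training runs `epochs` passes (default 4) of Adam over shuffled
#' minibatches.
#'
#' @param lr_text learning rate for the text-encoder group.
#' @param lr_graph learning rate for the graph-encoder + head group.
#' @param epochs number of epochs (>= 1).
#' @param batch_size minibatch size.
#' @param shuffle_seed seed controlling minibatch order.
#' @return A `train_config` list.
#' @export
train_config <- function(lr_text = 1e-4, lr_graph = 1e-3, epochs = 4L,
                         batch_size = 16L, shuffle_seed = 1L) {
  if (lr_text <= 0 || lr_graph <= 0) stop_config("learning rates must be positive")
  if (epochs < 1) stop_config("epochs must be >= 1")
  structure(list(lr_text = lr_text, lr_graph = lr_graph,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 shuffle_seed = as.integer(shuffle_seed)),
            class = "train_config")
}

#' Distillation configuration
#'
#' Constants of the teacher-bounded regression loss (see
#' [bounded_regression_loss()]) plus the teacher's per-record predictions.
#'
#' @param margin margin m >= 0 of the bound test.
#' @param nu weight of the bound term (>= 0).
#' @param teacher_predictions named numeric vector of teacher scores keyed
#'   by record id; must cover every training record.
#' @return A `distill_config` list.
#' @export
distill_config <- function(margin = 0, nu = 0.5, teacher_predictions) {
  if (margin < 0 || nu < 0) stop_config("margin and nu must be non-negative")
  structure(list(margin = margin, nu = nu,
                 teacher_predictions = teacher_predictions),
            class = "distill_config")
}

#' Teacher-bounded regression loss
#'
#' `loss = (student - gold)^2 + nu * B`, where the teacher-imitation term
#' `B = (student - teacher)^2` activates only when the student's squared
#' error plus the margin `m` exceeds the teacher's squared error, and is 0
#' otherwise: the student is pushed toward the teacher only while it is
#' doing worse than the teacher.
#'
#' @param student,teacher,gold real scores (vectorized).
#' @param m margin (>= 0).
#' @param nu bound-term weight (>= 0).
#' @return Real loss value(s).
#' @export
bounded_regression_loss <- function(student, teacher, gold, m = 0, nu = 0.5) {
  if (any(m < 0) || any(nu < 0)) stop_config("m and nu must be non-negative")
  se <- (student - gold)^2
  te <- (teacher - gold)^2
  b <- ifelse(se + m > te, (student - teacher)^2, 0)
  se + nu * b
}

adam_step <- function(tree, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g,
                      state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2,
                      state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  tree <- tree_map(function(p, m, v) p - lr * (m / c1) / (sqrt(v / c2) + eps),
                   tree, state$m, state$v)
  list(tree = tree, state = state)
}

# Shared minibatch loop. grad_fn(score, gold, id) returns list(loss, dscore).
train_loop <- function(model, prepared, config, grad_fn) {
  n <- length(prepared$items)
  if (n == 0) stop_input("training dataset is empty")
  tree <- param_tree(model)
  groups <- c("text", "graph", "head")
  lrs <- list(text = config$lr_text, graph = config$lr_graph,
              head = config$lr_graph)
  states <- lapply(groups, function(g)
    list(t = 0L, m = tree_zero(tree[[g]]), v = tree_zero(tree[[g]])))
  names(states) <- groups
  trace <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(config$shuffle_seed * 1000L + epoch, sample.int(n))
    starts <- seq(1, n, by = config$batch_size)
    epoch_loss <- 0
    for (b0 in starts) {
      idx <- ord[b0:min(b0 + config$batch_size - 1L, n)]
      bs <- length(idx)
      grads <- tree_zero(tree)
      model <- set_params(model, tree)
      for (i in idx) {
        item <- prepared$items[[i]]
        fwd <- fusion_forward_item(model, item, cache = TRUE)
        gg <- grad_fn(fwd$score, prepared$score[i], prepared$record_id[i])
        epoch_loss <- epoch_loss + gg$loss
        ds <- gg$dscore / bs
        hb <- head_backward(ds, fwd$cache$head, model$head, grads$head)
        grads$head <- hb$grads
        d_text <- model$text_config$output_dim
        d_g <- ncol(model$gcn$layer_weights[[model$gcn$n_layers]])
        sg <- split_head_grad(hb$dz, d_text, d_g, fwd$cache$gvec1,
                              fwd$cache$gvec2)
        grads$text <- text_backward(sg$dt, fwd$cache$text, model$text,
                                    grads$text)
        if (model$use_graph) {
          grads$graph <- graph_backward_cached(sg$dg1, fwd$cache$g1,
                                               model$gcn, grads$graph)
          grads$graph <- graph_backward_cached(sg$dg2, fwd$cache$g2,
                                               model$gcn, grads$graph)
        }
      }
      for (g in groups) {
        st <- adam_step(tree[[g]], grads[[g]], states[[g]], lrs[[g]])
        tree[[g]] <- st$tree
        states[[g]] <- st$state
      }
    }
    trace[epoch] <- epoch_loss / n
  }
  list(model = set_params(model, tree), loss_trace = trace)
}

#' Train a fusion model
#'
#' Minimizes mean squared error between predicted and gold scores on the
#' raw 0-5 scale with Adam, using the two configured learning-rate groups.
#' Fixed seeds make the loss trace reproducible run-to-run.
#'
#' @param model a `fusion_model`.
#' @param prepared a prepared dataset from [prepare_for_model()].
#' @param config a [train_config()].
#' @return List with elements `model` (trained) and `loss_trace`
#'   (per-epoch mean training loss).
#' @export
train_sts <- function(model, prepared, config = train_config()) {
  if (anyNA(prepared$score))
    stop_input("every training record needs a gold score")
  train_loop(model, prepared, config,
             function(s, y, id) list(loss = (s - y)^2, dscore = 2 * (s - y)))
}

#' Train a student model against an ensemble teacher
#'
#' As [train_sts()] but optimizing the teacher-bounded regression loss: the
#' teacher's soft labels pull the student only where the student is worse
#' than the teacher (see [bounded_regression_loss()]).
#'
#' @param model student `fusion_model`.
#' @param prepared prepared dataset from [prepare_for_model()].
#' @param config a [train_config()].
#' @param distill a [distill_config()] with teacher predictions covering
#'   every training record.
#' @return As [train_sts()].
#' @export
distill_sts <- function(model, prepared, config = train_config(),
                        distill) {
  if (anyNA(prepared$score))
    stop_input("every training record needs a gold score")
  tp <- distill$teacher_predictions
  miss <- setdiff(prepared$record_id, names(tp))
  if (length(miss) > 0)
    stop_input(sprintf("missing teacher predictions for %d record(s): %s",
                       length(miss), paste(utils::head(miss, 5), collapse = ", ")))
  m <- distill$margin; nu <- distill$nu
  train_loop(model, prepared, config, function(s, y, id) {
    t_ <- tp[[id]]
    active <- (s - y)^2 + m > (t_ - y)^2
    list(loss = (s - y)^2 + nu * if (active) (s - t_)^2 else 0,
         dscore = 2 * (s - y) + if (active) nu * 2 * (s - t_) else 0)
  })
}

#' Predict scores for a prepared dataset
#'
#' @param model a `fusion_model`.
#' @param prepared prepared dataset from [prepare_for_model()].
#' @param clamp clamp reported scores to \[0, 5\] (the rubric range).
#' @return data.frame with `record_id` and `score`.
#' @export
predict_sts <- function(model, prepared, clamp = TRUE) {
  s <- vapply(prepared$items,
              function(item) fusion_forward_item(model, item)$score, 0)
  if (clamp) s <- clamp(s, 0, 5)
  data.frame(record_id = prepared$record_id, score = s,
             stringsAsFactors = FALSE)
}

#' Ensemble prediction by unweighted averaging
#'
#' Per record, the prediction is the arithmetic mean of the member models'
#' raw scores, clamped to \[0, 5\] after averaging (averaging happens in the
#' models' native output space; the rubric projection is applied last).
#'
#' @param models non-empty list of `fusion_model`s (or any objects accepted
#'   by [predict_sts()] via a shared predict contract).
#' @param prepared either one prepared dataset shared by all members, or a
#'   list of per-member prepared datasets over the same records.
#' @return data.frame with `record_id` and `score`.
#' @export
ensemble_predict <- function(models, prepared) {
  if (length(models) == 0) stop_input("ensemble needs at least one model")
  shared <- !is.null(prepared$items)
  preds <- lapply(seq_along(models), function(i) {
    p <- if (shared) prepared else prepared[[i]]
    predict_sts(models[[i]], p, clamp = FALSE)
  })
  ids <- preds[[1]]$record_id
  for (p in preds)
    if (!identical(p$record_id, ids))
      stop_input("ensemble members predict over different records")
  s <- rowMeans(do.call(cbind, lapply(preds, `[[`, "score")))
  data.frame(record_id = ids, score = clamp(s, 0, 5),
             stringsAsFactors = FALSE)
}

#' Save / load a model checkpoint
#'
#' Single-file parameter archive with an embedded, versioned config
#' manifest.
#'
#' @param model a `fusion_model`.
#' @param path checkpoint path.
#' @return `load_model()` returns the `fusion_model`.
#' @export
save_model <- function(model, path) {
  saveRDS(list(format_version = 1L, package = "graphsts", model = model),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format_version, 1L))
    stop_format(sprintf("unsupported checkpoint format version in '%s'", path))
  obj$model
}
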