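# Small end-to-end fixtures are generated fresh from the synthetic module.
model_fixture <- function(seed = 5L, use_graph = TRUE, mode = "pretrained") {
  corpus <- tiny_corpus(seed = seed)
  sc <- precompute_corpus(corpus$dataset, corpus$lexicon, corpus$graph)
  vocab <- build_vocab(c(sc$dataset$text1, sc$dataset$text2))
  model <- init_fusion_model(
    text_encoder_config(emb_dim = 16L, n_blocks = 1L, max_len = 48L),
    vocab, feature_mode = mode, feature_dim = corpus$embeddings$dim,
    embedding_table = if (mode == "pretrained") corpus$embeddings else NULL,
    graph_hidden = 8L, graph_out = 6L, head_hidden = 8L,
    use_graph = use_graph, seed = seed)
  list(corpus = corpus, sc = sc, vocab = vocab, model = model,
       prepared = prepare_for_model(sc, model))
}

test_that("forward pass equals a step-by-step composition of the encoders", {
  fx <- model_fixture()
  m <- fx$model
  for (i in c(1L, 7L, 20L)) {
    g1 <- fx$sc$graphs1[[i]]; g2 <- fx$sc$graphs2[[i]]
    t1 <- fx$sc$dataset$text1[i]; t2 <- fx$sc$dataset$text2[i]
    got <- fusion_forward(m, t1, t2, g1, g2)
    # independent recomposition from the exported primitives
    tv <- encode_pair(t1, t2, m$text_config, m$text, vocab = m$vocab)
    fe <- function(g) init_node_features(g, m$feature$mode,
                                         table = m$feature$table,
                                         dim = m$feature$dim,
                                         seed = m$feature$seed)
    gv1 <- encode_graph(g1, fe(g1), m$gcn)
    gv2 <- encode_graph(g2, fe(g2), m$gcn)
    z <- c(tv, gv1, gv2, gv1 * gv2, abs(gv1 - gv2))
    s <- sum(pmax(as.numeric(z %*% m$head$Wh) + m$head$bh, 0) * m$head$wo) +
      m$head$bo
    expect_equal(got, s, tolerance = 1e-6)
  }
})

test_that("zero head weights give the bias; empty graphs zero the graph blocks", {
  fx <- model_fixture()
  m <- fx$model
  m$head$Wh[] <- 0
  m$head$wo[] <- 0
  m$head$bo <- 1.25
  g <- fx$sc$graphs1[[1]]
  expect_equal(fusion_forward(m, "any text", "other text", g, g), 1.25)

  # with both graphs empty the score depends only on the text block and bias
  m2 <- fx$model
  empty <- induce_sentence_graph(fx$corpus$graph, character(0))
  s_empty <- fusion_forward(m2, "alpha beta", "beta alpha", empty, empty)
  m3 <- m2
  m3$gcn$layer_weights <- lapply(m3$gcn$layer_weights, function(w) w * 10)
  expect_equal(fusion_forward(m3, "alpha beta", "beta alpha", empty, empty),
               s_empty)
})

test_that("bounded regression loss matches a piecewise oracle on a grid", {
  oracle <- function(s, t, y, m, nu) {
    b <- if ((s - y)^2 + m > (t - y)^2) (s - t)^2 else 0
    (s - y)^2 + nu * b
  }
  grid <- expand.grid(s = seq(0, 5, by = 1.25), t = seq(0, 5, by = 1.25),
                      y = seq(0, 5, by = 1.25), m = c(0, 0.5, 2),
                      nu = c(0, 0.5, 1))
  expect_gte(nrow(grid), 1000)
  got <- with(grid, bounded_regression_loss(s, t, y, m, nu))
  want <- mapply(oracle, grid$s, grid$t, grid$y, grid$m, grid$nu)
  expect_identical(got, unname(want))
  expect_true(all(got >= 0))
  # perfect student: loss 0 regardless of the teacher when m = 0
  expect_equal(bounded_regression_loss(3, 1, 3, m = 0, nu = 7), 0)
  # student strictly better than teacher by more than m: bound inactive
  expect_equal(bounded_regression_loss(3.1, 5, 3, m = 0.5, nu = 7),
               (3.1 - 3)^2)
  expect_error(bounded_regression_loss(1, 1, 1, m = -1),
               class = "graphsts_config_error")
})

test_that("analytic gradients match numerical differentiation", {
  fx <- model_fixture(seed = 11L)
  m <- fx$model
  pr <- fx$prepared
  ns <- asNamespace("graphsts")
  tree0 <- ns$param_tree(m)
  idx <- 1:3
  loss_fn <- function(tree) {
    mm <- ns$set_params(m, tree)
    s <- vapply(pr$items[idx], function(it)
      ns$fusion_forward_item(mm, it)$score, 0)
    mean((s - pr$score[idx])^2)
  }
  grads <- ns$tree_zero(tree0)
  d_text <- m$text_config$output_dim
  d_g <- ncol(m$gcn$layer_weights[[2]])
  for (i in idx) {
    fwd <- ns$fusion_forward_item(m, pr$items[[i]], cache = TRUE)
    ds <- 2 * (fwd$score - pr$score[i]) / length(idx)
    hb <- ns$head_backward(ds, fwd$cache$head, m$head, grads$head)
    grads$head <- hb$grads
    sg <- ns$split_head_grad(hb$dz, d_text, d_g, fwd$cache$gvec1,
                             fwd$cache$gvec2)
    grads$text <- ns$text_backward(sg$dt, fwd$cache$text, m$text, grads$text)
    grads$graph <- ns$graph_backward_cached(sg$dg1, fwd$cache$g1, m$gcn,
                                            grads$graph)
    grads$graph <- ns$graph_backward_cached(sg$dg2, fwd$cache$g2, m$gcn,
                                            grads$graph)
  }
  get_leaf <- function(tr, path) { for (k in path) tr <- tr[[k]]; tr }
  set_leaf <- function(tr, path, val) {
    if (length(path) == 1) tr[[path[[1]]]] <- val
    else tr[[path[[1]]]] <- set_leaf(tr[[path[[1]]]], path[-1], val)
    tr
  }
  paths <- list(list("head", "Wh"), list("head", "wo"), list("head", "bh"),
                list("text", "E"), list("text", "P"),
                list("text", "blocks", 1L, "Wq"),
                list("text", "blocks", 1L, "Wv"),
                list("graph", "W", 1L), list("graph", "W", 2L))
  set.seed(6)
  for (path in paths) {
    leaf <- get_leaf(tree0, path)
    g <- get_leaf(grads, path)
    for (j in sample(length(leaf), 4)) {
      eps <- 1e-5
      lp <- leaf; lp[j] <- lp[j] + eps
      lm <- leaf; lm[j] <- lm[j] - eps
      num <- (loss_fn(set_leaf(tree0, path, lp)) -
                loss_fn(set_leaf(tree0, path, lm))) / (2 * eps)
      expect_equal(g[j], num, tolerance = 1e-5)
    }
  }
})

test_that("a single record can be overfit and training is seed-deterministic", {
  fx <- model_fixture(seed = 8L)
  one <- prepare_for_model(fx$sc, fx$model,
                           ids = fx$sc$dataset$record_id[1])
  cfg <- train_config(epochs = 250L, batch_size = 1L, shuffle_seed = 2L)
  fit <- train_sts(fx$model, one, cfg)
  expect_lt(tail(fit$loss_trace, 1), 1e-2)

  cfg2 <- train_config(epochs = 3L, shuffle_seed = 4L)
  f1 <- train_sts(fx$model, fx$prepared, cfg2)
  f2 <- train_sts(fx$model, fx$prepared, cfg2)
  expect_identical(f1$loss_trace, f2$loss_trace)
  expect_identical(predict_sts(f1$model, fx$prepared),
                   predict_sts(f2$model, fx$prepared))

  # records without gold scores cannot be trained on
  broken <- fx$prepared
  broken$score[2] <- NA
  expect_error(train_sts(fx$model, broken, cfg2),
               class = "graphsts_input_error")
})

test_that("distillation with nu = 0 reduces to plain MSE training", {
  fx <- model_fixture(seed = 13L)
  cfg <- train_config(epochs = 2L, shuffle_seed = 7L)
  teacher <- setNames(rep(2.5, length(fx$prepared$record_id)),
                      fx$prepared$record_id)
  plain <- train_sts(fx$model, fx$prepared, cfg)
  dist <- distill_sts(fx$model, fx$prepared, cfg,
                      distill_config(margin = 0, nu = 0,
                                     teacher_predictions = teacher))
  expect_equal(dist$loss_trace, plain$loss_trace)
  expect_equal(predict_sts(dist$model, fx$prepared),
               predict_sts(plain$model, fx$prepared))
})

test_that("a gold-equal teacher makes the bounded loss dominate plain MSE", {
  # with teacher = gold and m = 0, B = (s - t)^2 whenever the student errs,
  # so the pointwise bounded loss is (1 + nu) * squared error
  s <- seq(-1, 6, by = 0.5)
  y <- rep(2, length(s))
  lb <- bounded_regression_loss(s, teacher = y, gold = y, m = 0, nu = 0.5)
  expect_true(all(lb >= (s - y)^2))
  expect_equal(lb, 1.5 * (s - y)^2)
})

test_that("distillation requires teacher coverage of all records", {
  fx <- model_fixture(seed = 13L)
  teacher <- setNames(rep(2, 3), fx$prepared$record_id[1:3])
  expect_error(
    distill_sts(fx$model, fx$prepared, train_config(epochs = 1L),
                distill_config(teacher_predictions = teacher)),
    class = "graphsts_input_error")
})

test_that("ensembles average raw member scores, then clamp", {
  fx <- model_fixture()
  make_const <- function(value) {
    m <- fx$model
    m$head$Wh[] <- 0; m$head$wo[] <- 0; m$head$bo <- value
    m
  }
  pr <- prepare_for_model(fx$sc, fx$model, ids = fx$sc$dataset$record_id[1:4])
  # one model: the ensemble is that model's prediction
  solo <- ensemble_predict(list(make_const(1.5)), pr)
  expect_equal(solo$score, rep(1.5, 4))
  # k copies of one model: unchanged
  expect_equal(ensemble_predict(rep(list(make_const(1.5)), 5), pr)$score,
               rep(1.5, 4))
  # {1, 2, 6} -> mean 3.0: the raw 6 enters the average before clamping
  trio <- ensemble_predict(list(make_const(1), make_const(2), make_const(6)),
                           pr)
  expect_equal(trio$score, rep(3, 4))
  # but a lone 6 clamps to 5 at reporting
  expect_equal(ensemble_predict(list(make_const(6)), pr)$score, rep(5, 4))
  expect_error(ensemble_predict(list(), pr), class = "graphsts_input_error")
})

test_that("checkpoints round-trip with their config manifest", {
  fx <- model_fixture()
  path <- tempfile(fileext = ".ckpt")
  save_model(fx$model, path)
  back <- load_model(path)
  expect_identical(back$head, fx$model$head)
  expect_identical(back$text_config, fx$model$text_config)
  p1 <- predict_sts(fx$model, fx$prepared)
  expect_identical(predict_sts(back, fx$prepared), p1)
})
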