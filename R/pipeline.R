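# End-to-end plumbing: tag the sentences, augment them with concept names
# and semantic types, induce per-sentence concept graphs, and package
# everything into model-ready items.

#' Precompute the model-independent view of a corpus
#'
#' Tags every sentence with the lexicon, applies the concept augmentation
#' exactly once per record, induces each sentence's concept subgraph from
#' the terminology graph, and caches the normalized propagation operators.
#' The result is shared by all models over the same corpus.
#'
#' @param dataset record data.frame (see [read_sts_dataset()]).
#' @param lexicon_entries lexicon entry data.frame (see [read_lexicon()]).
#' @param graph a `terminology_graph`.
#' @param use_names,use_semtypes augmentation flags (see
#'   [augment_with_concepts()]).
#' @return A `sts_corpus` list: `dataset` (augmented records), `graphs1`,
#'   `graphs2` (per-record induced graphs), `S1`, `S2` (normalized
#'   adjacency matrices).
#' @export
precompute_corpus <- function(dataset, lexicon_entries, graph,
                              use_names = TRUE, use_semtypes = TRUE) {
  lex <- build_lexicon(lexicon_entries)
  n <- nrow(dataset)
  graphs1 <- vector("list", n); graphs2 <- vector("list", n)
  S1 <- vector("list", n); S2 <- vector("list", n)
  cache <- new.env(parent = emptyenv())
  induce_cached <- function(cuis) {
    key <- paste(sort(unique(cuis)), collapse = "|")
    if (!nzchar(key)) key <- "<empty>"
    got <- cache[[key]]
    if (is.null(got)) {
      g <- induce_sentence_graph(graph, cuis)
      got <- list(g = g, S = normalized_adjacency(g$adjacency))
      cache[[key]] <- got
    }
    got
  }
  for (i in seq_len(n)) {
    m1 <- tag_sentence(dataset$text1[i], lex)
    m2 <- tag_sentence(dataset$text2[i], lex)
    dataset[i, ] <- augment_with_concepts(dataset[i, ], m1, m2,
                                          use_names = use_names,
                                          use_semtypes = use_semtypes)
    c1 <- induce_cached(m1$cui); c2 <- induce_cached(m2$cui)
    graphs1[[i]] <- c1$g; S1[[i]] <- c1$S
    graphs2[[i]] <- c2$g; S2[[i]] <- c2$S
  }
  structure(list(dataset = dataset, graphs1 = graphs1, graphs2 = graphs2,
                 S1 = S1, S2 = S2),
            class = "sts_corpus")
}

# Per-CUI feature lookup consistent with init_node_features().
feature_lookup <- function(cuis, feature) {
  out <- matrix(0, length(cuis), feature$dim, dimnames = list(cuis, NULL))
  have <- if (feature$mode == "pretrained")
    cuis %in% rownames(feature$table$vectors) else rep(FALSE, length(cuis))
  if (any(have))
    out[have, ] <- feature$table$vectors[cuis[have], , drop = FALSE]
  for (i in which(!have))
    out[i, ] <- with_seed(string_seed(cuis[i], feature$seed),
                          stats::rnorm(feature$dim) / sqrt(feature$dim))
  out
}

#' Prepare a corpus subset for one model
#'
#' Turns precomputed corpus records into model-ready items: joint token-id
#' sequences under the model's vocabulary, cached propagation operators and
#' node features under the model's initialization mode. Optionally appends
#' reversed-pair copies (sentences swapped, graphs swapped, scores kept) —
#' the training-time dataset doubling.
#'
#' @param corpus an `sts_corpus` from [precompute_corpus()].
#' @param model a `fusion_model`.
#' @param ids record ids to include (default all).
#' @param reverse_double append reversed-pair copies of the subset.
#' @return A `prepared_sts` list: `record_id`, `score`, `category`, `items`.
#' @export
prepare_for_model <- function(corpus, model, ids = NULL,
                              reverse_double = FALSE) {
  dataset <- corpus$dataset
  sel <- if (is.null(ids)) seq_len(nrow(dataset))
         else match(ids, dataset$record_id)
  if (anyNA(sel)) stop_input("ids not present in the corpus")
  all_cuis <- unique(unlist(c(lapply(corpus$graphs1[sel], `[[`, "node_ids"),
                              lapply(corpus$graphs2[sel], `[[`, "node_ids"))))
  lut <- if (length(all_cuis) > 0) feature_lookup(all_cuis, model$feature)
         else matrix(0, 0, model$feature$dim)
  feats <- function(g) {
    if (length(g$node_ids) == 0) return(matrix(0, 0, model$feature$dim))
    lut[g$node_ids, , drop = FALSE]
  }
  make_item <- function(i, rev = FALSE) {
    t1 <- dataset$text1[i]; t2 <- dataset$text2[i]
    if (rev) { tmp <- t1; t1 <- t2; t2 <- tmp }
    g1 <- if (rev) corpus$graphs2[[i]] else corpus$graphs1[[i]]
    g2 <- if (rev) corpus$graphs1[[i]] else corpus$graphs2[[i]]
    s1 <- if (rev) corpus$S2[[i]] else corpus$S1[[i]]
    s2 <- if (rev) corpus$S1[[i]] else corpus$S2[[i]]
    list(ids = pair_token_ids(t1, t2, model$vocab, model$text_config$max_len),
         S1 = s1, S2 = s2, F1 = feats(g1), F2 = feats(g2))
  }
  items <- lapply(sel, make_item)
  record_id <- dataset$record_id[sel]
  score <- dataset$score[sel]
  category <- dataset$category[sel]
  if (reverse_double) {
    items <- c(items, lapply(sel, make_item, rev = TRUE))
    record_id <- c(record_id, paste0(dataset$record_id[sel], ".rev"))
    score <- c(score, score)
    category <- c(category, category)
  }
  structure(list(record_id = record_id, score = score, category = category,
                 items = items),
            class = "prepared_sts")
}

#' Run the synthetic benchmark
#'
#' Generates (or reuses) a synthetic corpus, splits it into train /
#' validation / test, and trains and evaluates the standard model family:
#' the full fusion model with pretrained (spectral) concept embeddings, the
#' same model with random node-feature initialization, the text-only
#' ablation (graph blocks zeroed), and a seed-varied ensemble of full
#' models. Reports held-out test Pearson correlations.
#'
#' @param seed benchmark seed; drives corpus generation, splits, parameter
#'   initialization and shuffling.
#' @param config a [synthetic_config()] (its `seed` is overridden by
#'   `seed`).
#' @param n_test,n_val held-out test and validation sizes.
#' @param epochs training epochs.
#' @param ensemble_size number of seed-varied full models in the ensemble
#'   (0 skips the ensemble).
#' @param outdir where corpus files are written.
#' @param corpus optional pre-generated `synthetic_corpus` to reuse.
#' @return List with the trained models' held-out Pearson correlations
#'   (`r_full`, `r_random_init`, `r_text_only`, `r_ensemble`,
#'   `r_members`), the full model's `eval_report`, and the splits.
#' @export
run_benchmark <- function(seed = 1L, config = synthetic_config(),
                          n_test = 300L, n_val = 300L, epochs = 4L,
                          ensemble_size = 5L,
                          outdir = file.path(tempdir(),
                                             paste0("graphsts_bench_", seed)),
                          corpus = NULL) {
  config$seed <- as.integer(seed)
  if (is.null(corpus)) corpus <- simulate_corpus(config, outdir)
  sc <- precompute_corpus(corpus$dataset, corpus$lexicon, corpus$graph)
  n <- nrow(sc$dataset)
  sp1 <- split_dataset(sc$dataset, n - n_test, n_test, seed = seed)
  test_ids <- sp1$validation$record_id
  sp2 <- split_dataset(sp1$train, nrow(sp1$train) - n_val, n_val,
                       seed = seed + 1L)
  train_ids <- sp2$train$record_id
  vocab <- build_vocab(c(sc$dataset$text1[match(train_ids, sc$dataset$record_id)],
                         sc$dataset$text2[match(train_ids, sc$dataset$record_id)]))
  tcfg <- text_encoder_config()
  d_emb <- corpus$embeddings$dim
  fit_one <- function(mode, use_graph, model_seed) {
    model <- init_fusion_model(tcfg, vocab, feature_mode = mode,
                               feature_dim = d_emb,
                               embedding_table = if (mode == "pretrained")
                                 corpus$embeddings else NULL,
                               use_graph = use_graph, seed = model_seed)
    tr <- prepare_for_model(sc, model, ids = train_ids, reverse_double = TRUE)
    fit <- train_sts(model, tr, train_config(epochs = epochs,
                                             shuffle_seed = model_seed))
    te <- prepare_for_model(sc, fit$model, ids = test_ids)
    preds <- predict_sts(fit$model, te)
    list(model = fit$model, loss_trace = fit$loss_trace, preds = preds,
         report = evaluate(preds, sc$dataset))
  }
  full <- fit_one("pretrained", TRUE, seed)
  rand <- fit_one("random", TRUE, seed)
  text_only <- fit_one("random", FALSE, seed)
  r_members <- numeric(0)
  r_ensemble <- NA_real_
  if (ensemble_size > 0) {
    members <- list(full)
    if (ensemble_size > 1)
      for (k in seq_len(ensemble_size - 1L))
        members[[k + 1L]] <- fit_one("pretrained", TRUE, seed + 100L * k)
    r_members <- vapply(members, function(m) m$report$overall_r, 0)
    shared_te <- prepare_for_model(sc, members[[1]]$model, ids = test_ids)
    ens <- ensemble_predict(lapply(members, `[[`, "model"), shared_te)
    r_ensemble <- evaluate(ens, sc$dataset)$overall_r
  }
  list(r_full = full$report$overall_r,
       r_random_init = rand$report$overall_r,
       r_text_only = text_only$report$overall_r,
       r_ensemble = r_ensemble, r_members = r_members,
       full_report = full$report,
       loss_trace = full$loss_trace,
       train_ids = train_ids, val_ids = sp2$validation$record_id,
       test_ids = test_ids, corpus = corpus)
}
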