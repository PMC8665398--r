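#' Build a token vocabulary
#'
#' Tokens are lowercased alphanumeric runs, ranked by corpus frequency.
#' Ids are dense from 0 with three reserved entries: pad (0), unknown (1)
#' and the sentence-pair separator (2).
#'
#' @param texts character vector of training texts.
#' @param max_size maximum vocabulary size including the reserved entries.
#' @return A `token_vocab`: list with `tokens` (in id order), `index`
#'   (named integer map token -> id), `pad_id`, `unk_id`, `sep_id`.
#' @export
build_vocab <- function(texts, max_size = 5000L) {
  toks <- unlist(lapply(texts, function(t) tokenize_words(t)$token),
                 use.names = FALSE)
  tab <- sort(table(toks), decreasing = TRUE)
  keep <- utils::head(names(tab), max_size - 3L)
  tokens <- c("<pad>", "<unk>", "<sep>", keep)
  index <- seq_along(tokens) - 1L
  names(index) <- tokens
  structure(list(tokens = tokens, index = index, pad_id = 0L, unk_id = 1L,
                 sep_id = 2L), class = "token_vocab")
}

#' Read / write a vocabulary file (one token per line, id = line number - 1)
#' @param path file path.
#' @rdname build_vocab
#' @export
read_vocab <- function(path) {
  tokens <- readLines(path, warn = FALSE)
  index <- seq_along(tokens) - 1L
  names(index) <- tokens
  structure(list(tokens = tokens, index = index, pad_id = 0L, unk_id = 1L,
                 sep_id = 2L), class = "token_vocab")
}

#' @param vocab a `token_vocab`.
#' @rdname build_vocab
#' @export
write_vocab <- function(vocab, path) {
  writeLines(vocab$tokens, path)
  invisible(path)
}

#' Tokenize text to a fixed-length id sequence
#'
#' Lowercased alphanumeric tokenization; unknown tokens map to the unknown
#' id; the sequence is truncated or right-padded to `max_len`.
#'
#' @param text character scalar.
#' @param vocab a `token_vocab`.
#' @param max_len target sequence length.
#' @return Integer vector of length `max_len`.
#' @export
tokenize <- function(text, vocab, max_len = 64L) {
  toks <- tokenize_words(text)$token
  ids <- unname(vocab$index[toks])
  ids[is.na(ids)] <- vocab$unk_id
  ids <- utils::head(ids, max_len)
  c(ids, rep(vocab$pad_id, max_len - length(ids)))
}

# Unpadded joint id sequence for a sentence pair: text1 <sep> text2,
# truncated to max_len.
pair_token_ids <- function(text1, text2, vocab, max_len) {
  t1 <- tokenize_words(text1)$token
  t2 <- tokenize_words(text2)$token
  ids <- unname(vocab$index[c(t1, "<sep>", t2)])
  ids[is.na(ids)] <- vocab$unk_id
  utils::head(ids, max_len)
}

#' Text-encoder configuration
#'
#' The builtin encoder is a small trainable transformer-style model (token
#' plus position embeddings, `n_blocks` single-head self-attention blocks
#' with residual connections, mean pooling); its output dimension equals the
#' embedding dimension. The external adapter delegates to a user-supplied
#' callable with the same contract, the injection point for large pretrained
#' sentence-pair encoders; no checkpoints are bundled.
#'
#' @param encoder_kind `"builtin_small"` or `"external_adapter"`.
#' @param emb_dim embedding (= output) dimension of the builtin encoder.
#' @param n_blocks number of self-attention blocks (0 gives a
#'   bag-of-embeddings encoder).
#' @param max_len maximum joint sequence length for a sentence pair.
#' @param output_dim encoder output dimension.
#' @param checkpoint opaque identifier for an external checkpoint.
#' @return A `text_encoder_config` list.
#' @export
text_encoder_config <- function(encoder_kind = c("builtin_small",
                                                 "external_adapter"),
                                emb_dim = 64L, n_blocks = 2L, max_len = 64L,
                                output_dim = emb_dim, checkpoint = NULL) {
  encoder_kind <- match.arg(encoder_kind)
  if (output_dim <= 0) stop_config("output_dim must be positive")
  if (encoder_kind == "builtin_small" && output_dim != emb_dim)
    stop_config("the builtin encoder's output_dim equals its embedding dim")
  structure(list(encoder_kind = encoder_kind, emb_dim = as.integer(emb_dim),
                 n_blocks = as.integer(n_blocks),
                 max_len = as.integer(max_len),
                 output_dim = as.integer(output_dim),
                 checkpoint = checkpoint),
            class = "text_encoder_config")
}

#' Initialize builtin text-encoder parameters
#'
#' @param config a `text_encoder_config` with `encoder_kind =
#'   "builtin_small"`.
#' @param vocab a `token_vocab`.
#' @param seed integer seed.
#' @return Parameter list: `E` (vocab x dim token embeddings), `P`
#'   (max_len x dim position embeddings), `blocks` (per block: `Wq`, `Wk`,
#'   `Wv` square matrices).
#' @export
init_text_params <- function(config, vocab, seed = 1L) {
  d <- config$emb_dim
  v <- length(vocab$tokens)
  with_seed(seed, {
    params <- list(
      E = matrix(stats::rnorm(v * d, sd = 1 / sqrt(d)), v, d),
      P = matrix(stats::rnorm(config$max_len * d, sd = 0.5 / sqrt(d)),
                 config$max_len, d),
      blocks = lapply(seq_len(config$n_blocks), function(b) {
        s <- 1 / sqrt(d)
        list(Wq = matrix(stats::rnorm(d * d, sd = s), d, d),
             Wk = matrix(stats::rnorm(d * d, sd = s), d, d),
             Wv = matrix(stats::rnorm(d * d, sd = s), d, d))
      }))
    params
  })
}

softmax_rows <- function(x) {
  x <- x - apply(x, 1, max)
  e <- exp(x)
  e / rowSums(e)
}

# Forward pass over an unpadded id sequence; returns the pooled vector and,
# when cache = TRUE, the intermediates needed for the backward pass.
text_forward <- function(ids, params, cache = FALSE) {
  d <- ncol(params$E)
  T_ <- length(ids)
  if (T_ == 0) {
    out <- list(vec = numeric(d))
    if (cache) out$cache <- list(ids = ids)
    return(out)
  }
  X <- params$E[ids + 1L, , drop = FALSE] + params$P[seq_len(T_), , drop = FALSE]
  caches <- list()
  for (b in seq_along(params$blocks)) {
    blk <- params$blocks[[b]]
    Q <- X %*% blk$Wq; K <- X %*% blk$Wk; V <- X %*% blk$Wv
    A <- softmax_rows(Q %*% t(K) / sqrt(d))
    H <- A %*% V
    if (cache) caches[[b]] <- list(X = X, Q = Q, K = K, V = V, A = A)
    X <- X + H
  }
  out <- list(vec = colMeans(X))
  if (cache) out$cache <- list(ids = ids, caches = caches, T_ = T_)
  out
}

# Backward pass; returns parameter gradients accumulated into `grads`
# (a structure shaped like `params`).
text_backward <- function(dvec, cache, params, grads) {
  T_ <- cache$T_
  if (is.null(T_) || T_ == 0) return(grads)
  d <- ncol(params$E)
  dX <- matrix(rep(dvec / T_, each = T_), T_, d)
  for (b in rev(seq_along(params$blocks))) {
    blk <- params$blocks[[b]]
    cc <- cache$caches[[b]]
    dH <- dX                                  # residual: dX flows through both
    dA <- dH %*% t(cc$V)
    dV <- t(cc$A) %*% dH
    grads$blocks[[b]]$Wv <- grads$blocks[[b]]$Wv + t(cc$X) %*% dV
    dXb <- dV %*% t(blk$Wv)
    dS <- cc$A * (dA - rowSums(dA * cc$A))
    dQ <- dS %*% cc$K / sqrt(d)
    dK <- t(dS) %*% cc$Q / sqrt(d)
    grads$blocks[[b]]$Wq <- grads$blocks[[b]]$Wq + t(cc$X) %*% dQ
    grads$blocks[[b]]$Wk <- grads$blocks[[b]]$Wk + t(cc$X) %*% dK
    dXb <- dXb + dQ %*% t(blk$Wq) + dK %*% t(blk$Wk)
    dX <- dX + dXb
  }
  ids1 <- cache$ids + 1L
  for (i in seq_len(T_))
    grads$E[ids1[i], ] <- grads$E[ids1[i], ] + dX[i, ]
  grads$P[seq_len(T_), ] <- grads$P[seq_len(T_), , drop = FALSE] + dX
  grads
}

#' Encode a sentence pair into a fixed-length vector
#'
#' The pair is encoded jointly as one sequence `text1 <sep> text2`, so the
#' attention blocks can relate tokens across the two sentences. Output is
#' deterministic given parameters and inputs. The external adapter requires
#' `parameters$fn`, a callable `(text1, text2) -> numeric(output_dim)`.
#'
#' @param text1,text2 the sentence pair.
#' @param config a `text_encoder_config`.
#' @param parameters builtin parameter list from [init_text_params()], or a
#'   list with element `fn` for the external adapter.
#' @param vocab a `token_vocab` (builtin encoder only).
#' @return Numeric vector of length `config$output_dim`.
#' @export
encode_pair <- function(text1, text2, config, parameters, vocab = NULL) {
  if (config$encoder_kind == "external_adapter") {
    if (is.null(parameters$fn) || !is.function(parameters$fn))
      stop(errorCondition(
        paste("no external text-encoder adapter supplied; provide",
              "parameters$fn or use encoder_kind = 'builtin_small'"),
        class = c("graphsts_capability_error", "graphsts_error")))
    v <- as.numeric(parameters$fn(text1, text2))
    if (length(v) != config$output_dim)
      stop_config("external adapter returned a vector of the wrong length")
    return(v)
  }
  if (is.null(vocab)) stop_config("the builtin encoder requires a vocab")
  ids <- pair_token_ids(text1, text2, vocab, config$max_len)
  text_forward(ids, parameters)$vec
}
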