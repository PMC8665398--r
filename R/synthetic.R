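# Synthetic benchmark generator: a random connected ontology, a synonym
# lexicon, graph-aware concept embeddings and scored sentence pairs whose
# similarity signal is partly reachable only through graph proximity
# (synonym surfaces share a concept node, so lexical overlap alone
# under-measures similarity).

sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 1000003) * 131 + k) %% 2147483647L
}

#' Synthetic benchmark configuration
#'
#' Defaults define the package's standard benchmark conditions: a
#' 200-concept connected ontology, two surface forms per concept, 2000
#' scored pairs, latent similarity weighted 0.3 lexical / 0.7
#' graph-proximity, and Gaussian score noise with sd 0.3 on the 0-5 scale.
#'
#' @param n_concepts number of ontology concepts.
#' @param extra_edge_fraction extra random edges added on top of the
#'   spanning tree, as a fraction of `n_concepts`.
#' @param n_surface_forms surface forms (synonyms) per concept.
#' @param n_fillers size of the filler-token vocabulary.
#' @param n_pairs number of sentence pairs.
#' @param concepts_per_sentence inclusive range of concepts per sentence.
#' @param w_lex,w_graph weights of the lexical-overlap and graph-proximity
#'   components of the latent similarity; must sum to 1.
#' @param sigma sd of the Gaussian noise added to the 0-5 gold score.
#' @param embedding_dim dimension of the generated concept embeddings.
#' @param seed master seed; every random draw derives from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_concepts = 200L, extra_edge_fraction = 0.3,
                             n_surface_forms = 2L, n_fillers = 50L,
                             n_pairs = 2000L,
                             concepts_per_sentence = c(2L, 4L),
                             w_lex = 0.3, w_graph = 0.7, sigma = 0.3,
                             embedding_dim = 16L, seed = 1L) {
  stopifnot(n_concepts >= 2, n_surface_forms >= 1, n_pairs >= 1,
            sigma >= 0, extra_edge_fraction >= 0)
  if (abs(w_lex + w_graph - 1) > 1e-12)
    stop_config("w_lex + w_graph must equal 1")
  structure(list(n_concepts = as.integer(n_concepts),
                 extra_edge_fraction = extra_edge_fraction,
                 n_surface_forms = as.integer(n_surface_forms),
                 n_fillers = as.integer(n_fillers),
                 n_pairs = as.integer(n_pairs),
                 concepts_per_sentence = as.integer(concepts_per_sentence),
                 w_lex = w_lex, w_graph = w_graph, sigma = sigma,
                 embedding_dim = as.integer(embedding_dim),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Decode a Pruefer sequence into tree edges; uniform over labeled trees.
prufer_tree <- function(a, n) {
  if (n == 1) return(matrix(integer(0), 0, 2))
  if (n == 2) return(matrix(c(1L, 2L), 1, 2))
  deg <- tabulate(a, nbins = n) + 1L
  edges <- matrix(0L, n - 1L, 2L)
  k <- 1L
  for (x in a) {
    leaf <- which(deg == 1L)[1]
    edges[k, ] <- c(leaf, x); k <- k + 1L
    deg[leaf] <- 0L
    deg[x] <- deg[x] - 1L
  }
  edges[n - 1L, ] <- which(deg == 1L)
  edges
}

#' Generate a random connected ontology in RRF dialect
#'
#' Builds a uniformly random spanning tree on `n_concepts` (via a random
#' Pruefer sequence) plus `extra_edge_fraction * n_concepts` random extra
#' edges, and serializes it as MRCONSO-/MRREL-dialect files readable by
#' [read_concept_file()] and [read_relation_file()] with the standard
#' column maps. Concept rows carry source tag `"SYNTH_CT"` (plus decoy rows
#' under another source tag, as real concept files mix vocabularies); each
#' edge appears in both directions in the relation file, as released
#' relation files do.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory.
#' @return List with `concept_path`, `relation_path`, `concepts`
#'   (data.frame), `edges` (2-column integer matrix) and `source`
#'   (the source tag to filter on).
#' @export
generate_ontology <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- config$n_concepts
  cuis <- sprintf("C%07d", seq_len(n))
  pnames <- sprintf("pname%04d", seq_len(n))
  edges <- with_seed(sub_seed(config$seed, 1L), {
    tree <- prufer_tree(if (n > 2) sample.int(n, n - 2L, replace = TRUE)
                        else integer(0), n)
    key <- paste(pmin(tree[, 1], tree[, 2]), pmax(tree[, 1], tree[, 2]))
    m_extra <- round(config$extra_edge_fraction * n)
    extra <- matrix(integer(0), 0, 2)
    guard <- 0L
    while (nrow(extra) < m_extra && guard < 50L * m_extra + 100L) {
      guard <- guard + 1L
      uv <- sample.int(n, 2L)
      k <- paste(min(uv), max(uv))
      if (!k %in% key) {
        key <- c(key, k)
        extra <- rbind(extra, sort(uv))
      }
    }
    rbind(tree, extra)
  })
  blank <- function(k) paste(rep("", k), collapse = "|")
  # MRCONSO layout: CUI|LAT|TS|LUI|STT|SUI|ISPREF|AUI|SAUI|SCUI|SDUI|SAB|TTY|CODE|STR|SRL|SUPPRESS|CVF
  conso_row <- function(cui, sab, str)
    paste(cui, "ENG", "P", "", "PF", "", "Y", "", "", "", "", sab, "PT", "",
          str, "0", "N", "", sep = "|")
  conso <- c(vapply(seq_len(n), function(i)
               conso_row(cuis[i], "SYNTH_CT", pnames[i]), ""),
             vapply(seq_len(min(n, 10L)), function(i)
               conso_row(cuis[i], "OTHER_VOC", paste0("alt", pnames[i])), ""))
  concept_path <- file.path(dir, "MRCONSO.RRF")
  writeLines(conso, concept_path)
  # MRREL layout: CUI1|AUI1|STYPE1|REL|CUI2|AUI2|STYPE2|RELA|RUI|SRUI|SAB|SL|RG|DIR|SUPPRESS|CVF
  rel_row <- function(c1, c2)
    paste(c1, "", "CUI", "RO", c2, "", "CUI", "", "", "", "SYNTH_CT", "",
          "", "", "N", "", sep = "|")
  rel <- c(vapply(seq_len(nrow(edges)), function(k)
             rel_row(cuis[edges[k, 1]], cuis[edges[k, 2]]), ""),
           vapply(seq_len(nrow(edges)), function(k)
             rel_row(cuis[edges[k, 2]], cuis[edges[k, 1]]), ""))
  relation_path <- file.path(dir, "MRREL.RRF")
  writeLines(rel, relation_path)
  list(concept_path = concept_path, relation_path = relation_path,
       concepts = data.frame(cui = cuis, preferred_name = pnames,
                             source_vocab = "SYNTH_CT",
                             semantic_types = "", stringsAsFactors = FALSE),
       edges = edges, source = "SYNTH_CT")
}

#' Generate a synonym lexicon for a synthetic ontology
#'
#' Every concept receives `n_surface_forms` distinct single-token surface
#' forms, its preferred name, and one semantic type from a fixed small set.
#' Synonym surfaces share one CUI, so a text-only model cannot equate them
#' lexically while the graph sees a single node.
#'
#' @param config a [synthetic_config()].
#' @param ontology result of [generate_ontology()].
#' @param dir output directory.
#' @return List with `lexicon_path` and `entries` (lexicon data.frame).
#' @export
generate_lexicon <- function(config, ontology, dir) {
  n <- config$n_concepts
  k <- config$n_surface_forms
  semset <- c("ClinicalFinding", "Procedure", "PharmacologicSubstance",
              "BodyStructure")
  sem <- with_seed(sub_seed(config$seed, 2L),
                   sample(semset, n, replace = TRUE))
  entries <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(surface = sprintf("s%04d%s", i, letters[seq_len(k)]),
               cui = ontology$concepts$cui[i],
               preferred_name = ontology$concepts$preferred_name[i],
               semantic_types = sem[i], stringsAsFactors = FALSE)
  }))
  lexicon_path <- file.path(dir, "lexicon.tsv")
  write_lexicon(entries, lexicon_path)
  list(lexicon_path = lexicon_path, entries = entries)
}

#' Generate graph-aware concept embeddings
#'
#' Node coordinates from a spectral layout of the ontology (eigenvectors of
#' the graph Laplacian for the smallest nontrivial eigenvalues, diffusion
#' scaled), so that graph-nearby concepts receive similar vectors — a
#' self-contained stand-in for pretrained knowledge-graph embeddings,
#' written in word2vec text format.
#'
#' @param config a [synthetic_config()].
#' @param ontology result of [generate_ontology()].
#' @param dir output directory.
#' @return List with `embedding_path` and the `embedding_table`.
#' @export
generate_embeddings <- function(config, ontology, dir) {
  n <- config$n_concepts
  d <- config$embedding_dim
  A <- matrix(0, n, n)
  A[ontology$edges] <- 1
  A[ontology$edges[, c(2, 1), drop = FALSE]] <- 1
  L <- diag(rowSums(A)) - A
  eg <- eigen(L, symmetric = TRUE)
  d_eff <- min(d, n - 1L)
  # columns ordered by decreasing eigenvalue; smallest nontrivial ones are
  # at positions (n-1):(n-d_eff)
  idx <- seq(n - 1L, n - d_eff)
  vec <- eg$vectors[, idx, drop = FALSE]
  val <- eg$values[idx]
  # deterministic sign: largest-magnitude entry positive
  for (j in seq_len(ncol(vec))) {
    pivot <- which.max(abs(vec[, j]))
    if (vec[pivot, j] < 0) vec[, j] <- -vec[, j]
  }
  vec <- sweep(vec, 2, 1 / sqrt(pmax(val, 1e-8)), `*`)
  vec <- vec / max(abs(vec))
  if (d_eff < d) vec <- cbind(vec, matrix(0, n, d - d_eff))
  rownames(vec) <- ontology$concepts$cui
  embedding_path <- file.path(dir, "embeddings.txt")
  write_embeddings(vec, embedding_path)
  list(embedding_path = embedding_path,
       table = structure(list(dim = d, vectors = vec),
                         class = "embedding_table"))
}

#' Generate scored sentence pairs with a planted graph signal
#'
#' For each pair, two concept sets with controlled overlap/proximity are
#' sampled and rendered as filler tokens interleaved with randomly chosen
#' surface forms. The latent similarity is
#' `w_lex * J + w_graph * G`, with `J` the Jaccard overlap of the rendered
#' surface-token multisets and `G` the mean over cross-set concept pairs of
#' `1 / (1 + shortest-path distance)`; the gold score is
#' `clamp(5 * latent + Normal(0, sigma), 0, 5)`. Categories are assigned
#' round-robin (they exist to exercise the per-category evaluator, not to
#' carry meaning).
#'
#' @param config a [synthetic_config()].
#' @param ontology result of [generate_ontology()].
#' @param lexicon result of [generate_lexicon()].
#' @param dir output directory.
#' @return List with `dataset_path`, `manifest_path`, `dataset`
#'   (record data.frame) and `manifest` (per-pair latent components).
#' @export
generate_pairs <- function(config, ontology, lexicon, dir) {
  n <- config$n_concepts
  graph <- build_graph(ontology$concepts,
                       data.frame(cui1 = ontology$concepts$cui[ontology$edges[, 1]],
                                  cui2 = ontology$concepts$cui[ontology$edges[, 2]],
                                  rel_label = "RO", stringsAsFactors = FALSE))
  dist <- bfs_distance_matrix(graph, seq_len(n))
  near2 <- lapply(seq_len(n), function(i) which(dist[i, ] <= 2L))
  surfaces <- matrix(lexicon$entries$surface, nrow = config$n_surface_forms)
  # column i = surfaces of concept i
  fillers <- sprintf("w%03d", seq_len(config$n_fillers))
  cats <- c("status", "education", "meds", "miscellaneous")
  lo <- config$concepts_per_sentence[1]
  hi <- config$concepts_per_sentence[2]
  rows <- with_seed(sub_seed(config$seed, 3L), lapply(seq_len(config$n_pairs),
    function(i) {
      k1 <- sample(lo:hi, 1L)
      s1 <- sample.int(n, k1)
      alpha <- stats::runif(1)
      k2 <- sample(lo:hi, 1L)
      s2 <- unique(vapply(seq_len(k2), function(j) {
        if (stats::runif(1) < alpha) {
          anchor <- s1[sample.int(length(s1), 1L)]
          cand <- near2[[anchor]]
          cand[sample.int(length(cand), 1L)]
        } else sample.int(n, 1L)
      }, 0L))
      render <- function(cset) {
        surf <- vapply(cset, function(c_)
          surfaces[sample.int(nrow(surfaces), 1L), c_], "")
        fill <- sample(fillers, sample(3:6, 1L), replace = TRUE)
        toks <- c(surf, fill)
        list(text = paste(toks[sample.int(length(toks))], collapse = " "),
             surf = surf)
      }
      r1 <- render(s1); r2 <- render(s2)
      jn <- sum(!is.na(match(r1$surf, r2$surf)))
      j <- jn / (length(r1$surf) + length(r2$surf) - jn)
      g <- mean(1 / (1 + dist[s1, s2, drop = FALSE]))
      latent <- config$w_lex * j + config$w_graph * g
      gold <- clamp(5 * latent + stats::rnorm(1, 0, config$sigma), 0, 5)
      list(text1 = r1$text, text2 = r2$text, score = gold,
           category = cats[(i - 1L) %% 4L + 1L], j = j, g = g,
           latent = latent)
    }))
  dataset <- data.frame(
    record_id = sprintf("r%04d", seq_len(config$n_pairs)),
    text1 = vapply(rows, `[[`, "", "text1"),
    text2 = vapply(rows, `[[`, "", "text2"),
    score = round(vapply(rows, `[[`, 0, "score"), 6),
    category = vapply(rows, `[[`, "", "category"),
    stringsAsFactors = FALSE)
  dataset_path <- file.path(dir, "dataset.tsv")
  write_sts_dataset(dataset, dataset_path)
  manifest <- data.frame(record_id = dataset$record_id,
                         latent = vapply(rows, `[[`, 0, "latent"),
                         lexical_j = vapply(rows, `[[`, 0, "j"),
                         graph_g = vapply(rows, `[[`, 0, "g"),
                         stringsAsFactors = FALSE)
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, digits = NA, dataframe = "rows")
  list(dataset_path = dataset_path, manifest_path = manifest_path,
       dataset = dataset, manifest = manifest)
}

#' Generate a complete synthetic corpus
#'
#' Runs [generate_ontology()], [generate_lexicon()],
#' [generate_embeddings()] and [generate_pairs()], then reads every file
#' back through the package's own readers, returning the round-tripped
#' objects alongside the paths.
#'
#' @param config a [synthetic_config()].
#' @param outdir output directory (created if needed).
#' @return A `synthetic_corpus` list: `config`, file paths, `graph`
#'   (terminology graph re-read from the RRF files), `lexicon` (entries),
#'   `embeddings` (`embedding_table`), `dataset` (records re-read from the
#'   TSV) and `manifest`.
#' @export
simulate_corpus <- function(config = synthetic_config(), outdir = tempdir()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ont <- generate_ontology(config, outdir)
  lex <- generate_lexicon(config, ont, outdir)
  emb <- generate_embeddings(config, ont, outdir)
  pairs <- generate_pairs(config, ont, lex, outdir)
  concepts <- read_concept_file(ont$concept_path, ont$source)
  relations <- read_relation_file(ont$relation_path, concepts$cui)
  graph <- build_graph(concepts, relations)
  structure(list(config = config,
                 paths = list(concept = ont$concept_path,
                              relation = ont$relation_path,
                              lexicon = lex$lexicon_path,
                              embeddings = emb$embedding_path,
                              dataset = pairs$dataset_path,
                              manifest = pairs$manifest_path),
                 graph = graph,
                 lexicon = read_lexicon(lex$lexicon_path),
                 embeddings = read_embeddings(emb$embedding_path),
                 dataset = read_sts_dataset(pairs$dataset_path),
                 manifest = pairs$manifest),
            class = "synthetic_corpus")
}
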