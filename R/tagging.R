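#' Build a longest-match lexicon index
#'
#' The index backs the built-in dictionary tagger used in place of an
#' external concept tagger: surfaces are matched case-insensitively on token
#' boundaries, longest surface first. Duplicate surfaces keep the first
#' entry.
#'
#' @param entries data.frame with columns `surface`, `cui`, `preferred_name`,
#'   `semantic_types` (semicolon-joined).
#' @return A `lexicon` object supporting [tag_sentence()].
#' @export
build_lexicon <- function(entries) {
  if (nrow(entries) == 0) {
    return(structure(list(entries = entries, keys = character(0),
                          max_tokens = 0L), class = "lexicon"))
  }
  surf <- tolower(gsub("\\s+", " ", trimws(entries$surface)))
  stopifnot(all(nzchar(surf)))
  first <- !duplicated(surf)
  entries <- entries[first, , drop = FALSE]
  surf <- surf[first]
  toks <- lapply(surf, function(s) tokenize_words(s)$token)
  keys <- vapply(toks, paste, "", collapse = " ")
  structure(list(entries = entries, keys = keys,
                 max_tokens = max(vapply(toks, length, 0L))),
            class = "lexicon")
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf("lexicon: %d surfaces (longest = %d tokens)\n",
              length(x$keys), x$max_tokens))
  invisible(x)
}

# Word tokenization on non-alphanumeric boundaries, with 0-based half-open
# character offsets into the original string.
tokenize_words <- function(text) {
  m <- gregexpr("[[:alnum:]]+", text)[[1]]
  if (m[1] == -1)
    return(data.frame(token = character(0), start = integer(0),
                      end = integer(0)))
  start <- as.integer(m) - 1L
  end <- start + attr(m, "match.length")
  data.frame(token = tolower(regmatches(text, list(m))[[1]]),
             start = start, end = end, stringsAsFactors = FALSE)
}

empty_mentions <- function() {
  data.frame(start = integer(0), end = integer(0), matched_text = character(0),
             cui = character(0), preferred_name = character(0),
             semantic_types = character(0), stringsAsFactors = FALSE)
}

#' Tag a sentence with lexicon concepts
#'
#' Case-insensitive, token-boundary, left-to-right, longest-match-first,
#' non-overlapping matching. Offsets are 0-based half-open character
#' positions into the original sentence.
#'
#' @param sentence character scalar.
#' @param lexicon a `lexicon` from [build_lexicon()].
#' @return data.frame of mentions: `start`, `end`, `matched_text`, `cui`,
#'   `preferred_name`, `semantic_types`, sorted by `start`.
#' @export
tag_sentence <- function(sentence, lexicon) {
  toks <- tokenize_words(sentence)
  n <- nrow(toks)
  if (n == 0 || lexicon$max_tokens == 0) return(empty_mentions())
  out <- vector("list", n)
  k <- 0L
  i <- 1L
  while (i <= n) {
    hit <- 0L
    for (j in min(n, i + lexicon$max_tokens - 1L):i) {
      key <- paste(toks$token[i:j], collapse = " ")
      pos <- match(key, lexicon$keys)
      if (!is.na(pos)) { hit <- pos; hit_j <- j; break }
    }
    if (hit > 0L) {
      e <- lexicon$entries[hit, ]
      k <- k + 1L
      out[[k]] <- data.frame(
        start = toks$start[i], end = toks$end[hit_j],
        matched_text = substr(sentence, toks$start[i] + 1L, toks$end[hit_j]),
        cui = e$cui, preferred_name = e$preferred_name,
        semantic_types = e$semantic_types, stringsAsFactors = FALSE)
      i <- hit_j + 1L
    } else i <- i + 1L
  }
  if (k == 0L) return(empty_mentions())
  do.call(rbind, out[seq_len(k)])
}

#' Read / write a lexicon file
#'
#' TSV dialect: `surface TAB cui TAB preferred_name TAB semtype[;semtype...]`.
#'
#' @param path file path.
#' @return `read_lexicon()` returns the entry data.frame (not yet indexed).
#' @export
read_lexicon <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(surface = character(0), cui = character(0),
                      preferred_name = character(0),
                      semantic_types = character(0), stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(f, length, 0L) < 4L)
  if (length(short) > 0)
    stop_format("lexicon row needs 4 tab-separated fields", line = short[1],
                path = path)
  data.frame(surface = vapply(f, `[[`, "", 1), cui = vapply(f, `[[`, "", 2),
             preferred_name = vapply(f, `[[`, "", 3),
             semantic_types = vapply(f, `[[`, "", 4), stringsAsFactors = FALSE)
}

#' @param entries lexicon entry data.frame.
#' @rdname read_lexicon
#' @export
write_lexicon <- function(entries, path) {
  writeLines(paste(entries$surface, entries$cui, entries$preferred_name,
                   entries$semantic_types, sep = "\t"), path)
  invisible(path)
}

#' Parse external-tagger output
#'
#' Consumes concept-tagger exports in this package's TSV dialect:
#' `sentence_id TAB start TAB end TAB matched_text TAB cui TAB
#' preferred_name TAB semtype[;semtype...]`. When `sentences` (a named
#' character vector keyed by sentence id) is supplied, each mention's
#' `matched_text` is validated against the sentence slice.
#'
#' @param path tagger-output file path.
#' @param sentences optional named character vector of sentence texts.
#' @return Named list mapping sentence id to a mention data.frame as
#'   returned by [tag_sentence()].
#' @export
parse_tagger_output <- function(path, sentences = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines)
  lnum <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) return(list())
  f <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(f)) {
    if (length(f[[i]]) < 7L)
      stop_format("tagger-output row needs 7 tab-separated fields",
                  line = lnum[i], path = path)
  }
  start <- suppressWarnings(as.integer(vapply(f, `[[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(f, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) | start < 0L | end <= start)
  if (length(bad) > 0)
    stop_format("tagger-output offsets must satisfy 0 <= start < end",
                line = lnum[bad[1]], path = path)
  df <- data.frame(sentence_id = vapply(f, `[[`, "", 1), start = start,
                   end = end, matched_text = vapply(f, `[[`, "", 4),
                   cui = vapply(f, `[[`, "", 5),
                   preferred_name = vapply(f, `[[`, "", 6),
                   semantic_types = vapply(f, `[[`, "", 7),
                   stringsAsFactors = FALSE)
  if (!is.null(sentences)) {
    for (i in seq_len(nrow(df))) {
      sid <- df$sentence_id[i]
      if (!sid %in% names(sentences)) next
      s <- sentences[[sid]]
      if (df$end[i] > nchar(s) ||
          substr(s, df$start[i] + 1L, df$end[i]) != df$matched_text[i])
        stop_format(sprintf("mention text does not match sentence '%s' slice", sid),
                    line = lnum[i], path = path)
    }
  }
  ids <- unique(df$sentence_id)
  out <- lapply(ids, function(sid) {
    sub <- df[df$sentence_id == sid,
              c("start", "end", "matched_text", "cui", "preferred_name",
                "semantic_types"), drop = FALSE]
    rownames(sub) <- NULL
    sub[order(sub$start), , drop = FALSE]
  })
  names(out) <- ids
  out
}

#' Write tagger output for a set of sentences
#'
#' Runs [tag_sentence()] over each sentence and writes the TSV dialect read
#' back by [parse_tagger_output()].
#'
#' @param sentences named character vector (names are sentence ids).
#' @param lexicon a `lexicon`.
#' @param path output path.
#' @export
write_tagger_output <- function(sentences, lexicon, path) {
  rows <- character(0)
  for (sid in names(sentences)) {
    m <- tag_sentence(sentences[[sid]], lexicon)
    if (nrow(m) > 0)
      rows <- c(rows, paste(sid, m$start, m$end, m$matched_text, m$cui,
                            m$preferred_name, m$semantic_types, sep = "\t"))
  }
  writeLines(rows, path)
  invisible(path)
}
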