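#' Read / write a sentence-pair dataset
#'
#' TSV layout: `text1 TAB text2 TAB score[ TAB category]`; score may be empty
#' for unscored inference input. Record ids are assigned from the row number
#' on read unless an `record_id` column is written (controlled by `with_ids`).
#'
#' @param path file path.
#' @param with_ids whether the first column holds record ids.
#' @return data.frame with columns `record_id`, `text1`, `text2`, `score`
#'   (numeric, NA when absent) and `category` (NA when absent).
#' @export
read_sts_dataset <- function(path, with_ids = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(record_id = character(0), text1 = character(0),
                      text2 = character(0), score = numeric(0),
                      category = character(0), stringsAsFactors = FALSE)
  if (length(lines) == 0) return(empty)
  f <- strsplit(lines, "\t", fixed = TRUE)
  need <- if (with_ids) 3L else 2L
  short <- which(vapply(f, length, 0L) < need)
  if (length(short) > 0)
    stop_format(sprintf("dataset row needs at least %d tab-separated fields", need),
                line = short[1], path = path)
  get <- function(i, k) if (length(f[[i]]) >= k) f[[i]][[k]] else ""
  off <- if (with_ids) 1L else 0L
  n <- length(f)
  ids <- if (with_ids) vapply(f, `[[`, "", 1) else sprintf("r%04d", seq_len(n))
  score <- suppressWarnings(as.numeric(vapply(seq_len(n), get, "", off + 3L)))
  if (any(!is.na(score) & (score < 0 | score > 5)))
    stop_format("scores must lie in [0, 5]", path = path)
  cat_ <- vapply(seq_len(n), get, "", off + 4L)
  data.frame(record_id = ids,
             text1 = vapply(seq_len(n), get, "", off + 1L),
             text2 = vapply(seq_len(n), get, "", off + 2L),
             score = score,
             category = ifelse(nzchar(cat_), cat_, NA_character_),
             stringsAsFactors = FALSE)
}

#' @param dataset record data.frame as returned by [read_sts_dataset()].
#' @rdname read_sts_dataset
#' @export
write_sts_dataset <- function(dataset, path, with_ids = FALSE) {
  score <- ifelse(is.na(dataset$score), "",
                  formatC(dataset$score, format = "g", digits = 15))
  cat_ <- ifelse(is.na(dataset$category), "", dataset$category)
  body <- paste(dataset$text1, dataset$text2, score, cat_, sep = "\t")
  body <- sub("\t+$", "", body)
  if (with_ids) body <- paste(dataset$record_id, body, sep = "\t")
  writeLines(body, path)
  invisible(path)
}

append_unique <- function(text, pieces) {
  pieces <- pieces[nzchar(pieces)]
  pieces <- pieces[!duplicated(pieces)]
  if (length(pieces) == 0) return(text)
  paste(c(text, pieces), collapse = " ")
}

#' Concept-based sentence augmentation
#'
#' Appends, after the original sentence text, the preferred names of the
#' tagged concepts (in mention order) and then their semantic-type names, as
#' plain space-separated strings. Preferred names supply synonym and
#' abbreviation expansions (e.g. "pacu" carries its full preferred name into
#' the sentence); semantic types add coarse category cues. Duplicates within
#' one sentence's appended block are dropped, keeping first occurrence.
#' Scores and categories are never modified.
#'
#' @param record one-row record data.frame (see [read_sts_dataset()]).
#' @param mentions1,mentions2 mention data.frames for `text1` / `text2`.
#' @param use_names append preferred names.
#' @param use_semtypes append semantic-type names.
#' @return The augmented one-row record.
#' @export
augment_with_concepts <- function(record, mentions1, mentions2,
                                  use_names = TRUE, use_semtypes = TRUE) {
  if (!use_names && !use_semtypes) return(record)
  aug <- function(text, m) {
    pieces <- character(0)
    if (use_names && nrow(m) > 0)
      pieces <- c(pieces, m$preferred_name[!duplicated(m$preferred_name)])
    if (use_semtypes && nrow(m) > 0) {
      st <- unlist(lapply(m$semantic_types, split_semtypes), use.names = FALSE)
      pieces <- c(pieces, st[!duplicated(st)])
    }
    append_unique(text, pieces)
  }
  record$text1 <- aug(record$text1, mentions1)
  record$text2 <- aug(record$text2, mentions2)
  record
}

#' Augment every record of a dataset with tagged concepts
#'
#' Tags both sentences of each record with the lexicon and applies
#' [augment_with_concepts()] exactly once per record.
#'
#' @param dataset record data.frame.
#' @param lexicon a `lexicon` from [build_lexicon()].
#' @inheritParams augment_with_concepts
#' @return The augmented dataset.
#' @export
augment_dataset <- function(dataset, lexicon, use_names = TRUE,
                            use_semtypes = TRUE) {
  if (!use_names && !use_semtypes) return(dataset)
  for (i in seq_len(nrow(dataset))) {
    dataset[i, ] <- augment_with_concepts(
      dataset[i, ], tag_sentence(dataset$text1[i], lexicon),
      tag_sentence(dataset$text2[i], lexicon),
      use_names = use_names, use_semtypes = use_semtypes)
  }
  dataset
}

#' Reverse-pair dataset doubling
#'
#' Appends to the dataset a copy of every record with the two sentences
#' swapped, preserving scores and categories — an explicit hint that the
#' similarity task is agnostic to sentence order. Record ids of the copies
#' get a `.rev` suffix to stay unique.
#'
#' @param dataset record data.frame.
#' @return A data.frame with `2 * nrow(dataset)` rows: originals first, then
#'   the reversed copies in the same order.
#' @export
reverse_pair_double <- function(dataset) {
  if (nrow(dataset) == 0) return(dataset)
  rev <- dataset
  rev$text1 <- dataset$text2
  rev$text2 <- dataset$text1
  rev$record_id <- paste0(dataset$record_id, ".rev")
  out <- rbind(dataset, rev)
  rownames(out) <- NULL
  out
}
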