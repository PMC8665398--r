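#' Column maps for RRF-dialect files
#'
#' UMLS release files are pipe-delimited with fixed column positions. The
#' defaults follow the standard MRCONSO / MRREL layouts (1-based positions:
#' CUI = 1, SAB = 12, STR = 15 for concept rows; CUI1 = 1, REL = 4, CUI2 = 5
#' for relation rows). Miniature fixtures can remap positions.
#'
#' @param cui,sab,str 1-based column positions of the concept identifier,
#'   source-vocabulary tag and preferred-name string in a concept file.
#' @param stys optional column position of a semicolon-joined semantic-type
#'   field (not part of standard MRCONSO; provided for compact dialects).
#' @return A named list of integer column positions.
#' @export
rrf_concept_columns <- function(cui = 1L, sab = 12L, str = 15L, stys = NULL) {
  out <- list(cui = as.integer(cui), sab = as.integer(sab),
              str = as.integer(str))
  if (!is.null(stys)) out$stys <- as.integer(stys)
  out
}

#' @param cui1,rel,cui2 1-based column positions of the two endpoint concept
#'   identifiers and the relation label in a relation file.
#' @rdname rrf_concept_columns
#' @export
rrf_relation_columns <- function(cui1 = 1L, rel = 4L, cui2 = 5L) {
  list(cui1 = as.integer(cui1), rel = as.integer(rel), cui2 = as.integer(cui2))
}

read_rrf_rows <- function(path, max_col) {
  if (!file.exists(path)) stop_format(sprintf("cannot read RRF file '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(list())
  fields <- strsplit(lines, "|", fixed = TRUE)
  short <- which(vapply(fields, length, 0L) < max_col)
  if (length(short) > 0)
    stop_format(sprintf("row has fewer than %d pipe-delimited columns", max_col),
                line = short[1], path = path)
  fields
}

#' Read a concept (MRCONSO-dialect) file
#'
#' Retains rows whose source-vocabulary field equals `source_filter`, keeping
#' one entry per CUI (first occurrence wins) in order of first appearance.
#'
#' @param path path to a pipe-delimited concept file.
#' @param source_filter source vocabulary to retain (e.g. `"SNOMEDCT_US"`).
#' @param columns column map from [rrf_concept_columns()].
#' @return A data.frame with columns `cui`, `preferred_name`, `source_vocab`
#'   and `semantic_types` (semicolon-joined, empty unless the dialect carries
#'   a semantic-type column).
#' @export
read_concept_file <- function(path, source_filter,
                              columns = rrf_concept_columns()) {
  fields <- read_rrf_rows(path, max(unlist(columns)))
  empty <- data.frame(cui = character(0), preferred_name = character(0),
                      source_vocab = character(0), semantic_types = character(0),
                      stringsAsFactors = FALSE)
  if (length(fields) == 0) return(empty)
  cui <- vapply(fields, `[[`, "", columns$cui)
  sab <- vapply(fields, `[[`, "", columns$sab)
  str <- vapply(fields, `[[`, "", columns$str)
  sty <- if (!is.null(columns$stys)) vapply(fields, `[[`, "", columns$stys)
         else rep("", length(fields))
  keep <- sab == source_filter & nzchar(cui)
  cui <- cui[keep]; str <- str[keep]; sab <- sab[keep]; sty <- sty[keep]
  first <- !duplicated(cui)
  data.frame(cui = cui[first], preferred_name = str[first],
             source_vocab = sab[first], semantic_types = sty[first],
             stringsAsFactors = FALSE)
}

#' Read a relation (MRREL-dialect) file
#'
#' Retains rows whose both endpoints lie in `concept_ids`, with self-loops
#' removed. Duplicate and reciprocal rows are NOT collapsed here; that
#' happens in [build_graph()].
#'
#' @param path path to a pipe-delimited relation file.
#' @param concept_ids character vector of admissible concept identifiers.
#' @param columns column map from [rrf_relation_columns()].
#' @return A data.frame with columns `cui1`, `cui2`, `rel_label`.
#' @export
read_relation_file <- function(path, concept_ids,
                               columns = rrf_relation_columns()) {
  fields <- read_rrf_rows(path, max(unlist(columns)))
  empty <- data.frame(cui1 = character(0), cui2 = character(0),
                      rel_label = character(0), stringsAsFactors = FALSE)
  if (length(fields) == 0) return(empty)
  cui1 <- vapply(fields, `[[`, "", columns$cui1)
  cui2 <- vapply(fields, `[[`, "", columns$cui2)
  rel <- vapply(fields, `[[`, "", columns$rel)
  keep <- cui1 != cui2 & cui1 %in% concept_ids & cui2 %in% concept_ids
  data.frame(cui1 = cui1[keep], cui2 = cui2[keep], rel_label = rel[keep],
             stringsAsFactors = FALSE)
}
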