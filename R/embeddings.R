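#' Read / write concept embeddings (word2vec-style text)
#'
#' Format: optional header line `n dim`, then one `cui v1 v2 ... vd` line per
#' concept, space-separated. All vectors must share one dimension.
#'
#' @param path file path.
#' @return An `embedding_table`: list with `dim` (integer) and `vectors`
#'   (numeric matrix, one row per CUI, rownames = CUIs).
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop_format(sprintf("empty embedding file '%s'", path))
  f <- strsplit(trimws(lines), "[[:space:]]+")
  # header: two numeric tokens
  if (length(f[[1]]) == 2 && !anyNA(suppressWarnings(as.numeric(f[[1]]))))
    f <- f[-1]
  if (length(f) == 0) stop_format(sprintf("no vectors in embedding file '%s'", path))
  d <- length(f[[1]]) - 1L
  bad <- which(vapply(f, length, 0L) != d + 1L)
  if (length(bad) > 0)
    stop_format("embedding rows have inconsistent dimensions", line = bad[1],
                path = path)
  ids <- vapply(f, `[[`, "", 1)
  vec <- t(vapply(f, function(r) as.numeric(r[-1]), numeric(d)))
  if (anyNA(vec)) stop_format("non-numeric embedding value", path = path)
  rownames(vec) <- ids
  structure(list(dim = d, vectors = vec), class = "embedding_table")
}

#' @param table an `embedding_table` (or a numeric matrix with CUI rownames).
#' @param header write the `n dim` header line.
#' @rdname read_embeddings
#' @export
write_embeddings <- function(table, path, header = TRUE) {
  vec <- if (inherits(table, "embedding_table")) table$vectors else table
  lines <- paste(rownames(vec),
                 apply(vec, 1, function(r)
                   paste(formatC(r, format = "g", digits = 8), collapse = " ")))
  if (header) lines <- c(sprintf("%d %d", nrow(vec), ncol(vec)), lines)
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("embedding_table: %d concepts x %d dims\n",
              nrow(x$vectors), x$dim))
  invisible(x)
}
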