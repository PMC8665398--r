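# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stop_format <- function(msg, line = NULL, path = NULL) {
  loc <- if (!is.null(line)) sprintf(" (line %d%s)", line,
                                     if (!is.null(path)) paste0(" of ", path) else "")
         else ""
  stop(errorCondition(paste0(msg, loc),
                      class = c("graphsts_format_error", "graphsts_error")))
}

#' @keywords internal
stop_config <- function(msg) {
  stop(errorCondition(msg, class = c("graphsts_config_error", "graphsts_error")))
}

#' @keywords internal
stop_input <- function(msg) {
  stop(errorCondition(msg, class = c("graphsts_input_error", "graphsts_error")))
}

# Deterministic 31-bit seed derived from a string and a base seed; keeps
# per-concept random draws reproducible independently of draw order.
#' @keywords internal
string_seed <- function(x, seed) {
  h <- 0
  for (v in utf8ToInt(x)) h <- (h * 131 + v) %% 2147483647L
  as.integer((h + as.numeric(seed) * 7919) %% 2147483647)
}

# Evaluate an expression under a temporary RNG state.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @keywords internal
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Split a semicolon-joined semantic-type field into a character vector.
#' @keywords internal
split_semtypes <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
}
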