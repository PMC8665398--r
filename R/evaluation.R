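#' Pearson correlation coefficient
#'
#' Standard product-moment correlation, the task's evaluation metric.
#' Undefined cases (fewer than 2 observations, or a constant vector) raise
#' an error rather than returning 0, so that missing correlations never
#' silently enter comparisons.
#'
#' @param predictions,golds equal-length numeric vectors.
#' @return Real in \[-1, 1\].
#' @export
pearson <- function(predictions, golds) {
  if (length(predictions) != length(golds))
    stop_input("prediction and gold vectors differ in length")
  if (length(predictions) < 2)
    stop(errorCondition("Pearson correlation undefined for fewer than 2 observations",
                        class = c("graphsts_undefined_correlation", "graphsts_error")))
  if (stats::sd(predictions) == 0 || stats::sd(golds) == 0)
    stop(errorCondition("Pearson correlation undefined for a constant vector",
                        class = c("graphsts_undefined_correlation", "graphsts_error")))
  stats::cor(predictions, golds, method = "pearson")
}

#' Evaluate predictions overall and per category
#'
#' Computes the Pearson correlation on all records and on each category
#' subset; a subset with fewer than 2 members or constant golds/predictions
#' is reported as missing (`NA`), never coerced to 0. Category labels are
#' given dataset labels, never inferred.
#'
#' @param predictions data.frame with `record_id`, `score`.
#' @param dataset record data.frame with gold `score`s (and optional
#'   `category`).
#' @return An `eval_report`: list with `overall_r`, `n_overall`,
#'   `per_category_r` (named numeric, NA = missing) and `per_category_n`.
#' @export
evaluate <- function(predictions, dataset) {
  idx <- match(predictions$record_id, dataset$record_id)
  if (anyNA(idx))
    stop_input(sprintf("predictions reference unknown record id(s): %s",
                       paste(utils::head(predictions$record_id[is.na(idx)], 5),
                             collapse = ", ")))
  gold <- dataset$score[idx]
  cat_ <- dataset$category[idx]
  safe_r <- function(p, g) {
    tryCatch(pearson(p, g),
             graphsts_undefined_correlation = function(e) NA_real_)
  }
  cats <- sort(unique(cat_[!is.na(cat_)]))
  per_r <- vapply(cats, function(cc) {
    sel <- !is.na(cat_) & cat_ == cc
    safe_r(predictions$score[sel], gold[sel])
  }, 0)
  per_n <- vapply(cats, function(cc) sum(!is.na(cat_) & cat_ == cc), 0L)
  structure(list(overall_r = safe_r(predictions$score, gold),
                 n_overall = length(gold),
                 per_category_r = per_r, per_category_n = per_n),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: overall r = %s (n = %d)\n",
              formatC(x$overall_r, digits = 4, format = "f"), x$n_overall))
  if (length(x$per_category_r) > 0) {
    w <- max(nchar(names(x$per_category_r)))
    for (cc in names(x$per_category_r))
      cat(sprintf("  %-*s r = %s (n = %d)\n", w, cc,
                  ifelse(is.na(x$per_category_r[[cc]]), "NA",
                         formatC(x$per_category_r[[cc]], digits = 4,
                                 format = "f")),
                  x$per_category_n[[cc]]))
  }
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report an `eval_report`.
#' @param path output path.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(list(overall_r = report$overall_r,
                            n_overall = report$n_overall,
                            per_category_r = as.list(report$per_category_r),
                            per_category_n = as.list(report$per_category_n)),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Seeded train/validation split
#'
#' Seeded shuffle followed by a prefix split; the two parts are disjoint and
#' exhaustive.
#'
#' @param dataset record data.frame.
#' @param train_n,val_n part sizes; must sum to `nrow(dataset)`.
#' @param seed shuffle seed.
#' @return List with data.frames `train` and `validation`.
#' @export
split_dataset <- function(dataset, train_n, val_n, seed = 1L) {
  n <- nrow(dataset)
  if (train_n + val_n != n)
    stop_input(sprintf("train_n + val_n (%d) must equal the dataset size (%d)",
                       train_n + val_n, n))
  ord <- with_seed(seed, sample.int(n))
  tr <- dataset[ord[seq_len(train_n)], , drop = FALSE]
  va <- dataset[ord[train_n + seq_len(val_n)], , drop = FALSE]
  rownames(tr) <- rownames(va) <- NULL
  list(train = tr, validation = va)
}
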