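#' Confusion matrix over the five sleep stages
#'
#' Rows are human-scored labels, columns are predicted labels, both in
#' the canonical order (W, N1, N2, N3, REM); cell `(i, j)` counts epochs
#' of true stage `i` predicted as stage `j`.
#'
#' @param truth,pred character vectors (or factors) of stages, equal length.
#' @return A 5x5 integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(truth, pred) {
  if (length(truth) != length(pred))
    abort(sprintf("truth (%d) and pred (%d) differ in length", length(truth), length(pred)))
  if (length(truth) == 0) abort("cannot build a confusion matrix from zero epochs")
  t_f <- stage_factor(as.character(truth))
  p_f <- stage_factor(as.character(pred))
  cm <- unclass(table(t_f, p_f))
  dimnames(cm) <- list(truth = sleep_stages, predicted = sleep_stages)
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Row-normalise a confusion matrix
#'
#' Converts counts to per-row proportions (the empirical probability that
#' stage `i` is predicted as stage `j`); empty rows stay zero.
#'
#' @param cm a [confusion_matrix()].
#' @return A 5x5 numeric matrix with unit row sums for non-empty rows.
#' @export
row_normalize <- function(cm) {
  rs <- rowSums(cm)
  out <- sweep(unclass(cm), 1, pmax(rs, 1), "/")
  out[rs == 0, ] <- 0
  out
}

#' Overall agreement metrics
#'
#' `accuracy()` is the fraction of correctly scored epochs;
#' `cohens_kappa()` is the chance-corrected agreement
#' `(p_o - p_e) / (1 - p_e)` with `p_e` from the row/column marginals;
#' `macro_f1()` is the unweighted mean of the per-class F1 scores, where
#' a class counts as 0 when precision + recall is 0 and classes that are
#' empty in both the truth rows and the prediction columns are excluded
#' from the mean.
#'
#' @param cm a [confusion_matrix()].
#' @return A scalar.
#' @export
accuracy <- function(cm) {
  n <- sum(cm)
  if (n == 0) abort("empty confusion matrix")
  sum(diag(cm)) / n
}

#' @rdname accuracy
#' @export
cohens_kappa <- function(cm) {
  n <- sum(cm)
  if (n == 0) abort("empty confusion matrix")
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - pe) < 1e-15) {
    if (po >= 1 - 1e-15) return(1)
    abort("kappa undefined: expected agreement is 1 but observed agreement is not")
  }
  (po - pe) / (1 - pe)
}

#' @rdname accuracy
#' @export
macro_f1 <- function(cm) {
  n <- sum(cm)
  if (n == 0) abort("empty confusion matrix")
  f1 <- per_class_f1(cm)
  keep <- !(rowSums(cm) == 0 & colSums(cm) == 0)
  mean(f1[keep])
}

#' Per-class recall and F1
#'
#' Recall is the diagonal over the truth row sum (the per-class accuracy
#' of the scorer); F1 combines it with precision (diagonal over the
#' prediction column sum).  Classes absent from the truth get `NaN`
#' recall and 0 F1 unless also never predicted.
#'
#' @param cm a [confusion_matrix()].
#' @return Named numeric vector over the five stages.
#' @export
per_class_recall <- function(cm) {
  stats::setNames(diag(cm) / rowSums(cm), sleep_stages)
}

#' @rdname per_class_recall
#' @export
per_class_f1 <- function(cm) {
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  stats::setNames(f1, sleep_stages)
}

#' Full metrics report for one set of predictions
#'
#' @param truth,pred stage vectors, equal length (scored epochs only).
#' @return A one-row tibble: `n_epochs`, `accuracy`, `kappa`, `mf1`, and
#'   per-class recall columns `recall_W ... recall_REM`.
#' @export
staging_metrics <- function(truth, pred) {
  cm <- confusion_matrix(truth, pred)
  rec <- per_class_recall(cm)
  out <- tibble(n_epochs = sum(cm), accuracy = accuracy(cm),
                kappa = cohens_kappa(cm), mf1 = macro_f1(cm))
  for (s in sleep_stages) out[[paste0("recall_", s)]] <- unname(rec[s])
  out
}

#' Stable / transitional epoch split
#'
#' An epoch is *stable* if both its immediate neighbours exist within the
#' record and carry the same label; otherwise it is *transitional*.  The
#' first and last epochs of a record are therefore always transitional,
#' keeping the partition exhaustive.
#'
#' @param stages character vector of stages for one record, in temporal
#'   order.
#' @return Character vector (`"stable"` / `"transitional"`), same length.
#' @export
stability_split <- function(stages) {
  stages <- as.character(stages)
  n <- length(stages)
  if (n == 0) return(character(0))
  out <- rep("transitional", n)
  if (n >= 3) {
    i <- 2:(n - 1)
    stable <- stages[i] == stages[i - 1] & stages[i] == stages[i + 1]
    out[i][stable] <- "stable"
  }
  out
}

#' Per-record metrics
#'
#' Computes one metrics row per PSG record (by-record statistics, as used
#' for boxplots).  Per-class recall is reported as `NA` (not 0) for
#' stages absent from that record's human scoring, and the per-record
#' macro-F1 averages only over stages present in the truth.
#'
#' @param df data frame with columns `record_id`, `truth`, `pred`.
#' @return A tibble with one row per record.
#' @export
by_record_metrics <- function(df) {
  stopifnot(all(c("record_id", "truth", "pred") %in% names(df)))
  dplyr::group_by(df, .data$record_id) |>
    dplyr::group_modify(function(d, key) {
      cm <- confusion_matrix(d$truth, d$pred)
      present <- rowSums(cm) > 0
      rec <- per_class_recall(cm)
      rec[!present] <- NA_real_
      f1 <- per_class_f1(cm)
      out <- tibble(n_epochs = sum(cm), accuracy = accuracy(cm),
                    kappa = cohens_kappa(cm), mf1 = mean(f1[present]))
      for (s in sleep_stages) out[[paste0("recall_", s)]] <- unname(rec[s])
      out
    }) |>
    dplyr::ungroup()
}

#' Write a metrics report as JSON
#'
#' Schema-versioned JSON with the overall metrics and the confusion
#' counts.
#'
#' @param truth,pred stage vectors.
#' @param path output path.
#' @param extra optional named list merged into the report.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(truth, pred, path, extra = NULL) {
  cm <- confusion_matrix(truth, pred)
  rep <- c(list(schema = "nocturnet-metrics-1"),
           as.list(staging_metrics(truth, pred)),
           list(confusion = unclass(cm)), extra)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a confusion matrix as labelled CSV
#'
#' 6x6 layout: header row and first column carry the stage labels.
#'
#' @param cm a [confusion_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_confusion_csv <- function(cm, path) {
  df <- data.frame(truth = sleep_stages, unclass(cm), check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %d epochs, accuracy %.3f\n", sum(x), accuracy(x)))
  print(unclass(x))
  invisible(x)
}
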