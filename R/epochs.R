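#' Align a preprocessed recording with its hypnogram into 30-s epochs
#'
#' Epoch `i` (0-based) covers samples `[i*3750, (i+1)*3750)` of the
#' 125 Hz recording.  The dataset keeps the tensors of *all* epochs
#' (including `UNSCORED` ones, which remain available as temporal context
#' for their neighbours) but only scored epochs count as samples: they
#' appear in `class_counts` and are used for training and evaluation.
#' If the hypnogram is longer than the signal the extra labels are dropped
#' with a warning; if the signal is longer, trailing samples are ignored.
#'
#' @param rec a [psg_record] preprocessed to 125 Hz.
#' @param hyp a [hypnogram] for the same recording.
#' @return An object of class `psg_epochs`: list with `x` (array
#'   `5 x 3750 x n`, channels in canonical order), `meta` (tibble with
#'   `record_id`, `epoch`, `stage`, `scored`), and `class_counts`.
#' @export
epoch_record <- function(rec, hyp) {
  stopifnot(inherits(rec, "psg_record"))
  if (any(abs(rec$srate - target_rate_hz) > 1e-6))
    abort("epoch_record expects a recording preprocessed to 125 Hz")
  stages <- hypnogram_stages(hyp)
  spe <- samples_per_epoch()
  sig_len <- min(lengths(rec$signals))
  n_full <- sig_len %/% spe
  if (length(stages) > n_full) {
    warn(sprintf("hypnogram (%d epochs) longer than signal (%d full epochs); truncating",
                 length(stages), n_full))
  }
  n <- min(length(stages), n_full)
  if (n < 1) abort("recording shorter than one 30-s epoch")
  stages <- stages[seq_len(n)]
  x <- array(0, dim = c(5L, spe, n))
  for (k in seq_along(psg_channels)) {
    s <- rec$signals[[psg_channels[k]]]
    x[k, , ] <- s[seq_len(n * spe)]
  }
  scored <- stages %in% sleep_stages
  if (!any(scored)) abort("no scored epochs retained (all UNSCORED)")
  meta <- tibble(record_id = rec$record_id,
                 epoch = seq_len(n) - 1L,
                 stage = stages,
                 scored = scored)
  new_psg_epochs(x, meta)
}

new_psg_epochs <- function(x, meta) {
  cc <- table(factor(meta$stage[meta$scored], levels = sleep_stages))
  structure(list(x = x, meta = meta,
                 class_counts = stats::setNames(as.integer(cc), sleep_stages)),
            class = "psg_epochs")
}

#' Number of scored epochs in a dataset
#' @param ds a `psg_epochs` dataset.
#' @export
n_scored <- function(ds) sum(ds$meta$scored)

#' Concatenate epoch datasets from several recordings
#'
#' Record boundaries are preserved through the `record_id` column, so
#' context windows never cross recordings.
#'
#' @param ... `psg_epochs` objects (or a single list of them).
#' @return A `psg_epochs` dataset.
#' @export
bind_epochs <- function(...) {
  dss <- list(...)
  if (length(dss) == 1 && !inherits(dss[[1]], "psg_epochs")) dss <- dss[[1]]
  stopifnot(all(vapply(dss, inherits, logical(1), "psg_epochs")))
  x <- array(0, dim = c(5L, dim(dss[[1]]$x)[2], sum(vapply(dss, function(d) dim(d$x)[3], numeric(1)))))
  at <- 0L
  for (d in dss) {
    n <- dim(d$x)[3]
    x[, , at + seq_len(n)] <- d$x
    at <- at + n
  }
  new_psg_epochs(x, dplyr::bind_rows(lapply(dss, function(d) d$meta)))
}

#' Subset an epoch dataset to selected recordings
#'
#' @param ds a `psg_epochs` dataset.
#' @param record_ids character vector of record identifiers to keep.
#' @return A `psg_epochs` dataset containing only those recordings.
#' @export
subset_record <- function(ds, record_ids) {
  stopifnot(inherits(ds, "psg_epochs"))
  rows <- which(ds$meta$record_id %in% record_ids)
  if (length(rows) == 0) abort("no matching records in dataset")
  new_psg_epochs(ds$x[, , rows, drop = FALSE], ds$meta[rows, ])
}

#' Epoch an unlabeled recording for inference
#'
#' Cuts a preprocessed recording into 30-s epochs without a hypnogram
#' (all epochs marked `UNSCORED`), for staging new data with
#' [predict.stagenet()].
#'
#' @param rec a [psg_record] preprocessed to 125 Hz.
#' @return A `psg_epochs` dataset with no scored epochs.
#' @export
epoch_signal <- function(rec) {
  stopifnot(inherits(rec, "psg_record"))
  spe <- samples_per_epoch()
  n <- min(lengths(rec$signals)) %/% spe
  if (n < 1) abort("recording shorter than one 30-s epoch")
  x <- array(0, dim = c(5L, spe, n))
  for (k in seq_along(psg_channels)) x[k, , ] <- rec$signals[[psg_channels[k]]][seq_len(n * spe)]
  new_psg_epochs(x, tibble(record_id = rec$record_id, epoch = seq_len(n) - 1L,
                           stage = "UNSCORED", scored = FALSE))
}

#' Extract the context window around one epoch
#'
#' Returns the `2N+1` epoch tensors centred on the requested epoch, in
#' temporal order.  Context uses raw temporal adjacency within the record
#' (unscored neighbours included); positions before the start or after the
#' end of the record are filled by replicating the record's first or last
#' epoch.
#'
#' @param ds a `psg_epochs` dataset.
#' @param record_id which recording.
#' @param epoch_index 0-based epoch index within that recording.
#' @param n_context number of epochs on each side (default 2).
#' @return List with `center_index`, `indices` (0-based epoch indices after
#'   edge clamping) and `tensors` (`5 x 3750 x (2N+1)` array).
#' @export
context_window <- function(ds, record_id, epoch_index, n_context = 2) {
  stopifnot(inherits(ds, "psg_epochs"), n_context >= 0)
  rows <- which(ds$meta$record_id == record_id)
  if (length(rows) == 0) abort(sprintf("record '%s' not in dataset", record_id))
  pos <- match(epoch_index, ds$meta$epoch[rows])
  if (is.na(pos)) abort(sprintf("epoch %d not present in record '%s'", epoch_index, record_id))
  rel <- (pos - n_context):(pos + n_context)
  rel <- pmin(pmax(rel, 1L), length(rows))
  idx <- rows[rel]
  list(center_index = epoch_index,
       indices = ds$meta$epoch[idx],
       tensors = ds$x[, , idx, drop = FALSE])
}

#' @export
print.psg_epochs <- function(x, ...) {
  cc <- x$class_counts
  cat(sprintf("<psg_epochs> %d epochs (%d scored) from %d record(s)\n",
              nrow(x$meta), sum(x$meta$scored), length(unique(x$meta$record_id))))
  cat("  ", paste(sprintf("%s=%d", names(cc), cc), collapse = " "), "\n")
  invisible(x)
}
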