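#' Hypnogram objects
#'
#' A hypnogram is the sequence of sleep/wake stage labels, one per
#' 30-second epoch.  `hypnogram()` builds one from a character vector of
#' stage tokens (`W`, `N1`, `N2`, `N3`, `REM`, optionally `UNSCORED`); the
#' result is a tibble with columns `epoch` (0-based integer) and `stage`
#' (factor) carrying class `"hypnogram"`.
#'
#' @param stages character vector of stage tokens, one per epoch.
#' @return A tibble of class `hypnogram` with columns `epoch` and `stage`.
#' @examples
#' hypnogram(c("W", "N1", "N2", "N2", "REM"))
#' @export
hypnogram <- function(stages) {
  if (length(stages) < 1) abort("a hypnogram must contain at least one epoch")
  out <- tibble(
    epoch = seq_along(stages) - 1L,
    stage = stage_factor(stages, allow_unscored = TRUE)
  )
  class(out) <- c("hypnogram", class(out))
  out
}

#' Read / write hypnogram CSV files
#'
#' The hypnogram CSV dialect has a header `epoch,stage`, a 0-based integer
#' epoch index, and one row per 30-second epoch with stage tokens in
#' `W`, `N1`, `N2`, `N3`, `REM`, `UNSCORED`.
#'
#' @param path file path.
#' @return `read_hypnogram()` returns a [hypnogram] tibble;
#'   `write_hypnogram()` returns `path` invisibly.
#' @export
read_hypnogram <- function(path) {
  if (!file.exists(path)) abort(sprintf("hypnogram file not found: %s", path))
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) abort(sprintf("cannot parse %s: %s", path, conditionMessage(e))))
  if (nrow(df) == 0) abort(sprintf("hypnogram file %s contains no epochs", path))
  if (!all(c("epoch", "stage") %in% names(df)))
    abort(sprintf("hypnogram file %s must have header 'epoch,stage'", path))
  bad <- which(!(df$stage %in% hypnogram_tokens))
  if (length(bad) > 0) {
    abort(sprintf("unknown stage token '%s' at line %d of %s",
                  df$stage[bad[1]], bad[1] + 1L, path))
  }
  if (!identical(as.integer(df$epoch), seq_len(nrow(df)) - 1L))
    abort(sprintf("epoch column of %s must be 0,1,2,... in order", path))
  hypnogram(df$stage)
}

#' @param hyp a [hypnogram] (or character vector of stages).
#' @rdname read_hypnogram
#' @export
write_hypnogram <- function(hyp, path) {
  stages <- hypnogram_stages(hyp)
  df <- data.frame(epoch = seq_along(stages) - 1L, stage = stages)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Accept a hypnogram tibble or a bare character vector of stages.
hypnogram_stages <- function(hyp) {
  if (is.data.frame(hyp)) {
    if (!("stage" %in% names(hyp))) abort("hypnogram data frame needs a 'stage' column")
    as.character(hyp$stage)
  } else {
    assert_stages(as.character(hyp), allow_unscored = TRUE)
  }
}

#' @export
print.hypnogram <- function(x, ...) {
  st <- table(factor(as.character(x$stage), levels = hypnogram_tokens))
  cat(sprintf("<hypnogram> %d epochs (%.1f h): %s\n",
              nrow(x), nrow(x) * epoch_length_s / 3600,
              paste(sprintf("%s=%d", names(st), st), collapse = " ")))
  invisible(x)
}
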