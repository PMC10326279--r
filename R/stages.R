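#' Canonical sleep stages and PSG channels
#'
#' The five AASM sleep/wake stages in the fixed order used throughout the
#' package (`W`, `N1`, `N2`, `N3`, `REM`), and the canonical five-channel
#' PSG montage (`C3`, `C4`, `EOGL`, `EOGR`, `EMG`).  All stage vectors,
#' probability matrices and confusion matrices follow this order; argmax
#' ties are broken towards the earlier stage in this order.
#'
#' @format `sleep_stages` is a character vector of length 5;
#'   `psg_channels` is a character vector of length 5.
#' @export
sleep_stages <- c("W", "N1", "N2", "N3", "REM")

#' @rdname sleep_stages
#' @export
psg_channels <- c("C3", "C4", "EOGL", "EOGR", "EMG")

# Tokens allowed in hypnogram files: the 5 stages plus UNSCORED.
hypnogram_tokens <- c(sleep_stages, "UNSCORED")

#' Epoch geometry constants
#'
#' Scored PSG is divided into 30-second epochs; after preprocessing all
#' channels are sampled at 125 Hz, so one epoch holds 3750 samples per
#' channel.
#'
#' @name epoch_geometry
#' @export
epoch_length_s <- 30

#' @rdname epoch_geometry
#' @export
target_rate_hz <- 125

samples_per_epoch <- function(rate = target_rate_hz) as.integer(round(epoch_length_s * rate))

assert_stages <- function(x, allow_unscored = FALSE, arg = "stages") {
  ok <- if (allow_unscored) hypnogram_tokens else sleep_stages
  x <- as.character(x)
  bad <- !(x %in% ok)
  if (any(bad)) {
    abort(sprintf("%s contains invalid stage token(s): %s (allowed: %s)",
                  arg, paste(unique(x[bad]), collapse = ", "),
                  paste(ok, collapse = ", ")))
  }
  x
}

stage_factor <- function(x, allow_unscored = FALSE) {
  factor(assert_stages(x, allow_unscored),
         levels = if (allow_unscored) hypnogram_tokens else sleep_stages)
}
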