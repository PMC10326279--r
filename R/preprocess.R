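#' Preprocessing configuration
#'
#' Defaults follow standard PSG practice for staging models: EEG and EOG
#' are band-passed 0.3-35 Hz, chin EMG is high-passed at 10 Hz, amplitudes
#' are clipped to +/-500 uV, and all channels are resampled to 125 Hz.
#' No normalisation or artifact rejection is applied beyond this.
#'
#' @param eeg_band length-2 numeric, EEG/EOG band edges in Hz.
#' @param emg_highpass EMG high-pass edge in Hz.
#' @param clip_uv clipping amplitude in uV (hard saturation at +/- this value).
#' @param target_rate output sampling rate in Hz.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(eeg_band = c(0.3, 35), emg_highpass = 10,
                              clip_uv = 500, target_rate = 125) {
  stopifnot(length(eeg_band) == 2, eeg_band[1] > 0, eeg_band[2] > eeg_band[1],
            emg_highpass > 0, clip_uv > 0, target_rate > 0)
  structure(list(eeg_band = as.numeric(eeg_band),
                 emg_highpass = as.numeric(emg_highpass),
                 clip_uv = as.numeric(clip_uv),
                 target_rate = as.numeric(target_rate)),
            class = "preprocess_config")
}

#' Load a preprocessing configuration from YAML
#'
#' Reads keys `eeg_band`, `emg_highpass`, `clip_uv`, `target_rate`;
#' missing keys fall back to the defaults of [preprocess_config()].
#'
#' @param path YAML file path.
#' @return A `preprocess_config`.
#' @export
read_preprocess_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("eeg_band", "emg_highpass", "clip_uv", "target_rate")
  bad <- setdiff(names(y), known)
  if (length(bad) > 0) abort(sprintf("unknown preprocessing key(s): %s", paste(bad, collapse = ", ")))
  do.call(preprocess_config, y)
}

# Zero-phase forward-backward Butterworth filtering. Band-pass is realised
# as cascaded 4th-order high-pass and low-pass sections; the very low
# normalised high-pass edge (0.3 Hz) stays numerically safe at order 4.
zero_phase_filter <- function(x, fs, high = NULL, low = NULL) {
  if (!is.null(high)) {
    hp <- signal::butter(4, high / (fs / 2), type = "high")
    x <- signal::filtfilt(hp, x)
  }
  if (!is.null(low)) {
    lp <- signal::butter(4, low / (fs / 2), type = "low")
    x <- signal::filtfilt(lp, x)
  }
  x
}

# Rational approximation p/q of a rate ratio for polyphase resampling.
rate_ratio <- function(from, to, max_den = 1024) {
  r <- to / from
  best <- c(1L, 1L); err <- Inf
  for (q in seq_len(max_den)) {
    p <- round(r * q)
    if (p < 1) next
    e <- abs(p / q - r)
    if (e < err - 1e-15) { err <- e; best <- c(as.integer(p), as.integer(q)) }
    if (err < 1e-12) break
  }
  if (err > 1e-6) abort(sprintf("cannot express rate ratio %g/%g as a small rational", to, from))
  best
}

#' Preprocess a PSG recording
#'
#' Applies, in order: zero-phase Butterworth filtering (EEG/EOG band-pass
#' `eeg_band`, EMG high-pass `emg_highpass`), hard amplitude clipping at
#' `+/- clip_uv`, and polyphase resampling of every channel to
#' `target_rate`.  Input sampling rates must be at least 70 Hz so that the
#' 35 Hz EEG band is representable.
#'
#' @param rec a [psg_record].
#' @param cfg a [preprocess_config()].
#' @return A [psg_record] with all channels at `cfg$target_rate` Hz.
#' @export
preprocess_psg <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "psg_record"))
  if (!inherits(cfg, "preprocess_config")) abort("cfg must be a preprocess_config")
  out <- rec$signals
  for (ch in psg_channels) {
    x <- rec$signals[[ch]]
    fs <- rec$srate[[ch]]
    if (!all(is.finite(x))) abort(sprintf("channel %s contains non-finite samples", ch))
    if (fs < 70) abort(sprintf("channel %s sampled at %g Hz; at least 70 Hz required", ch, fs))
    if (ch == "EMG") {
      x <- zero_phase_filter(x, fs, high = cfg$emg_highpass)
    } else {
      x <- zero_phase_filter(x, fs, high = cfg$eeg_band[1], low = cfg$eeg_band[2])
    }
    x <- pmin(cfg$clip_uv, pmax(-cfg$clip_uv, x))
    if (abs(fs - cfg$target_rate) > 1e-9) {
      pq <- rate_ratio(fs, cfg$target_rate)
      x <- as.numeric(signal::resample(x, pq[1], pq[2]))
      # polyphase output length can differ by a sample; pin to the exact count
      n_out <- round(length(rec$signals[[ch]]) * cfg$target_rate / fs)
      if (length(x) > n_out) x <- x[seq_len(n_out)]
      if (length(x) < n_out) x <- c(x, rep(x[length(x)], n_out - length(x)))
      # resampling can overshoot at sharp edges; the clip bound is a contract
      x <- pmin(cfg$clip_uv, pmax(-cfg$clip_uv, x))
    }
    out[[ch]] <- x
  }
  psg_record(rec$record_id, out,
             srate = stats::setNames(rep(cfg$target_rate, 5), psg_channels),
             start_time = rec$start_time)
}
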