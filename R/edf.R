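#' PSG recording objects
#'
#' A `psg_record` holds the five canonical polysomnography channels
#' (`C3`, `C4`, `EOGL`, `EOGR`, `EMG`) as numeric vectors in microvolts,
#' with a per-channel sampling rate in Hz.  Before preprocessing the rates
#' may differ between channels; [preprocess_psg()] brings everything to a
#' common 125 Hz.
#'
#' @param record_id character scalar identifying the recording.
#' @param signals named list of numeric vectors (one per canonical channel).
#' @param srate named numeric vector of sampling rates (Hz), same names.
#' @param start_time optional character timestamp.
#' @return An object of class `psg_record`.
#' @export
psg_record <- function(record_id, signals, srate, start_time = NULL) {
  if (!all(psg_channels %in% names(signals)))
    abort(sprintf("signals must contain channels %s", paste(psg_channels, collapse = ", ")))
  signals <- signals[psg_channels]
  srate <- srate[psg_channels]
  for (ch in psg_channels) {
    if (!all(is.finite(signals[[ch]])))
      abort(sprintf("channel %s contains non-finite samples", ch))
    if (!is.finite(srate[[ch]]) || srate[[ch]] <= 0)
      abort(sprintf("channel %s has invalid sampling rate", ch))
  }
  structure(list(record_id = as.character(record_id), signals = signals,
                 srate = srate, start_time = start_time),
            class = "psg_record")
}

#' @export
print.psg_record <- function(x, ...) {
  cat(sprintf("<psg_record> %s\n", x$record_id))
  for (ch in psg_channels) {
    cat(sprintf("  %-5s %8d samples @ %g Hz (%.1f s)\n", ch,
                length(x$signals[[ch]]), x$srate[[ch]],
                length(x$signals[[ch]]) / x$srate[[ch]]))
  }
  invisible(x)
}

# ---- minimal EDF (16-bit European Data Format) reader / writer ----------
# EDF stores ASCII headers (256 bytes + 256 per signal) followed by data
# records of little-endian int16 samples; physical values are recovered by
# the linear map between the digital and physical min/max of each signal.

edf_pad <- function(x, n) {
  x <- as.character(x)
  if (nchar(x) > n) x <- substr(x, 1, n)
  formatC(x, width = -n)
}

edf_num <- function(x, n) {
  s <- if (abs(x - round(x)) < 1e-9) sprintf("%d", as.integer(round(x)))
       else formatC(x, digits = 6, format = "g")
  if (nchar(s) > n) abort(sprintf("EDF header field overflow: %s", s))
  edf_pad(s, n)
}

#' Write a PSG recording to an EDF file
#'
#' Signals are quantised to 16 bits over a symmetric physical range covering
#' each channel (physical dimension `uV`), using one-second data records.
#' Every channel must contain a whole number of seconds; trailing partial
#' seconds are truncated with a warning.
#'
#' @param rec a [psg_record].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "psg_record"))
  rates <- rec$srate
  if (any(abs(rates - round(rates)) > 1e-9))
    abort("write_edf requires integer sampling rates per channel")
  n_sec <- floor(min(vapply(psg_channels, function(ch)
    length(rec$signals[[ch]]) / rates[[ch]], numeric(1))))
  if (n_sec < 1) abort("recording shorter than one EDF data record (1 s)")
  if (any(vapply(psg_channels, function(ch)
    length(rec$signals[[ch]]) > n_sec * rates[[ch]], logical(1))))
    warn("write_edf: truncating channels to a whole number of seconds")

  ns <- length(psg_channels)
  pr <- vapply(psg_channels, function(ch) {
    m <- max(1, max(abs(rec$signals[[ch]]), na.rm = TRUE))
    ceiling(m)
  }, numeric(1))
  dmin <- -32768; dmax <- 32767

  con <- tryCatch(file(path, "wb"), error = function(e)
    abort(sprintf("cannot open %s for writing: %s", path, conditionMessage(e))))
  on.exit(close(con))
  wchar <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  # fixed header (256 bytes)
  wchar(edf_pad("0", 8))
  wchar(edf_pad(rec$record_id, 80))
  wchar(edf_pad(sprintf("Startdate X nocturnet simulated"), 80))
  wchar(edf_pad("01.01.00", 8))
  wchar(edf_pad(if (is.null(rec$start_time)) "00.00.00" else rec$start_time, 8))
  wchar(edf_num(256 + 256 * ns, 8))
  wchar(edf_pad("", 44))
  wchar(edf_num(n_sec, 8))
  wchar(edf_num(1, 8))
  wchar(edf_num(ns, 4))
  # signal headers (256 bytes per signal, field-major)
  for (ch in psg_channels) wchar(edf_pad(ch, 16))
  for (ch in psg_channels) wchar(edf_pad("simulated", 80))
  for (ch in psg_channels) wchar(edf_pad("uV", 8))
  for (ch in psg_channels) wchar(edf_num(-pr[[ch]], 8))
  for (ch in psg_channels) wchar(edf_num(pr[[ch]], 8))
  for (ch in psg_channels) wchar(edf_num(dmin, 8))
  for (ch in psg_channels) wchar(edf_num(dmax, 8))
  for (ch in psg_channels) wchar(edf_pad("", 80))
  for (ch in psg_channels) wchar(edf_num(rates[[ch]], 8))
  for (ch in psg_channels) wchar(edf_pad("", 32))
  # data records: per second, per signal
  dig <- lapply(psg_channels, function(ch) {
    x <- rec$signals[[ch]][seq_len(n_sec * rates[[ch]])]
    d <- round((x + pr[[ch]]) / (2 * pr[[ch]]) * (dmax - dmin) + dmin)
    as.integer(pmin(dmax, pmax(dmin, d)))
  })
  for (s in seq_len(n_sec)) {
    for (i in seq_along(psg_channels)) {
      r <- rates[[psg_channels[i]]]
      writeBin(dig[[i]][((s - 1) * r + 1):(s * r)], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read a five-channel PSG recording from an EDF file
#'
#' Reads EDF/EDF+ continuous recordings, converts amplitudes to microvolts
#' and maps channel labels onto the canonical montage
#' `C3, C4, EOGL, EOGR, EMG`.  `channel_map` is a named character vector
#' `c("EEG C3-A2" = "C3", ...)` translating the labels found in the file to
#' canonical names; canonical labels in the file are recognised without a
#' map.  Missing canonical channels or non-voltage physical dimensions are
#' errors.
#'
#' @param path EDF file path.
#' @param channel_map named character vector, file label to canonical label.
#' @return A [psg_record] with original per-channel sampling rates, in uV.
#' @export
read_edf <- function(path, channel_map = NULL) {
  if (!file.exists(path)) abort(sprintf("EDF file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  rstr <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rnum <- function(n) as.numeric(rstr(n))
  version <- rstr(8)
  if (!identical(version, "0")) abort(sprintf("%s is not a valid EDF file (version '%s')", path, version))
  patient <- rstr(80); rstr(80)
  rstr(8); start_time <- rstr(8)
  rstr(8); rstr(44)
  n_rec <- rnum(8); rec_dur <- rnum(8); ns <- as.integer(rnum(4))
  if (is.na(ns) || ns < 1) abort(sprintf("%s: malformed EDF header", path))
  labels  <- vapply(seq_len(ns), function(i) rstr(16), character(1))
  for (i in seq_len(ns)) rstr(80)
  units   <- vapply(seq_len(ns), function(i) rstr(8), character(1))
  pmin    <- vapply(seq_len(ns), function(i) rnum(8), numeric(1))
  pmax    <- vapply(seq_len(ns), function(i) rnum(8), numeric(1))
  dmin    <- vapply(seq_len(ns), function(i) rnum(8), numeric(1))
  dmax    <- vapply(seq_len(ns), function(i) rnum(8), numeric(1))
  for (i in seq_len(ns)) rstr(80)
  spr     <- vapply(seq_len(ns), function(i) rnum(8), numeric(1))
  for (i in seq_len(ns)) rstr(32)

  # resolve canonical channels through the map
  mapped <- labels
  if (!is.null(channel_map)) {
    hit <- labels %in% names(channel_map)
    mapped[hit] <- unname(channel_map[labels[hit]])
  }
  idx <- match(psg_channels, mapped)
  if (anyNA(idx)) {
    abort(sprintf("EDF file %s is missing canonical channel(s) %s; available labels: %s",
                  path, paste(psg_channels[is.na(idx)], collapse = ", "),
                  paste(labels, collapse = ", ")))
  }
  uv_scale <- function(u) {
    key <- tolower(gsub("[^a-zA-Z]", "", u))
    switch(key, uv = 1, v = 1e6, mv = 1e3,
           abort(sprintf("physical dimension '%s' is not voltage-like (uV/mV/V)", u)))
  }
  scales <- vapply(units[idx], uv_scale, numeric(1))

  raw <- readBin(con, integer(), n = n_rec * sum(spr), size = 2, endian = "little")
  offs <- c(0, cumsum(spr))
  per_rec <- sum(spr)
  signals <- stats::setNames(vector("list", 5), psg_channels)
  for (k in seq_along(psg_channels)) {
    i <- idx[k]
    pick <- as.vector(outer(seq_len(spr[i]) + offs[i], (seq_len(n_rec) - 1) * per_rec, `+`))
    d <- raw[pick]
    phys <- pmin[i] + (d - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
    signals[[psg_channels[k]]] <- phys * scales[k]
  }
  psg_record(record_id = if (nzchar(patient)) patient else basename(path),
             signals = signals,
             srate = stats::setNames(spr[idx] / rec_dur, psg_channels),
             start_time = start_time)
}
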