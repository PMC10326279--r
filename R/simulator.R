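#' Default sleep-stage transition matrix
#'
#' A 5x5 row-stochastic Markov transition matrix over (W, N1, N2, N3, REM)
#' whose stationary distribution equals `target` exactly (up to floating
#' point), by construction: a sleep-structured proposal kernel is turned
#' into a Metropolis-Hastings chain with `target` as its invariant law.
#' The default target reproduces typical overnight stage proportions in a
#' large adult population cohort (W 28.7%, N1 3.7%, N2 41.0%, N3 12.6%,
#' REM 14.0%).  The proposal favours the physiological routes
#' W - N1 - N2 - N3 and N2 - REM with sticky self-transitions, giving
#' bout lengths of minutes rather than single epochs.
#'
#' @param target stationary stage probabilities, length 5, summing to 1.
#' @return A 5x5 matrix with dimnames `sleep_stages`.
#' @export
sleep_transition_matrix <- function(target = c(W = 0.287, N1 = 0.037, N2 = 0.410,
                                               N3 = 0.126, REM = 0.140)) {
  stopifnot(length(target) == 5, all(target > 0), abs(sum(target) - 1) < 1e-8)
  pi <- as.numeric(target) / sum(target)
  # sleep-structured proposal kernel (rows W, N1, N2, N3, REM)
  Q <- rbind(
    c(0.880, 0.100, 0.005, 0.002, 0.013),
    c(0.150, 0.400, 0.430, 0.005, 0.015),
    c(0.020, 0.020, 0.900, 0.040, 0.020),
    c(0.010, 0.002, 0.058, 0.920, 0.010),
    c(0.030, 0.020, 0.040, 0.002, 0.908)
  )
  P <- matrix(0, 5, 5, dimnames = list(sleep_stages, sleep_stages))
  for (i in 1:5) for (j in 1:5) {
    if (i != j) P[i, j] <- Q[i, j] * min(1, (pi[j] * Q[j, i]) / (pi[i] * Q[i, j]))
  }
  diag(P) <- 1 - rowSums(P)
  P
}

#' Stationary distribution of a stage transition matrix
#'
#' Left eigenvector of the transition matrix for eigenvalue 1, normalised
#' to sum to one.  The matrix must be row-stochastic and irreducible
#' (every stage reachable from every other); reducible matrices are an
#' error because their stationary law is not unique.
#'
#' @param tm 5x5 row-stochastic matrix.
#' @return Named numeric vector of length 5.
#' @export
stationary_distribution <- function(tm) {
  stopifnot(is.matrix(tm), nrow(tm) == 5, ncol(tm) == 5)
  if (any(tm < -1e-12) || any(abs(rowSums(tm) - 1) > 1e-8))
    abort("tm must be row-stochastic")
  # reachability check: (I + A)^4 must be positive for irreducibility
  A <- (tm > 0) * 1
  R <- diag(5) + A
  for (k in 1:3) R <- R %*% (diag(5) + A)
  if (any(R == 0)) abort("transition matrix is reducible; stationary distribution not unique")
  e <- eigen(t(tm))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < -1e-10)) abort("no valid stationary distribution found")
  stats::setNames(pmax(v, 0) / sum(pmax(v, 0)), sleep_stages)
}

# Evaluate code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a hypnogram from a stage transition matrix
#'
#' Samples a Markov chain of 30-s epoch labels.  The initial stage is
#' drawn from the stationary distribution so that long chains match the
#' configured stage proportions without burn-in.
#'
#' @param n_epochs number of epochs to simulate.
#' @param tm transition matrix (default [sleep_transition_matrix()]).
#' @param seed optional integer seed (chain is reproducible per seed).
#' @return A [hypnogram].
#' @export
simulate_hypnogram <- function(n_epochs, tm = sleep_transition_matrix(), seed = NULL) {
  stopifnot(n_epochs >= 1)
  with_seed(seed, {
    cum <- t(apply(tm, 1, cumsum))
    init <- tryCatch(stationary_distribution(tm),
                     error = function(e) rep(1 / 5, 5))
    s <- integer(n_epochs)
    u <- runif(n_epochs)
    s[1] <- findInterval(u[1], cumsum(init)) + 1L
    if (s[1] > 5L) s[1] <- 5L
    for (i in seq_len(n_epochs - 1L)) {
      k <- sum(u[i + 1L] > cum[s[i], ]) + 1L
      s[i + 1L] <- min(k, 5L)
    }
    hypnogram(sleep_stages[s])
  })
}

#' Stage-conditioned signal profile
#'
#' Describes, per stage, the spectral content and transient events of the
#' five simulated channels: EEG band RMS amplitudes (uV) over a common
#' band grid (delta 0.5-2, theta 4-7, alpha 8-12, sigma 12-14,
#' beta 15-30 Hz), EOG band amplitudes, broadband (20-60 Hz) chin EMG
#' tone, and per-epoch Poisson rates of transient grapho-elements
#' (sleep spindles and K-complexes for N2/N3, slow eye movements for
#' N1/REM, rapid eye movements for REM).  The defaults give each stage a
#' clearly separable signature: alpha-dominant wake with high muscle tone,
#' theta-dominant N1, spindle/K-complex N2, high-amplitude delta N3, and
#' low-tone REM with rapid eye movements.
#'
#' @return A list with elements `bands`, `eeg_rms`, `eog_rms`, `emg_rms`,
#'   `rates` (all stage-indexed).
#' @export
stage_signal_profile <- function() {
  bands <- data.frame(name = c("delta", "theta", "alpha", "sigma", "beta"),
                      f_lo = c(0.5, 4, 8, 12, 15),
                      f_hi = c(2, 7, 12, 14, 30))
  m <- function(...) {
    out <- rbind(...)
    dimnames(out) <- list(sleep_stages, bands$name)
    out
  }
  list(
    bands = bands,
    eeg_rms = m(c(4, 4, 20, 2, 6),
                c(6, 18, 4, 2, 3),
                c(12, 10, 3, 3, 2),
                c(50, 8, 3, 2, 2),
                c(6, 12, 4, 2, 3)),
    eog_rms = m(c(8, 2, 6, 1, 2),
                c(12, 5, 2, 1, 1),
                c(4, 3, 1, 1, 1),
                c(10, 3, 1, 1, 1),
                c(8, 4, 2, 1, 1)),
    emg_rms = stats::setNames(c(30, 14, 9, 6, 3), sleep_stages),
    rates = matrix(c(0, 0, 0, 0,      # W:   spindle, kcomplex, sem, rem
                     0, 0, 3, 0,      # N1
                     3, 1.5, 0, 0,    # N2
                     0, 0.5, 0, 0,    # N3
                     0, 0, 1, 8),     # REM
                   nrow = 5, byrow = TRUE,
                   dimnames = list(sleep_stages, c("spindle", "kcomplex", "sem", "rem")))
  )
}

# Two-sided FFT amplitude mask: shaping white noise with it gives each
# band its configured RMS in expectation (epoch-to-epoch fluctuation kept).
band_mask <- function(n, rate, f_lo, f_hi, rms) {
  f <- pmin(0:(n - 1), n - (0:(n - 1))) * rate / n
  a2 <- numeric(n)
  for (b in seq_along(f_lo)) {
    if (rms[b] <= 0) next
    sel <- f >= f_lo[b] & f < f_hi[b]
    m <- sum(sel)
    if (m == 0) next
    a2[sel] <- a2[sel] + rms[b]^2 * n / m
  }
  sqrt(a2)
}

band_noise <- function(n, rate, f_lo, f_hi, rms) {
  a <- band_mask(n, rate, f_lo, f_hi, rms)
  if (all(a == 0)) return(numeric(n))
  z <- fft(stats::rnorm(n))
  Re(fft(z * a, inverse = TRUE)) / n
}

hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = n))

add_transient <- function(x, at, shape) {
  idx <- at + seq_along(shape) - 1L
  keep <- idx >= 1L & idx <= length(x)
  x[idx[keep]] <- x[idx[keep]] + shape[keep]
  x
}

# Effective per-stage generation parameters, with the N1 ambiguity blend:
# at ambiguity lambda an N1 epoch draws its spectral profile as a
# (1-lambda, lambda) mixture of the N1 profile and a mimicked stage
# (W or N2), including transient rates and EMG tone, so the epoch itself
# becomes uninformative while the surrounding stage sequence remains so.
effective_profile <- function(stage, profile, lambda = 0, mimic = NULL) {
  eeg <- profile$eeg_rms[stage, ]
  eog <- profile$eog_rms[stage, ]
  emg <- profile$emg_rms[[stage]]
  rates <- profile$rates[stage, ]
  if (stage == "N1" && lambda > 0) {
    if (is.null(mimic)) mimic <- sample(c("W", "N2"), 1)
    eeg <- (1 - lambda) * eeg + lambda * profile$eeg_rms[mimic, ]
    eog <- (1 - lambda) * eog + lambda * profile$eog_rms[mimic, ]
    emg <- (1 - lambda) * emg + lambda * profile$emg_rms[[mimic]]
    rates <- (1 - lambda) * rates + lambda * profile$rates[mimic, ]
  }
  list(eeg = eeg, eog = eog, emg = emg, rates = rates)
}

#' Simulate one 30-s PSG epoch for a given stage
#'
#' Generates a `5 x (30*rate)` matrix (canonical channel order, uV):
#' band-limited Gaussian EEG/EOG per the stage profile, broadband EMG
#' tone, and scheduled transients (spindle bursts, K-complex-like
#' biphasic waves, slow and rapid eye movements).  A lognormal amplitude
#' jitter (sd 0.15) is applied per channel and epoch.  With
#' `lambda > 0`, N1 epochs are spectrally blended towards a mimicked
#' stage (see [stage_signal_profile()]).
#'
#' @param stage one of `W`, `N1`, `N2`, `N3`, `REM`.
#' @param profile a [stage_signal_profile()].
#' @param rate sampling rate in Hz (125 for training-ready epochs).
#' @param lambda N1 ambiguity level in `[0, 1]`.
#' @param mimic optional mimicked stage for N1 (`W` or `N2`); drawn at
#'   random when `NULL`.
#' @return Numeric matrix `5 x 30*rate`.
#' @export
simulate_epoch <- function(stage, profile = stage_signal_profile(), rate = target_rate_hz,
                           lambda = 0, mimic = NULL) {
  stage <- match.arg(stage, sleep_stages)
  if (stage == "N1" && lambda > 0 && is.null(mimic)) mimic <- sample(c("W", "N2"), 1)
  n <- samples_per_epoch(rate)
  sm <- stage_masks(stage, profile, rate, lambda, mimic)
  x <- matrix(0, 5, n, dimnames = list(psg_channels, NULL))
  for (ch in psg_channels) {
    a <- sm$mask[, ch]
    jit <- exp(stats::rnorm(1, 0, 0.15))
    if (any(a > 0)) x[ch, ] <- jit * Re(fft(fft(stats::rnorm(n)) * a, inverse = TRUE)) / n
  }
  x <- add_epoch_transients(x, sm$rates, rate)
  x[x > 500] <- 500
  x[x < -500] <- -500
  x
}

#' Simulation configuration
#'
#' @param n_records number of simulated recordings.
#' @param epochs_per_record epochs per recording (default 840, i.e. 7 h).
#' @param seed integer seed; fully determines the simulated data.
#' @param tm stage transition matrix.
#' @param profile stage signal profile.
#' @param lambda N1 ambiguity level in `[0, 1]`: 0 keeps the distinct N1
#'   theta signature, 1 makes N1 epochs spectrally indistinguishable from
#'   a mimicked W or N2 epoch so only the stage context identifies them.
#' @param raw_rate sampling rate (Hz) for raw signal export via
#'   [simulate_psg()]; 250 Hz by default so the preprocessing resampler is
#'   exercised nontrivially.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_records = 30, epochs_per_record = 840, seed = 1,
                       tm = sleep_transition_matrix(),
                       profile = stage_signal_profile(),
                       lambda = 0, raw_rate = 250) {
  stopifnot(n_records >= 1, epochs_per_record >= 1, lambda >= 0, lambda <= 1)
  structure(list(n_records = n_records, epochs_per_record = epochs_per_record,
                 seed = seed, tm = tm, profile = profile, lambda = lambda,
                 raw_rate = raw_rate),
            class = "sim_config")
}

# Scheduled transient grapho-elements for one epoch (modifies x in place).
add_epoch_transients <- function(x, rates, rate) {
  n <- ncol(x)
  n_sp <- stats::rpois(1, rates[["spindle"]])
  if (n_sp > 0) for (k in seq_len(n_sp)) {
    dur <- round(0.7 * rate)
    t <- seq_len(dur) / rate
    shape <- 15 * sin(2 * pi * 13 * t) * hann(dur)
    at <- sample.int(n - dur, 1)
    x["C3", ] <- add_transient(x["C3", ], at, shape)
    x["C4", ] <- add_transient(x["C4", ], at, 0.8 * shape)
  }
  n_kc <- stats::rpois(1, rates[["kcomplex"]])
  if (n_kc > 0) for (k in seq_len(n_kc)) {
    dur <- round(1.0 * rate)
    t <- seq_len(dur) / dur
    shape <- -65 * sin(2 * pi * t) * hann(dur)
    at <- sample.int(n - dur, 1)
    x["C3", ] <- add_transient(x["C3", ], at, shape)
    x["C4", ] <- add_transient(x["C4", ], at, 0.9 * shape)
  }
  n_sem <- stats::rpois(1, rates[["sem"]])
  if (n_sem > 0) for (k in seq_len(n_sem)) {
    dur <- round(4 * rate)
    t <- seq_len(dur) / rate
    shape <- 30 * sin(2 * pi * 0.3 * t) * hann(dur)
    at <- sample.int(max(1, n - dur), 1)
    x["EOGL", ] <- add_transient(x["EOGL", ], at, shape)
    x["EOGR", ] <- add_transient(x["EOGR", ], at, -shape)
  }
  n_rem <- stats::rpois(1, rates[["rem"]])
  if (n_rem > 0) for (k in seq_len(n_rem)) {
    dur <- round(0.3 * rate)
    shape <- 40 * hann(dur)^2
    at <- sample.int(n - dur, 1)
    x["EOGL", ] <- add_transient(x["EOGL", ], at, shape)
    x["EOGR", ] <- add_transient(x["EOGR", ], at, -shape)
  }
  x
}

# FFT masks (per channel) and transient rates for one generation key.
stage_masks <- function(stage, profile, rate, lambda = 0, mimic = NULL) {
  n <- samples_per_epoch(rate)
  p <- effective_profile(stage, profile, lambda, mimic)
  bands <- profile$bands
  eeg <- band_mask(n, rate, bands$f_lo, bands$f_hi, p$eeg)
  eog <- band_mask(n, rate, bands$f_lo, bands$f_hi, p$eog)
  emg <- band_mask(n, rate, 20, min(60, rate / 2 * 0.96), p$emg)
  list(mask = cbind(C3 = eeg, C4 = eeg, EOGL = eog, EOGR = eog, EMG = emg),
       rates = p$rates)
}

# One record's 125 Hz epoch signals: masks are cached per generation key
# (stage, or N1 with its mimicked stage) and the FFT noise shaping is
# batched over all epochs of the record with mvfft.
simulate_record_signals <- function(stages, profile, lambda, rate = target_rate_hz) {
  n <- samples_per_epoch(rate)
  nE <- length(stages)
  x <- array(0, dim = c(5, n, nE), dimnames = list(psg_channels, NULL, NULL))
  scored <- which(stages != "UNSCORED")
  if (length(scored) == 0) return(x)
  # generation key per epoch (N1 epochs draw their mimicked stage first)
  keys <- stages
  if (lambda > 0) {
    n1 <- which(stages == "N1")
    if (length(n1) > 0) keys[n1] <- paste0("N1.", sample(c("W", "N2"), length(n1), TRUE))
  }
  cache <- list()
  for (key in unique(keys[scored])) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    cache[[key]] <- stage_masks(parts[1], profile, rate, lambda,
                                mimic = if (length(parts) > 1) parts[2] else NULL)
  }
  mask_idx <- match(keys[scored], names(cache))
  jit <- matrix(exp(stats::rnorm(5 * length(scored), 0, 0.15)), 5, length(scored))
  # complex packing: the real and imaginary parts of mask-shaped complex
  # white noise are two independent real shaped-noise epochs (the masks are
  # symmetric), halving the FFT count; epochs are grouped by generation key
  # so one mask vector serves the whole group
  tmp <- array(0, dim = c(n, length(scored), 5))
  for (ch in seq_along(psg_channels)) {
    for (ki in seq_along(cache)) {
      cols <- which(mask_idx == ki)
      if (length(cols) == 0) next
      a <- cache[[ki]]$mask[, ch]
      if (all(a == 0)) next
      m2 <- ceiling(length(cols) / 2)
      # spectra of complex white noise are complex white noise (scaled by
      # sqrt(n)), so sample directly in the frequency domain and skip the
      # forward transform
      Z <- matrix(complex(real = stats::rnorm(n * m2, sd = sqrt(n)),
                          imaginary = stats::rnorm(n * m2, sd = sqrt(n))), n, m2)
      Y <- stats::mvfft(Z * a, inverse = TRUE) / n
      Y <- cbind(Re(Y), Im(Y))[, seq_along(cols), drop = FALSE]
      tmp[, cols, ch] <- sweep(Y, 2, jit[ch, cols], "*")
    }
  }
  x[, , scored] <- aperm(tmp, c(3, 1, 2))
  dimnames(x)[[1]] <- psg_channels
  has_events <- vapply(cache, function(cc) sum(cc$rates) > 0, logical(1))
  for (j in seq_along(scored)) {
    if (!has_events[[mask_idx[j]]]) next
    i <- scored[j]
    x[, , i] <- add_epoch_transients(x[, , i], cache[[keys[i]]]$rates, rate)
  }
  x[x > 500] <- 500
  x[x < -500] <- -500
  x
}

#' Simulate an epoched multi-record PSG dataset
#'
#' For each record, a hypnogram is drawn from the transition matrix and a
#' 125 Hz signal is synthesised per epoch.  Returns training-ready epochs
#' plus the per-record hypnograms.  Output is fully determined by
#' `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return List with `epochs` (a `psg_epochs` dataset across all records)
#'   and `hypnograms` (named list of [hypnogram]s).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    dss <- vector("list", cfg$n_records)
    hyps <- vector("list", cfg$n_records)
    for (r in seq_len(cfg$n_records)) {
      id <- sprintf("sim-%03d", r)
      hyp <- simulate_hypnogram(cfg$epochs_per_record, cfg$tm)
      stages <- as.character(hyp$stage)
      x <- simulate_record_signals(stages, cfg$profile, cfg$lambda)
      meta <- tibble(record_id = id, epoch = seq_along(stages) - 1L,
                     stage = stages, scored = stages %in% sleep_stages)
      dss[[r]] <- new_psg_epochs(x, meta)
      hyps[[r]] <- hyp
      names(hyps)[r] <- id
    }
    list(epochs = bind_epochs(dss), hypnograms = hyps)
  })
}

#' Simulate a raw PSG recording for signal-level tests
#'
#' Produces a continuous [psg_record] at `cfg$raw_rate` (default 250 Hz)
#' together with its hypnogram, suitable for EDF export and for
#' exercising [preprocess_psg()].
#'
#' @param cfg a [sim_config()]; only the first record's worth of epochs is
#'   generated (`epochs_per_record`).
#' @param record_id identifier for the recording.
#' @return List with `record` (a [psg_record]) and `hypnogram`.
#' @export
simulate_psg <- function(cfg, record_id = "sim-001") {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    hyp <- simulate_hypnogram(cfg$epochs_per_record, cfg$tm)
    stages <- as.character(hyp$stage)
    x <- simulate_record_signals(stages, cfg$profile, cfg$lambda, rate = cfg$raw_rate)
    n <- dim(x)[2] * dim(x)[3]
    signals <- stats::setNames(lapply(seq_len(5), function(k) as.numeric(x[k, , ])),
                               psg_channels)
    rec <- psg_record(record_id, signals,
                      srate = stats::setNames(rep(cfg$raw_rate, 5), psg_channels))
    list(record = rec, hypnogram = hyp)
  })
}
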