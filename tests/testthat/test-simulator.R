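test_that("the default transition matrix is calibrated to the target stage mix", {
  tm <- sleep_transition_matrix()
  expect_equal(unname(rowSums(tm)), rep(1, 5), tolerance = 1e-12)
  pi <- stationary_distribution(tm)
  expect_equal(unname(pi), c(0.287, 0.037, 0.410, 0.126, 0.140), tolerance = 1e-6)
  # two-method oracle: eigen solution vs long power iteration
  v <- rep(1 / 5, 5)
  for (i in 1:2000) v <- as.numeric(v %*% tm)
  expect_equal(unname(pi), v, tolerance = 1e-10)
  # uniform-row matrix has the uniform stationary law
  expect_equal(unname(stationary_distribution(matrix(0.2, 5, 5))), rep(0.2, 5))
  # reducible chains are rejected
  red <- diag(5)
  expect_error(stationary_distribution(red), "reducible")
  expect_error(stationary_distribution(matrix(0.3, 5, 5)), "row-stochastic")
})

test_that("hypnogram simulation is seed-reproducible with calibrated proportions", {
  h1 <- simulate_hypnogram(500, seed = 11)
  h2 <- simulate_hypnogram(500, seed = 11)
  expect_identical(h1, h2)
  expect_false(identical(h1, simulate_hypnogram(500, seed = 12)))
  # long chain: empirical mix near the stationary law within a
  # Markov-aware (batch-means) Monte-Carlo tolerance
  n <- 100000
  h <- simulate_hypnogram(n, seed = 4)
  st <- as.character(h$stage)
  for (k in seq_along(sleep_stages)) {
    ind <- as.numeric(st == sleep_stages[k])
    bm <- colMeans(matrix(ind, ncol = 200))
    se <- sd(bm) / sqrt(200)
    target <- c(0.287, 0.037, 0.410, 0.126, 0.140)[k]
    expect_lt(abs(mean(ind) - target), 4 * se + 1e-4)
  }
  # absorbing wake: after the first W the chain never leaves
  abs_tm <- matrix(0, 5, 5, dimnames = list(sleep_stages, sleep_stages))
  abs_tm["W", "W"] <- 1
  abs_tm["N1", "W"] <- 1
  abs_tm[3:5, "N1"] <- 1
  habs <- simulate_hypnogram(50, tm = abs_tm, seed = 1)
  st <- as.character(habs$stage)
  first_w <- match("W", st)
  expect_true(all(st[first_w:50] == "W"))
})

test_that("stage-conditioned epochs carry the expected spectral signatures", {
  bandpower <- function(x, lo, hi, fs = 125) {
    n <- length(x)
    p <- Mod(fft(x))^2 / n
    f <- (0:(n - 1)) * fs / n
    sum(p[f >= lo & f < hi & f <= fs / 2])
  }
  set.seed(5)
  n3_ok <- 0
  for (i in 1:100) {
    e <- simulate_epoch("N3")
    if (bandpower(e["C3", ], 0.5, 2) > bandpower(e["C3", ], 8, 12)) n3_ok <- n3_ok + 1
  }
  expect_gte(n3_ok, 95)  # delta dominates alpha in deep sleep
  # EMG tone ordering: wake tone exceeds deep-sleep tone
  set.seed(6)
  w_rms <- replicate(100, sd(simulate_epoch("W")["EMG", ]))
  n3_rms <- replicate(100, sd(simulate_epoch("N3")["EMG", ]))
  expect_gt(mean(w_rms), mean(n3_rms))
  expect_gt(mean(w_rms > n3_rms), 0.95)
  # zero-amplitude profile produces silence
  p0 <- stage_signal_profile()
  p0$eeg_rms[] <- 0
  p0$eog_rms[] <- 0
  p0$emg_rms[] <- 0
  p0$rates[] <- 0
  expect_equal(max(abs(simulate_epoch("N2", p0))), 0)
  # amplitudes always respect the recording range
  expect_lte(max(abs(simulate_epoch("N3"))), 500)
})

test_that("datasets are deterministic and bookkeeping matches the hypnograms", {
  cfg <- sim_config(n_records = 2, epochs_per_record = 15, seed = 31)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$epochs$x, d2$epochs$x)
  expect_identical(d1$hypnograms, d2$hypnograms)
  tallies <- table(factor(unlist(lapply(d1$hypnograms, function(h) as.character(h$stage))),
                          levels = sleep_stages))
  expect_equal(unname(d1$epochs$class_counts), as.integer(tallies))
  # the streaming store holds the same data
  st <- simulate_training_store(cfg)
  expect_identical(st$meta$stage, d1$epochs$meta$stage)
  expect_equal(st$class_counts, d1$epochs$class_counts)
})

test_that("N1 ambiguity removes epoch-level evidence but spares context", {
  bandfeat <- function(e) {
    n <- ncol(e)
    f <- (0:(n - 1)) * 125 / n
    p <- function(row, lo, hi) {
      s <- Mod(fft(e[row, ]))^2
      log1p(sum(s[f >= lo & f < hi]))
    }
    # rows in canonical order: 1 C3, 3 EOGL, 5 EMG
    c(p(1, 0.5, 2), p(1, 4, 7), p(1, 8, 12), p(1, 12, 14),
      p(3, 0.3, 2), p(5, 20, 60))
  }
  probe_auc <- function(lambda, n_per = 80, seed = 17) {
    set.seed(seed)
    xs <- rbind(
      t(replicate(n_per, bandfeat(simulate_epoch("N1", lambda = lambda)))),
      t(replicate(n_per / 2, bandfeat(simulate_epoch("W")))),
      t(replicate(n_per / 2, bandfeat(simulate_epoch("N2")))))
    y <- c(rep(1, n_per), rep(0, n_per))
    fit <- suppressWarnings(glm(y ~ ., data = data.frame(xs), family = binomial))
    suppressMessages(as.numeric(pROC::auc(y, fitted(fit))))
  }
  a0 <- probe_auc(0)
  a5 <- probe_auc(0.5)
  a1 <- probe_auc(1)
  # single-epoch separability decays monotonically in the ambiguity dial
  expect_gt(a0, 0.9)
  expect_gte(a0, a5 - 0.02)
  expect_gte(a5, a1 - 0.02)
  expect_lt(a1, 0.75)

  # with full ambiguity, a probe seeing +/-2 flanking epochs still finds N1
  # clearly above chance, and beats the same probe without context
  set.seed(23)
  sim <- simulate_dataset(sim_config(n_records = 3, epochs_per_record = 300,
                                     seed = 23, lambda = 1))
  feats <- t(sapply(seq_len(dim(sim$epochs$x)[3]), function(i) bandfeat(sim$epochs$x[, , i])))
  y <- as.integer(sim$epochs$meta$stage == "N1")
  n <- length(y)
  sh <- function(d) feats[pmin(pmax(seq_len(n) + d, 1), n), ]
  ctx <- cbind(sh(-2), sh(-1), feats, sh(1), sh(2))
  f_solo <- suppressWarnings(glm(y ~ ., data = data.frame(feats), family = binomial))
  f_ctx <- suppressWarnings(glm(y ~ ., data = data.frame(ctx), family = binomial))
  auc_solo <- suppressMessages(as.numeric(pROC::auc(y, fitted(f_solo))))
  auc_ctx <- suppressMessages(as.numeric(pROC::auc(y, fitted(f_ctx))))
  expect_gt(auc_ctx, auc_solo)
  expect_gt(auc_ctx, 0.65)
})
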