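test_that("channel attention follows softmax(MLP(avg) + MLP(max))", {
  # identity-like MLP: each path reduces to relu(x), verified against a
  # scalar step-by-step recomputation
  Fm <- matrix(c(1, -2, 0.5,
                 2, 0, -1,
                 -1, 3, 0.25,
                 0.5, 1, 2), 3, 4)
  pp <- list(W1 = diag(3), b1 = rep(0, 3), W2 = diag(3), b2 = rep(0, 3))
  got <- channel_attention(Fm, pp)
  u <- numeric(3)
  for (c in 1:3) {
    avg <- mean(Fm[c, ])
    mx <- max(Fm[c, ])
    u[c] <- max(avg, 0) + max(mx, 0)
  }
  want <- exp(u) / sum(exp(u))
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(sum(got), 1, tolerance = 1e-12)
  # scalar case: softmax of a single channel is 1
  expect_equal(channel_attention(matrix(rnorm(7), 1, 7),
                                 list(W1 = matrix(1), b1 = 0, W2 = matrix(1), b2 = 0)),
               1)
})

test_that("temporal attention is 1 + softmax of the channel-max trace", {
  Fm <- matrix(c(1, 3, 2, 0), 2, 2)  # channel max per time = (3, 2)
  got <- temporal_attention(Fm)
  expect_equal(got, 1 + exp(c(3, 2) - 3) / sum(exp(c(3, 2) - 3)), tolerance = 1e-12)
  expect_equal(round(got, 4), c(1.7311, 1.2689))
  expect_equal(temporal_attention(matrix(rnorm(3), 3, 1)), 2)
})

test_that("attention invariants hold over random feature maps", {
  set.seed(42)
  pp <- list(W1 = matrix(rnorm(4 * 8), 4, 8), b1 = rnorm(4),
             W2 = matrix(rnorm(8 * 4), 8, 4), b2 = rnorm(8))
  for (i in 1:200) {
    Fm <- matrix(rnorm(8 * 15, sd = runif(1, 0.1, 5)), 8, 15)
    mc <- channel_attention(Fm, pp)
    mt <- temporal_attention(Fm)
    expect_lt(abs(sum(mc) - 1), 1e-6)
    expect_true(all(mc > 0))
    expect_true(all(mt > 1) && all(mt < 2))
    expect_lt(abs(sum(mt - 1) - 1), 1e-6)
  }
})

test_that("attention maps from all three blocks satisfy the invariants", {
  m <- init_stagenet(tiny_config(), seed = 5)
  sim <- tiny_dataset(4)
  x <- sim$epochs$x[, , 2]
  for (b in 1:3) {
    bf <- attention_block(if (b == 1) x else out, m, b)
    out <- bf$out
    expect_lt(abs(sum(bf$channel_attention) - 1), 1e-4)   # float path
    expect_true(all(bf$channel_attention >= 0))  # softmax may underflow in float
    expect_true(all(bf$temporal_attention >= 1) && all(bf$temporal_attention <= 2))
    expect_lt(abs(sum(bf$temporal_attention - 1) - 1), 1e-3)
  }
  expect_error(attention_block(x, m, 2), "input channels")
})

test_that("block output length follows the stride arithmetic", {
  m <- init_stagenet(tiny_config(), seed = 5)
  x <- matrix(rnorm(5 * 3750), 5, 3750)
  bf <- attention_block(x, m, 1)
  expect_equal(ncol(bf$out), ceiling(ceiling(3750 / 4) / 2))
  expect_equal(nrow(bf$out), 4)
})

test_that("zeroed convolutions leave only the projected skip path", {
  m <- init_stagenet(tiny_config(), seed = 5)
  for (nm in c("b1.conv1", "b1.conv2")) m$params[[nm]][] <- 0
  m$params[["b1.att.W1"]][] <- 0
  m$params[["b1.att.W2"]][] <- 0
  x <- matrix(rnorm(5 * 3750), 5, 3750)
  bf <- attention_block(x, m, 1)
  # attention-weighted F is a (zero +/- beta) constant; with zero beta the
  # residual path dominates: out = relu(projected skip)
  sel <- pmin(0:(ncol(bf$out) - 1) * 8, 3749)
  xs <- x[, sel + 1]
  # eval-mode BN at initialisation (running mean 0, var 1) is ~identity
  want <- pmax(m$params[["b1.proj"]] %*% xs / sqrt(1 + 1e-5), 0)
  expect_equal(unname(bf$out), unname(want), tolerance = 1e-4)
})

test_that("feature extraction returns the configured dimension deterministically", {
  cfg <- tiny_config()
  m <- init_stagenet(cfg, seed = 3)
  sim <- tiny_dataset(3)
  x <- sim$epochs$x[, , 1]
  f1 <- extract_features(x, m)
  expect_length(f1, 8)
  expect_identical(f1, extract_features(x, m))
  # default configuration yields 256 features
  m256 <- init_stagenet(stagenet_config(), seed = 1)
  expect_length(extract_features(x, m256), 256)
  expect_error(extract_features(matrix(0, 5, 100), m), "5 x 3750")
})

test_that("branch heads are softmax classifiers with the stated geometry", {
  cfg <- tiny_config()
  m <- init_stagenet(cfg, seed = 3)
  f <- rnorm(8)
  pe <- elb_forward(f, m)
  expect_equal(sum(pe), 1, tolerance = 1e-12)
  expect_named(pe, sleep_stages)
  # zero weights -> uniform output
  m0 <- m
  for (nm in grep("^(elb|slb)", names(m0$params), value = TRUE)) m0$params[[nm]][] <- 0
  expect_equal(unname(elb_forward(f, m0)), rep(0.2, 5), tolerance = 1e-12)
  win <- lapply(1:5, function(i) rnorm(8))
  expect_equal(unname(slb_forward(win, m0)), rep(0.2, 5), tolerance = 1e-12)
  # fixed single-layer weights match a hand-computed affine + softmax
  m1 <- init_stagenet(stagenet_config(block_channels = c(4, 6, 8), elb_hidden = integer(0),
                                      slb_hidden = integer(0), mlp_reduction_ratio = 2),
                      seed = 2)
  W <- m1$params[["elb.fc1.W"]]
  b <- as.numeric(m1$params[["elb.fc1.b"]])
  z <- as.numeric(W %*% f + b)
  expect_equal(unname(elb_forward(f, m1)), unname(exp(z - max(z)) / sum(exp(z - max(z)))),
               tolerance = 1e-12)
  # SLB input is the ordered concatenation: order sensitivity + 1280 default
  w1 <- slb_forward(win, m)
  w2 <- slb_forward(rev(win), m)
  expect_false(isTRUE(all.equal(w1, w2)))
  mdef <- init_stagenet(stagenet_config(), seed = 1)
  expect_equal(ncol(mdef$params[["slb.fc1.W"]]), 1280)
  expect_error(slb_forward(win[1:3], m), "window of 5")
  expect_error(elb_forward(rnorm(3), m), "expects 8 features")
})

test_that("prediction mixes branches and breaks ties deterministically", {
  m <- init_stagenet(tiny_config(), seed = 7)
  sim <- tiny_dataset(10, seed = 5)
  pr <- predict(m, sim$epochs)
  expect_equal(nrow(pr), 10)
  p <- as.matrix(pr[, paste0("p_", sleep_stages)])
  expect_equal(unname(rowSums(p)), rep(1, 10), tolerance = 1e-5)
  # degenerate mixtures reduce to a single branch
  pr1 <- predict(m, sim$epochs, alpha_test = 1)
  ep_arg <- sleep_stages[apply(as.matrix(pr1[, paste0("ep_", sleep_stages)]), 1, which.max)]
  expect_identical(pr1$pred, ep_arg)
  pr0 <- predict(m, sim$epochs, alpha_test = 0)
  sq_arg <- sleep_stages[apply(as.matrix(pr0[, paste0("seq_", sleep_stages)]), 1, which.max)]
  expect_identical(pr0$pred, sq_arg)
  expect_error(predict(m, sim$epochs, alpha_test = 1.5), "0, 1")
  # mixture monotonicity: when both branches agree the mixture agrees for all alpha
  for (a in c(0, 0.25, 0.5, 0.75, 1)) {
    pra <- predict(m, sim$epochs, alpha_test = a)
    agree <- pr1$pred == pr0$pred
    expect_identical(pra$pred[agree], pr1$pred[agree])
  }
  # equal probabilities tie-break to the earlier stage: zero-weight heads
  m0 <- m
  for (nm in grep("^(elb|slb)", names(m0$params), value = TRUE)) m0$params[[nm]][] <- 0
  pru <- predict(m0, sim$epochs)
  expect_true(all(pru$pred == "W"))
})

test_that("parameter shapes are a pure function of the configuration", {
  cfg <- tiny_config()
  m1 <- init_stagenet(cfg, seed = 1)
  m2 <- init_stagenet(cfg, seed = 99)
  expect_identical(lapply(m1$params, dim), lapply(m2$params, dim))
  expect_identical(init_stagenet(cfg, seed = 1)$params, m1$params)
  # golden shape table for the tiny configuration
  shp <- vapply(m1$params, function(p) paste(dim(p), collapse = "x"), character(1))
  expect_equal(unname(shp[c("b1.conv1", "b2.conv2", "b3.att.W1", "elb.fc1.W", "slb.fc1.W")]),
               c("4x35", "6x42", "4x8", "8x8", "12x40"))
})

test_that("checkpoints round-trip through disk", {
  m <- init_stagenet(tiny_config(), seed = 13)
  path <- withr::local_tempfile(fileext = ".rds")
  save_stagenet(m, path)
  m2 <- load_stagenet(path)
  expect_identical(m2$params, m$params)
  expect_identical(m2$class_order, sleep_stages)
  sim <- tiny_dataset(5)
  expect_identical(predict(m, sim$epochs)$pred, predict(m2, sim$epochs)$pred)
})
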