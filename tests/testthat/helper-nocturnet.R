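# Shared fixtures: all synthetic data is generated in code at test time.

# small but structurally complete model configuration
tiny_config <- function(...) {
  stagenet_config(block_channels = c(4, 6, 8), elb_hidden = 8, slb_hidden = c(12, 8),
                  mlp_reduction_ratio = 2, ...)
}

# fast training-scale configuration used by trainer smoke tests
smoke_config <- function(...) {
  stagenet_config(block_channels = c(8, 16, 32), elb_hidden = 16, slb_hidden = c(64, 32),
                  mlp_reduction_ratio = 4,
                  block_strides = matrix(c(8, 4, 2, 2, 2, 2), 3, 2, byrow = TRUE), ...)
}

# one simulated record as an epoch dataset + store
tiny_dataset <- function(n_epochs = 12, seed = 2, lambda = 0) {
  simulate_dataset(sim_config(n_records = 1, epochs_per_record = n_epochs,
                              seed = seed, lambda = lambda))
}

# 3-stage, strongly separable toy chain (W / N2 / N3 only)
toy_transition_matrix <- function() {
  tm <- matrix(1e-9, 5, 5, dimnames = list(sleep_stages, sleep_stages))
  tm["W", c("W", "N2")] <- c(0.9, 0.1)
  tm["N2", c("W", "N2", "N3")] <- c(0.05, 0.85, 0.1)
  tm["N3", c("N2", "N3")] <- c(0.1, 0.9)
  tm["N1", "W"] <- 1
  tm["REM", "W"] <- 1
  tm / rowSums(tm)
}

# ---------------------------------------------------------------------------
# Independent double-precision replica of the training-mode forward pass.
# Used as the oracle for finite-difference gradient checks; written from the
# model definition, sharing no code with the C++ implementation.

im2col_r <- function(A, C, T, B, k, stride, pad) {
  To <- (T + 2 * pad - k) %/% stride + 1
  P <- matrix(0, C * k, To * B)
  for (b in 0:(B - 1)) for (t in 0:(To - 1)) {
    in0 <- t * stride - pad
    for (kk in 0:(k - 1)) {
      ti <- in0 + kk
      if (ti >= 0 && ti < T) P[kk * C + 1:C, b * To + t + 1] <- A[, b * T + ti + 1]
    }
  }
  attr(P, "To") <- To
  P
}

bn_r <- function(Y, g, b) {
  mu <- rowMeans(Y)
  v <- rowMeans((Y - mu)^2)
  sweep(sweep(Y, 1, mu) / sqrt(v + 1e-5), 1, as.numeric(g), "*") + as.numeric(b)
}

softmax_r <- function(u) {
  e <- exp(u - max(u))
  e / sum(e)
}

att_r <- function(Fm, W1, b1, W2, b2) {
  mlp <- function(x) W2 %*% pmax(W1 %*% x + b1, 0) + b2
  mc <- softmax_r(as.numeric(mlp(rowMeans(Fm)) + mlp(apply(Fm, 1, max))))
  mt <- 1 + softmax_r(apply(Fm, 2, max))
  sweep(sweep(Fm, 1, mc, "*"), 2, mt, "*")
}

# returns c(L, L_ep, L_seq) for a combined context-window batch
forward_loss_r <- function(p, cfg, Xall, Tin, nI, batch_samples, labs, alpha, w, nctx) {
  A <- Xall
  T <- Tin
  Cin <- 5
  for (i in seq_along(cfg$block_channels)) {
    Cout <- cfg$block_channels[i]
    s1 <- cfg$block_strides[i, 1]
    s2 <- cfg$block_strides[i, 2]
    k <- cfg$kernel_width
    pad <- k %/% 2
    tg <- function(s) p[[sprintf("b%d.%s", i, s)]]
    P1 <- im2col_r(A, Cin, T, nI, k, s1, pad)
    T1 <- attr(P1, "To")
    R1 <- pmax(bn_r(tg("conv1") %*% P1, tg("bn1.gamma"), tg("bn1.beta")), 0)
    P2 <- im2col_r(R1, Cout, T1, nI, k, s2, pad)
    T2 <- attr(P2, "To")
    Fm <- bn_r(tg("conv2") %*% P2, tg("bn2.gamma"), tg("bn2.beta"))
    G <- matrix(0, Cout, T2 * nI)
    for (b in 0:(nI - 1)) {
      G[, b * T2 + 1:T2] <- att_r(Fm[, b * T2 + 1:T2, drop = FALSE],
                                  tg("att.W1"), as.numeric(tg("att.b1")),
                                  tg("att.W2"), as.numeric(tg("att.b2")))
    }
    sel <- pmin(0:(T2 - 1) * (s1 * s2), T - 1)
    Xs <- matrix(0, Cin, T2 * nI)
    for (b in 0:(nI - 1)) Xs[, b * T2 + 1:T2] <- A[, b * T + sel + 1]
    S <- bn_r(tg("proj") %*% Xs, tg("bnp.gamma"), tg("bnp.beta"))
    A <- pmax(G + S, 0)
    T <- T2
    Cin <- Cout
  }
  Fd <- nrow(A)
  feats <- sapply(0:(nI - 1), function(b) rowMeans(A[, b * T + 1:T, drop = FALSE]))
  mlp_fw <- function(prefix, x) {
    l <- 1
    a <- x
    repeat {
      W <- p[[sprintf("%s.fc%d.W", prefix, l)]]
      if (is.null(W)) break
      z <- W %*% a + as.numeric(p[[sprintf("%s.fc%d.b", prefix, l)]])
      a <- if (!is.null(p[[sprintf("%s.fc%d.W", prefix, l + 1)]])) pmax(z, 0) else z
      l <- l + 1
    }
    a
  }
  Wn <- 2 * nctx + 1
  B <- length(batch_samples)
  fctr <- feats[, (batch_samples - 1) * Wn + nctx + 1, drop = FALSE]
  p_ep <- apply(mlp_fw("elb", fctr), 2, softmax_r)
  fwin <- matrix(0, Fd * Wn, B)
  for (j in 1:B) fwin[, j] <- as.numeric(feats[, (batch_samples[j] - 1) * Wn + 1:Wn])
  p_seq <- apply(mlp_fw("slb", fwin), 2, softmax_r)
  L_ep <- mean(-log(pmax(p_ep[cbind(labs, 1:B)], 1e-12)))
  wy <- w[labs]
  L_seq <- sum(wy * -log(pmax(p_seq[cbind(labs, 1:B)], 1e-12))) / sum(wy)
  c(L = alpha * L_ep + (1 - alpha) * L_seq, L_ep = L_ep, L_seq = L_seq)
}

# assemble the combined context-window batch matching the C++ layout
replica_batch <- function(sim, centers, nctx = 2) {
  n <- dim(sim$epochs$x)[3]
  inst <- unlist(lapply(centers, function(cg) pmin(pmax((cg - nctx):(cg + nctx), 0), n - 1)))
  Tin <- dim(sim$epochs$x)[2]
  Xall <- matrix(0, 5, Tin * length(inst))
  for (i in seq_along(inst)) Xall[, (i - 1) * Tin + 1:Tin] <- sim$epochs$x[, , inst[i] + 1]
  labs <- match(sim$epochs$meta$stage[centers + 1], sleep_stages)
  list(Xall = Xall, Tin = Tin, nI = length(inst), labs = labs)
}
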