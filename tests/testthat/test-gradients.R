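# The hand-written backward pass is validated against an independent
# double-precision replica of the forward pass (helper-nocturnet.R) by
# central finite differences, separately for the gated transitive
# objective and the ungated sequence-only objective.

cfg <- tiny_config()
model <- init_stagenet(cfg, seed = 11)
sim <- tiny_dataset(12, seed = 2)
store <- as_training_store(sim$epochs)
centers <- c(3L, 6L, 8L)
wts <- class_weights(c(W = 5, N1 = 1, N2 = 4, N3 = 2, REM = 2))
rb <- replica_batch(sim, centers)

replica_loss <- function(params, alpha, w) {
  forward_loss_r(params, cfg, rb$Xall, rb$Tin, rb$nI, seq_along(centers),
                 rb$labs, alpha, as.numeric(w), cfg$n_context)
}

fd_grad <- function(params, pname, idx, target, alpha, w, h = 1e-6) {
  params[[pname]][idx] <- params[[pname]][idx] + h
  lp <- replica_loss(params, alpha, w)[target]
  params[[pname]][idx] <- params[[pname]][idx] - 2 * h
  lm <- replica_loss(params, alpha, w)[target]
  unname((lp - lm) / (2 * h))
}

test_that("the C++ forward pass agrees with the double-precision replica", {
  g <- stagenet_gradients(model, store, centers, alpha = 0.6, weights = wts)
  L <- replica_loss(model$params, 0.6, wts)
  expect_equal(g$loss, unname(L["L"]), tolerance = 1e-5)
  expect_equal(g$loss_ep, unname(L["L_ep"]), tolerance = 1e-5)
  expect_equal(g$loss_seq, unname(L["L_seq"]), tolerance = 1e-5)
})

test_that("transitive gradients equal alpha * dL_ep for every component class", {
  g <- stagenet_gradients(model, store, centers, alpha = 0.6, weights = wts)
  set.seed(4)
  for (pn in c("b1.conv1", "b2.conv2", "b3.bn2.gamma", "b3.att.W1",
               "b2.bnp.gamma", "b1.bn1.beta", "elb.fc1.W")) {
    idx <- sample(length(model$params[[pn]]), 1)
    fd <- 0.6 * fd_grad(model$params, pn, idx, "L_ep", 0.6, wts)
    expect_equal(g$grads[[pn]][idx], fd, tolerance = 1e-3,
                 label = sprintf("grad %s[%d]", pn, idx))
  }
  # SLB head trains from (1-alpha) * weighted L_seq
  idx <- 5L
  fd <- 0.4 * fd_grad(model$params, "slb.fc1.W", idx, "L_seq", 0.6, wts)
  expect_equal(g$grads[["slb.fc1.W"]][idx], fd, tolerance = 1e-3)
})

test_that("ungated regimes backpropagate the sequence loss into the CNN", {
  wu <- stats::setNames(rep(1, 5), sleep_stages)
  g <- stagenet_gradients(model, store, centers, alpha = 0, weights = wu, regime = "none")
  set.seed(9)
  for (pn in c("b1.conv1", "b3.att.W1", "b2.bn2.gamma", "slb.fc1.W")) {
    idx <- sample(length(model$params[[pn]]), 1)
    fd <- fd_grad(model$params, pn, idx, "L_seq", 0, wu)
    expect_equal(g$grads[[pn]][idx], fd, tolerance = 1e-3,
                 label = sprintf("grad %s[%d]", pn, idx))
  }
})

test_that("the gradient gate blocks the sequence loss from CNN and ELB exactly", {
  # alpha = 0: the whole loss is the (gated) sequence loss
  g0 <- stagenet_gradients(model, store, centers, alpha = 0, weights = wts)
  cnn_elb <- grep("^(b[0-9]|elb)", names(g0$grads), value = TRUE)
  for (nm in cnn_elb) expect_identical(max(abs(g0$grads[[nm]])), 0)
  # alpha = 1: no gradient reaches the SLB
  g1 <- stagenet_gradients(model, store, centers, alpha = 1, weights = wts)
  for (nm in grep("^slb", names(g1$grads), value = TRUE))
    expect_identical(max(abs(g1$grads[[nm]])), 0)
  # CNN gradients are bitwise independent of the sequence-loss weights
  ga <- stagenet_gradients(model, store, centers, alpha = 0.5, weights = wts)
  gb <- stagenet_gradients(model, store, centers, alpha = 0.5,
                           weights = stats::setNames(c(1, 50, 1, 1, 1), sleep_stages))
  for (nm in cnn_elb) expect_identical(ga$grads[[nm]], gb$grads[[nm]])
  # exact scaling: doubling alpha from 0.5 to 1 doubles every CNN gradient
  # bitwise (power-of-two scaling is exact in binary floating point)
  for (nm in cnn_elb) expect_identical(g1$grads[[nm]], 2 * ga$grads[[nm]])
})
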