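#' Model configuration for the two-branch staging network
#'
#' The feature extractor is three cascaded 1-d attention residual blocks
#' (two k-wide convolutions, batch normalisation, channel then temporal
#' attention, projected skip connection), followed by global average
#' pooling to a feature vector whose length equals the last block width.
#' The classifier has two branches: the epoch learning branch (ELB) scores
#' the centre epoch from its own features; the sequential learning branch
#' (SLB) scores it from the concatenated features of the `2N+1` epoch
#' context window.  At test time the stage is the argmax of
#' `alpha_test * p_ep + (1 - alpha_test) * p_seq`.
#'
#' @param block_channels widths of the three residual blocks; the last one
#'   is the feature dimension (default `c(64, 128, 256)`).
#' @param kernel_width convolution kernel width (odd; default 7).
#' @param mlp_reduction_ratio bottleneck ratio of the shared channel-attention
#'   MLP (default 16; the hidden width is at least 1).
#' @param n_context epochs of context on each side for the SLB (default 2).
#' @param elb_hidden,slb_hidden hidden-layer widths of the two branches.
#' @param alpha_test branch mixing weight at test time (default 0.5).
#' @param block_strides integer matrix, one row per block, giving the
#'   temporal strides of the block's two convolutions.  The default
#'   `(4, 2)` per block reduces 3750 input samples to 15 steps before
#'   pooling; pooling absorbs the exact schedule.
#' @return A list of class `stagenet_config`.
#' @export
stagenet_config <- function(block_channels = c(64, 128, 256),
                            kernel_width = 7,
                            mlp_reduction_ratio = 16,
                            n_context = 2,
                            elb_hidden = c(128),
                            slb_hidden = c(512, 128),
                            alpha_test = 0.5,
                            block_strides = NULL) {
  if (kernel_width %% 2 != 1) abort("kernel_width must be odd")
  if (alpha_test < 0 || alpha_test > 1) abort("alpha_test must be in [0, 1]")
  if (n_context < 0) abort("n_context must be non-negative")
  nb <- length(block_channels)
  if (is.null(block_strides)) block_strides <- matrix(rep(c(4L, 2L), each = nb), nb, 2)
  block_strides <- matrix(as.integer(block_strides), nb, 2)
  structure(list(
    in_channels = 5L, in_samples = samples_per_epoch(),
    block_channels = as.integer(block_channels),
    kernel_width = as.integer(kernel_width),
    mlp_reduction_ratio = as.integer(mlp_reduction_ratio),
    n_context = as.integer(n_context),
    n_classes = 5L,
    elb_hidden = as.integer(elb_hidden),
    slb_hidden = as.integer(slb_hidden),
    alpha_test = alpha_test,
    block_strides = block_strides,
    feature_dim = as.integer(block_channels[nb])
  ), class = "stagenet_config")
}

as_mat <- function(x) if (is.matrix(x)) x else matrix(x, ncol = 1)

he_init <- function(nr, nc, fan_in) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)

#' Initialise a staging network
#'
#' Builds the full parameter set (He-normal convolution and linear
#' weights, unit-gamma batch norm) for a [stagenet_config()].  The
#' parameter list layout is the on-disk checkpoint format.
#'
#' @param config a [stagenet_config()].
#' @param seed integer seed; initialisation is reproducible per seed.
#' @return An object of class `stagenet`: list with `config`, `params`,
#'   `class_order` and `version`.
#' @export
init_stagenet <- function(config = stagenet_config(), seed = 1) {
  stopifnot(inherits(config, "stagenet_config"))
  with_seed(seed, {
    p <- list()
    k <- config$kernel_width
    cin <- config$in_channels
    for (i in seq_along(config$block_channels)) {
      cout <- config$block_channels[i]
      ch <- max(1L, cout %/% config$mlp_reduction_ratio)
      tag <- function(s) sprintf("b%d.%s", i, s)
      p[[tag("conv1")]] <- he_init(cout, cin * k, cin * k)
      p[[tag("conv2")]] <- he_init(cout, cout * k, cout * k)
      for (bn in c("bn1", "bn2", "bnp")) {
        p[[tag(paste0(bn, ".gamma"))]] <- as_mat(rep(1, cout))
        p[[tag(paste0(bn, ".beta"))]] <- as_mat(rep(0, cout))
        p[[tag(paste0(bn, ".mean"))]] <- as_mat(rep(0, cout))
        p[[tag(paste0(bn, ".var"))]] <- as_mat(rep(1, cout))
      }
      p[[tag("att.W1")]] <- he_init(ch, cout, cout)
      p[[tag("att.b1")]] <- as_mat(rep(0, ch))
      p[[tag("att.W2")]] <- he_init(cout, ch, ch)
      p[[tag("att.b2")]] <- as_mat(rep(0, cout))
      p[[tag("proj")]] <- he_init(cout, cin, cin)
      cin <- cout
    }
    mlp_params <- function(prefix, dims) {
      for (l in seq_len(length(dims) - 1)) {
        p[[sprintf("%s.fc%d.W", prefix, l)]] <<- he_init(dims[l + 1], dims[l], dims[l])
        p[[sprintf("%s.fc%d.b", prefix, l)]] <<- as_mat(rep(0, dims[l + 1]))
      }
    }
    fd <- config$feature_dim
    mlp_params("elb", c(fd, config$elb_hidden, config$n_classes))
    mlp_params("slb", c(fd * (2 * config$n_context + 1), config$slb_hidden, config$n_classes))
    structure(list(config = config, params = p, class_order = sleep_stages,
                   version = "nocturnet-checkpoint-1"),
              class = "stagenet")
  })
}

cfg_for_cpp <- function(config) {
  c(unclass(config), list())
}

softmax <- function(u) {
  e <- exp(u - max(u))
  e / sum(e)
}

#' Channel attention map
#'
#' For an intermediate feature map `F` (channels x time), pools over the
#' temporal axis by average and by max, passes both descriptors through a
#' shared bottleneck MLP, sums, and applies a softmax over channels:
#' `Mc = softmax(MLP(avgpool(F)) + MLP(maxpool(F)))`.  Entries are
#' positive and sum to one.
#'
#' @param f numeric matrix, channels x time.
#' @param params list with `W1`, `b1`, `W2`, `b2` (the shared MLP), or a
#'   `stagenet` model plus `block` to use that block's attention MLP.
#' @param block block number when `params` is a `stagenet`.
#' @return Numeric vector of length `nrow(f)` summing to 1.
#' @export
channel_attention <- function(f, params, block = 1) {
  stopifnot(is.matrix(f), all(is.finite(f)))
  if (inherits(params, "stagenet")) {
    p <- params$params
    params <- list(W1 = p[[sprintf("b%d.att.W1", block)]],
                   b1 = p[[sprintf("b%d.att.b1", block)]],
                   W2 = p[[sprintf("b%d.att.W2", block)]],
                   b2 = p[[sprintf("b%d.att.b2", block)]])
  }
  mlp <- function(x) params$W2 %*% pmax(params$W1 %*% x + as.numeric(params$b1), 0) +
    as.numeric(params$b2)
  u <- mlp(rowMeans(f)) + mlp(apply(f, 1, max))
  as.numeric(softmax(as.numeric(u)))
}

#' Temporal attention map
#'
#' Parameter-free: takes the channel-axis maximum at each time step,
#' applies a softmax over time, and adds 1, so every entry lies strictly
#' in (1, 2) and the gains above baseline sum to one:
#' `Mt = 1 + softmax(maxpool_channel(F))`.  The cascaded softmax bounds
#' the gain and prevents runaway temporal emphasis.
#'
#' @param f numeric matrix, channels x time.
#' @return Numeric vector of length `ncol(f)`, entries in (1, 2).
#' @export
temporal_attention <- function(f) {
  stopifnot(is.matrix(f), all(is.finite(f)))
  v <- apply(f, 2, max)
  1 + as.numeric(softmax(v))
}

#' Forward one attention residual block
#'
#' Runs a single 1-d attention residual block of the model in evaluation
#' mode: conv(k) - BN - ReLU - conv(k) - BN, channel then temporal
#' attention applied multiplicatively, plus a 1x1-projected strided skip
#' connection and final ReLU.
#'
#' @param x numeric matrix, input channels x time (channel count must
#'   match the block's input width).
#' @param model a `stagenet`.
#' @param block block number (1-based).
#' @return List with `out` (output feature map), `channel_attention` and
#'   `temporal_attention` vectors.
#' @export
attention_block <- function(x, model, block = 1) {
  stopifnot(inherits(model, "stagenet"), is.matrix(x))
  cin <- if (block == 1) model$config$in_channels else model$config$block_channels[block - 1]
  if (nrow(x) != cin)
    abort(sprintf("block %d expects %d input channels, got %d", block, cin, nrow(x)))
  cpp_block_forward(model$params, cfg_for_cpp(model$config), as.integer(block), x)
}

#' Extract epoch features
#'
#' Runs the full three-block attention CNN plus global average pooling on
#' one or more preprocessed 30-s epochs, in evaluation mode.
#'
#' @param epoch a `5 x 3750` matrix, or a `5 x 3750 x m` array.
#' @param model a `stagenet`.
#' @return A feature matrix `feature_dim x m` (a vector if `m = 1`).
#' @export
extract_features <- function(epoch, model) {
  stopifnot(inherits(model, "stagenet"))
  if (is.matrix(epoch)) epoch <- array(epoch, dim = c(dim(epoch), 1))
  if (!(length(dim(epoch)) == 3 && dim(epoch)[1] == model$config$in_channels &&
        dim(epoch)[2] == model$config$in_samples))
    abort(sprintf("epoch tensor must be %d x %d (x m)",
                  model$config$in_channels, model$config$in_samples))
  f <- cpp_features(model$params, cfg_for_cpp(model$config), epoch)
  if (ncol(f) == 1) as.numeric(f) else f
}

mlp_forward_r <- function(p, prefix, x) {
  l <- 1
  a <- as.numeric(x)
  repeat {
    W <- p[[sprintf("%s.fc%d.W", prefix, l)]]
    if (is.null(W)) break
    b <- as.numeric(p[[sprintf("%s.fc%d.b", prefix, l)]])
    z <- as.numeric(W %*% a + b)
    nxt <- !is.null(p[[sprintf("%s.fc%d.W", prefix, l + 1)]])
    a <- if (nxt) pmax(z, 0) else z
    l <- l + 1
  }
  a
}

#' Branch forward passes
#'
#' `elb_forward()` scores a single epoch's feature vector through the
#' epoch learning branch; `slb_forward()` concatenates the `2N+1` context
#' feature vectors in temporal order and scores them through the
#' sequential learning branch.  Both return softmax stage probabilities
#' in the canonical order (W, N1, N2, N3, REM).
#'
#' @param features numeric feature vector of length `feature_dim`.
#' @param model a `stagenet`.
#' @return Named numeric probability vector of length 5 summing to 1.
#' @export
elb_forward <- function(features, model) {
  stopifnot(inherits(model, "stagenet"))
  if (length(features) != model$config$feature_dim)
    abort(sprintf("ELB expects %d features, got %d", model$config$feature_dim, length(features)))
  stats::setNames(softmax(mlp_forward_r(model$params, "elb", features)), sleep_stages)
}

#' @param window list (or matrix with one column per epoch) of `2N+1`
#'   feature vectors in temporal order.
#' @rdname elb_forward
#' @export
slb_forward <- function(window, model) {
  stopifnot(inherits(model, "stagenet"))
  if (is.matrix(window)) window <- lapply(seq_len(ncol(window)), function(i) window[, i])
  need <- 2 * model$config$n_context + 1
  if (length(window) != need)
    abort(sprintf("SLB expects a window of %d feature vectors, got %d", need, length(window)))
  x <- unlist(window, use.names = FALSE)
  if (length(x) != model$config$feature_dim * need)
    abort("window features have the wrong dimension")
  stats::setNames(softmax(mlp_forward_r(model$params, "slb", x)), sleep_stages)
}

argmax_stage <- function(p) sleep_stages[apply(p, 2, which.max)]

#' Predict sleep stages for an epoched dataset
#'
#' Runs the trained network in evaluation mode over every epoch of the
#' dataset (unscored epochs are staged too; they still provide context
#' for their neighbours) and mixes the two branch outputs with weight
#' `alpha_test`: `p = alpha_test * p_ep + (1 - alpha_test) * p_seq`.
#' Ties in the argmax are broken towards the earlier stage in
#' (W, N1, N2, N3, REM).
#'
#' @param object a `stagenet` model.
#' @param ds a `psg_epochs` dataset or an `epoch_store`.
#' @param alpha_test branch mixing weight in `[0, 1]`; defaults to the
#'   model configuration (0.5).
#' @param ... unused.
#' @return A tibble with one row per epoch: `record_id`, `epoch`,
#'   `stage` (human label or `NA` for unscored), `pred`, and probability
#'   columns `p_W ... p_REM` plus per-branch columns `ep_*`, `seq_*`.
#' @export
predict.stagenet <- function(object, ds, alpha_test = NULL, ...) {
  if (is.null(alpha_test)) alpha_test <- object$config$alpha_test
  if (alpha_test < 0 || alpha_test > 1) abort("alpha_test must be in [0, 1]")
  store <- if (inherits(ds, "epoch_store")) ds else as_training_store(ds)
  idx <- seq_len(nrow(store$meta)) - 1L
  fw <- cpp_forward(object$params, cfg_for_cpp(object$config), store$ptr, idx)
  p <- alpha_test * fw$p_ep + (1 - alpha_test) * fw$p_seq
  out <- store$meta[, c("record_id", "epoch", "stage")]
  out$stage[!(out$stage %in% sleep_stages)] <- NA
  out$pred <- argmax_stage(p)
  pm <- t(p); colnames(pm) <- paste0("p_", sleep_stages)
  em <- t(fw$p_ep); colnames(em) <- paste0("ep_", sleep_stages)
  sm <- t(fw$p_seq); colnames(sm) <- paste0("seq_", sleep_stages)
  dplyr::bind_cols(out, as_tibble(pm), as_tibble(em), as_tibble(sm))
}

#' Build a training store from an epoched dataset
#'
#' Copies the epoch tensors into a compact single-precision store used by
#' the training and prediction backends.  Record boundaries are kept so
#' context windows never cross recordings.
#'
#' @param ds a `psg_epochs` dataset.
#' @return An object of class `epoch_store` (external pointer + metadata).
#' @export
as_training_store <- function(ds) {
  stopifnot(inherits(ds, "psg_epochs"))
  spe <- dim(ds$x)[2]
  ptr <- cpp_store_new(dim(ds$x)[3], spe)
  order_rows <- integer(0)
  for (rid in unique(ds$meta$record_id)) {
    rows <- which(ds$meta$record_id == rid)
    labs <- match(ds$meta$stage[rows], sleep_stages)
    labs[is.na(labs)] <- 0L
    labs <- labs - 1L  # -1 marks unscored
    cpp_store_add(ptr, ds$x[, , rows, drop = FALSE], as.integer(labs))
    order_rows <- c(order_rows, rows)
  }
  structure(list(ptr = ptr, meta = ds$meta[order_rows, ], class_counts = ds$class_counts),
            class = "epoch_store")
}

#' @export
print.stagenet <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<stagenet> blocks [%s], %d features, N=%d context, %s parameters\n",
              paste(x$config$block_channels, collapse = ","),
              x$config$feature_dim, x$config$n_context, format(np, big.mark = ",")))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single file holding the parameter list, the model
#' configuration, the class order and a schema version tag.
#'
#' @param model a `stagenet`.
#' @param path checkpoint file path.
#' @return `load_stagenet()` returns the `stagenet`; `save_stagenet()`
#'   returns `path` invisibly.
#' @export
save_stagenet <- function(model, path) {
  stopifnot(inherits(model, "stagenet"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_stagenet
#' @export
load_stagenet <- function(path) {
  x <- readRDS(path)
  if (!identical(x$version, "nocturnet-checkpoint-1"))
    abort(sprintf("unsupported checkpoint version: %s", x$version))
  class(x$config) <- "stagenet_config"
  structure(x, class = "stagenet")
}
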