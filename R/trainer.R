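#' Transitive mixing schedule
#'
#' The branch-mixing factor decays quadratically over training epochs:
#' `alpha(T) = 1 - (T / T_max)^2`, starting at 1 (all weight on the
#' unweighted epoch branch loss) and reaching 0 at `T_max` (all weight on
#' the class-weighted sequence branch loss).  Learning therefore shifts
#' from universal epoch patterns to rebalanced contextual decisions.
#'
#' @param t current training epoch, `0 <= t <= t_max`.
#' @param t_max total number of training epochs (> 0).
#' @return `1 - (t / t_max)^2`.
#' @export
alpha_at <- function(t, t_max) {
  if (t_max <= 0) abort("t_max must be positive")
  if (any(t < 0) || any(t > t_max)) abort("t must lie in [0, t_max]")
  1 - (t / t_max)^2
}

#' Inverse-frequency class weights
#'
#' Weights are proportional to the inverse of the per-class sample counts
#' and normalised so their mean is 1, keeping the weighted sequence loss
#' on the same scale as the unweighted epoch loss.
#'
#' @param counts named vector of per-stage training counts (all > 0).
#' @return Named numeric weights over `sleep_stages`, mean 1.
#' @export
class_weights <- function(counts) {
  counts <- counts[sleep_stages]
  if (anyNA(counts) || any(counts <= 0))
    abort(paste("every stage needs a positive training count;",
                "drop the empty class or merge additional records"))
  w <- 1 / as.numeric(counts)
  stats::setNames(w / mean(w), sleep_stages)
}

#' Combined two-branch training loss
#'
#' `L = alpha * L_ep + (1 - alpha) * L_seq`, where `L_ep` is the
#' unweighted mean cross-entropy of the epoch-branch probabilities and
#' `L_seq` is the class-weighted cross-entropy of the sequence-branch
#' probabilities, normalised by the sum of the sample weights in the
#' batch.  Probabilities are clamped at `1e-12` before the log.
#'
#' @param p_ep,p_seq numeric matrices of stage probabilities, one row per
#'   sample, columns in canonical stage order.
#' @param y character vector of true stages.
#' @param alpha mixing factor in `[0, 1]`.
#' @param weights named per-stage weights (e.g. [class_weights()]);
#'   uniform by default.
#' @return A one-row tibble with `loss_ep`, `loss_seq`, `loss`, `alpha`.
#' @export
combined_loss <- function(p_ep, p_seq, y, alpha,
                          weights = stats::setNames(rep(1, 5), sleep_stages)) {
  p_ep <- matrix(p_ep, ncol = 5)
  p_seq <- matrix(p_seq, ncol = 5)
  if (alpha < 0 || alpha > 1) abort("alpha must be in [0, 1]")
  yi <- match(assert_stages(y), sleep_stages)
  if (length(yi) != nrow(p_ep) || length(yi) != nrow(p_seq))
    abort("batch shapes of p_ep, p_seq and y disagree")
  pick <- cbind(seq_along(yi), yi)
  l_ep <- mean(-log(pmax(p_ep[pick], 1e-12)))
  wy <- as.numeric(weights[sleep_stages][yi])
  l_seq <- sum(wy * -log(pmax(p_seq[pick], 1e-12))) / sum(wy)
  tibble(loss_ep = l_ep, loss_seq = l_seq,
         loss = alpha * l_ep + (1 - alpha) * l_seq, alpha = alpha)
}

#' Training configuration
#'
#' Defaults are the full-scale settings (Adam, batch 200, initial
#' learning rate 1e-3 decayed by `lr_decay_factor` once after
#' `lr_decay_at_fraction` of the iterations, 140,000 iterations with
#' 3,500 iterations per training epoch).  Scaled-down runs override
#' `iterations`, `batch_size` and `epochs_per_train_epoch`.
#'
#' @param iterations total mini-batch iterations.
#' @param batch_size mini-batch size.
#' @param lr initial Adam learning rate.
#' @param lr_decay_at_fraction fraction of training after which the
#'   learning rate is multiplied by `lr_decay_factor` (once).
#' @param lr_decay_factor multiplicative decay (0.1 = decay to 10%).
#' @param epochs_per_train_epoch iterations per training epoch; the
#'   mixing factor alpha is recomputed and validation runs at each
#'   training-epoch boundary.
#' @param seed integer seed for batch sampling (training is deterministic
#'   per seed on a fixed platform).
#' @param alpha_test branch mixture used for validation/model selection.
#' @return A list of class `train_config`.
#' @export
train_config <- function(iterations = 140000, batch_size = 200, lr = 0.001,
                         lr_decay_at_fraction = 0.7, lr_decay_factor = 0.1,
                         epochs_per_train_epoch = 3500, seed = 1,
                         alpha_test = 0.5) {
  stopifnot(iterations > 0, batch_size > 0, lr > 0,
            lr_decay_at_fraction > 0, lr_decay_at_fraction < 1,
            lr_decay_factor > 0, epochs_per_train_epoch > 0)
  structure(list(iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size), lr = lr,
                 lr_decay_at_fraction = lr_decay_at_fraction,
                 lr_decay_factor = lr_decay_factor,
                 epochs_per_train_epoch = as.integer(epochs_per_train_epoch),
                 seed = as.integer(seed), alpha_test = alpha_test),
            class = "train_config")
}

regime_code <- function(regime) {
  switch(match.arg(regime, c("transitive", "none", "weighted")),
         transitive = 0L, none = 1L, weighted = 2L)
}

# Weights used inside the trainer: inverse-frequency over classes present
# in the training data; classes with no samples never enter the loss and
# get weight 0. "none" regime uses uniform weights.
trainer_weights <- function(counts, regime) {
  if (regime %in% c("none")) return(stats::setNames(rep(1, 5), sleep_stages))
  w <- rep(0, 5)
  pres <- which(counts > 0)
  if (length(pres) == 0) abort("training set contains no scored epochs")
  wi <- 1 / counts[pres]
  w[pres] <- wi / mean(wi)
  stats::setNames(w, sleep_stages)
}

# Build one store holding the training records followed by the validation
# records; returns 0-based index sets.
build_train_store <- function(train_ds, val_ds = NULL) {
  ds <- if (is.null(val_ds)) train_ds else bind_epochs(list(train_ds, val_ds))
  store <- as_training_store(ds)
  n_train <- nrow(train_ds$meta)
  lab <- match(store$meta$stage, sleep_stages)
  train_idx <- which(!is.na(lab) & seq_along(lab) <= n_train) - 1L
  val_idx <- if (is.null(val_ds)) integer(0) else (n_train + seq_len(nrow(val_ds$meta))) - 1L
  list(store = store, train_idx = train_idx, val_idx = val_idx)
}

#' Train a staging network
#'
#' Runs the two-branch training loop: at each training-epoch boundary the
#' mixing factor is recomputed as `alpha_at(T, T_max)`; each mini-batch
#' minimises `alpha * L_ep + (1 - alpha) * L_seq` with the sequence loss
#' gradient-gated (it reaches the SLB only, never the CNN or ELB);
#' Adam updates all branches.  Validation macro-F1 is computed once per
#' training epoch and the best checkpoint (last wins on ties) is
#' returned.  Ablation regimes: `"none"` and `"weighted"` drop the epoch
#' branch from the loss and train the CNN through the (un)weighted
#' sequence loss without gating.
#'
#' @param model a `stagenet` (initial parameters).
#' @param train_ds,val_ds `psg_epochs` datasets; validation optional.
#' @param config a [train_config()].
#' @param regime `"transitive"` (default), `"none"` or `"weighted"`.
#' @return An object of class `stagenet_fit`: `model` (best checkpoint),
#'   `final_model`, `history` (per-iteration tibble), `validation`
#'   (per-epoch tibble), `class_weights`, `regime`, `config`.
#' @export
train_stagenet <- function(model, train_ds, val_ds = NULL,
                           config = train_config(), regime = "transitive") {
  stopifnot(inherits(model, "stagenet"), inherits(config, "train_config"))
  bs <- build_train_store(train_ds, val_ds)
  wts <- trainer_weights(as.numeric(train_ds$class_counts), regime)
  train_core(model, bs$store, bs$train_idx, bs$val_idx, config, regime, wts)
}

# Core loop shared by train_stagenet() and run_rebalancing_comparison():
# operates directly on an epoch store with explicit 0-based index sets.
train_core <- function(model, store, train_idx, val_idx, config, regime, wts) {
  t_max <- as.integer(ceiling(config$iterations / config$epochs_per_train_epoch))
  tcfg <- list(iterations = config$iterations, batch_size = config$batch_size,
               lr = config$lr, lr_decay_at_fraction = config$lr_decay_at_fraction,
               lr_decay_factor = config$lr_decay_factor,
               epochs_per_train_epoch = config$epochs_per_train_epoch,
               t_max = t_max, seed = config$seed, regime = regime_code(regime),
               alpha_test = config$alpha_test, class_weights = as.numeric(wts))
  res <- cpp_train(model$params, cfg_for_cpp(model$config), store$ptr,
                   as.integer(train_idx), as.integer(val_idx), tcfg)
  hist <- as_tibble(stats::setNames(as.data.frame(res$history),
                                    c("iteration", "train_epoch", "alpha",
                                      "loss_ep", "loss_seq", "loss", "lr")))
  val <- as_tibble(stats::setNames(as.data.frame(res$val_log),
                                   c("iteration", "train_epoch", "accuracy",
                                     "kappa", "mf1")))
  best <- model
  best$params <- res$best_params
  final <- model
  final$params <- res$params
  structure(list(model = best, final_model = final, history = hist,
                 validation = val, best_mf1 = res$best_mf1,
                 best_iteration = res$best_iter, class_weights = wts,
                 regime = regime, config = config),
            class = "stagenet_fit")
}

#' @export
print.stagenet_fit <- function(x, ...) {
  cat(sprintf("<stagenet_fit> regime=%s, %d iterations, best val MF1 %.4f @ iter %d\n",
              x$regime, nrow(x$history), x$best_mf1, as.integer(x$best_iteration)))
  invisible(x)
}

#' One-batch loss and gradients (diagnostic)
#'
#' Computes the combined loss and the exact parameter gradients for a
#' chosen mini-batch without updating the model.  Useful for verifying
#' the gradient gate: with `regime = "transitive"` the sequence loss
#' reaches only the SLB parameters, so at `alpha = 0` every CNN and ELB
#' gradient is exactly zero.
#'
#' @param model a `stagenet`.
#' @param store an `epoch_store` (see [as_training_store()]).
#' @param centers 0-based epoch indices forming the batch.
#' @param alpha mixing factor.
#' @param weights per-stage weights (default uniform).
#' @param regime training regime as in [train_stagenet()].
#' @return List with `grads` (named list of gradient matrices), `loss_ep`,
#'   `loss_seq`, `loss`.
#' @export
stagenet_gradients <- function(model, store, centers, alpha,
                               weights = stats::setNames(rep(1, 5), sleep_stages),
                               regime = "transitive") {
  stopifnot(inherits(model, "stagenet"), inherits(store, "epoch_store"))
  res <- cpp_grads(model$params, cfg_for_cpp(model$config), store$ptr,
                   as.integer(centers), alpha, as.numeric(weights[sleep_stages]),
                   regime_code(regime))
  list(grads = res$grads, loss_ep = res$L_ep, loss_seq = res$L_seq, loss = res$L)
}
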