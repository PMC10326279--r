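#' Simulate an epoched dataset directly into a training store
#'
#' Streams one simulated record at a time into the single-precision
#' training store, so large multi-record datasets (e.g. 30 records of
#' 840 epochs) never exist as a full double-precision R array.
#'
#' @param cfg a [sim_config()].
#' @return An `epoch_store` with `meta` describing every epoch.
#' @export
simulate_training_store <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n_total <- cfg$n_records * cfg$epochs_per_record
  ptr <- cpp_store_new(n_total, samples_per_epoch())
  metas <- vector("list", cfg$n_records)
  with_seed(cfg$seed, {
    for (r in seq_len(cfg$n_records)) {
      id <- sprintf("sim-%03d", r)
      hyp <- simulate_hypnogram(cfg$epochs_per_record, cfg$tm)
      stages <- as.character(hyp$stage)
      x <- simulate_record_signals(stages, cfg$profile, cfg$lambda)
      labs <- match(stages, sleep_stages)
      labs[is.na(labs)] <- 0L
      cpp_store_add(ptr, x, as.integer(labs - 1L))
      metas[[r]] <- tibble(record_id = id, epoch = seq_along(stages) - 1L,
                           stage = stages, scored = stages %in% sleep_stages)
      rm(x)
    }
  })
  meta <- dplyr::bind_rows(metas)
  cc <- table(factor(meta$stage[meta$scored], levels = sleep_stages))
  structure(list(ptr = ptr, meta = meta,
                 class_counts = stats::setNames(as.integer(cc), sleep_stages)),
            class = "epoch_store")
}

eval_on_store <- function(model, store, idx, alpha_test, use_mixture) {
  fw <- cpp_forward(model$params, cfg_for_cpp(model$config), store$ptr, as.integer(idx))
  p <- if (use_mixture) alpha_test * fw$p_ep + (1 - alpha_test) * fw$p_seq else fw$p_seq
  pred <- argmax_stage(p)
  truth <- store$meta$stage[idx + 1L]
  keep <- truth %in% sleep_stages
  list(truth = truth[keep], pred = pred[keep],
       record_id = store$meta$record_id[idx + 1L][keep])
}

#' Rebalancing-strategy comparison on simulated data
#'
#' Trains the same architecture under three regimes on identical data and
#' batch sequences, then evaluates on a held-out test split:
#' \describe{
#'   \item{`none`}{sequence branch only, unweighted cross-entropy (no
#'     rebalancing); the CNN trains through the sequence loss.}
#'   \item{`weighted`}{sequence branch only, inverse-frequency weighted
#'     cross-entropy.}
#'   \item{`transitive`}{the full two-branch schedule with the gradient
#'     gate.}
#' }
#' The expected pattern is a trade-off: weighting buys N1 recall at the
#' cost of overall accuracy, and the transitive schedule recovers most of
#' the N1 recall while keeping accuracy close to the unweighted model.
#' Records are split 80/10/10 into train/validation/test; the best
#' validation-MF1 checkpoint per regime is evaluated.
#'
#' @param sim_cfg a [sim_config()]; its seed is replaced per replicate.
#' @param model_cfg a [stagenet_config()].
#' @param train_cfg a [train_config()]; its seed is replaced per replicate.
#' @param regimes subset of `c("none", "weighted", "transitive")`.
#' @param seeds integer vector; one independent replicate (fresh data,
#'   fresh initialisation) per seed.  Within a seed, all regimes share
#'   byte-identical data, initial parameters and batch sequences.
#' @return An object of class `rebalancing_comparison`: list with
#'   `metrics` (tibble: seed, regime, accuracy, kappa, mf1, per-class
#'   recall) and `confusions` (named list of [confusion_matrix()]).
#' @export
run_rebalancing_comparison <- function(sim_cfg = sim_config(),
                                       model_cfg = stagenet_config(),
                                       train_cfg = train_config(),
                                       regimes = c("none", "weighted", "transitive"),
                                       seeds = 1:3) {
  regimes <- match.arg(regimes, c("none", "weighted", "transitive"), several.ok = TRUE)
  rows <- list()
  confusions <- list()
  for (s in seeds) {
    scfg <- sim_cfg
    scfg$seed <- s
    store <- simulate_training_store(scfg)
    n <- scfg$n_records
    n_te <- max(1L, round(0.1 * n))
    n_val <- max(1L, round(0.1 * n))
    n_tr <- n - n_te - n_val
    if (n_tr < 1) abort("need at least 3 records for a train/val/test split")
    rec_ids <- unique(store$meta$record_id)
    split_of <- rep(c("train", "val", "test"), c(n_tr, n_val, n_te))
    rec_split <- stats::setNames(split_of, rec_ids)
    grp <- rec_split[store$meta$record_id]
    lab_ok <- store$meta$stage %in% sleep_stages
    train_idx <- which(grp == "train" & lab_ok) - 1L
    val_idx <- which(grp == "val") - 1L
    test_idx <- which(grp == "test") - 1L
    counts <- table(factor(store$meta$stage[grp == "train" & lab_ok],
                           levels = sleep_stages))
    model0 <- init_stagenet(model_cfg, seed = s)
    tcfg <- train_cfg
    tcfg$seed <- as.integer(s)
    for (reg in regimes) {
      wts <- trainer_weights(as.numeric(counts), reg)
      fit <- train_core(model0, store, train_idx, val_idx, tcfg, reg, wts)
      ev <- eval_on_store(fit$model, store, test_idx, tcfg$alpha_test,
                          use_mixture = (reg == "transitive"))
      cm <- confusion_matrix(ev$truth, ev$pred)
      confusions[[sprintf("seed%s_%s", s, reg)]] <- cm
      m <- staging_metrics(ev$truth, ev$pred)
      rows[[length(rows) + 1]] <- dplyr::bind_cols(tibble(seed = s, regime = reg), m)
    }
    rm(store)
    gc(verbose = FALSE)
  }
  structure(list(metrics = dplyr::bind_rows(rows), confusions = confusions,
                 regimes = regimes, seeds = seeds),
            class = "rebalancing_comparison")
}

#' @export
print.rebalancing_comparison <- function(x, ...) {
  cat("<rebalancing_comparison>\n")
  print(as.data.frame(x$metrics[, c("seed", "regime", "n_epochs", "accuracy",
                                    "kappa", "mf1", "recall_N1")]))
  invisible(x)
}
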