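#' Tidy a fitted staging network
#'
#' One row per parameter tensor of the best checkpoint, with its role
#' (feature extractor, epoch branch or sequence branch) and size.
#'
#' @param x a `stagenet_fit`.
#' @param ... unused.
#' @return A tibble with columns `parameter`, `component`, `rows`,
#'   `cols`, `n`.
#' @method tidy stagenet_fit
#' @export
tidy.stagenet_fit <- function(x, ...) {
  p <- x$model$params
  comp <- function(nm) {
    if (startsWith(nm, "elb.")) "elb" else if (startsWith(nm, "slb.")) "slb" else "cnn"
  }
  tibble(parameter = names(p),
         component = vapply(names(p), comp, character(1)),
         rows = vapply(p, nrow, integer(1)),
         cols = vapply(p, ncol, integer(1)),
         n = vapply(p, length, integer(1)))
}

#' Glance at a fitted staging network
#'
#' @param x a `stagenet_fit`.
#' @param ... unused.
#' @return A one-row tibble: regime, iterations, best validation MF1 and
#'   iteration, final mixing factor, parameter count.
#' @method glance stagenet_fit
#' @export
glance.stagenet_fit <- function(x, ...) {
  tibble(regime = x$regime,
         iterations = nrow(x$history),
         best_iteration = as.integer(x$best_iteration),
         best_val_mf1 = x$best_mf1,
         final_alpha = x$history$alpha[nrow(x$history)],
         n_parameters = sum(vapply(x$model$params, length, numeric(1))))
}

#' Tidy a confusion matrix
#'
#' @param x a [confusion_matrix()].
#' @param ... unused.
#' @return A long tibble with `truth`, `predicted`, `n` and the
#'   row-normalised proportion `prop_row`.
#' @method tidy confusion_matrix
#' @export
tidy.confusion_matrix <- function(x, ...) {
  pr <- row_normalize(x)
  df <- tidyr::expand_grid(truth = sleep_stages, predicted = sleep_stages)
  df$n <- as.integer(unclass(x)[cbind(match(df$truth, sleep_stages),
                                      match(df$predicted, sleep_stages))])
  df$prop_row <- pr[cbind(match(df$truth, sleep_stages),
                          match(df$predicted, sleep_stages))]
  df
}
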