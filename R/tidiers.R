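#' Tidy the training curve of a classifier
#' @param x A `scar_classifier` from [train_classifier()].
#' @param ... Unused.
#' @return The per-epoch curve tibble (`epoch`, `train_accuracy`,
#'   `test_accuracy`, `loss`).
#' @export
tidy.scar_classifier <- function(x, ...) {
  x$curve %||% tibble::tibble(epoch = integer(), train_accuracy = numeric(),
                              test_accuracy = numeric(), loss = numeric())
}

#' One-row summary of a trained classifier
#' @inheritParams tidy.scar_classifier
#' @return A tibble with attention type, parameter count, epochs trained and
#'   final accuracies.
#' @export
glance.scar_classifier <- function(x, ...) {
  cv <- tidy(x)
  tibble::tibble(attention = x$config$attention,
                 input_size = x$config$input_size,
                 n_parameters = n_params(x$net),
                 epochs = nrow(cv),
                 train_accuracy = if (nrow(cv)) cv$train_accuracy[nrow(cv)] else NA_real_,
                 test_accuracy = if (nrow(cv)) cv$test_accuracy[nrow(cv)] else NA_real_)
}

#' Tidy an evaluation report into ROC points
#' @param x A `scar_eval` from [evaluate_classifier()].
#' @param ... Unused.
#' @return The ROC tibble (`threshold`, `fpr`, `tpr`).
#' @export
tidy.scar_eval <- function(x, ...) x$roc

#' One-row summary of an evaluation report
#' @inheritParams tidy.scar_eval
#' @return A tibble with `accuracy`, `auc` and the test-set size.
#' @export
glance.scar_eval <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, auc = x$auc, n = sum(x$confusion))
}

#' Tidy a sigma-filter result
#' @param x A `filter_result` from [sigma_filter()].
#' @param ... Unused.
#' @return The per-image report tibble (`source_id`, `score`, `cluster`,
#'   `kept`).
#' @export
tidy.filter_result <- function(x, ...) x$report

#' One-row summary of a sigma-filter result
#' @inheritParams tidy.filter_result
#' @return A tibble with counts, removed fraction, center and sigma.
#' @export
glance.filter_result <- function(x, ...) {
  tibble::tibble(n = nrow(x$report), n_kept = length(x$kept_ids),
                 n_removed = length(x$removed_ids),
                 removed_fraction = length(x$removed_ids) / nrow(x$report),
                 center = x$center[1], sigma = x$sigma[1],
                 k_sigma = x$k_sigma)
}
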