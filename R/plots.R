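image_long <- function(m, value = "intensity") {
  d <- expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  d[[value]] <- as.vector(m)
  tibble::as_tibble(d)
}

#' Plot images of a dataset
#'
#' @param dataset A dataset tibble.
#' @param n Number of images to show (first `n` rows).
#' @return A ggplot faceted by `source_id`.
#' @export
plot_images <- function(dataset, n = 8) {
  rows <- head(dataset, n)
  df <- dplyr::bind_rows(purrr::map2(rows$pixels, rows$source_id, function(m, id) {
    dplyr::mutate(image_long(m), source_id = id)
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::facet_wrap(~source_id) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Overlay Grad-CAM heatmaps on their images
#'
#' @param heatmaps A [grad_cam()] result.
#' @param dataset The matching dataset tibble.
#' @param n Number of images to show.
#' @param threshold Heatmap values below this are fully transparent.
#' @return A ggplot faceted by `source_id`.
#' @export
plot_heatmaps <- function(heatmaps, dataset, n = 8, threshold = 0.2) {
  rows <- head(heatmaps, n)
  px <- dataset$pixels[match(rows$source_id, dataset$source_id)]
  base <- dplyr::bind_rows(purrr::map2(px, rows$source_id, function(m, id) {
    dplyr::mutate(image_long(m), source_id = id)
  }))
  hm <- dplyr::bind_rows(purrr::map2(rows$heatmap, rows$source_id, function(m, id) {
    dplyr::mutate(image_long(m, "activation"), source_id = id)
  }))
  hm$activation[hm$activation < threshold] <- NA
  ggplot2::ggplot(base, ggplot2::aes(.data$col, -.data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1),
                                 guide = "none") +
    ggplot2::geom_raster(data = hm, ggplot2::aes(alpha = .data$activation),
                         fill = "red", na.rm = TRUE) +
    ggplot2::scale_alpha(range = c(0, 0.7), limits = c(0, 1)) +
    ggplot2::facet_wrap(~source_id) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Training-curve plot for a classifier
#' @param object A trained `scar_classifier`.
#' @param ... Unused.
#' @return A ggplot of per-epoch train/test accuracy.
#' @export
autoplot.scar_classifier <- function(object, ...) {
  cv <- tidy(object)
  df <- tidyr::pivot_longer(cv, c("train_accuracy", "test_accuracy"),
                            names_to = "set", values_to = "accuracy")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$accuracy,
                                   colour = .data$set)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(title = "Classification accuracy curve", colour = NULL)
}

#' ROC plot for an evaluation report
#' @param object A `scar_eval`.
#' @param ... Unused.
#' @return A ggplot of the ROC curve, AUC in the subtitle.
#' @export
autoplot.scar_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = 2, colour = "grey") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  subtitle = sprintf("AUC = %.3f", object$auc))
}

#' Score distribution of a sigma-filter result
#' @param object A `filter_result`.
#' @param ... Unused.
#' @return A ggplot histogram of PC1 scores with the keep band marked.
#' @export
autoplot.filter_result <- function(object, ...) {
  lim <- object$center[1] + c(-1, 1) * object$k_sigma * object$sigma[1]
  ggplot2::ggplot(object$report, ggplot2::aes(.data$score, fill = .data$kept)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::geom_vline(xintercept = lim, linetype = 2) +
    ggplot2::labs(x = "PC1 score", fill = "kept")
}
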