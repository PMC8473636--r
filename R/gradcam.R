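#' Grad-CAM heatmaps for a classifier
#'
#' For each image, the gradient of the target-class logit with respect to
#' the last convolutional feature map (the activation just before global
#' pooling) is averaged over space to weight the channels; the weighted sum
#' is rectified, bilinearly upsampled to the image size, and normalized to
#' a maximum of 1 (an identically-zero map stays zero).
#'
#' @param model A `scar_classifier`.
#' @param dataset A dataset tibble at the model's input size.
#' @param target_class `"scar"` (default) or `"control"`.
#' @param batch_size Images per forward/backward pass.
#' @return A tibble with `source_id`, `label`, `target_class` and a
#'   `heatmap` list-column of H x W maps in \[0,1\].
#' @export
grad_cam <- function(model, dataset, target_class = "scar", batch_size = 64) {
  if (!target_class %in% model$classes)
    abort(sprintf("unknown target class '%s'", target_class))
  check_input_size(model, dataset)
  cls_idx <- match(target_class, model$classes)
  layers <- model$net$sub
  gc_i <- model$gc_index
  n <- nrow(dataset)
  maps <- vector("list", n)
  for (s in seq(1, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1, n)
    x <- stack_images(dataset$pixels[idx])
    caches <- vector("list", length(layers))
    A <- NULL
    for (i in seq_along(layers)) {
      r <- layer_fwd(layers[[i]], x)
      x <- r$y
      caches[[i]] <- r$cache
      if (i == gc_i) A <- x
    }
    nb <- length(idx)
    dy <- matrix(0, 2, nb)
    dy[cls_idx, ] <- 1                         # d(class logit)
    for (i in rev(seq_along(layers))) {
      if (i <= gc_i) break
      dy <- layer_bwd(layers[[i]], caches[[i]], dy)$dx
    }
    dA <- dy                                   # (h, w, C, nb)
    d <- dim(A)
    w <- matrix(colMeans(array(dA, c(d[1] * d[2], d[3] * d[4]))), d[3], d[4])
    for (j in seq_len(nb)) {
      cam <- matrix(0, d[1], d[2])
      for (c in seq_len(d[3])) cam <- cam + w[c, j] * A[, , c, j]
      cam <- pmax(cam, 0)
      cam <- resize_pixels(cam, model$config$input_size)
      cam <- pmax(cam, 0)
      if (max(cam) > 0) cam <- cam / max(cam)
      maps[[idx[j]]] <- cam
    }
  }
  tibble::tibble(source_id = dataset$source_id, label = dataset$label,
                 target_class = target_class, heatmap = maps)
}

#' Fraction of heatmap pixels at or above a threshold
#'
#' The region-of-interest (ROI) area of a normalized heatmap; smaller
#' values mean a more focused activation.  Nonincreasing in `threshold`.
#'
#' @param heatmap An H x W map in \[0,1\].
#' @param threshold Activation threshold in (0,1).
#' @return A fraction in \[0,1\].
#' @export
roi_fraction <- function(heatmap, threshold = 0.5) {
  check_number(threshold, "threshold", lower = 1e-12, upper = 1 - 1e-12)
  mean(heatmap >= threshold)
}

#' Overlap between a thresholded heatmap and a ground-truth scar mask
#'
#' Intersection-over-union (IoU) of the binary map `heatmap >= threshold`
#' with the mask.  An empty mask has no defined overlap and yields `NA`.
#'
#' @param heatmap An H x W map in \[0,1\].
#' @param scar_mask A binary matrix of the same shape.
#' @param threshold Activation threshold in (0,1).
#' @return IoU in \[0,1\], or `NA_real_` for an empty mask.
#' @export
localization_overlap <- function(heatmap, scar_mask, threshold = 0.5) {
  if (!identical(dim(heatmap), dim(scar_mask)))
    abort("heatmap and mask shapes differ")
  if (sum(scar_mask) == 0) return(NA_real_)
  hot <- heatmap >= threshold
  m <- scar_mask > 0
  inter <- sum(hot & m)
  union <- sum(hot | m)
  if (union == 0) 0 else inter / union
}

#' Per-image ROI and localization statistics for a heatmap set
#'
#' @param heatmaps A [grad_cam()] result.
#' @param dataset The matching dataset (for ground-truth masks, if any).
#' @param threshold Activation threshold.
#' @return The heatmap tibble with `roi_fraction` and (when masks exist)
#'   `overlap` columns appended.
#' @export
heatmap_stats <- function(heatmaps, dataset = NULL, threshold = 0.5) {
  out <- dplyr::mutate(heatmaps,
    roi_fraction = purrr::map_dbl(.data$heatmap, roi_fraction, threshold = threshold))
  if (!is.null(dataset) && "mask" %in% names(dataset)) {
    masks <- dataset$mask[match(out$source_id, dataset$source_id)]
    out$overlap <- purrr::map2_dbl(out$heatmap, masks, function(h, m) {
      if (is.null(m)) NA_real_ else localization_overlap(h, m, threshold)
    })
  }
  out
}
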