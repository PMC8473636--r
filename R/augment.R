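#' Traditional augmentation plan
#'
#' One plan per class: `n_rotations` evenly spaced nonzero rotations per
#' image plus (optionally) one flipped, one shifted and one scaled copy.
#' The rotation angles are `i * 360 / (n_rotations + 1)` for
#' `i = 1..n_rotations`, so no rotation duplicates the original and a class
#' with `b` base images yields exactly
#' `b * (1 + n_rotations + n_extras)` pool images — e.g. 557 scar images
#' with 8 rotations and all three extras give 557 x 12 = 6,684.
#'
#' @param n_rotations Rotations per image (8 for the scar class and 72 for
#'   the control class in the motivating imbalance).
#' @param include_flip,include_shift,include_scale Enable the single extra
#'   copies (all `TRUE` by default).
#' @param shift_fraction Maximum translation per axis as a fraction of the
#'   image size (0 < f < 0.5).
#' @param scale_range Multiplicative zoom interval within (0.5, 2).
#' @param seed Integer seed; shift offsets and scale factors are drawn
#'   deterministically from the seed and each image's `source_id`.
#' @return An `augmentation_plan` list.
#' @export
augmentation_plan <- function(n_rotations = 8, include_flip = TRUE,
                              include_shift = TRUE, include_scale = TRUE,
                              shift_fraction = 0.1, scale_range = c(0.9, 1.1),
                              seed = 0) {
  check_number(n_rotations, "n_rotations", lower = 0, integer = TRUE)
  check_number(shift_fraction, "shift_fraction", lower = 1e-9, upper = 0.5 - 1e-9)
  check_range(scale_range, "scale_range", 0.5 + 1e-9, 2 - 1e-9)
  check_number(seed, "seed", lower = 0, integer = TRUE)
  structure(list(n_rotations = as.integer(n_rotations),
                 include_flip = isTRUE(include_flip),
                 include_shift = isTRUE(include_shift),
                 include_scale = isTRUE(include_scale),
                 shift_fraction = shift_fraction,
                 scale_range = scale_range,
                 seed = as.integer(seed)),
            class = "augmentation_plan")
}

n_extras <- function(plan)
  sum(plan$include_flip, plan$include_shift, plan$include_scale)

# Stable 31-bit hash of a source id, for per-image deterministic draws.
id_hash <- function(id) {
  v <- utf8ToInt(id)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2147483647
  as.integer(h)
}

# Apply a geometric op to pixels and (if present) the binary mask.
transform_record <- function(record, provenance, suffix, fpx, fmask = fpx) {
  out <- record
  out$pixels <- list(clamp01(fpx(record$pixels[[1]])))
  if (!is.null(record$mask[[1]]))
    out$mask <- list((fmask(record$mask[[1]]) >= 0.5) * 1)
  out$provenance <- provenance
  out$source_id <- paste0(record$source_id, "_", suffix)
  out
}

#' Rotate every image in a dataset
#'
#' Rotation is about the image center, counterclockwise-positive, bilinear,
#' zero-filled outside the frame; the angle is normalized mod 360 before
#' resampling so a 360-degree rotation is the identity.
#'
#' @param dataset A dataset tibble (one or more rows).
#' @param angle Rotation angle in degrees.
#' @return The dataset with rotated `pixels` (and masks), provenance
#'   `"rotated"`, and `source_id`s suffixed by the angle.
#' @export
rotate_image <- function(dataset, angle) {
  check_number(angle, "angle")
  rows <- lapply(seq_len(nrow(dataset)), function(i) {
    transform_record(dataset[i, ], "rotated", sprintf("rot%g", angle %% 360),
                     function(m) rotate_pixels(m, angle))
  })
  dplyr::bind_rows(rows)
}

#' All augmented copies of each image under a plan
#'
#' Returns, per input image: the original, `n_rotations` rotated copies,
#' and one flipped / shifted / scaled copy for each enabled extra.  The
#' shift offset and scale factor are fixed functions of
#' `(plan$seed, source_id)`, so the output is fully deterministic.
#'
#' @param dataset A dataset tibble.
#' @param plan An [augmentation_plan()].
#' @return A tibble of `nrow(dataset) * (1 + n_rotations + n_extras)` records.
#' @export
transform_copies <- function(dataset, plan) {
  if (!inherits(plan, "augmentation_plan")) abort("`plan` must be an augmentation_plan")
  keep <- intersect(c("source_id", "label", "provenance", "pixels", "mask"),
                    names(dataset))
  dataset <- dataset[, keep]
  rows <- lapply(seq_len(nrow(dataset)), function(i) {
    rec <- dataset[i, ]
    out <- list(rec)
    n <- plan$n_rotations
    if (n > 0) {
      angles <- seq_len(n) * 360 / (n + 1)
      out <- c(out, lapply(angles, function(a) {
        transform_record(rec, "rotated", sprintf("rot%03.0f", a),
                         function(m) rotate_pixels(m, a))
      }))
    }
    rseed <- seed_add(plan$seed, id_hash(rec$source_id))
    draws <- with_seed(rseed, list(
      dx = runif(1, -1, 1) * plan$shift_fraction,
      dy = runif(1, -1, 1) * plan$shift_fraction,
      sc = runif(1, plan$scale_range[1], plan$scale_range[2])))
    if (plan$include_flip)
      out <- c(out, list(transform_record(rec, "flipped", "flip", flip_pixels)))
    if (plan$include_shift) {
      sz <- nrow(rec$pixels[[1]])
      out <- c(out, list(transform_record(
        rec, "shifted", "shift",
        function(m) shift_pixels(m, draws$dx * sz, draws$dy * sz))))
    }
    if (plan$include_scale)
      out <- c(out, list(transform_record(
        rec, "scaled", "scale", function(m) scale_pixels(m, draws$sc))))
    dplyr::bind_rows(out)
  })
  dplyr::bind_rows(rows)
}

#' Build the per-class augmented image pool
#'
#' @param dataset A labeled dataset tibble.
#' @param plans A single [augmentation_plan()] used for every class, or a
#'   named list of plans keyed by class label.
#' @return An `image_pool` tibble of augmented records; per-class counts are
#'   available via [pool_counts()].
#' @export
build_pool <- function(dataset, plans) {
  if (inherits(plans, "augmentation_plan")) {
    plans <- setNames(rep(list(plans), length(unique(dataset$label))),
                      unique(dataset$label))
  }
  classes <- unique(dataset$label)
  miss <- setdiff(classes, names(plans))
  if (length(miss) > 0)
    abort(paste0("no augmentation plan for class(es): ", paste(miss, collapse = ", ")))
  pool <- dplyr::bind_rows(lapply(classes, function(cl) {
    transform_copies(dataset[dataset$label == cl, ], plans[[cl]])
  }))
  class(pool) <- c("image_pool", class(pool))
  pool
}

#' Per-class record counts of a pool or dataset
#' @param pool A dataset/pool tibble.
#' @return A tibble with columns `label` and `n`.
#' @export
pool_counts <- function(pool) {
  dplyr::count(tibble::as_tibble(pool), .data$label, name = "n")
}

#' Images the minority class lacks relative to the majority
#'
#' The sampling deficit used when balancing classes before augmentation:
#' e.g. 104 controls against 557 scar images leave a deficit of 453.
#'
#' @param n_minority,n_majority Class sizes, `n_majority >= n_minority >= 0`.
#' @return `n_majority - n_minority`.
#' @export
balance_deficit <- function(n_minority, n_majority) {
  check_number(n_minority, "n_minority", lower = 0, integer = TRUE)
  check_number(n_majority, "n_majority", lower = 0, integer = TRUE)
  if (n_minority > n_majority)
    abort(sprintf("n_minority (%d) exceeds n_majority (%d)", n_minority, n_majority))
  as.integer(n_majority - n_minority)
}

#' Sample a balanced training set from an image pool
#'
#' Draws `factor * n_base_majority` images per class, uniformly without
#' replacement from each class's pool — e.g. 4x augmentation of a majority
#' base of 557 yields 2,228 images per class.
#'
#' @param pool An [build_pool()] output (or any labeled dataset tibble).
#' @param factor Augmentation scale (positive integer).
#' @param n_base_majority Majority-class base image count.
#' @param seed Integer seed; sampling is deterministic given the seed.
#' @return A balanced tibble of `factor * n_base_majority` records per class.
#' @export
sample_balanced <- function(pool, factor, n_base_majority, seed = 0) {
  check_number(factor, "factor", lower = 1, integer = TRUE)
  check_number(n_base_majority, "n_base_majority", lower = 0, integer = TRUE)
  n_per <- factor * n_base_majority
  counts <- pool_counts(pool)
  for (i in seq_len(nrow(counts))) {
    if (counts$n[i] < n_per)
      abort(sprintf("class '%s' pool has %d images, %d required",
                    counts$label[i], counts$n[i], n_per))
  }
  idx <- with_seed(seed, {
    unlist(lapply(sort(unique(pool$label)), function(cl) {
      sample(which(pool$label == cl), n_per)
    }))
  })
  out <- tibble::as_tibble(pool)[sort(idx), ]
  out
}
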