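#' Write an image dataset as PNG files plus a manifest
#'
#' Each record becomes an 8-bit grayscale PNG named after its `source_id`;
#' ground-truth scar masks (when present) are written as parallel
#' `*_mask.png` files.  The manifest CSV records
#' `source_id, filename, label, provenance, mask_filename`.
#'
#' @param dataset A dataset tibble (see [make_phantom_dataset()]).
#' @param directory Output directory, created if missing.
#' @param manifest_file Manifest filename within `directory`.
#' @return The manifest tibble, invisibly.
#' @export
write_dataset <- function(dataset, directory, manifest_file = "manifest.csv") {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  has_mask <- "mask" %in% names(dataset)
  rows <- purrr::pmap(dataset, function(source_id, label, provenance, pixels, ...) {
    extra <- list(...)
    fn <- paste0(source_id, ".png")
    png::writePNG(clamp01(pixels), file.path(directory, fn))
    mfn <- NA_character_
    if (has_mask && !is.null(extra$mask)) {
      mfn <- paste0(source_id, "_mask.png")
      png::writePNG(clamp01(extra$mask), file.path(directory, mfn))
    }
    tibble::tibble(source_id = source_id, filename = fn, label = label,
                   provenance = provenance, mask_filename = mfn)
  })
  manifest <- dplyr::bind_rows(rows)
  if (nrow(manifest) == 0)
    manifest <- tibble::tibble(source_id = character(), filename = character(),
                               label = character(), provenance = character(),
                               mask_filename = character())
  write.csv(manifest, file.path(directory, manifest_file), row.names = FALSE)
  invisible(manifest)
}

#' Read an image dataset described by a manifest
#'
#' Images are rescaled to \[0,1\] by their format's maximum value (the PNG
#' reader does this natively); color images are collapsed to grayscale by
#' averaging channels, since MR magnitude images are single-channel.
#'
#' @param directory Directory holding the image files.
#' @param manifest A manifest tibble/data frame, or the path of a manifest
#'   CSV (default `manifest.csv` inside `directory`).
#' @return A dataset tibble with one row per manifest row.
#' @export
read_dataset <- function(directory, manifest = NULL) {
  if (is.null(manifest)) manifest <- file.path(directory, "manifest.csv")
  if (is.character(manifest))
    manifest <- tibble::as_tibble(read.csv(manifest, stringsAsFactors = FALSE))
  validate_manifest(manifest)
  if (nrow(manifest) == 0) return(empty_dataset())
  missing <- manifest$filename[!file.exists(file.path(directory, manifest$filename))]
  if (length(missing) > 0)
    abort(paste0("missing image file(s): ", paste(missing, collapse = ", ")))
  px <- purrr::map(manifest$filename, function(fn) read_gray_png(file.path(directory, fn)))
  masks <- if ("mask_filename" %in% names(manifest)) {
    purrr::map(manifest$mask_filename, function(fn) {
      if (is.na(fn)) NULL
      else (read_gray_png(file.path(directory, fn)) >= 0.5) * 1
    })
  } else rep(list(NULL), nrow(manifest))
  tibble::tibble(source_id = manifest$source_id, label = manifest$label,
                 provenance = manifest$provenance, pixels = px, mask = masks)
}

read_gray_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) {
    nc <- min(dim(x)[3], 3)            # drop alpha, average color channels
    x <- apply(x[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
  }
  x
}

validate_manifest <- function(manifest) {
  need <- c("source_id", "filename", "label", "provenance")
  miss <- setdiff(need, names(manifest))
  if (length(miss) > 0)
    abort(paste0("manifest lacks column(s): ", paste(miss, collapse = ", ")))
  if (anyDuplicated(manifest$source_id))
    abort("manifest source_id values must be unique")
  bad <- setdiff(unique(manifest$label), c("scar", "control"))
  if (length(bad) > 0)
    abort(paste0("unknown label(s): ", paste(bad, collapse = ", ")))
  invisible(manifest)
}

#' Stratified train/test split
#'
#' Draws exactly `n_test_per_class` records per class into the test set,
#' uniformly at random, before any augmentation — so no augmented copy of a
#' test image can leak into training.  Splitting is at the image level;
#' phantom datasets have no patient grouping to respect.
#'
#' @param dataset A dataset tibble.
#' @param n_test_per_class Test-set size per class.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return A list with tibbles `train` and `test`; their `source_id` sets
#'   partition the input.
#' @export
split_dataset <- function(dataset, n_test_per_class, seed = 0) {
  check_number(n_test_per_class, "n_test_per_class", lower = 0, integer = TRUE)
  counts <- table(dataset$label)
  for (cl in names(counts)) {
    if (counts[[cl]] < n_test_per_class)
      abort(sprintf("class '%s' has %d records, need >= %d for the test split",
                    cl, counts[[cl]], n_test_per_class))
  }
  test_ids <- with_seed(seed, {
    unlist(lapply(sort(unique(dataset$label)), function(cl) {
      ids <- dataset$source_id[dataset$label == cl]
      sample(ids, n_test_per_class)
    }))
  })
  list(train = dataset[!dataset$source_id %in% test_ids, ],
       test = dataset[dataset$source_id %in% test_ids, ])
}
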