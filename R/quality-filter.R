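#' Fixed feature-extraction backbone
#'
#' The classifier backbone with a `d`-dimensional linear head and frozen,
#' seeded random weights: a "random-feature" embedding.  Random convolutional
#' features are a standard distance-preserving embedding and keep the
#' package self-contained; an externally trained backbone can be supplied
#' instead via `model` (e.g. a classifier fine-tuned elsewhere), mirroring
#' the ImageNet-pretrained extractor used in the original setting.
#'
#' @param input_size Image side the backbone accepts.
#' @param d Embedding dimension (1000 by default).
#' @param seed Seed fixing the random weights.
#' @param model Optional `scar_classifier` whose convolutional trunk should
#'   be reused; its head is replaced by the seeded `d`-dimensional map.
#' @return A `feature_backbone` handle for [extract_features()].
#' @export
feature_backbone <- function(input_size = 64, d = 1000, seed = 0, model = NULL) {
  check_number(d, "d", lower = 1, integer = TRUE)
  base <- model %||% build_classifier(
    classifier_config(input_size = input_size, attention = "none", seed = seed))
  layers <- base$net$sub
  layers <- layers[seq_len(length(layers) - 1L)]    # drop the 2-logit head
  chead <- dim(layers[[base$gc_index - 1L]]$par$W)[4]
  head <- with_seed(seed_add(seed, 1), lay_dense(chead, d))
  structure(list(net = lay_seq(c(layers, list(head))),
                 input_size = base$config$input_size, d = as.integer(d),
                 id = sprintf("random-feature-%d-%d", base$config$input_size, seed)),
            class = "feature_backbone")
}

#' Embed images as fixed-dimension feature vectors
#'
#' Deterministic for fixed backbone weights: duplicated images yield
#' identical rows.
#'
#' @param dataset A dataset tibble; image size must match the backbone.
#' @param backbone A [feature_backbone()].
#' @param batch_size Forward-pass batch size.
#' @return An `n x d` matrix with `source_id` rownames and the backbone id
#'   as attribute `"backbone"`.
#' @export
extract_features <- function(dataset, backbone, batch_size = 128) {
  if (nrow(dataset) == 0)
    return(structure(matrix(0, 0, backbone$d), backbone = backbone$id))
  sz <- nrow(dataset$pixels[[1]])
  if (sz != backbone$input_size)
    abort(sprintf("backbone expects %d-pixel images, dataset has %d",
                  backbone$input_size, sz))
  n <- nrow(dataset)
  out <- matrix(0, n, backbone$d)
  for (s in seq(1, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1, n)
    x <- stack_images(dataset$pixels[idx])
    out[idx, ] <- t(layer_fwd(backbone$net, x)$y)
  }
  rownames(out) <- dataset$source_id
  attr(out, "backbone") <- backbone$id
  out
}

#' First-principal-component scores of an embedding
#'
#' Projects centered embeddings onto the top principal axis.  The sign is
#' fixed by making the largest-magnitude loading positive, so scores are
#' reproducible across platforms.
#'
#' @param embeddings An `n x d` matrix, `n >= 2`.
#' @return A length-`n` numeric vector of centered scores (sum 0), with the
#'   input rownames.
#' @export
pca_first_component <- function(embeddings) {
  if (nrow(embeddings) < 2) abort("PCA needs at least 2 rows")
  p <- prcomp(embeddings, center = TRUE, scale. = FALSE, rank. = 1)
  v <- p$rotation[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  scores <- as.vector(scale(embeddings, center = TRUE, scale = FALSE) %*% v)
  names(scores) <- rownames(embeddings)
  scores
}

#' One-sigma outlier filter via k-means
#'
#' Clusters the 1-D scores with k-means (k = 1 by default, whose fixed
#' point is the mean), then removes scores farther than
#' `k_sigma` population standard deviations from their centroid.  For
#' Gaussian scores and `k_sigma = 1` this removes a fraction approaching
#' `2 * pnorm(-1)` (about 31.7%, "nearly 30%").  Boundary scores are kept.
#'
#' @param scores Numeric vector of per-image scores (names = image ids).
#' @param k_sigma Threshold multiplier (> 0).
#' @param k_centers Number of k-means centroids.
#' @param seed Seed for k-means starts when `k_centers > 1`.
#' @return A `filter_result`: `report` tibble (`source_id`, `score`,
#'   `cluster`, `kept`), `center`, `sigma`, `kept_ids`, `removed_ids`,
#'   `k_sigma`.
#' @export
sigma_filter <- function(scores, k_sigma = 1, k_centers = 1, seed = 0) {
  if (length(scores) < 1) abort("need at least one score")
  check_number(k_sigma, "k_sigma", lower = 1e-12)
  check_number(k_centers, "k_centers", lower = 1, integer = TRUE)
  ids <- names(scores) %||% as.character(seq_along(scores))
  if (k_centers == 1 || length(unique(scores)) == 1) {
    cl <- rep(1L, length(scores))
    centers <- mean(scores)
  } else {
    km <- with_seed(seed, kmeans(matrix(scores), centers = k_centers, nstart = 5))
    cl <- km$cluster
    centers <- as.vector(km$centers)
  }
  sigma <- vapply(seq_along(centers), function(k) {
    s <- scores[cl == k]
    sqrt(mean((s - centers[k])^2))           # population SD
  }, 1)
  kept <- abs(scores - centers[cl]) <= k_sigma * sigma[cl] + 1e-12
  structure(list(report = tibble::tibble(source_id = ids, score = unname(scores),
                                         cluster = cl, kept = kept),
                 center = centers, sigma = sigma,
                 kept_ids = ids[kept], removed_ids = ids[!kept],
                 k_sigma = k_sigma),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("<filter_result> kept %d / %d (removed %.1f%%); center %.4g, sigma %.4g\n",
              length(x$kept_ids), nrow(x$report),
              100 * length(x$removed_ids) / nrow(x$report),
              x$center[1], x$sigma[1]))
  invisible(x)
}

#' Feature mean and covariance of an embedding
#' @param embeddings An `n x d` matrix, `n >= 2`.
#' @return A `gaussian_summary`: `mu` (length-`d` mean) and `sigma`
#'   (`d x d` sample covariance, divisor `n - 1`).
#' @export
gaussian_summary <- function(embeddings) {
  if (nrow(embeddings) < 2) abort("need at least 2 rows for a covariance")
  structure(list(mu = colMeans(embeddings), sigma = stats::cov(embeddings)),
            class = "gaussian_summary")
}

symmetrize <- function(A) (A + t(A)) / 2

# PSD matrix square root by eigendecomposition, eigenvalues clipped at 0.
sqrtm_psd <- function(A) {
  e <- eigen(symmetrize(A), symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

check_summary <- function(s, name) {
  if (!inherits(s, "gaussian_summary")) abort(paste0("`", name, "` must be a gaussian_summary"))
  if (max(abs(s$sigma - t(s$sigma))) > 1e-8)
    abort(paste0("`", name, "` covariance is not symmetric"))
  ev <- eigen(symmetrize(s$sigma), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-6 * max(abs(ev), 1))
    abort(paste0("`", name, "` covariance is not positive semidefinite"))
  invisible(s)
}

#' Fréchet inception distance between two Gaussian feature summaries
#'
#' `FID = ||mu_r - mu_g||^2 + Tr(S_r + S_g - 2 (S_r S_g)^{1/2})`, with the
#' matrix square root computed in the symmetrized form
#' `(S_r^{1/2} S_g S_r^{1/2})^{1/2}` and eigenvalues clipped at zero.
#' The result is symmetric in its arguments and 0 when they coincide.
#'
#' @param real,generated [gaussian_summary()] objects of equal dimension.
#' @return A nonnegative scalar (up to numerical tolerance).
#' @export
fid <- function(real, generated) {
  check_summary(real, "real"); check_summary(generated, "generated")
  if (length(real$mu) != length(generated$mu))
    abort(sprintf("dimension mismatch: %d vs %d", length(real$mu),
                  length(generated$mu)))
  sr <- symmetrize(real$sigma); sg <- symmetrize(generated$sigma)
  srh <- sqrtm_psd(sr)
  cross <- sqrtm_psd(srh %*% sg %*% srh)
  sum((real$mu - generated$mu)^2) + sum(diag(sr)) + sum(diag(sg)) -
    2 * sum(diag(cross))
}

#' FID between two image sets under a common backbone
#' @param real,generated Dataset tibbles (each with >= 2 images).
#' @param backbone A [feature_backbone()].
#' @return The FID scalar.
#' @export
fid_score <- function(real, generated, backbone) {
  fid(gaussian_summary(extract_features(real, backbone)),
      gaussian_summary(extract_features(generated, backbone)))
}

#' Filter generated images per class
#'
#' Applies the embed / PCA / one-sigma pipeline separately to each class of
#' a generated dataset (generation and evaluation are per-category) and
#' returns the surviving records.
#'
#' @param dataset A labeled dataset tibble of generated images.
#' @param backbone A [feature_backbone()].
#' @param k_sigma Threshold multiplier.
#' @return A list: `kept` (filtered dataset tibble) and `results` (named
#'   list of per-class `filter_result`s).
#' @export
filter_images <- function(dataset, backbone, k_sigma = 1) {
  classes <- sort(unique(dataset$label))
  results <- list()
  kept_ids <- character()
  for (cl in classes) {
    sub <- dataset[dataset$label == cl, ]
    emb <- extract_features(sub, backbone)
    fr <- sigma_filter(pca_first_component(emb), k_sigma = k_sigma)
    results[[cl]] <- fr
    kept_ids <- c(kept_ids, fr$kept_ids)
  }
  list(kept = dataset[dataset$source_id %in% kept_ids, ], results = results)
}
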