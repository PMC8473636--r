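test_that("feature extraction is deterministic with one row per image", {
  d <- head(tiny_data(), 6)
  bb <- feature_backbone(64, d = 50, seed = 3)
  emb <- extract_features(d, bb)
  expect_equal(dim(emb), c(6L, 50L))
  expect_equal(rownames(emb), d$source_id)
  dup <- d[c(1, 1), ]
  e2 <- extract_features(dup, bb)
  expect_identical(e2[1, ], e2[2, ])
  # visually distinct phantoms embed differently
  expect_gt(max(abs(emb[1, ] - emb[2, ])), 0)
  bad <- resize_dataset(d, 32)
  expect_error(extract_features(bad, bb), "32")
})

test_that("default backbone emits 1000-dimensional features", {
  bb <- feature_backbone(seed = 1)
  expect_equal(bb$d, 1000L)
  emb <- extract_features(head(tiny_data(), 2), bb)
  expect_equal(ncol(emb), 1000L)
  expect_true(all(is.finite(emb)))
})

test_that("PC1 scores: axis-aligned case, centering, eigen oracle", {
  x <- cbind(c(3, 1, 4, 1, 5), 0, 0)
  sc <- pca_first_component(x)
  expect_equal(abs(sc), abs(x[, 1] - mean(x[, 1])))
  expect_lt(abs(sum(sc)), 1e-9)

  set.seed(7)
  z <- rnorm(40)
  y <- cbind(z + rnorm(40, sd = 0.1), 2 * z + rnorm(40, sd = 0.1))
  sc <- pca_first_component(y)
  # oracle: dense eigendecomposition of the covariance matrix
  ev <- eigen(stats::cov(y), symmetric = TRUE)$vectors[, 1]
  if (ev[which.max(abs(ev))] < 0) ev <- -ev
  expect_equal(sc, as.vector(scale(y, scale = FALSE) %*% ev),
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_error(pca_first_component(y[1, , drop = FALSE]), "2")
})

test_that("sigma filter: degenerate, hand-computed, and Gaussian-mass cases", {
  all_same <- sigma_filter(rep(2.5, 8))
  expect_equal(length(all_same$kept_ids), 8)
  expect_equal(all_same$sigma, 0)

  fr <- sigma_filter(c(0, 0, 0, 10))
  expect_equal(fr$center, 2.5)
  expect_equal(fr$sigma, sqrt(mean((c(0, 0, 0, 10) - 2.5)^2)))
  expect_equal(fr$sigma, 4.330127, tolerance = 1e-6)
  expect_setequal(fr$removed_ids, "4")
  expect_setequal(fr$kept_ids, c("1", "2", "3"))

  set.seed(13)
  fr <- sigma_filter(rnorm(1e5))
  frac <- length(fr$removed_ids) / 1e5
  expect_lt(abs(frac - 2 * pnorm(-1)), 0.01)

  # boundary scores are kept (inclusive rule)
  sc <- c(-1, 1)                      # center 0, sigma 1: both on the border
  expect_equal(length(sigma_filter(sc)$kept_ids), 2)
})

test_that("k-means with one centroid reduces to the mean", {
  set.seed(5)
  x <- rnorm(200, mean = 3)
  fr <- sigma_filter(x)
  expect_equal(fr$center, mean(x))
  km <- kmeans(matrix(x), centers = 1)
  expect_equal(as.vector(km$centers), fr$center)
})

test_that("gaussian summary gives column means and n-1 covariance", {
  x <- rbind(c(0, 0), c(2, 0))
  gs <- gaussian_summary(x)
  expect_equal(gs$mu, c(1, 0))
  expect_equal(gs$sigma, matrix(c(2, 0, 0, 0), 2))
  dup <- rbind(c(1, 2, 3), c(1, 2, 3))
  expect_equal(gaussian_summary(dup)$sigma, matrix(0, 3, 3))
  set.seed(2)
  r <- gaussian_summary(matrix(rnorm(50), 10))
  expect_equal(r$sigma, t(r$sigma))
  expect_error(gaussian_summary(x[1, , drop = FALSE]), "2")
})

test_that("FID closed forms: identity, mean shift, commuting covariances", {
  gs <- function(mu, sigma) structure(list(mu = mu, sigma = sigma),
                                      class = "gaussian_summary")
  A <- gs(c(0, 0), diag(2))
  expect_lt(abs(fid(A, A)), 1e-6)
  B <- gs(c(1, 0), diag(2))
  expect_equal(fid(A, B), 1, tolerance = 1e-8)
  C <- gs(c(0, 0), 4 * diag(2))
  expect_equal(fid(A, C), 2, tolerance = 1e-8)   # Tr(5I - 2*2I)
  expect_equal(fid(A, B), fid(B, A))
  expect_error(fid(A, gs(c(0, 0, 0), diag(3))), "mismatch")
})

test_that("FID matches a dense eigensolver oracle and is a symmetric premetric", {
  gs <- function(mu, sigma) structure(list(mu = mu, sigma = sigma),
                                      class = "gaussian_summary")
  set.seed(31)
  for (i in 1:5) {
    d <- sample(2:10, 1)
    A <- gs(rnorm(d), random_psd(d))
    B <- gs(rnorm(d), random_psd(d))
    got <- fid(A, B)
    # independent route: Tr((Sr Sg)^{1/2}) from the eigenvalues of the
    # (nonsymmetric) product Sr %*% Sg
    ev <- eigen(A$sigma %*% B$sigma, only.values = TRUE)$values
    oracle <- sum((A$mu - B$mu)^2) + sum(diag(A$sigma)) + sum(diag(B$sigma)) -
      2 * sum(sqrt(pmax(Re(ev), 0)))
    expect_equal(got, oracle, tolerance = 1e-6)
    expect_equal(got, fid(B, A), tolerance = 1e-8)
    expect_gte(got, -1e-6)
    expect_lt(abs(fid(A, A)), 1e-6)
  }
})

test_that("per-class filtering partitions each class's images", {
  d <- tiny_data()
  bb <- feature_backbone(64, d = 40, seed = 9)
  out <- filter_images(d, bb)
  expect_named(out$results, c("control", "scar"))
  for (cl in names(out$results)) {
    rep <- out$results[[cl]]$report
    expect_equal(nrow(rep), sum(d$label == cl))
    expect_setequal(c(out$results[[cl]]$kept_ids, out$results[[cl]]$removed_ids),
                    d$source_id[d$label == cl])
  }
  expect_true(all(out$kept$source_id %in% d$source_id))
})
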