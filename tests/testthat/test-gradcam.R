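test_that("heatmap of the analytic mean-activation model equals relu(x) normalized", {
  m <- analytic_model(16)
  set.seed(3)
  img <- matrix(runif(16 * 16, -0.2, 1), 16, 16)
  d <- tibble::tibble(source_id = "a", label = "scar", provenance = "original",
                      pixels = list(pmin(pmax(img, 0), 1)), mask = list(NULL))
  hm <- grad_cam(m, d, target_class = "scar")$heatmap[[1]]
  A <- d$pixels[[1]]                 # relu is identity on [0,1] pixels
  expect_equal(hm, A / max(A), tolerance = 1e-10)
})

test_that("an all-negative weighted sum collapses to the zero heatmap", {
  m <- analytic_model(16, w_scar = -1)
  d <- head(resize_dataset(tiny_data(), 16), 1)
  hm <- grad_cam(m, d, target_class = "scar")$heatmap[[1]]
  expect_true(all(hm == 0))
})

test_that("heatmaps from trained models stay in [0,1] with max 1", {
  m <- .fixtures$trained_small
  if (is.null(m))
    m <- train_classifier(tiny_data(), tiny_data(),
                          classifier_config(epochs = 2, seed = 1))
  d <- head(tiny_data(), 4)
  hm <- grad_cam(m, d)
  for (h in hm$heatmap) {
    expect_true(all(h >= 0 & h <= 1))
    expect_true(max(h) == 1 || all(h == 0))
    expect_equal(dim(h), c(64L, 64L))
  }
  expect_error(grad_cam(m, d, target_class = "infarct"), "unknown")
})

test_that("roi_fraction counts thresholded pixels and is monotone", {
  expect_equal(roi_fraction(matrix(0, 4, 4)), 0)
  expect_equal(roi_fraction(matrix(1, 4, 4)), 1)
  half <- matrix(rep(c(0.9, 0.1), each = 8), 4, 4)
  expect_equal(roi_fraction(half, 0.5), 0.5)
  set.seed(4)
  h <- matrix(runif(64), 8, 8)
  fr <- vapply(seq(0.05, 0.95, by = 0.1), function(t) roi_fraction(h, t), 1)
  expect_true(all(diff(fr) <= 0))
})

test_that("localization overlap is IoU with an undefined empty-mask case", {
  mask <- matrix(0, 4, 4); mask[1:2, 1:2] <- 1
  hm_same <- mask
  expect_equal(localization_overlap(hm_same, mask), 1)
  hm_disj <- matrix(0, 4, 4); hm_disj[3:4, 3:4] <- 1
  expect_equal(localization_overlap(hm_disj, mask), 0)
  hm_double <- mask; hm_double[3:4, 1:2] <- 1   # covers mask + equal extra
  expect_equal(localization_overlap(hm_double, mask), 0.5)
  expect_true(is.na(localization_overlap(hm_same, matrix(0, 4, 4))))
  expect_error(localization_overlap(hm_same, matrix(0, 3, 3)), "shape")
})

test_that("heatmap_stats appends per-image ROI and overlap columns", {
  m <- analytic_model(64)
  d <- head(tiny_data()[tiny_data()$label == "scar", ], 3)
  st <- heatmap_stats(grad_cam(m, d), d)
  expect_true(all(c("roi_fraction", "overlap") %in% names(st)))
  expect_true(all(st$roi_fraction >= 0 & st$roi_fraction <= 1))
  expect_true(all(st$overlap >= 0 & st$overlap <= 1))
})
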