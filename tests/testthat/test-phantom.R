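test_that("phantom generation is deterministic and class-correct", {
  p <- phantom_params()
  a <- make_phantom("scar", p, seed = 7)
  b <- make_phantom("scar", p, seed = 7)
  expect_identical(a$pixels[[1]], b$pixels[[1]])
  expect_identical(a$mask[[1]], b$mask[[1]])

  ctrl <- make_phantom("control", p, seed = 7)
  expect_equal(sum(ctrl$mask[[1]]), 0)
  expect_true(sum(a$mask[[1]]) > 0)
})

test_that("scar arc is brighter than the surrounding ring", {
  p <- phantom_params(scar_intensity_range = c(0.3, 0.5), noise_sd = 0)
  for (seed in 1:5) {
    rec <- make_phantom("scar", p, seed = seed)
    px <- rec$pixels[[1]]
    mask <- rec$mask[[1]] > 0
    m <- rec$meta[[1]]
    n <- nrow(px)
    xs <- seq_len(n) - 0.5
    r <- sqrt((matrix(xs, n, n, byrow = TRUE) - m$cx)^2 +
              (matrix(xs, n, n) - m$cy)^2)
    ring <- r > m$r_inner & r <= m$r_outer & !mask
    expect_gte(mean(px[mask]) - mean(px[ring]), 0.2)
  }
})

test_that("dataset generation respects counts, seeds and invariants", {
  expect_equal(nrow(make_phantom_dataset(0, 0)), 0)

  d <- tiny_data()
  expect_equal(sum(d$label == "scar"), 24)
  expect_equal(sum(d$label == "control"), 24)
  expect_false(anyDuplicated(d$source_id) > 0)
  for (px in d$pixels) {
    expect_true(all(px >= 0 & px <= 1))
    expect_equal(dim(px), c(64L, 64L))
  }
  # scar masks nonempty, control masks empty
  expect_true(all(purrr::map2_lgl(d$mask, d$label,
    ~ (sum(.x) > 0) == (.y == "scar"))))

  d2 <- make_phantom_dataset(5, 5, seed = 1)
  d3 <- make_phantom_dataset(5, 5, seed = 2)
  expect_false(identical(d2$pixels, d3$pixels))
  expect_identical(d2$pixels, make_phantom_dataset(5, 5, seed = 1)$pixels)
})

test_that("ring-maximum statistic separates the classes", {
  d <- ring_annulus_max(tiny_data())
  thr <- (max(d$ring_max[d$label == "control"]) +
          min(d$ring_max[d$label == "scar"])) / 2
  acc <- mean((d$ring_max > thr) == (d$label == "scar"))
  expect_gte(acc, 0.9)
})

test_that("invalid parameters are rejected by name", {
  expect_error(phantom_params(image_size = 15), "image_size")
  expect_error(phantom_params(image_size = 17), "even")
  expect_error(phantom_params(scar_intensity_range = c(0.5, 0.3)),
               "scar_intensity_range")
  expect_error(phantom_params(noise_sd = -1), "noise_sd")
  expect_error(make_phantom("lesion"), "label")
})
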