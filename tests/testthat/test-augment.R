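test_that("transform_copies returns the documented record count", {
  rec <- make_phantom("scar", phantom_params(), seed = 1)
  out <- transform_copies(rec, augmentation_plan(n_rotations = 8, seed = 5))
  expect_equal(nrow(out), 12)      # 1 + 8 + flip + shift + scale
  expect_equal(sum(out$provenance == "rotated"), 8)
  expect_equal(sum(out$provenance == "original"), 1)

  none <- augmentation_plan(n_rotations = 0, include_flip = FALSE,
                            include_shift = FALSE, include_scale = FALSE)
  expect_equal(nrow(transform_copies(rec, none)), 1)

  again <- transform_copies(rec, augmentation_plan(n_rotations = 8, seed = 5))
  expect_identical(out$pixels, again$pixels)
})

test_that("rotation angles are evenly spaced and never duplicate the original", {
  rec <- make_phantom("scar", phantom_params(noise_sd = 0), seed = 2)
  out <- transform_copies(rec, augmentation_plan(n_rotations = 3))
  rots <- out$pixels[out$provenance == "rotated"]
  for (r in rots) expect_gt(max(abs(r - rec$pixels[[1]])), 0.01)
})

test_that("pool counts obey the closed-form for random plans", {
  full <- tiny_data()
  d <- full[c(1:4, 25:28), ]           # four images of each class
  set.seed(42)
  for (i in 1:4) {
    nr <- sample(0:6, 1)
    fl <- runif(1) > 0.5; sh <- runif(1) > 0.5; sc <- runif(1) > 0.5
    plan <- augmentation_plan(nr, fl, sh, sc, seed = i)
    pool <- build_pool(d, plan)
    expect_equal(nrow(pool), 8 * (1 + nr + fl + sh + sc))
  }
  expect_equal(nrow(build_pool(d[0, ], augmentation_plan())), 0)
  expect_error(build_pool(d, list(scar = augmentation_plan())), "control")
})

test_that("balance_deficit reproduces the class imbalance arithmetic", {
  expect_equal(balance_deficit(104, 557), 453)
  expect_equal(balance_deficit(5, 5), 0)
  expect_equal(balance_deficit(0, 7), 7)
  expect_error(balance_deficit(8, 3), "exceeds")
})

test_that("balanced sampling draws exact per-class counts without replacement", {
  d <- tiny_data()
  pool <- build_pool(d, augmentation_plan(n_rotations = 2, seed = 9))
  bal <- sample_balanced(pool, 2, 20, seed = 4)
  cnt <- pool_counts(bal)
  expect_equal(cnt$n, c(40L, 40L))
  expect_false(anyDuplicated(bal$source_id) > 0)
  expect_identical(bal$source_id,
                   sample_balanced(pool, 2, 20, seed = 4)$source_id)
  expect_error(sample_balanced(pool, 10, 20, seed = 1), "required")
})

test_that("augmented images keep shape, range and mask semantics", {
  rec <- make_phantom("scar", phantom_params(), seed = 3)
  out <- transform_copies(rec, augmentation_plan(n_rotations = 2, seed = 1))
  for (i in seq_len(nrow(out))) {
    expect_equal(dim(out$pixels[[i]]), c(64L, 64L))
    expect_true(all(out$pixels[[i]] >= 0 & out$pixels[[i]] <= 1))
    expect_true(all(out$mask[[i]] %in% c(0, 1)))
    expect_gt(sum(out$mask[[i]]), 0)
  }
})
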