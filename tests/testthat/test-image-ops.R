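rot <- scaraug:::rotate_pixels

test_that("rotation identities: 0, 360, and the exact 90-degree oracle", {
  m <- test_pattern(4)
  expect_equal(rot(m, 0), m)
  expect_equal(rot(m, 360), m)
  expect_equal(rot(m, -360), m)
  # 90 degrees counterclockwise == transpose then vertical flip
  expect_equal(rot(m, 90), t(m)[4:1, ])
  m5 <- test_pattern(5)
  expect_equal(rot(m5, 90), t(m5)[5:1, ])
  expect_equal(rot(rot(m5, 90), 90), rot(m5, 180))
})

test_that("geometric ops preserve shape and [0,1] range", {
  img <- tiny_data()$pixels[[1]]
  for (out in list(rot(img, 37.3), scaraug:::flip_pixels(img),
                   scaraug:::shift_pixels(img, 3.7, -2.1),
                   scaraug:::scale_pixels(img, 1.08),
                   scaraug:::scale_pixels(img, 0.91))) {
    expect_equal(dim(out), dim(img))
    expect_true(all(out >= 0 & out <= 1))
  }
})

test_that("flip and integer shift are exact", {
  m <- test_pattern(6)
  expect_equal(scaraug:::flip_pixels(m), m[, 6:1])
  sh <- scaraug:::shift_pixels(m, 2, 1)
  expect_equal(sh[2:6, 3:6], m[1:5, 1:4])
  expect_true(all(sh[1, ] == 0) && all(sh[, 1:2] == 0))
})

test_that("block averaging and resizing behave", {
  m <- matrix(rep(c(0, 1), each = 2, times = 8), 4, 8)
  expect_equal(dim(scaraug:::block_mean(m, 2)), c(2L, 4L))
  expect_equal(scaraug:::block_mean(matrix(1:16 / 16, 4), 4),
               matrix(mean(1:16 / 16)))
  cst <- matrix(0.4, 8, 8)
  expect_equal(scaraug:::resize_pixels(cst, 16), matrix(0.4, 16, 16))
  expect_equal(scaraug:::resize_pixels(cst, 4), matrix(0.4, 4, 4))
  # identity resize returns the input unchanged
  expect_identical(scaraug:::resize_pixels(cst, 8), cst)
})
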