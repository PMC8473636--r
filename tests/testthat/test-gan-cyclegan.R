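test_that("cycle loss: identity, max-range and toy hand computation", {
  x <- array(runif(3 * 3 * 1 * 2), c(3, 3, 1, 2))
  expect_equal(cycle_loss(x, x), 0)
  ones <- array(1, c(2, 2)); zeros <- array(0, c(2, 2))
  expect_equal(cycle_loss(ones, zeros), 1)
  expect_equal(cycle_loss(c(1, 2), c(0, 0)), 1.5)
  expect_error(cycle_loss(ones, array(0, c(3, 2))), "mismatch")
})

test_that("untrained translators map valid images into the valid range", {
  cfg <- cyclegan_config(image_size = 32, steps = 0, seed = 1)
  a <- head(small32()[small32()$label == "control", ], 5)
  b <- head(small32()[small32()$label == "scar", ], 5)
  gan <- train_cyclegan(a, b, cfg)
  out <- translate_images(gan, a, to = "scar")
  expect_equal(nrow(out), 5)
  expect_true(all(out$label == "scar"))
  expect_true(all(out$provenance == "gan_cyclegan"))
  for (m in out$pixels) {
    expect_equal(dim(m), c(32L, 32L))
    expect_true(all(m >= 0 & m <= 1))
  }
  expect_equal(nrow(translate_images(gan, a[0, ], to = "scar")), 0)
  out2 <- translate_images(gan, a, to = "scar")
  expect_identical(out$pixels, out2$pixels)
  expect_error(translate_images(gan, a, to = "lesion"), "scar")
  expect_error(train_cyclegan(a[0, ], b, cfg), "nonempty")
})

test_that("identity-initialized translators have zero initial cycle loss", {
  cfg <- cyclegan_config(image_size = 32, steps = 0, init = "identity", seed = 2)
  a <- head(small32()[small32()$label == "control", ], 4)
  b <- head(small32()[small32()$label == "scar", ], 4)
  gan <- train_cyclegan(a, b, cfg)
  xa <- scaraug:::stack_images(a$pixels)
  fake_b <- scaraug:::layer_fwd(gan$G, xa)$y
  rec_a <- scaraug:::layer_fwd(gan$F, fake_b)$y
  expect_equal(cycle_loss(xa, rec_a), 0)
})

test_that("desk-scale training reduces held-out cycle loss below untrained", {
  d <- small32()
  a <- d[d$label == "control", ][1:24, ]
  b <- d[d$label == "scar", ][1:24, ]
  hold_a <- d[d$label == "control", ][25:30, ]
  hold_b <- d[d$label == "scar", ][25:30, ]
  cyc <- function(gan) {
    xa <- scaraug:::stack_images(hold_a$pixels)
    xb <- scaraug:::stack_images(hold_b$pixels)
    fb <- scaraug:::layer_fwd(gan$G, xa)$y
    ra <- scaraug:::layer_fwd(gan$F, fb)$y
    fa <- scaraug:::layer_fwd(gan$F, xb)$y
    rb <- scaraug:::layer_fwd(gan$G, fa)$y
    cycle_loss(xa, ra) + cycle_loss(xb, rb)
  }
  gan0 <- train_cyclegan(a, b, cyclegan_config(image_size = 32, steps = 0,
                                               seed = 8))
  gan <- train_cyclegan(a, b, cyclegan_config(image_size = 32, steps = 120,
                                              batch_size = 6, seed = 8))
  expect_lt(cyc(gan), cyc(gan0))
})
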