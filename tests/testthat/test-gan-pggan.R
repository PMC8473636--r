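test_that("fade_blend endpoints and midpoint are exact", {
  coarse <- array(0.2, c(4, 4, 1, 2))
  fine <- array(0.6, c(4, 4, 1, 2))
  expect_equal(fade_blend(coarse, fine, 0), coarse)
  expect_equal(fade_blend(coarse, fine, 1), fine)
  expect_equal(fade_blend(coarse, fine, 0.5), array(0.4, c(4, 4, 1, 2)))
  expect_error(fade_blend(coarse, array(0.6, c(8, 8, 1, 2)), 0.5), "shape")
  expect_error(fade_blend(coarse, fine, 1.5), "alpha")
})

test_that("schedule validation catches bad resolutions", {
  expect_error(progressive_schedule(target_resolution = 24), "powers of 2")
  expect_error(progressive_schedule(start_resolution = 32,
                                    target_resolution = 16), "<=")
})

test_that("the untrained generator climbs the resolution ladder 4-8-16", {
  sched <- progressive_schedule(4, 16, steps_per_stage = 0, latent_dim = 16,
                                seed = 2)
  g <- scaraug:::with_seed(2, scaraug:::pggan_build_g(sched))
  expect_equal(g$K, 2L)                        # stages at 4, 8, 16
  z <- matrix(rnorm(16 * 3), 16)
  for (stage in 0:2) {
    y <- scaraug:::pggan_g_fwd(g, z, stage, 1)$y
    expect_equal(dim(y), c(4L * 2^stage, 4L * 2^stage, 1L, 3L))
    expect_true(all(y >= 0 & y <= 1))
  }
})

test_that("a zero-step schedule yields a valid start-resolution handle", {
  pool <- head(small32()[small32()$label == "scar", ], 6)
  h <- train_pggan(pool, progressive_schedule(4, 16, steps_per_stage = 0,
                                              latent_dim = 8, seed = 1))
  expect_equal(h$resolution, 4L)
  out <- generate_images(h, 5, seed = 3)
  expect_equal(nrow(out), 5)
  expect_equal(dim(out$pixels[[1]]), c(4L, 4L))
  expect_true(all(vapply(out$pixels, function(m) all(m >= 0 & m <= 1), TRUE)))
  expect_true(all(out$provenance == "gan_pggan"))
  expect_true(all(out$label == "scar"))
  expect_equal(nrow(generate_images(h, 0)), 0)
  out2 <- generate_images(h, 5, seed = 3)
  expect_identical(out$pixels, out2$pixels)
})

test_that("generator output is continuous in the fade coefficient", {
  sched <- progressive_schedule(4, 16, steps_per_stage = 0, latent_dim = 8,
                                seed = 5)
  g <- scaraug:::with_seed(5, scaraug:::pggan_build_g(sched))
  z <- matrix(rnorm(8 * 2), 8)
  eps <- 1e-4
  y1 <- scaraug:::pggan_g_fwd(g, z, 2, 0.5 - eps)$y
  y2 <- scaraug:::pggan_g_fwd(g, z, 2, 0.5 + eps)$y
  expect_lt(max(abs(y2 - y1)), 10 * eps)
  # endpoints of the fade match the pure coarse/fine paths
  ya <- scaraug:::pggan_g_fwd(g, z, 2, 1)$y
  yb <- scaraug:::pggan_g_fwd(g, z, 2, 1 - 1e-9)$y
  expect_equal(ya, yb, tolerance = 1e-6)
})

test_that("training errors on empty or mixed pools and is seed-reproducible", {
  sched <- progressive_schedule(4, 8, steps_per_stage = 2, fade_steps = 2,
                                latent_dim = 8, batch_size = 4, seed = 9)
  expect_error(train_pggan(small32()[0, ], sched), "empty")
  expect_error(train_pggan(small32(), sched), "class")
  pool <- head(small32()[small32()$label == "control", ], 8)
  h1 <- train_pggan(pool, sched)
  h2 <- train_pggan(pool, sched)
  expect_equal(h1$resolution, 8L)
  g1 <- generate_images(h1, 3, seed = 1)
  g2 <- generate_images(h2, 3, seed = 1)
  expect_identical(g1$pixels, g2$pixels)
})

test_that("short desk-scale training moves generated images toward the class", {
  pool <- small32()[small32()$label == "scar", ]
  sched <- progressive_schedule(4, 16, steps_per_stage = 80, fade_steps = 40,
                                latent_dim = 32, batch_size = 8, seed = 21)
  h <- train_pggan(pool, sched)
  # resemblance to the class: spatial correlation of the mean generated
  # image with the mean real image (absolute brightness oscillates during
  # short adversarial training, spatial structure does not)
  mean_real <- Reduce(`+`, lapply(pool$pixels, scaraug:::resize_pixels,
                                  H_out = 16)) / nrow(pool)
  resemblance <- function(dd) {
    mg <- Reduce(`+`, lapply(dd$pixels, scaraug:::resize_pixels, H_out = 16)) /
      nrow(dd)
    cor(as.vector(mean_real), as.vector(mg))
  }
  trained <- resemblance(generate_images(h, 32, seed = 4))
  h0 <- train_pggan(head(pool, 8),
                    progressive_schedule(4, 16, steps_per_stage = 0,
                                         latent_dim = 32, seed = 21))
  untrained <- resemblance(generate_images(h0, 32, seed = 4))
  expect_gt(trained, untrained)
  expect_gt(trained, 0.5)
})
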