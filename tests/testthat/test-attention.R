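test_that("zero-weight channel attention gates every channel by sigmoid(0)", {
  U <- array(runif(5 * 5 * 3 * 2), c(5, 5, 3, 2))
  unit <- channel_attention_unit(3, W1 = matrix(0, 3, 1), W2 = matrix(0, 1, 3))
  expect_equal(channel_attention(U, unit), 0.5 * U)
})

test_that("the two-channel hand-computed CA example matches", {
  U <- array(c(2, 4), c(1, 1, 2))
  unit <- channel_attention_unit(2, W1 = c(0.5, 0.5), W2 = c(1, -1))
  out <- channel_attention(U, unit)
  s <- 1 / (1 + exp(-c(3, -3)))
  expect_equal(as.vector(out), c(2, 4) * s, tolerance = 1e-6)
  expect_equal(as.vector(out), c(1.9052, 0.1897), tolerance = 1e-4)
})

test_that("zero-weight spatial attention halves the map; 1x1 kernel matches formula", {
  U <- array(runif(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  unit0 <- spatial_attention_unit(3, W = array(0, c(3, 3, 1, 1)))
  expect_equal(spatial_attention(U, unit0), 0.5 * U)

  U1 <- array(runif(4 * 4), c(4, 4, 1))
  w <- 1.7
  unit1 <- spatial_attention_unit(1, W = array(w, c(1, 1, 1, 1)), b = 0)
  expect_equal(spatial_attention(U1, unit1),
               (1 / (1 + exp(-w * U1))) * U1, tolerance = 1e-12)
})

test_that("attention masks stay strictly inside (0,1) and shapes are kept", {
  set.seed(1)
  U <- array(rnorm(8 * 8 * 4 * 3), c(8, 8, 4, 3))
  ca <- channel_attention_unit(4, seed = 2)
  sa <- spatial_attention_unit(3, seed = 3)
  fca <- scaraug:::layer_fwd(ca, U)
  expect_true(all(fca$cache$s > 0 & fca$cache$s < 1))
  fsa <- scaraug:::layer_fwd(sa, U)
  expect_true(all(fsa$cache$s > 0 & fsa$cache$s < 1))
  expect_equal(dim(fca$y), dim(U))
  expect_equal(dim(fsa$y), dim(U))
})

test_that("mix attention equals the sum of channel and spatial attention", {
  set.seed(4)
  U <- array(rnorm(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  ca <- channel_attention_unit(3, seed = 5)
  sa <- spatial_attention_unit(3, seed = 6)
  expect_equal(mix_attention(U, ca, sa),
               channel_attention(U, ca) + spatial_attention(U, sa),
               tolerance = 1e-6)
  # zero-weight units: MA output reduces to the identity
  ca0 <- channel_attention_unit(3, W1 = matrix(0, 3, 1), W2 = matrix(0, 1, 3))
  sa0 <- spatial_attention_unit(3, W = array(0, c(3, 3, 1, 1)))
  expect_equal(mix_attention(U, ca0, sa0), U)
})

test_that("channel mismatch raises a validation error", {
  U <- array(runif(4 * 4 * 5), c(4, 4, 5))
  unit <- channel_attention_unit(3)
  expect_error(channel_attention(U, unit), "channels")
})
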