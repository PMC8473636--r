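# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# A small phantom dataset: 24 per class at 64 px.
tiny_data <- function() {
  memo("tiny_data", make_phantom_dataset(24, 24, phantom_params(), seed = 11))
}

# A 32 px dataset for cheap GAN tests.
small32 <- function() {
  memo("small32",
       make_phantom_dataset(30, 30, phantom_params(image_size = 32), seed = 12))
}

# Deterministic asymmetric test pattern.
test_pattern <- function(n = 4) matrix(seq_len(n * n) / (n * n), n, n)

# A minimal hand-built classifier whose scar logit is the spatial mean of
# relu(x): lets Grad-CAM be checked against an analytic answer.
analytic_model <- function(input_size = 16, w_scar = 1) {
  dense <- scaraug:::lay_dense(1, 2)
  dense$par$W <- matrix(c(0, w_scar), 1, 2)
  dense$par$b <- c(0, 0)
  structure(list(
    net = scaraug:::lay_seq(scaraug:::lay_act("relu"), scaraug:::lay_gap(), dense),
    gc_index = 1L,
    config = list(input_size = input_size),
    classes = c("control", "scar")),
    class = "scar_classifier")
}

random_psd <- function(d) {
  a <- matrix(rnorm(d * d), d)
  crossprod(a) / d + diag(d) * 0.1
}
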