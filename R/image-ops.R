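# Low-level grayscale image geometry.  An image is an H x W numeric matrix
# in [0,1]; rows run top to bottom, columns left to right, pixel centers at
# integer coordinates.  All resampling is bilinear with zero fill outside
# the source, matching the augmentation contract.

# Sample img at fractional (row, col) coordinate matrices.
bilinear_sample <- function(img, src_r, src_c) {
  H <- nrow(img); W <- ncol(img)
  r0 <- floor(src_r); c0 <- floor(src_c)
  fr <- src_r - r0; fc <- src_c - c0
  out <- 0
  for (dr in 0:1) {
    for (dc in 0:1) {
      r <- r0 + dr; c <- c0 + dc
      w <- (if (dr == 0) 1 - fr else fr) * (if (dc == 0) 1 - fc else fc)
      ok <- r >= 1 & r <= H & c >= 1 & c <= W
      rc <- pmin(pmax(r, 1), H); cc <- pmin(pmax(c, 1), W)
      v <- img[cbind(as.vector(rc), as.vector(cc))]
      out <- out + w * ifelse(ok, v, 0)
    }
  }
  matrix(out, nrow(src_r), ncol(src_r))
}

target_grid <- function(H, W) {
  list(r = matrix(seq_len(H), H, W), c = matrix(seq_len(W), H, W, byrow = TRUE))
}

# Rotate counterclockwise (as displayed) about the image center by `angle`
# degrees.  cospi/sinpi keep right angles exact so 90-degree rotations are
# lossless on the pixel grid.
rotate_pixels <- function(img, angle) {
  angle <- angle %% 360
  H <- nrow(img); W <- ncol(img)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  ct <- cospi(angle / 180); st <- sinpi(angle / 180)
  g <- target_grid(H, W)
  u <- g$c - cx; v <- g$r - cy
  bilinear_sample(img, st * u + ct * v + cy, ct * u - st * v + cx)
}

flip_pixels <- function(img) img[, rev(seq_len(ncol(img))), drop = FALSE]

# Translate by (dx, dy) pixels (positive = right/down), zero fill.
shift_pixels <- function(img, dx, dy) {
  g <- target_grid(nrow(img), ncol(img))
  bilinear_sample(img, g$r - dy, g$c - dx)
}

# Scale about the center by `factor` (> 1 zooms in), zero fill.
scale_pixels <- function(img, factor) {
  H <- nrow(img); W <- ncol(img)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  g <- target_grid(H, W)
  bilinear_sample(img, (g$r - cy) / factor + cy, (g$c - cx) / factor + cx)
}

resize_pixels <- function(img, H_out, W_out = H_out) {
  H <- nrow(img); W <- ncol(img)
  if (H == H_out && W == W_out) return(img)
  sr <- (seq_len(H_out) - 0.5) * H / H_out + 0.5
  sc <- (seq_len(W_out) - 0.5) * W / W_out + 0.5
  # clamp to centers so edge pixels extend rather than fade to zero
  sr <- pmin(pmax(sr, 1), H); sc <- pmin(pmax(sc, 1), W)
  bilinear_sample(img, matrix(sr, H_out, W_out), matrix(sc, H_out, W_out, byrow = TRUE))
}

# Exact f x f block averaging (supersampling reduction); dims must divide.
block_mean <- function(img, f) {
  H <- nrow(img); W <- ncol(img)
  stopifnot(H %% f == 0, W %% f == 0)
  h <- H %/% f; w <- W %/% f
  m <- colMeans(array(img, c(f, h, W)), dims = 1)        # h x W
  t(colMeans(array(t(m), c(f, w, h)), dims = 1))         # h x w
}

# Stack a list of H x W matrices into an (H, W, 1, N) array and back.
stack_images <- function(imgs) {
  H <- nrow(imgs[[1]]); W <- ncol(imgs[[1]])
  array(unlist(imgs, use.names = FALSE), c(H, W, 1L, length(imgs)))
}

unstack_images <- function(x) {
  d <- dim(x)
  lapply(seq_len(d[4]), function(n) matrix(x[, , 1L, n], d[1], d[2]))
}
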