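# Attention units: channel (squeeze-and-excitation), spatial, and mix.
# Channel attention gates each channel by S = sigmoid(W2 relu(W1 z)) where
# z is the globally average-pooled channel descriptor; spatial attention
# gates each pixel by a sigmoid(conv(channel-mean map)); mix attention adds
# the two gated maps.

lay_ca <- function(channels, reduction = 4, W1 = NULL, W2 = NULL,
                   b1 = NULL, b2 = NULL) {
  cr <- max(1L, as.integer(round(channels / reduction)))
  if (is.null(W1)) W1 <- he_init(c(channels, cr), channels)
  W1 <- matrix(W1, channels)
  cr <- ncol(W1)
  if (is.null(W2)) W2 <- he_init(c(cr, channels), cr)
  W2 <- matrix(W2, cr, channels)
  new_layer("ca", par = list(W1 = W1, b1 = b1 %||% numeric(ncol(W1)),
                             W2 = W2, b2 = b2 %||% numeric(channels)),
            channels = as.integer(channels))
}

#' @export
layer_fwd.lay_ca <- function(layer, x) {
  d <- dim(x)
  if (d[3] != layer$channels)
    abort(sprintf("channel attention built for %d channels, input has %d",
                  layer$channels, d[3]))
  HW <- d[1] * d[2]
  z <- matrix(colMeans(array(x, c(HW, d[3] * d[4]))), d[3], d[4])
  a <- crossprod(layer$par$W1, z) + layer$par$b1
  h <- pmax(a, 0)
  s <- 1 / (1 + exp(-(crossprod(layer$par$W2, h) + layer$par$b2)))
  list(y = bcast_mul_channel_cpp(x, s),
       cache = list(x = x, z = z, a = a, h = h, s = s))
}

#' @export
layer_bwd.lay_ca <- function(layer, cache, dy) {
  d <- dim(cache$x); HW <- d[1] * d[2]
  ds <- channel_dot_cpp(dy, cache$x)
  dspre <- ds * cache$s * (1 - cache$s)
  dh <- layer$par$W2 %*% dspre
  da <- dh * (cache$a > 0)
  dz <- layer$par$W1 %*% da
  dx <- bcast_mul_channel_cpp(dy, cache$s) +
    bcast_channel_const_cpp(dz / HW, d[1], d[2])
  list(dx = dx,
       grads = list(W1 = cache$z %*% t(da), b1 = rowSums(da),
                    W2 = cache$h %*% t(dspre), b2 = rowSums(dspre)))
}

lay_sa <- function(kernel = 3, W = NULL, b = NULL) {
  if (kernel %% 2 == 0) abort("spatial attention kernel must be odd")
  if (is.null(W)) W <- he_init(c(kernel, kernel, 1, 1), kernel * kernel)
  new_layer("sa", par = list(W = array(W, c(kernel, kernel, 1, 1)),
                             b = b %||% 0),
            kernel = as.integer(kernel))
}

#' @export
layer_fwd.lay_sa <- function(layer, x) {
  d <- dim(x)
  m <- array(colMeans(aperm(x, c(3, 1, 2, 4))), c(d[1], d[2], 1, d[4]))
  a <- conv2d_fwd_cpp(m, layer$par$W, layer$par$b, 1L, same_pad(layer$kernel))
  s <- 1 / (1 + exp(-a)); dim(s) <- dim(a)
  sarr <- s[, , rep(1L, d[3]), , drop = FALSE]
  list(y = x * sarr, cache = list(x = x, m = m, s = s, sarr = sarr))
}

#' @export
layer_bwd.lay_sa <- function(layer, cache, dy) {
  d <- dim(cache$x)
  ds <- array(rowSums(array(aperm(dy * cache$x, c(1, 2, 4, 3)),
                            c(d[1] * d[2] * d[4], d[3]))),
              c(d[1], d[2], 1, d[4]))
  dspre <- ds * cache$s * (1 - cache$s)
  r <- conv2d_bwd_cpp(cache$m, layer$par$W, dspre, 1L, same_pad(layer$kernel))
  dm <- r$dx / d[3]
  dx <- dy * cache$sarr + dm[, , rep(1L, d[3]), , drop = FALSE]
  list(dx = dx, grads = list(W = r$dw, b = r$db))
}

lay_ma <- function(ca, sa) new_layer("ma", sub = list(ca, sa))

#' @export
layer_fwd.lay_ma <- function(layer, x) {
  rc <- layer_fwd(layer$sub[[1]], x)
  rs <- layer_fwd(layer$sub[[2]], x)
  list(y = rc$y + rs$y, cache = list(rc$cache, rs$cache))
}

#' @export
layer_bwd.lay_ma <- function(layer, cache, dy) {
  rc <- layer_bwd(layer$sub[[1]], cache[[1]], dy)
  rs <- layer_bwd(layer$sub[[2]], cache[[2]], dy)
  list(dx = rc$dx + rs$dx, grads = list(sub = list(rc$grads, rs$grads)))
}

lay_identity <- function() new_layer("identity")

#' @export
layer_fwd.lay_identity <- function(layer, x) list(y = x, cache = NULL)

#' @export
layer_bwd.lay_identity <- function(layer, cache, dy) list(dx = dy, grads = NULL)

make_attention_layer <- function(attention, channels, se_reduction = 4,
                                 sa_kernel = 3) {
  switch(attention,
         none = lay_identity(),
         CA = lay_ca(channels, se_reduction),
         SA = lay_sa(sa_kernel),
         MA = lay_ma(lay_ca(channels, se_reduction), lay_sa(sa_kernel)),
         abort(paste0("unknown attention '", attention, "'; use none/CA/SA/MA")))
}

as_feature_map <- function(U) {
  if (is.matrix(U)) dim(U) <- c(dim(U), 1L, 1L)
  if (length(dim(U)) == 3) dim(U) <- c(dim(U), 1L)
  if (length(dim(U)) != 4) abort("feature map must be (H, W, C[, N])")
  U
}

#' Channel (squeeze-and-excitation) attention unit
#'
#' Builds a channel-gating unit: the feature map is average-pooled per
#' channel into a descriptor `z`, passed through a bottleneck
#' (`W1`, ReLU) and an expansion (`W2`, sigmoid) to a mask
#' `S = sigmoid(W2 relu(W1 z))` in (0,1), which rescales each channel.
#'
#' @param channels Channel count the unit accepts.
#' @param reduction Bottleneck ratio `r` (descriptor is compressed to
#'   `round(channels / r)` units, at least 1).
#' @param W1,W2,b1,b2 Optional explicit weights (`W1`: channels x bottleneck,
#'   `W2`: bottleneck x channels); random He initialization otherwise.
#' @param seed Seed for the random initialization.
#' @return An attention unit usable with [channel_attention()].
#' @export
channel_attention_unit <- function(channels, reduction = 4, W1 = NULL,
                                   W2 = NULL, b1 = NULL, b2 = NULL, seed = 0) {
  with_seed(seed, lay_ca(channels, reduction, W1, W2, b1, b2))
}

#' Spatial attention unit
#'
#' Gates each pixel by `sigmoid(conv(mean over channels))` with an odd
#' square kernel.
#'
#' @param kernel Odd kernel size.
#' @param W,b Optional explicit kernel/bias.
#' @param seed Seed for the random initialization.
#' @return An attention unit usable with [spatial_attention()].
#' @export
spatial_attention_unit <- function(kernel = 3, W = NULL, b = NULL, seed = 0) {
  with_seed(seed, lay_sa(kernel, W, b))
}

#' Apply channel attention to a feature map
#' @param U A feature map array `(H, W, C)` or `(H, W, C, N)`.
#' @param unit A [channel_attention_unit()].
#' @return The gated feature map, same shape as `U`.
#' @export
channel_attention <- function(U, unit) {
  d0 <- dim(U); U <- as_feature_map(U)
  y <- layer_fwd(unit, U)$y
  dim(y) <- d0
  y
}

#' Apply spatial attention to a feature map
#' @inheritParams channel_attention
#' @param unit A [spatial_attention_unit()].
#' @return The gated feature map, same shape as `U`.
#' @export
spatial_attention <- function(U, unit) {
  d0 <- dim(U); U <- as_feature_map(U)
  y <- layer_fwd(unit, U)$y
  dim(y) <- d0
  y
}

#' Apply mix attention (channel + spatial) to a feature map
#'
#' The mix-attention output is the elementwise sum of the channel-attended
#' and spatially-attended maps.
#'
#' @inheritParams channel_attention
#' @param ca_unit A [channel_attention_unit()].
#' @param sa_unit A [spatial_attention_unit()].
#' @return The attended feature map, same shape as `U`.
#' @export
mix_attention <- function(U, ca_unit, sa_unit) {
  channel_attention(U, ca_unit) + spatial_attention(U, sa_unit)
}
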