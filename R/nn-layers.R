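# A minimal, fully deterministic conv-net engine.
#
# Feature maps are (H, W, C, N) arrays; vector features are (C, N) matrices.
# A layer is a list with class "lay_<type>"; simple layers keep their
# parameter arrays in $par, composite layers keep child layers in $sub.
# layer_fwd() returns list(y, cache); layer_bwd() consumes that cache and
# the upstream gradient and returns list(dx, grads), where grads mirrors
# $par (simple) or holds $sub, a list of child grads (composite).

new_layer <- function(type, ...) structure(list(...), class = c(paste0("lay_", type), "nn_layer"))

layer_fwd <- function(layer, x) UseMethod("layer_fwd")
layer_bwd <- function(layer, cache, dy) UseMethod("layer_bwd")

he_init <- function(dims, fan_in, gain = 2) {
  array(rnorm(prod(dims), 0, sqrt(gain / fan_in)), dims)
}

same_pad <- function(k) as.integer((k - 1) / 2)

# ---- standard convolution ----------------------------------------------

lay_conv <- function(cin, cout, k = 3, stride = 1, pad = same_pad(k),
                     init_gain = 2, zero_init = FALSE) {
  W <- if (zero_init) array(0, c(k, k, cin, cout))
       else he_init(c(k, k, cin, cout), k * k * cin, init_gain)
  new_layer("conv", par = list(W = W, b = numeric(cout)),
            stride = as.integer(stride), pad = as.integer(pad))
}

#' @export
layer_fwd.lay_conv <- function(layer, x) {
  list(y = conv2d_fwd_cpp(x, layer$par$W, layer$par$b, layer$stride, layer$pad),
       cache = x)
}

#' @export
layer_bwd.lay_conv <- function(layer, cache, dy) {
  r <- conv2d_bwd_cpp(cache, layer$par$W, dy, layer$stride, layer$pad)
  list(dx = r$dx, grads = list(W = r$dw, b = r$db))
}

# ---- depthwise convolution ---------------------------------------------

lay_dwconv <- function(c, k = 3, stride = 1, pad = same_pad(k)) {
  new_layer("dwconv",
            par = list(W = he_init(c(k, k, c), k * k), b = numeric(c)),
            stride = as.integer(stride), pad = as.integer(pad))
}

#' @export
layer_fwd.lay_dwconv <- function(layer, x) {
  list(y = dwconv2d_fwd_fast(x, layer$par$W, layer$par$b, layer$stride, layer$pad),
       cache = x)
}

#' @export
layer_bwd.lay_dwconv <- function(layer, cache, dy) {
  r <- dwconv2d_bwd_fast(cache, layer$par$W, dy, layer$stride, layer$pad)
  list(dx = r$dx, grads = list(W = r$dw, b = r$db))
}

# ---- dense --------------------------------------------------------------

lay_dense <- function(cin, cout, zero_init = FALSE) {
  W <- if (zero_init) matrix(0, cin, cout) else he_init(c(cin, cout), cin)
  new_layer("dense", par = list(W = W, b = numeric(cout)))
}

#' @export
layer_fwd.lay_dense <- function(layer, x) {
  list(y = crossprod(layer$par$W, x) + layer$par$b, cache = x)
}

#' @export
layer_bwd.lay_dense <- function(layer, cache, dy) {
  list(dx = layer$par$W %*% dy,
       grads = list(W = cache %*% t(dy), b = rowSums(dy)))
}

# ---- activations --------------------------------------------------------

ACT_CODES <- c(relu = 0L, relu6 = 1L, lrelu = 2L, sigmoid = 3L, tanh = 4L,
               clamp01 = 5L)

lay_act <- function(kind, alpha = 0.2) {
  if (!kind %in% names(ACT_CODES)) abort(paste0("unknown activation ", kind))
  new_layer("act", kind = kind, code = ACT_CODES[[kind]], alpha = alpha)
}

#' @export
layer_fwd.lay_act <- function(layer, x) {
  y <- act_fwd_cpp(x, layer$code, layer$alpha)
  # sigmoid/tanh backward needs the output, the rectifiers the input
  list(y = y, cache = if (layer$code %in% c(3L, 4L)) y else x)
}

#' @export
layer_bwd.lay_act <- function(layer, cache, dy) {
  list(dx = act_bwd_cpp(cache, dy, layer$code, layer$alpha), grads = NULL)
}

# ---- global average pooling: (H,W,C,N) -> (C,N) -------------------------

lay_gap <- function() new_layer("gap")

#' @export
layer_fwd.lay_gap <- function(layer, x) {
  d <- dim(x)
  y <- matrix(colMeans(array(x, c(d[1] * d[2], d[3] * d[4]))), d[3], d[4])
  list(y = y, cache = d)
}

#' @export
layer_bwd.lay_gap <- function(layer, cache, dy) {
  d <- cache
  list(dx = bcast_channel_const_cpp(dy / (d[1] * d[2]), d[1], d[2]),
       grads = NULL)
}

# ---- flatten: (H,W,C,N) -> (HWC, N) -------------------------------------

lay_flatten <- function() new_layer("flatten")

#' @export
layer_fwd.lay_flatten <- function(layer, x) {
  d <- dim(x)
  list(y = matrix(x, prod(d[1:3]), d[4]), cache = d)
}

#' @export
layer_bwd.lay_flatten <- function(layer, cache, dy) {
  list(dx = array(dy, cache), grads = NULL)
}

# ---- reshape: (K, N) -> (H,W,C,N) ---------------------------------------

lay_reshape <- function(H, W, C) new_layer("reshape", d = c(H, W, C))

#' @export
layer_fwd.lay_reshape <- function(layer, x) {
  N <- ncol(x)
  list(y = array(x, c(layer$d, N)), cache = nrow(x))
}

#' @export
layer_bwd.lay_reshape <- function(layer, cache, dy) {
  list(dx = matrix(dy, cache, dim(dy)[4]), grads = NULL)
}

# ---- nearest-neighbour 2x upsampling / 2x2 average pooling --------------

lay_upsample2 <- function() new_layer("upsample2")

upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , , drop = FALSE]
}

# Sum each 2x2 block of the first two dims (adjoint of upsample2).
blocksum2 <- function(x) {
  d <- dim(x)
  s <- colSums(array(x, c(2, d[1] / 2 * d[2] * d[3] * d[4])), dims = 1)
  s <- array(s, c(d[1] / 2, d[2], d[3], d[4]))
  s <- aperm(s, c(2, 1, 3, 4))
  s <- colSums(array(s, c(2, d[2] / 2 * d[1] / 2 * d[3] * d[4])), dims = 1)
  aperm(array(s, c(d[2] / 2, d[1] / 2, d[3], d[4])), c(2, 1, 3, 4))
}

#' @export
layer_fwd.lay_upsample2 <- function(layer, x) list(y = upsample2(x), cache = NULL)

#' @export
layer_bwd.lay_upsample2 <- function(layer, cache, dy) {
  list(dx = blocksum2(dy), grads = NULL)
}

lay_avgpool2 <- function() new_layer("avgpool2")

#' @export
layer_fwd.lay_avgpool2 <- function(layer, x) list(y = blocksum2(x) / 4, cache = NULL)

#' @export
layer_bwd.lay_avgpool2 <- function(layer, cache, dy) {
  list(dx = upsample2(dy) / 4, grads = NULL)
}

# ---- sequential composite ----------------------------------------------

lay_seq <- function(...) {
  sub <- list(...)
  if (length(sub) == 1 && is.list(sub[[1]]) && !inherits(sub[[1]], "nn_layer"))
    sub <- sub[[1]]
  new_layer("seq", sub = sub)
}

#' @export
layer_fwd.lay_seq <- function(layer, x) {
  caches <- vector("list", length(layer$sub))
  for (i in seq_along(layer$sub)) {
    r <- layer_fwd(layer$sub[[i]], x)
    x <- r$y
    caches[[i]] <- r$cache
  }
  list(y = x, cache = caches)
}

# Backprop through sublayers end..(stop_after+1); stop_after = 0 reaches dx.
seq_bwd <- function(layer, caches, dy, stop_after = 0) {
  grads <- vector("list", length(layer$sub))
  for (i in rev(seq_along(layer$sub))) {
    if (i <= stop_after) break
    r <- layer_bwd(layer$sub[[i]], caches[[i]], dy)
    dy <- r$dx
    grads[i] <- list(r$grads)      # keep NULL slots (no-parameter layers)
  }
  list(dx = dy, grads = list(sub = grads))
}

#' @export
layer_bwd.lay_seq <- function(layer, cache, dy) seq_bwd(layer, cache, dy)

# ---- residual block around a sequential body ----------------------------

lay_resblock <- function(body, residual = TRUE) {
  new_layer("resblock", sub = list(body), residual = residual)
}

#' @export
layer_fwd.lay_resblock <- function(layer, x) {
  r <- layer_fwd(layer$sub[[1]], x)
  list(y = if (layer$residual) r$y + x else r$y, cache = r$cache)
}

#' @export
layer_bwd.lay_resblock <- function(layer, cache, dy) {
  r <- layer_bwd(layer$sub[[1]], cache, dy)
  list(dx = if (layer$residual) r$dx + dy else r$dx,
       grads = list(sub = list(r$grads)))
}

# ---- optimizers ---------------------------------------------------------

zeros_like <- function(x) {
  if (is.null(dim(x))) numeric(length(x)) else array(0, dim(x))
}

# One Adam step over a layer tree; state is built lazily alongside it.
adam_update <- function(layer, grads, state, lr, t, b1 = 0.9, b2 = 0.999,
                        eps = 1e-8) {
  if (!is.null(layer$par) && !is.null(grads)) {
    if (is.null(state)) state <- list(m = lapply(layer$par, zeros_like),
                                      v = lapply(layer$par, zeros_like))
    for (nm in names(layer$par)) {
      g <- grads[[nm]]
      if (is.null(g)) next
      state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
      state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
      mhat <- state$m[[nm]] / (1 - b1^t)
      vhat <- state$v[[nm]] / (1 - b2^t)
      layer$par[[nm]] <- layer$par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  if (!is.null(layer$sub) && !is.null(grads$sub)) {
    if (is.null(state$sub)) state$sub <- vector("list", length(layer$sub))
    for (i in seq_along(layer$sub)) {
      if (is.null(grads$sub[[i]])) next
      r <- adam_update(layer$sub[[i]], grads$sub[[i]], state$sub[[i]], lr, t,
                       b1, b2, eps)
      layer$sub[[i]] <- r$layer
      state$sub[i] <- list(r$state)   # may be NULL: keep the slot
    }
  }
  list(layer = layer, state = state)
}

# Momentum SGD over a layer tree.
sgd_update <- function(layer, grads, state, lr, momentum = 0.9) {
  if (!is.null(layer$par) && !is.null(grads)) {
    if (is.null(state)) state <- list(v = lapply(layer$par, zeros_like))
    for (nm in names(layer$par)) {
      g <- grads[[nm]]
      if (is.null(g)) next
      state$v[[nm]] <- momentum * state$v[[nm]] + g
      layer$par[[nm]] <- layer$par[[nm]] - lr * state$v[[nm]]
    }
  }
  if (!is.null(layer$sub) && !is.null(grads$sub)) {
    if (is.null(state$sub)) state$sub <- vector("list", length(layer$sub))
    for (i in seq_along(layer$sub)) {
      if (is.null(grads$sub[[i]])) next
      r <- sgd_update(layer$sub[[i]], grads$sub[[i]], state$sub[[i]], lr, momentum)
      layer$sub[[i]] <- r$layer
      state$sub[i] <- list(r$state)   # may be NULL: keep the slot
    }
  }
  list(layer = layer, state = state)
}

# Elementwise sum of two gradient trees (either may be NULL).
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  out <- a
  for (nm in names(a)) {
    if (nm == "sub") {
      for (i in seq_along(a$sub))     # [i] <- list(): keep NULL slots
        out$sub[i] <- list(grads_add(a$sub[[i]], b$sub[[i]]))
    } else if (!is.null(a[[nm]]) && !is.null(b[[nm]])) {
      out[[nm]] <- a[[nm]] + b[[nm]]
    }
  }
  out
}

# Count parameters in a layer tree.
n_params <- function(layer) {
  n <- if (!is.null(layer$par)) sum(vapply(layer$par, length, 1L)) else 0L
  if (!is.null(layer$sub)) n <- n + sum(vapply(layer$sub, n_params, 1L))
  n
}
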