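#' Progressive-growing GAN schedule
#'
#' Training starts at `start_resolution` (4 x 4) and doubles the working
#' resolution per stage up to `target_resolution`; at each transition the
#' new high-resolution branch is blended in with a fade coefficient alpha
#' ramping linearly 0 to 1 over `fade_steps` optimizer steps.
#'
#' @param start_resolution,target_resolution Powers of 2, start <= target.
#' @param steps_per_stage Optimizer steps at each resolution after the fade.
#' @param fade_steps Steps over which alpha ramps at each transition.
#' @param latent_dim Noise dimension fed to the generator.
#' @param batch_size,learning_rate Optimizer settings (Adam).
#' @param seed Master seed for initialization, noise and batch sampling.
#' @return A `progressive_schedule` list.
#' @export
progressive_schedule <- function(start_resolution = 4, target_resolution = 32,
                                 steps_per_stage = 200, fade_steps = 100,
                                 latent_dim = 64, batch_size = 16,
                                 learning_rate = 3e-4, seed = 0) {
  check_number(start_resolution, "start_resolution", lower = 2, integer = TRUE)
  check_number(target_resolution, "target_resolution", lower = 2, integer = TRUE)
  if (!is_pow2(start_resolution) || !is_pow2(target_resolution))
    abort("resolutions must be powers of 2")
  if (start_resolution > target_resolution)
    abort("start_resolution must be <= target_resolution")
  check_number(steps_per_stage, "steps_per_stage", lower = 0, integer = TRUE)
  check_number(fade_steps, "fade_steps", lower = 0, integer = TRUE)
  check_number(latent_dim, "latent_dim", lower = 1, integer = TRUE)
  check_number(batch_size, "batch_size", lower = 1, integer = TRUE)
  check_number(learning_rate, "learning_rate", lower = 0)
  structure(list(start_resolution = as.integer(start_resolution),
                 target_resolution = as.integer(target_resolution),
                 steps_per_stage = as.integer(steps_per_stage),
                 fade_steps = as.integer(fade_steps),
                 latent_dim = as.integer(latent_dim),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "progressive_schedule")
}

#' Blend coarse and fine image batches during a stage transition
#'
#' Elementwise `(1 - alpha) * coarse + alpha * fine`; the coarse batch must
#' already be upsampled to the fine batch's shape.
#'
#' @param coarse,fine Arrays of identical shape.
#' @param alpha Fade coefficient in \[0, 1\].
#' @return The blended array.
#' @export
fade_blend <- function(coarse, fine, alpha) {
  check_number(alpha, "alpha", lower = 0, upper = 1)
  if (!identical(dim(coarse) %||% length(coarse), dim(fine) %||% length(fine)))
    abort("coarse and fine shapes differ")
  (1 - alpha) * coarse + alpha * fine
}

g_channels <- function(res) max(8L, as.integer(128 / res))

lay_group <- function(sub) new_layer("group", sub = sub)

# Generator tree: sub = list(base, stages-group, toGray-group).
pggan_build_g <- function(schedule) {
  K <- as.integer(log2(schedule$target_resolution / schedule$start_resolution))
  r0 <- schedule$start_resolution
  ch0 <- g_channels(r0)
  base <- lay_seq(lay_dense(schedule$latent_dim, r0 * r0 * ch0),
                  lay_reshape(r0, r0, ch0), lay_act("lrelu"),
                  lay_conv(ch0, ch0, k = 3), lay_act("lrelu"))
  stages <- lapply(seq_len(K), function(k) {
    lay_seq(lay_conv(g_channels(r0 * 2^(k - 1)), g_channels(r0 * 2^k), k = 3),
            lay_act("lrelu"))
  })
  togray <- lapply(0:K, function(k) lay_conv(g_channels(r0 * 2^k), 1, k = 1))
  new_layer("group", sub = list(base, lay_group(stages), lay_group(togray)),
            K = K, start = r0, latent_dim = schedule$latent_dim)
}

# Forward pass at `stage` (0-based) with fade coefficient alpha.
pggan_g_fwd <- function(g, z, stage, alpha = 1) {
  base <- g$sub[[1]]; stages <- g$sub[[2]]$sub; togray <- g$sub[[3]]$sub
  rb <- layer_fwd(base, z)
  feats <- list(rb$y)
  scaches <- vector("list", stage)
  for (k in seq_len(stage)) {
    rk <- layer_fwd(stages[[k]], upsample2(feats[[k]]))
    feats[[k + 1]] <- rk$y
    scaches[[k]] <- rk$cache
  }
  fade <- stage > 0 && alpha < 1
  tg_hi <- layer_fwd(togray[[stage + 1]], feats[[stage + 1]])
  if (fade) {
    tg_lo <- layer_fwd(togray[[stage]], feats[[stage]])
    pre <- fade_blend(upsample2(tg_lo$y), tg_hi$y, alpha)
  } else tg_lo <- NULL
  if (!fade) pre <- tg_hi$y
  y <- 1 / (1 + exp(-pre)); dim(y) <- dim(pre)
  list(y = y, cache = list(base = rb$cache, stages = scaches,
                           tg_hi = tg_hi$cache,
                           tg_lo = if (fade) tg_lo$cache,
                           y = y, stage = stage, alpha = alpha, fade = fade))
}

pggan_g_bwd <- function(g, cache, dy) {
  base <- g$sub[[1]]; stages <- g$sub[[2]]$sub; togray <- g$sub[[3]]$sub
  K <- g$K
  stage <- cache$stage; alpha <- cache$alpha
  dpre <- dy * cache$y * (1 - cache$y)
  tg_grads <- vector("list", K + 1)
  sg_grads <- vector("list", K)
  dhi <- if (cache$fade) alpha * dpre else dpre
  r_hi <- layer_bwd(togray[[stage + 1]], cache$tg_hi, dhi)
  tg_grads[[stage + 1]] <- r_hi$grads
  dfeat <- r_hi$dx                      # gradient at feats[[stage+1]]
  dfeat_lo_extra <- NULL
  if (cache$fade) {
    r_lo <- layer_bwd(togray[[stage]], cache$tg_lo,
                      blocksum2((1 - alpha) * dpre))
    tg_grads[[stage]] <- r_lo$grads
    dfeat_lo_extra <- r_lo$dx
  }
  for (k in rev(seq_len(stage))) {
    rk <- layer_bwd(stages[[k]], cache$stages[[k]], dfeat)
    sg_grads[[k]] <- rk$grads
    dfeat <- blocksum2(rk$dx)
    if (!is.null(dfeat_lo_extra) && k == stage) {
      dfeat <- dfeat + dfeat_lo_extra
      dfeat_lo_extra <- NULL
    }
  }
  rb <- layer_bwd(base, cache$base, dfeat)
  list(dz = rb$dx,
       grads = list(sub = list(rb$grads, list(sub = sg_grads),
                               list(sub = tg_grads))))
}

# Discriminator tree: sub = list(fromGray-group, stages-group, final).
pggan_build_d <- function(schedule) {
  K <- as.integer(log2(schedule$target_resolution / schedule$start_resolution))
  r0 <- schedule$start_resolution
  fromgray <- lapply(0:K, function(k) {
    lay_seq(lay_conv(1, g_channels(r0 * 2^k), k = 1), lay_act("lrelu"))
  })
  stages <- lapply(seq_len(K), function(k) {
    lay_seq(lay_conv(g_channels(r0 * 2^k), g_channels(r0 * 2^(k - 1)), k = 3),
            lay_act("lrelu"))
  })
  ch0 <- g_channels(r0)
  final <- lay_seq(lay_conv(ch0, ch0, k = 3), lay_act("lrelu"),
                   lay_flatten(), lay_dense(r0 * r0 * ch0, 1))
  new_layer("group", sub = list(lay_group(fromgray), lay_group(stages), final),
            K = K, start = r0)
}

pggan_d_fwd <- function(d, x, stage, alpha = 1) {
  fromgray <- d$sub[[1]]$sub; stages <- d$sub[[2]]$sub; final <- d$sub[[3]]
  fade <- stage > 0 && alpha < 1
  r_in <- layer_fwd(fromgray[[stage + 1]], x)
  h <- r_in$y
  scaches <- vector("list", stage)
  skip_cache <- NULL
  for (k in rev(seq_len(stage))) {
    rk <- layer_fwd(stages[[k]], h)
    scaches[[k]] <- rk$cache
    h <- blocksum2(rk$y) / 4            # 2x average pooling
    if (fade && k == stage) {
      r_skip <- layer_fwd(fromgray[[stage]], blocksum2(x) / 4)
      skip_cache <- r_skip$cache
      h <- fade_blend(r_skip$y, h, alpha)
    }
  }
  rf <- layer_fwd(final, h)
  list(y = rf$y,
       cache = list(x = x, in_cache = r_in$cache, scaches = scaches,
                    skip_cache = skip_cache, final = rf$cache,
                    stage = stage, alpha = alpha, fade = fade))
}

pggan_d_bwd <- function(d, cache, dy) {
  fromgray <- d$sub[[1]]$sub; stages <- d$sub[[2]]$sub; final <- d$sub[[3]]
  K <- d$K
  stage <- cache$stage; alpha <- cache$alpha
  fg_grads <- vector("list", K + 1)
  sg_grads <- vector("list", K)
  rf <- layer_bwd(final, cache$final, dy)
  dh <- rf$dx
  dx_extra <- 0
  for (k in seq_len(stage)) {
    if (cache$fade && k == stage) {
      r_skip <- layer_bwd(fromgray[[stage]], cache$skip_cache, (1 - alpha) * dh)
      fg_grads[[stage]] <- r_skip$grads
      dx_extra <- upsample2(r_skip$dx) / 4
      dh <- alpha * dh
    }
    rk <- layer_bwd(stages[[k]], cache$scaches[[k]], upsample2(dh) / 4)
    sg_grads[[k]] <- rk$grads
    dh <- rk$dx
  }
  r_in <- layer_bwd(fromgray[[stage + 1]], cache$in_cache, dh)
  fg_grads[[stage + 1]] <- r_in$grads
  list(dx = r_in$dx + dx_extra,
       grads = list(sub = list(list(sub = fg_grads), list(sub = sg_grads),
                               rf$grads)))
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
sigm <- function(x) 1 / (1 + exp(-x))

#' Train a progressive-growing GAN on one class
#'
#' Trains generator and discriminator with the nonsaturating logistic GAN
#' objective and Adam, growing the resolution from
#' `schedule$start_resolution` to `schedule$target_resolution`; at each
#' transition alpha ramps linearly over `fade_steps` steps and then stays
#' at 1.  The run is fully seeded.  With `steps_per_stage = 0` no stage is
#' trained and the returned handle stays at the start resolution.
#'
#' @param pool A single-class dataset tibble (images are resized to each
#'   working resolution as needed).
#' @param schedule A [progressive_schedule()].
#' @param verbose Print per-stage progress.
#' @return A `pggan_generator` handle for [generate_images()].
#' @export
train_pggan <- function(pool, schedule = progressive_schedule(), verbose = FALSE) {
  if (nrow(pool) == 0) abort("image pool is empty")
  if (length(unique(pool$label)) != 1)
    abort("PGGAN trains per class; pool has several labels")
  class_tag <- pool$label[1]
  g <- with_seed(schedule$seed, pggan_build_g(schedule))
  d <- with_seed(seed_add(schedule$seed, 1), pggan_build_d(schedule))
  K <- g$K
  final_stage <- 0L
  if (schedule$steps_per_stage > 0) {
    gs <- NULL; ds <- NULL; t_g <- 0; t_d <- 0
    n_fade_by_stage <- c(0L, rep(schedule$fade_steps, K))
    step_seeds <- derive_seeds(seed_add(schedule$seed, 2),
                               sum(n_fade_by_stage + schedule$steps_per_stage))
    t_all <- 0
    resized <- list()
    for (stage in 0:K) {
      res <- schedule$start_resolution * 2^stage
      key <- as.character(res)
      if (is.null(resized[[key]]))
        resized[[key]] <- lapply(pool$pixels, resize_pixels, H_out = res)
      reals <- resized[[key]]
      n_fade <- n_fade_by_stage[stage + 1]
      for (step in seq_len(n_fade + schedule$steps_per_stage)) {
        alpha <- if (step <= n_fade) step / (n_fade + 1) else 1
        t_all <- t_all + 1
        draws <- with_seed(step_seeds[t_all], list(
          idx = sample.int(length(reals), min(schedule$batch_size, length(reals))),
          z1 = matrix(rnorm(g$latent_dim * schedule$batch_size), g$latent_dim),
          z2 = matrix(rnorm(g$latent_dim * schedule$batch_size), g$latent_dim)))
        idx <- draws$idx; z1 <- draws$z1; z2 <- draws$z2

        xr <- stack_images(reals[idx])
        # --- discriminator step
        fake <- pggan_g_fwd(g, z1, stage, alpha)
        dr <- pggan_d_fwd(d, xr, stage, alpha)
        df <- pggan_d_fwd(d, fake$y, stage, alpha)
        nb <- ncol(z1)
        gr_r <- pggan_d_bwd(d, dr$cache, matrix(-sigm(-dr$y) / nb, 1))
        gr_f <- pggan_d_bwd(d, df$cache, matrix(sigm(df$y) / nb, 1))
        upd <- adam_update(d, grads_add(gr_r$grads, gr_f$grads), ds,
                           schedule$learning_rate, t_d <- t_d + 1)
        d <- upd$layer; ds <- upd$state
        # --- generator step
        fake <- pggan_g_fwd(g, z2, stage, alpha)
        df <- pggan_d_fwd(d, fake$y, stage, alpha)
        gb <- pggan_d_bwd(d, df$cache, matrix(-sigm(-df$y) / nb, 1))
        gg <- pggan_g_bwd(g, fake$cache, gb$dx)
        upd <- adam_update(g, gg$grads, gs, schedule$learning_rate,
                           t_g <- t_g + 1)
        g <- upd$layer; gs <- upd$state
      }
      final_stage <- stage
      if (verbose) message(sprintf("stage %d (%dpx) done", stage, res))
    }
  }
  structure(list(g = g, d = d, stage = final_stage,
                 resolution = schedule$start_resolution * 2^final_stage,
                 class_tag = class_tag, schedule = schedule),
            class = "pggan_generator")
}

#' Generate images from a trained PGGAN handle
#'
#' @param handle A `pggan_generator` from [train_pggan()].
#' @param n Number of images (>= 0).
#' @param seed Seed for the latent draws; fixed seeds give identical batches.
#' @return A dataset tibble of `n` records at the handle's resolution,
#'   provenance `"gan_pggan"`, labeled with the handle's class.
#' @export
generate_images <- function(handle, n, seed = 0) {
  UseMethod("generate_images")
}

#' @export
generate_images.pggan_generator <- function(handle, n, seed = 0) {
  check_number(n, "n", lower = 0, integer = TRUE)
  if (n == 0) return(empty_dataset())
  z <- with_seed(seed, matrix(rnorm(handle$g$latent_dim * n), handle$g$latent_dim))
  imgs <- list()
  for (s in seq(1, n, by = 64)) {
    idx <- s:min(s + 63, n)
    y <- pggan_g_fwd(handle$g, z[, idx, drop = FALSE], handle$stage, 1)$y
    imgs <- c(imgs, unstack_images(y))
  }
  tibble::tibble(
    source_id = sprintf("pggan_%s_s%d_%05d", handle$class_tag, seed, seq_len(n)),
    label = handle$class_tag, provenance = "gan_pggan",
    pixels = imgs, mask = rep(list(NULL), n))
}

#' @export
print.pggan_generator <- function(x, ...) {
  cat(sprintf("<pggan_generator> class '%s', %dx%d (stage %d of %d)\n",
              x$class_tag, x$resolution, x$resolution, x$stage, x$g$K))
  invisible(x)
}
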