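#' CycleGAN configuration
#'
#' Unpaired image-to-image translation between the control and scar
#' domains: two residual translators (G: a to b, F: b to a) trained with a
#' least-squares adversarial loss plus `lambda_cycle` times the two
#' cycle-consistency L1 losses.
#'
#' @param image_size Square image side (even).
#' @param lambda_cycle Nonnegative cycle-consistency weight (10 by default).
#' @param steps Optimizer steps.
#' @param batch_size,learning_rate Adam settings.
#' @param init `"random"` (default) or `"identity"`; an identity-initialized
#'   translator maps every image to itself, so the initial cycle loss is 0.
#' @param seed Master seed.
#' @return A `cyclegan_config` list.
#' @export
cyclegan_config <- function(image_size = 64, lambda_cycle = 10, steps = 200,
                            batch_size = 8, learning_rate = 1e-3,
                            init = "random", seed = 0) {
  check_number(image_size, "image_size", lower = 8, integer = TRUE)
  if (image_size %% 2 != 0) abort("`image_size` must be even")
  check_number(lambda_cycle, "lambda_cycle", lower = 0)
  check_number(steps, "steps", lower = 0, integer = TRUE)
  check_number(batch_size, "batch_size", lower = 1, integer = TRUE)
  check_number(learning_rate, "learning_rate", lower = 0)
  if (!init %in% c("random", "identity")) abort("`init` must be random/identity")
  check_number(seed, "seed", lower = 0, integer = TRUE)
  structure(list(image_size = as.integer(image_size),
                 lambda_cycle = lambda_cycle, steps = as.integer(steps),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, init = init,
                 seed = as.integer(seed)),
            class = "cyclegan_config")
}

#' Cycle-consistency loss
#'
#' Mean absolute pixel difference between a batch and its reconstruction
#' through the forward and backward translators.
#'
#' @param x,x_reconstructed Arrays (or matrices) of identical shape.
#' @return A nonnegative scalar, 0 iff the inputs are identical.
#' @export
cycle_loss <- function(x, x_reconstructed) {
  if (!identical(dim(x) %||% length(x),
                 dim(x_reconstructed) %||% length(x_reconstructed)))
    abort("shape mismatch between batch and reconstruction")
  mean(abs(x - x_reconstructed))
}

# Residual translator: y = clamp01(x + conv stack(x)); zero-initializing
# the last conv makes it the identity on [0,1] images.
build_translator <- function(config) {
  lay_seq(
    lay_resblock(lay_seq(
      lay_conv(1, 8, k = 3), lay_act("lrelu"),
      lay_conv(8, 8, k = 3), lay_act("lrelu"),
      lay_conv(8, 1, k = 3, zero_init = config$init == "identity",
               init_gain = 0.05)),
      residual = TRUE),
    lay_act("clamp01"))
}

build_patch_d <- function(config) {
  s4 <- config$image_size / 4
  lay_seq(lay_conv(1, 8, k = 3, stride = 2), lay_act("lrelu"),
          lay_conv(8, 16, k = 3, stride = 2), lay_act("lrelu"),
          lay_flatten(), lay_dense(s4 * s4 * 16, 1))
}

#' Train a CycleGAN between two image domains
#'
#' @param domain_a,domain_b Nonempty single-class dataset tibbles (e.g.
#'   control and scar training images) at the configured size.
#' @param config A [cyclegan_config()].
#' @param verbose Print progress every 50 steps.
#' @return A `cyclegan` object holding the two translators (`G`: a to b,
#'   `F`: b to a), the domain labels, and the training history.
#' @export
train_cyclegan <- function(domain_a, domain_b, config = cyclegan_config(),
                           verbose = FALSE) {
  if (nrow(domain_a) == 0 || nrow(domain_b) == 0)
    abort("both domains must be nonempty")
  G <- with_seed(config$seed, build_translator(config))
  F_ <- with_seed(seed_add(config$seed, 1), build_translator(config))
  DA <- with_seed(seed_add(config$seed, 2), build_patch_d(config))
  DB <- with_seed(seed_add(config$seed, 3), build_patch_d(config))
  sG <- sF <- sDA <- sDB <- NULL
  t_ <- 0
  history <- vector("list", config$steps)
  step_seeds <- if (config$steps > 0) derive_seeds(seed_add(config$seed, 4), config$steps)
  for (step in seq_len(config$steps)) {
    idx <- with_seed(step_seeds[step], list(
      a = sample.int(nrow(domain_a), min(config$batch_size, nrow(domain_a))),
      b = sample.int(nrow(domain_b), min(config$batch_size, nrow(domain_b)))))
    xa <- stack_images(domain_a$pixels[idx$a])
    xb <- stack_images(domain_b$pixels[idx$b])
    nb <- dim(xa)[4]; npx <- length(xa)
    t_ <- t_ + 1

    # generator/translator update
    fG <- layer_fwd(G, xa);  fake_b <- fG$y
    fF <- layer_fwd(F_, fake_b); rec_a <- fF$y
    fF2 <- layer_fwd(F_, xb); fake_a <- fF2$y
    fG2 <- layer_fwd(G, fake_a); rec_b <- fG2$y
    dDB <- layer_fwd(DB, fake_b)
    dDA <- layer_fwd(DA, fake_a)

    lam <- config$lambda_cycle
    bF <- seq_bwd(F_, fF$cache, lam * sign(rec_a - xa) / npx)
    bDB <- seq_bwd(DB, dDB$cache, 2 * (dDB$y - 1) / nb)
    bG_main <- seq_bwd(G, fG$cache, bF$dx + bDB$dx)
    bG2 <- seq_bwd(G, fG2$cache, lam * sign(rec_b - xb) / npx)
    bDA <- seq_bwd(DA, dDA$cache, 2 * (dDA$y - 1) / nb)
    bF2_main <- seq_bwd(F_, fF2$cache, bG2$dx + bDA$dx)
    uG <- adam_update(G, grads_add(bG_main$grads, bG2$grads), sG,
                      config$learning_rate, t_)
    uF <- adam_update(F_, grads_add(bF$grads, bF2_main$grads), sF,
                      config$learning_rate, t_)
    G <- uG$layer; sG <- uG$state
    F_ <- uF$layer; sF <- uF$state

    # discriminator updates (fresh forward on detached fakes)
    for (side in list(list(D = DB, s = sDB, real = xb, fake = fake_b, id = "B"),
                      list(D = DA, s = sDA, real = xa, fake = fake_a, id = "A"))) {
      fr <- layer_fwd(side$D, side$real)
      ff <- layer_fwd(side$D, side$fake)
      gr <- grads_add(seq_bwd(side$D, fr$cache, 2 * (fr$y - 1) / nb)$grads,
                      seq_bwd(side$D, ff$cache, 2 * ff$y / nb)$grads)
      u <- adam_update(side$D, gr, side$s, config$learning_rate, t_)
      if (side$id == "B") { DB <- u$layer; sDB <- u$state }
      else { DA <- u$layer; sDA <- u$state }
    }

    cyc <- cycle_loss(xa, rec_a) + cycle_loss(xb, rec_b)
    history[[step]] <- tibble::tibble(step = step, cycle = cyc)
    if (verbose && step %% 50 == 0)
      message(sprintf("step %d: cycle loss %.4f", step, cyc))
  }
  structure(list(G = G, F = F_, DA = DA, DB = DB,
                 label_a = domain_a$label[1], label_b = domain_b$label[1],
                 config = config,
                 history = if (config$steps > 0) dplyr::bind_rows(history)
                           else tibble::tibble(step = integer(), cycle = numeric())),
            class = "cyclegan")
}

#' Translate images to the other domain
#'
#' Applies the trained translator mapping into class `to`; outputs keep the
#' \[0,1\] range by construction and are tagged provenance
#' `"gan_cyclegan"` with the target domain's label.
#'
#' @param gan A [train_cyclegan()] result.
#' @param dataset Source-domain images at the configured size.
#' @param to Target class label (one of the two training domains).
#' @return A dataset tibble of translated records, one per input.
#' @export
translate_images <- function(gan, dataset, to) {
  if (!to %in% c(gan$label_a, gan$label_b))
    abort(sprintf("`to` must be '%s' or '%s'", gan$label_a, gan$label_b))
  if (nrow(dataset) == 0) return(empty_dataset())
  sz <- nrow(dataset$pixels[[1]])
  if (sz != gan$config$image_size)
    abort(sprintf("translator expects %d-pixel images, dataset has %d",
                  gan$config$image_size, sz))
  tr <- if (to == gan$label_b) gan$G else gan$F
  out <- list()
  for (s in seq(1, nrow(dataset), by = 64)) {
    idx <- s:min(s + 63, nrow(dataset))
    y <- layer_fwd(tr, stack_images(dataset$pixels[idx]))$y
    out <- c(out, unstack_images(y))
  }
  tibble::tibble(source_id = paste0("cyc_", to, "_", dataset$source_id),
                 label = to, provenance = "gan_cyclegan",
                 pixels = out, mask = rep(list(NULL), nrow(dataset)))
}

#' @export
print.cyclegan <- function(x, ...) {
  cat(sprintf("<cyclegan> %s <-> %s, %dpx, %d steps trained\n",
              x$label_a, x$label_b, x$config$image_size, x$config$steps))
  invisible(x)
}
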