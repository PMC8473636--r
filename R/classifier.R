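#' Classifier configuration
#'
#' A MobileNetV2-style binary classifier: a strided stem convolution
#' followed by inverted residual blocks (1x1 expansion, 3x3 depthwise,
#' linear 1x1 projection, residual when stride 1 and channels match), a
#' final 1x1 convolution, global average pooling and a two-logit head.
#' An attention unit (none / channel / spatial / mix) is inserted in every
#' inverted residual block after the depthwise stage.
#'
#' @param input_size Input image side in pixels (power of 2, >= 16).
#' @param width_multiplier Channel-width scale; 0.5 is the desk-scale
#'   default, 1 mirrors the standard width.
#' @param attention One of `"none"`, `"CA"`, `"SA"`, `"MA"`. Channel
#'   attention is the default, the unit found most effective for this task.
#' @param se_reduction Channel-attention bottleneck ratio.
#' @param sa_kernel Spatial-attention kernel size (odd).
#' @param expansion Inverted-residual expansion factor.
#' @param init `"random"` (seeded He initialization) or `"pretrained"`
#'   (load `weights_file`, an RDS written by [save_classifier()]).
#' @param weights_file Path of pretrained weights when `init = "pretrained"`.
#' @param epochs,batch_size,learning_rate,optimizer Training loop settings;
#'   optimizer is `"adam"` or `"sgd"` (momentum 0.9).
#' @param seed Master seed for initialization, shuffling and batching.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(input_size = 64, width_multiplier = 0.5,
                              attention = "CA", se_reduction = 4,
                              sa_kernel = 3, expansion = 4,
                              init = "random", weights_file = NULL,
                              epochs = 15, batch_size = 32,
                              learning_rate = 1e-3, optimizer = "adam",
                              seed = 0) {
  check_number(input_size, "input_size", lower = 16, integer = TRUE)
  if (!is_pow2(input_size)) abort("`input_size` must be a power of 2")
  check_number(width_multiplier, "width_multiplier", lower = 1e-3)
  if (!attention %in% c("none", "CA", "SA", "MA"))
    abort("`attention` must be one of none/CA/SA/MA")
  check_number(se_reduction, "se_reduction", lower = 1, integer = TRUE)
  check_number(sa_kernel, "sa_kernel", lower = 1, integer = TRUE)
  if (sa_kernel %% 2 == 0) abort("`sa_kernel` must be odd")
  if (!init %in% c("random", "pretrained")) abort("`init` must be random/pretrained")
  if (init == "pretrained" && (is.null(weights_file) || !file.exists(weights_file)))
    abort("init = 'pretrained' requires an existing `weights_file`")
  if (!optimizer %in% c("adam", "sgd")) abort("`optimizer` must be adam/sgd")
  check_number(epochs, "epochs", lower = 0, integer = TRUE)
  check_number(batch_size, "batch_size", lower = 1, integer = TRUE)
  check_number(learning_rate, "learning_rate", lower = 0)
  check_number(seed, "seed", lower = 0, integer = TRUE)
  structure(list(input_size = as.integer(input_size),
                 width_multiplier = width_multiplier, attention = attention,
                 se_reduction = as.integer(se_reduction),
                 sa_kernel = as.integer(sa_kernel),
                 expansion = as.integer(expansion), init = init,
                 weights_file = weights_file, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

scale_ch <- function(base, wm) max(4L, as.integer(round(base * wm)))

# Inverted residual block: expand -> depthwise -> attention -> project.
inverted_residual <- function(cin, cout, stride, config) {
  cexp <- cin * config$expansion
  body <- lay_seq(
    lay_conv(cin, cexp, k = 1),
    lay_act("relu6"),
    lay_dwconv(cexp, k = 3, stride = stride),
    lay_act("relu6"),
    make_attention_layer(config$attention, cexp, config$se_reduction,
                         config$sa_kernel),
    lay_conv(cexp, cout, k = 1))
  lay_resblock(body, residual = stride == 1 && cin == cout)
}

#' Build a classifier model
#'
#' Constructs the network for a [classifier_config()]; initialization is
#' deterministic for a fixed config and seed.  The depth adapts to
#' `input_size` so that the last convolutional feature map (the Grad-CAM
#' target) is always 8 x 8.
#'
#' @param config A [classifier_config()].
#' @return A `scar_classifier` model handle.
#' @export
build_classifier <- function(config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  wm <- config$width_multiplier
  n_down <- as.integer(log2(config$input_size)) - 3L   # final map is 8x8
  base_ch <- c(24, 32, 64, 96, 160, 320)
  model <- with_seed(config$seed, {
    layers <- list(lay_conv(1, scale_ch(16, wm), k = 3, stride = 2),
                   lay_act("relu6"))
    cin <- scale_ch(16, wm)
    for (k in seq_len(max(0L, n_down - 1L))) {
      cout <- scale_ch(base_ch[k], wm)
      layers <- c(layers, list(inverted_residual(cin, cout, 2L, config),
                               inverted_residual(cout, cout, 1L, config)))
      cin <- cout
    }
    cout <- scale_ch(base_ch[max(1L, n_down)], wm)
    layers <- c(layers, list(inverted_residual(cin, cout, 1L, config)))
    chead <- scale_ch(128, wm)
    layers <- c(layers, list(lay_conv(cout, chead, k = 1),
                             lay_act("relu6")))
    gc_index <- length(layers)                 # activation after last conv
    layers <- c(layers, list(lay_gap(), lay_dense(chead, 2)))
    list(net = lay_seq(layers), gc_index = gc_index)
  })
  out <- structure(list(net = model$net, gc_index = model$gc_index,
                        config = config, classes = c("control", "scar"),
                        curve = NULL),
                   class = "scar_classifier")
  if (config$init == "pretrained") {
    w <- readRDS(config$weights_file)
    if (!is.null(w$par_tree)) w <- w$par_tree   # save_classifier() format
    out$net <- copy_params(out$net, w)
  }
  out
}

# Transfer a saved parameter tree into a layer tree of identical shape.
copy_params <- function(layer, saved) {
  if (!is.null(layer$par)) {
    for (nm in names(layer$par)) {
      if (!identical(dim(layer$par[[nm]]), dim(saved$par[[nm]])) &&
          length(layer$par[[nm]]) != length(saved$par[[nm]]))
        abort("pretrained weights do not match the model architecture")
      layer$par[[nm]] <- saved$par[[nm]]
    }
  }
  if (!is.null(layer$sub))
    for (i in seq_along(layer$sub))
      layer$sub[[i]] <- copy_params(layer$sub[[i]], saved$sub[[i]])
  layer
}

extract_params <- function(layer) {
  out <- list()
  if (!is.null(layer$par)) out$par <- layer$par
  if (!is.null(layer$sub)) out$sub <- lapply(layer$sub, extract_params)
  out
}

#' Save / load classifier weights
#' @param model A `scar_classifier`.
#' @param path RDS file path.
#' @return `save_classifier` returns `path` invisibly; `load_classifier`
#'   returns the model.
#' @export
save_classifier <- function(model, path) {
  saveRDS(list(par_tree = extract_params(model$net), config = model$config,
               curve = model$curve), path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  s <- readRDS(path)
  model <- build_classifier(s$config)
  model$net <- copy_params(model$net, s$par_tree)
  model$curve <- s$curve
  model
}

dataset_batch <- function(dataset, idx = seq_len(nrow(dataset))) {
  x <- stack_images(dataset$pixels[idx])
  y <- 1L + (dataset$label[idx] == "scar")   # 1 = control, 2 = scar
  list(x = x, y = y)
}

softmax_cols <- function(logits) {
  z <- sweep(logits, 2, apply(logits, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# Cross-entropy loss and gradient for (2, N) logits and class indices.
ce_loss <- function(logits, y) {
  p <- softmax_cols(logits)
  n <- length(y)
  picked <- p[cbind(y, seq_len(n))]
  d <- p
  d[cbind(y, seq_len(n))] <- d[cbind(y, seq_len(n))] - 1
  list(loss = -mean(log(pmax(picked, 1e-12))), dlogits = d / n,
       pred = max.col(t(p)))
}

model_logits <- function(model, x) layer_fwd(model$net, x)$y

#' Predict class scores for a dataset
#' @param object A trained `scar_classifier`.
#' @param dataset A dataset tibble whose images match the configured size.
#' @param batch_size Forward-pass batch size.
#' @param ... Unused.
#' @return A tibble with `source_id`, `label`, `.pred_scar` (softmax scar
#'   probability) and `.pred_class`.
#' @export
predict.scar_classifier <- function(object, dataset, batch_size = 128, ...) {
  check_input_size(object, dataset)
  n <- nrow(dataset)
  scores <- numeric(n)
  for (s in seq(1, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1, n)
    b <- dataset_batch(dataset, idx)
    p <- softmax_cols(model_logits(object, b$x))
    scores[idx] <- p[2, ]
  }
  tibble::tibble(source_id = dataset$source_id, label = dataset$label,
                 .pred_scar = scores,
                 .pred_class = ifelse(scores >= 0.5, "scar", "control"))
}

check_input_size <- function(model, dataset) {
  if (nrow(dataset) == 0) abort("dataset is empty")
  sz <- nrow(dataset$pixels[[1]])
  if (sz != model$config$input_size)
    abort(sprintf("model expects %d-pixel images, dataset has %d",
                  model$config$input_size, sz))
}

#' Train the classifier
#'
#' Minibatch cross-entropy training with the configured optimizer; the
#' whole run (initialization, shuffling, updates) is deterministic for a
#' fixed config seed.  Per-epoch train/test accuracy and mean training
#' loss are recorded in the model's `curve`.
#'
#' @param train_set,test_set Dataset tibbles; the training set must contain
#'   both classes.
#' @param config A [classifier_config()].
#' @param verbose Print per-epoch progress.
#' @return A trained `scar_classifier` with a `curve` tibble
#'   (`epoch`, `train_accuracy`, `test_accuracy`, `loss`).
#' @export
train_classifier <- function(train_set, test_set, config = classifier_config(),
                             verbose = FALSE) {
  if (nrow(train_set) == 0) abort("training set is empty")
  if (length(unique(train_set$label)) < 2)
    abort("training set must contain both classes")
  model <- build_classifier(config)
  n <- nrow(train_set)
  state <- NULL
  t_step <- 0
  curve <- vector("list", config$epochs)
  seeds <- if (config$epochs > 0) derive_seeds(seed_add(config$seed, 1), config$epochs) else integer()
  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(seeds[ep], sample.int(n))
    correct <- 0; losses <- c()
    for (s in seq(1, n, by = config$batch_size)) {
      idx <- ord[s:min(s + config$batch_size - 1, n)]
      b <- dataset_batch(train_set, idx)
      fw <- layer_fwd(model$net, b$x)
      l <- ce_loss(fw$y, b$y)
      correct <- correct + sum(l$pred == b$y)
      losses <- c(losses, l$loss)
      bw <- seq_bwd(model$net, fw$cache, l$dlogits)
      t_step <- t_step + 1
      upd <- if (config$optimizer == "adam")
        adam_update(model$net, bw$grads, state, config$learning_rate, t_step)
      else sgd_update(model$net, bw$grads, state, config$learning_rate)
      model$net <- upd$layer
      state <- upd$state
    }
    test_acc <- if (nrow(test_set) > 0) {
      pr <- predict(model, test_set)
      mean(pr$.pred_class == test_set$label)
    } else NA_real_
    curve[[ep]] <- tibble::tibble(epoch = ep, train_accuracy = correct / n,
                                  test_accuracy = test_acc,
                                  loss = mean(losses))
    if (verbose)
      message(sprintf("epoch %d: train %.3f test %.3f loss %.4f", ep,
                      correct / n, test_acc, mean(losses)))
  }
  model$curve <- if (config$epochs > 0) dplyr::bind_rows(curve) else
    tibble::tibble(epoch = integer(), train_accuracy = numeric(),
                   test_accuracy = numeric(), loss = numeric())
  model
}

#' Evaluate a classifier on a test set
#'
#' Accuracy, per-class accuracy, confusion counts, the ROC curve over all
#' score thresholds and its trapezoid-rule AUC.
#'
#' @param model A trained `scar_classifier`.
#' @param test_set A nonempty dataset tibble.
#' @return A `scar_eval` list: `accuracy`, `per_class` tibble, `confusion`
#'   (2 x 2 matrix, rows = truth), `roc` tibble (`threshold`, `fpr`, `tpr`)
#'   and `auc`.
#' @export
evaluate_classifier <- function(model, test_set) {
  if (nrow(test_set) == 0) abort("test set is empty")
  pr <- predict(model, test_set)
  truth <- test_set$label
  acc <- mean(pr$.pred_class == truth)
  per_class <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(truth = truth, ok = pr$.pred_class == truth),
                    .data$truth),
    accuracy = mean(.data$ok), n = dplyr::n(), .groups = "drop")
  confusion <- table(factor(truth, c("control", "scar")),
                     factor(pr$.pred_class, c("control", "scar")))
  roc <- roc_points(pr$.pred_scar, truth == "scar")
  structure(list(accuracy = acc, per_class = per_class,
                 confusion = unclass(confusion),
                 roc = roc, auc = trapezoid_auc(roc$fpr, roc$tpr)),
            class = "scar_eval")
}

# ROC over every distinct score threshold (plus the two endpoints).
roc_points <- function(scores, is_pos) {
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  P <- sum(is_pos); Ng <- sum(!is_pos)
  tpr <- vapply(thr, function(t) if (P == 0) 0 else sum(scores >= t & is_pos) / P, 1)
  fpr <- vapply(thr, function(t) if (Ng == 0) 0 else sum(scores >= t & !is_pos) / Ng, 1)
  tibble::tibble(threshold = thr, fpr = fpr, tpr = tpr)
}

trapezoid_auc <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  sum(diff(fpr[o]) * (head(tpr[o], -1) + tpr[o][-1]) / 2)
}

#' @export
print.scar_classifier <- function(x, ...) {
  cat(sprintf("<scar_classifier> %dpx, attention = %s, %s parameters\n",
              x$config$input_size, x$config$attention,
              format(n_params(x$net), big.mark = ",")))
  if (!is.null(x$curve) && nrow(x$curve) > 0)
    cat(sprintf("  trained %d epochs; final test accuracy %.3f\n",
                max(x$curve$epoch), x$curve$test_accuracy[nrow(x$curve)]))
  invisible(x)
}

#' @export
print.scar_eval <- function(x, ...) {
  cat(sprintf("<scar_eval> accuracy %.3f, AUC %.3f\n", x$accuracy, x$auc))
  print(x$confusion)
  invisible(x)
}
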