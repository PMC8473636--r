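#' Resize every image of a dataset
#' @param dataset A dataset tibble.
#' @param size Target square side in pixels.
#' @return The dataset with resized `pixels` (and masks, re-binarized).
#' @export
resize_dataset <- function(dataset, size) {
  check_number(size, "size", lower = 2, integer = TRUE)
  dataset$pixels <- lapply(dataset$pixels, function(m) clamp01(resize_pixels(m, size)))
  if ("mask" %in% names(dataset))
    dataset$mask <- lapply(dataset$mask, function(m) {
      if (is.null(m)) NULL else (resize_pixels(m, size) >= 0.5) * 1
    })
  dataset
}

#' Pipeline run configuration
#'
#' A single master seed derives every stage's seed deterministically, so a
#' rerun with the same configuration reproduces all counts and seeded
#' outputs.  Any field can be overridden; the defaults describe a
#' desk-scale experiment.
#'
#' @param seed Master seed.
#' @param outdir Output directory for artifacts and the JSON summary.
#' @param n_scar,n_control Phantom counts per class.
#' @param n_test_per_class Stratified test split size.
#' @param phantom A [phantom_params()] object.
#' @param n_rotations_scar,n_rotations_control Rotation multiplicities.
#' @param aug_factor Balanced-sampling scale ("4x augmentation").
#' @param gan `"pggan"`, `"cyclegan"` or `"none"`.
#' @param gan_resolution,gan_steps,gan_fade_steps PGGAN schedule knobs;
#'   `gan_steps` doubles as CycleGAN step count.
#' @param n_generate Generated images per class.
#' @param k_sigma Sigma-filter threshold multiplier.
#' @param feature_dim Embedding dimension for filtering/FID.
#' @param classifier A [classifier_config()]; its seed/input size are
#'   overridden by the pipeline.
#' @param roi_threshold Grad-CAM ROI threshold.
#' @param write_images Also write PNG + manifest artifacts per stage.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1, outdir = tempfile("scaraug_run_"),
                       n_scar = 120, n_control = 120, n_test_per_class = 20,
                       phantom = phantom_params(),
                       n_rotations_scar = 8, n_rotations_control = 8,
                       aug_factor = 4, gan = "pggan", gan_resolution = 16,
                       gan_steps = 150, gan_fade_steps = 50, n_generate = 60,
                       k_sigma = 1, feature_dim = 1000,
                       classifier = classifier_config(epochs = 5),
                       roi_threshold = 0.5, write_images = FALSE) {
  if (!gan %in% c("pggan", "cyclegan", "none"))
    abort("`gan` must be pggan/cyclegan/none")
  structure(as.list(environment()), class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields of the YAML override [run_config()] defaults; nested
#' `phantom:` and `classifier:` maps override those constructors' defaults.
#'
#' @param path YAML file path.
#' @param ... Further overrides applied after the file.
#' @return A `run_config`.
#' @export
load_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path) %||% list()
  if (!is.null(y$phantom)) y$phantom <- do.call(phantom_params, y$phantom)
  if (!is.null(y$classifier)) y$classifier <- do.call(classifier_config, y$classifier)
  do.call(run_config, utils::modifyList(y, list(...)))
}

pipeline_stages <- c("phantom", "augment", "gan", "filter", "train", "explain")

require_stage <- function(bundle, what, needed_for) {
  if (is.null(bundle[[what]]))
    abort(sprintf("stage '%s' needs the '%s' stage output; run '%s' first",
                  needed_for, what, what))
}

#' Run the augmentation/classification pipeline
#'
#' Orchestrates the workflow: phantom generation, stratified split,
#' traditional augmentation with balanced sampling, per-class GAN training
#' and generation, PCA/k-means sigma filtering with FID scoring, classifier
#' training, and Grad-CAM explanation.  Every stage appends its key metrics
#' to a JSON summary in `config$outdir` and logs its derived seed.
#'
#' @param config A [run_config()].
#' @param stages Subset of
#'   `c("phantom", "augment", "gan", "filter", "train", "explain")`.
#' @param bundle A previous [run_pipeline()] result to extend (stage
#'   outputs already present are reused).
#' @param verbose Print stage progress.
#' @return A results bundle (list of per-stage outputs plus `summary`).
#' @export
run_pipeline <- function(config = run_config(), stages = pipeline_stages,
                         bundle = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad) > 0)
    abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  stages <- pipeline_stages[pipeline_stages %in% stages]
  bundle <- bundle %||% list(summary = list(master_seed = config$seed))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))

  if ("phantom" %in% stages) {
    sd <- stage_seed(config$seed, "phantom")
    say("phantom stage (seed %d)", sd)
    data <- make_phantom_dataset(config$n_scar, config$n_control,
                                 config$phantom, seed = sd)
    split <- split_dataset(data, config$n_test_per_class,
                           seed = stage_seed(config$seed, "split"))
    if (config$write_images)
      write_dataset(data, file.path(config$outdir, "phantom"))
    bundle$phantom <- list(data = data, train = split$train, test = split$test,
                           seed = sd)
    bundle$summary$phantom <- list(seed = sd, n_scar = config$n_scar,
                                   n_control = config$n_control,
                                   n_train = nrow(split$train),
                                   n_test = nrow(split$test))
  }

  if ("augment" %in% stages) {
    require_stage(bundle, "phantom", "augment")
    sd <- stage_seed(config$seed, "augment")
    say("augment stage (seed %d)", sd)
    train <- bundle$phantom$train
    plans <- list(
      scar = augmentation_plan(config$n_rotations_scar, seed = sd),
      control = augmentation_plan(config$n_rotations_control,
                                  seed = seed_add(sd, 1)))
    pool <- build_pool(train, plans)
    n_base_majority <- max(pool_counts(train)$n)
    balanced <- sample_balanced(pool, config$aug_factor, n_base_majority,
                                seed = sd)
    if (config$write_images)
      write_dataset(balanced, file.path(config$outdir, "augmented"))
    bundle$augment <- list(pool = pool, balanced = balanced, seed = sd)
    bundle$summary$augment <- list(
      seed = sd, pool_counts = as.list(setNames(pool_counts(pool)$n,
                                                pool_counts(pool)$label)),
      balanced_per_class = config$aug_factor * n_base_majority)
  }

  if ("gan" %in% stages && config$gan != "none") {
    require_stage(bundle, "phantom", "gan")
    sd <- stage_seed(config$seed, "gan")
    say("gan stage: %s (seed %d)", config$gan, sd)
    train <- bundle$phantom$train
    gen <- list()
    if (config$gan == "pggan") {
      handles <- list()
      for (cl in sort(unique(train$label))) {
        sched <- progressive_schedule(
          target_resolution = config$gan_resolution,
          steps_per_stage = config$gan_steps,
          fade_steps = config$gan_fade_steps,
          seed = seed_add(sd, match(cl, sort(unique(train$label)))))
        handles[[cl]] <- train_pggan(train[train$label == cl, ], sched)
        gen[[cl]] <- generate_images(handles[[cl]], config$n_generate,
                                     seed = seed_add(sd, 10))
      }
      bundle$gan <- list(type = "pggan", handles = handles, seed = sd)
    } else {
      sz <- config$phantom$image_size
      cg <- cyclegan_config(image_size = sz, steps = config$gan_steps, seed = sd)
      ctrl <- train[train$label == "control", ]
      scar <- train[train$label == "scar", ]
      gan <- train_cyclegan(ctrl, scar, cg)
      gen$scar <- translate_images(gan, ctrl, to = "scar")
      gen$control <- translate_images(gan, scar, to = "control")
      if (config$n_generate < nrow(gen$scar))
        gen$scar <- head(gen$scar, config$n_generate)
      if (config$n_generate < nrow(gen$control))
        gen$control <- head(gen$control, config$n_generate)
      bundle$gan <- list(type = "cyclegan", gan = gan, seed = sd)
    }
    bundle$gan$generated <- dplyr::bind_rows(gen)
    if (config$write_images)
      write_dataset(bundle$gan$generated, file.path(config$outdir, "generated"))
    bundle$summary$gan <- list(seed = sd, type = config$gan,
                               n_generated = nrow(bundle$gan$generated))
  }

  if ("filter" %in% stages && config$gan != "none") {
    require_stage(bundle, "gan", "filter")
    sd <- stage_seed(config$seed, "filter")
    say("filter stage (seed %d)", sd)
    gen <- bundle$gan$generated
    # the backbone needs at least 16-px inputs; embed upscaled copies when
    # the GAN resolution is lower, but keep the original generated pixels
    sz <- max(16L, nrow(gen$pixels[[1]]))
    backbone <- feature_backbone(input_size = sz, d = config$feature_dim,
                                 seed = sd)
    gen_emb <- resize_dataset(gen, sz)
    flt <- filter_images(gen_emb, backbone, k_sigma = config$k_sigma)
    flt$kept <- gen[gen$source_id %in% flt$kept$source_id, ]
    real_ref <- resize_dataset(bundle$phantom$train, sz)
    fids <- list()
    for (cl in sort(unique(gen$label))) {
      r <- real_ref[real_ref$label == cl, ]
      g_all <- gen_emb[gen_emb$label == cl, ]
      g_kept <- gen_emb[gen_emb$source_id %in% flt$kept$source_id &
                          gen_emb$label == cl, ]
      fids[[cl]] <- list(
        unfiltered = if (nrow(g_all) >= 2) fid_score(r, g_all, backbone) else NA,
        filtered = if (nrow(g_kept) >= 2) fid_score(r, g_kept, backbone) else NA)
    }
    reports <- lapply(flt$results, function(fr) glance(fr))
    bundle$filter <- list(kept = flt$kept, results = flt$results,
                          backbone = backbone, fids = fids, seed = sd)
    bundle$summary$filter <- list(seed = sd, fid = fids,
                                  kept = nrow(flt$kept), total = nrow(gen),
                                  per_class = reports)
  }

  if ("train" %in% stages) {
    require_stage(bundle, "augment", "train")
    sd <- stage_seed(config$seed, "train")
    say("train stage (seed %d)", sd)
    cc <- config$classifier
    cc$seed <- sd
    cc$input_size <- config$phantom$image_size
    train_set <- bundle$augment$balanced
    if (!is.null(bundle$filter) && nrow(bundle$filter$kept) > 0) {
      extra <- resize_dataset(bundle$filter$kept, cc$input_size)
      train_set <- dplyr::bind_rows(train_set, extra)
    }
    model <- train_classifier(train_set, bundle$phantom$test, cc,
                              verbose = verbose)
    eval <- evaluate_classifier(model, bundle$phantom$test)
    bundle$train <- list(model = model, eval = eval, seed = sd)
    bundle$summary$train <- c(list(seed = sd), as.list(glance(eval)))
  }

  if ("explain" %in% stages) {
    require_stage(bundle, "train", "explain")
    sd <- stage_seed(config$seed, "explain")
    say("explain stage (seed %d)", sd)
    test <- bundle$phantom$test
    scars <- test[test$label == "scar", ]
    hm <- grad_cam(bundle$train$model, scars, target_class = "scar")
    st <- heatmap_stats(hm, scars, threshold = config$roi_threshold)
    bundle$explain <- list(heatmaps = st, seed = sd)
    bundle$summary$explain <- list(
      seed = sd, n = nrow(st),
      mean_roi_fraction = mean(st$roi_fraction),
      mean_overlap = mean(st$overlap, na.rm = TRUE))
  }

  jsonlite::write_json(bundle$summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  bundle
}
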