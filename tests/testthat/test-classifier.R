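test_that("model construction is seeded and attention adds parameters", {
  cfg <- classifier_config(seed = 5)
  m1 <- build_classifier(cfg)
  m2 <- build_classifier(cfg)
  expect_identical(m1$net, m2$net)

  p_none <- scaraug:::n_params(build_classifier(
    classifier_config(attention = "none", seed = 5))$net)
  p_ca <- scaraug:::n_params(build_classifier(
    classifier_config(attention = "CA", seed = 5))$net)
  p_ma <- scaraug:::n_params(build_classifier(
    classifier_config(attention = "MA", seed = 5))$net)
  expect_gt(p_ca, p_none)
  expect_gt(p_ma, p_ca)
})

test_that("forward pass yields two logits per image at any attention setting", {
  d <- head(tiny_data(), 5)
  x <- scaraug:::stack_images(d$pixels)
  for (att in c("none", "CA", "SA", "MA")) {
    m <- build_classifier(classifier_config(attention = att, seed = 2))
    logits <- scaraug:::model_logits(m, x)
    expect_equal(dim(logits), c(2L, 5L))
    expect_true(all(is.finite(logits)))
  }
})

test_that("zero-epoch training returns an untrained model at chance level", {
  d <- tiny_data()
  cfg <- classifier_config(epochs = 0, seed = 3)
  m <- train_classifier(d, d, cfg)
  expect_equal(nrow(m$curve), 0)
  pr <- predict(m, d)
  expect_gt(mean(pr$.pred_class == d$label), 0.25)
  expect_lt(mean(pr$.pred_class == d$label), 0.75)
  expect_error(train_classifier(d[d$label == "scar", ], d, cfg), "both classes")
  expect_error(train_classifier(d[0, ], d, cfg), "empty")
})

test_that("a short training run learns the phantom task and logs its curve", {
  d <- tiny_data()
  sp <- split_dataset(d, 6, seed = 1)
  cfg <- classifier_config(epochs = 6, batch_size = 16, seed = 7)
  m <- train_classifier(sp$train, sp$test, cfg)
  cv <- tidy(m)
  expect_equal(nrow(cv), 6)
  expect_true(all(cv$train_accuracy >= 0 & cv$train_accuracy <= 1))
  expect_gt(cv$train_accuracy[6], cv$train_accuracy[1])
  g <- glance(m)
  expect_equal(g$attention, "CA")
  # determinism of the full training loop
  m2 <- train_classifier(sp$train, sp$test, cfg)
  expect_identical(m$curve, m2$curve)
  .fixtures$trained_small <- m
  .fixtures$split_small <- sp
})

test_that("evaluation: confusion counts, accuracy and trapezoid AUC", {
  m <- .fixtures$trained_small
  sp <- .fixtures$split_small
  ev <- evaluate_classifier(m, sp$test)
  expect_equal(sum(ev$confusion), nrow(sp$test))
  expect_equal(ev$accuracy, sum(diag(ev$confusion)) / sum(ev$confusion))
  expect_gte(ev$auc, 0)
  expect_lte(ev$auc, 1)
  expect_equal(glance(ev)$n, 12)
})

test_that("ROC/AUC agree with hand enumeration and the pROC oracle", {
  roc <- scaraug:::roc_points
  auc <- function(s, p) scaraug:::trapezoid_auc(roc(s, p)$fpr, roc(s, p)$tpr)
  # hand-built 4-image case: scars ranked strictly above controls
  s <- c(0.9, 0.8, 0.4, 0.6); pos <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(auc(s, pos), 1)
  # at the 0.5 threshold the 0.6-scoring control is a false positive: 3/4
  expect_equal(mean((s >= 0.5) == pos), 0.75)
  # constant scores: chance-level ranking
  expect_equal(auc(rep(0.3, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  # random scores against pROC (fixed direction: higher score = positive)
  set.seed(9)
  sc <- runif(40); lab <- runif(40) > 0.4
  expect_equal(auc(sc, lab),
               as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                              direction = "<",
                                              levels = c(FALSE, TRUE)))),
               tolerance = 1e-10)
})

test_that("weights survive a save/load round trip", {
  m <- .fixtures$trained_small
  path <- withr::local_tempfile(fileext = ".rds")
  save_classifier(m, path)
  m2 <- load_classifier(path)
  d <- head(tiny_data(), 4)
  expect_equal(predict(m, d)$.pred_scar, predict(m2, d)$.pred_scar)
  # pretrained init via config
  cfg <- m$config
  cfg$init <- "pretrained"
  expect_error(classifier_config(init = "pretrained"), "weights_file")
})

test_that("invalid configurations are rejected", {
  expect_error(classifier_config(input_size = 48), "power of 2")
  expect_error(classifier_config(attention = "CBAM"), "none/CA/SA/MA")
  expect_error(classifier_config(sa_kernel = 4), "odd")
  expect_error(classifier_config(optimizer = "lbfgs"), "adam/sgd")
})
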