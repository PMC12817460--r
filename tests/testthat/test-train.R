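test_that("stratified folds are balanced, disjoint and exhaustive", {
  lab <- rep(c("a", "b"), each = 50)
  sp <- stratified_kfold_split(lab, k = 5, seed = 3)
  for (f in sp$folds)
    expect_equal(as.integer(table(lab[f])), c(10L, 10L))
  expect_equal(sort(unlist(sp$folds)), 1:100)
  expect_equal(sum(vapply(sp$folds, length, integer(1))), 100L)

  set.seed(77)
  for (rep in 1:5) {
    lab <- sample(letters[1:6], 200, TRUE, prob = runif(6))
    sp <- suppressWarnings(stratified_kfold_split(lab, k = 5))
    for (cl in unique(lab)) {
      cnt <- vapply(sp$folds, function(f) sum(lab[f] == cl), integer(1))
      expect_lte(max(abs(cnt - sum(lab == cl) / 5)), 1)
    }
  }
})

test_that("classes smaller than k are assigned round-robin with a warning", {
  lab <- c(rep("big", 20), "rare", "rare")
  expect_warning(sp <- stratified_kfold_split(lab, k = 5, seed = 1),
                 "round-robin")
  expect_equal(sum(vapply(sp$folds, function(f) sum(lab[f] == "rare"),
                          integer(1))), 2L)
})

test_that("a held-out test fraction is stratified and disjoint from the folds", {
  lab <- rep(c("a", "b"), each = 50)
  sp <- stratified_kfold_split(lab, k = 5, seed = 2, test_fraction = 0.2)
  expect_equal(length(sp$test_ids), 20L)
  expect_equal(as.integer(table(lab[sp$test_ids])), c(10L, 10L))
  expect_length(intersect(unlist(sp$folds), sp$test_ids), 0L)
})

classes5 <- c(85562004, 51185008, 89546000, 818983003, 72696002)

test_that("the reference CNN recovers separable phantom classes", {
  data <- make_phantom_dataset(500, classes5, seed = 13)
  cfg <- training_config(task = "examined", loss = "cross_entropy",
                         max_epochs = 15, patience = 8, seed = 21)
  fit <- train_classifier(data, cfg)
  expect_gte(fit$val_accuracy, 0.9)
  expect_equal(fit$history$val_loss[fit$best_epoch],
               min(fit$history$val_loss))
})

test_that("training stops after `patience` epochs without improvement", {
  data <- make_phantom_dataset(60, classes5[1:3], seed = 5)
  cfg <- training_config(max_epochs = 50, patience = 8, lr = 0, seed = 2)
  fit <- train_classifier(data, cfg)
  expect_equal(nrow(fit$history), 1L + 8L)
  expect_equal(fit$best_epoch, 1L)
})

test_that("training is deterministic in the seed", {
  data <- make_phantom_dataset(60, classes5[1:3], seed = 6)
  cfg <- training_config(max_epochs = 2, patience = 1, seed = 31)
  f1 <- train_classifier(data, cfg)
  f2 <- train_classifier(data, cfg)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$history, f2$history)
})

test_that("multi-label training predicts visible label sets", {
  set.seed(41)
  n <- 120
  y <- sample(classes5[1:3], n, TRUE)
  x <- lapply(seq_len(n), function(i)
    generate_phantom(phantom_spec(y[i]), seed = 400 + i))
  yv <- lapply(y, function(cl) cl)  # visible = examined here
  cfg <- training_config(task = "visible", loss = "cross_entropy",
                         max_epochs = 25, patience = 10, seed = 3)
  fit <- train_classifier(list(x = x, y = yv), cfg)
  pred <- predict(fit, x[1:10], type = "class")
  expect_true(is.list(pred))
  expect_gte(fit$val_accuracy, 0.5)
})

test_that("grid search returns the dominant configuration and a full table", {
  data <- make_phantom_dataset(100, classes5[1:4], seed = 8)
  good <- training_config(max_epochs = 6, patience = 5, image_size = 16,
                          seed = 9)
  destroy <- augmentation_config(p_dihedral = 0, p_rotate = 0, p_zoom = 1,
                                 zoom_range = c(0.02, 0.03), warp = 0,
                                 p_light = 0, crop_scale = c(1, 1))
  bad <- training_config(max_epochs = 6, patience = 5, image_size = 16,
                         augment = destroy, invert_p = 0, seed = 9)
  gs <- suppressWarnings(grid_search_cv(data, list(bad, good), k = 5, seed = 4))
  expect_equal(gs$best_index, 2L)
  expect_equal(nrow(gs$table), 10L)  # |grid| x k rows
  expect_named(gs$summary, c("config", "mean_accuracy"))

  single <- suppressWarnings(grid_search_cv(data, list(good), k = 2, seed = 4))
  expect_identical(single$best_config, good)
})

test_that("hierarchical-loss training never has level-1 accuracy below leaf accuracy", {
  hier <- load_hierarchy()
  data <- make_phantom_dataset(200, classes5, seed = 17)
  cfg <- training_config(loss = "hierarchical", max_epochs = 8, patience = 6,
                         seed = 19)
  fit <- train_classifier(data, cfg)
  pred <- predict(fit, data$x, type = "class")
  lvl1 <- function(code) expand_to_levels(code, hier)[["level1"]]
  leaf_acc <- mean(pred == data$y)
  l1_acc <- mean(vapply(pred, lvl1, "") == vapply(data$y, lvl1, ""))
  expect_gte(l1_acc, leaf_acc)
})
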