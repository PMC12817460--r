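test_that("metrics are exact on degenerate and hand-tallied cases", {
  y <- c("A", "B", "A", "B")
  m_perfect <- compute_metrics(y, y)
  expect_equal(m_perfect$accuracy, 1)
  expect_equal(m_perfect$precision, 1)
  expect_equal(m_perfect$recall, 1)
  expect_equal(m_perfect$f1, 1)

  m_wrong <- compute_metrics(y, c("B", "A", "B", "A"))
  expect_equal(m_wrong$accuracy, 0)

  # one FP and one FN on class A: P(A) = 2/3, R(A) = 2/3
  yt <- c("A", "A", "A", "B")
  yp <- c("A", "A", "B", "A")
  m <- compute_metrics(yt, yp)
  a <- m$per_class[m$per_class$class == "A", ]
  expect_equal(a$precision, 2 / 3)
  expect_equal(a$recall, 2 / 3)
  expect_equal(a$support, 3)
  expect_error(compute_metrics(character(0), character(0)), "empty")
})

test_that("per-class support sums to the total label count", {
  yt <- list(c("A", "B"), "B", c("A", "C"))
  yp <- list("A", c("B", "C"), c("A", "C"))
  m <- compute_metrics(yt, yp)
  expect_equal(sum(m$per_class$support), 5)
  expect_true(all(vapply(m[c("accuracy", "precision", "recall", "f1")],
                         function(v) v >= 0 && v <= 1, logical(1))))
})

test_that("confusion counts match a brute-force tally and conserve totals", {
  set.seed(12)
  classes <- LETTERS[1:4]
  yt <- lapply(1:50, function(i) sample(classes, sample(1:3, 1)))
  yp <- lapply(1:50, function(i) sample(classes, sample(1:3, 1)))
  cm <- confusion_counts(yt, yp)
  for (cl in classes) {
    tp <- sum(mapply(function(a, b) cl %in% a && cl %in% b, yt, yp))
    fp <- sum(mapply(function(a, b) !(cl %in% a) && cl %in% b, yt, yp))
    fn <- sum(mapply(function(a, b) cl %in% a && !(cl %in% b), yt, yp))
    row <- cm[cm$class == cl, ]
    expect_equal(row$tp, tp)
    expect_equal(row$fp, fp)
    expect_equal(row$fn, fn)
    expect_equal(row$tp + row$fp + row$tn + row$fn, 50)
  }
})

test_that("metrics agree with the confusion-count formulas", {
  set.seed(13)
  yt <- sample(LETTERS[1:3], 60, TRUE)
  yp <- sample(LETTERS[1:3], 60, TRUE)
  m <- compute_metrics(yt, yp)
  cm <- m$confusion
  expect_equal(m$per_class$precision,
               ifelse(cm$tp + cm$fp > 0, cm$tp / (cm$tp + cm$fp), 0))
  expect_equal(m$per_class$recall,
               ifelse(cm$tp + cm$fn > 0, cm$tp / (cm$tp + cm$fn), 0))
  cross <- attr(cm, "cross")
  expect_equal(sum(diag(cross)), sum(cm$tp))
})

test_that("t-SNE is shape-correct, seed-deterministic and separates clusters", {
  set.seed(14)
  X <- rbind(matrix(rnorm(40 * 5), 40, 5),
             matrix(rnorm(40 * 5, mean = 12), 40, 5))
  lab <- rep(1:2, each = 40)
  Y1 <- tsne_projection(X, seed = 5)
  expect_equal(dim(Y1), c(80L, 2L))
  expect_identical(Y1, tsne_projection(X, seed = 5))
  sil <- cluster::silhouette(lab, dist(Y1))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
  expect_error(tsne_projection(X[1:2, ]), "at least 3")

  f <- tempfile(fileext = ".csv")
  tsne_projection(X[1:10, ], seed = 1, file = f, labels = lab[1:10])
  expect_equal(nrow(read.csv(f)), 10L)
})

test_that("class activation maps are the weighted feature maps, normalized", {
  data <- make_phantom_dataset(40, c(85562004, 51185008), seed = 23)
  cfg <- training_config(max_epochs = 2, patience = 1, seed = 7)
  fit <- suppressWarnings(train_classifier(data, cfg))
  img <- data$x[[1]]
  cam <- class_activation_map(fit, img, 85562004)
  expect_equal(dim(cam), dim(img))
  expect_gte(min(cam), 0); expect_lte(max(cam), 1)

  # zero classifier weights give the uniform zero map
  fit0 <- fit
  fit0$weights$Wfc[] <- 0
  expect_true(all(class_activation_map(fit0, img, 85562004) == 0))

  # weighted-sum contract on the raw maps (weights 2 and -1)
  f <- predict(fit, list(img), type = "feat")
  d <- attr(f, "feat_dim")
  maps <- array(f[1, ], dim = d)
  fit2 <- fit
  fit2$weights$Wfc[] <- 0
  fit2$weights$Wfc[1, 1] <- 2
  fit2$weights$Wfc[2, 1] <- -1
  raw <- 2 * maps[, , 1] - maps[, , 2]
  raw_up <- resize_image(raw, dim(img))
  expected <- (raw_up - min(raw_up)) / (max(raw_up) - min(raw_up))
  got <- class_activation_map(fit2, img, fit$classes[1])
  expect_equal(got, expected, tolerance = 1e-12)
  expect_error(class_activation_map(list(), img, 1), "unsupported")
})
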