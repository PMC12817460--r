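#' Training configuration
#'
#' Mirrors the experiment protocol: at most 50 epochs with early stopping
#' at patience 8, batch size 64, shuffling, and stratified 5-fold grid
#' search for tuning. Two tasks are supported: \code{"examined"}
#' (single-label, softmax) and \code{"visible"} (multi-label, per-class
#' sigmoid with a 0.5 decision threshold).
#'
#' @param task \code{"examined"} or \code{"visible"}.
#' @param loss \code{"cross_entropy"} or \code{"hierarchical"}.
#' @param weights [loss_weights()] for the hierarchical loss.
#' @param max_epochs,patience early-stopping protocol; \code{patience}
#'   must be smaller than \code{max_epochs}.
#' @param batch minibatch size.
#' @param shuffle shuffle training order each epoch.
#' @param lr Adam learning rate (the grid-search default grid is
#'   \code{c(1e-3, 1e-4)}).
#' @param image_size square input size fed to the backbone (pixels).
#' @param augment optional [augmentation_config()] applied to training
#'   batches (\code{NULL} = none).
#' @param invert_p training-time random inversion probability (only used
#'   when \code{augment} is given).
#' @param seed integer seed; the whole training run is deterministic in it.
#' @return object of class \code{training_config}.
#' @export
training_config <- function(task = c("examined", "visible"),
                            loss = c("cross_entropy", "hierarchical"),
                            weights = loss_weights(),
                            max_epochs = 50L, patience = 8L, batch = 64L,
                            shuffle = TRUE, lr = 1e-3, image_size = 32L,
                            augment = NULL, invert_p = 0.5, seed = 1L) {
  task <- match.arg(task); loss <- match.arg(loss)
  if (patience >= max_epochs) stop("patience must be smaller than max_epochs")
  structure(list(task = task, loss = loss, weights = weights,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), batch = as.integer(batch),
                 shuffle = shuffle, lr = lr,
                 image_size = as.integer(image_size), augment = augment,
                 invert_p = invert_p, seed = as.integer(seed)),
            class = "training_config")
}

#' Stratified k-fold split with an optional held-out test set
#'
#' Shuffles within each class (seeded) and deals the members of every
#' class cyclically across the k folds, so each per-class fold count is
#' within 1 of \code{n_class / k}. Classes with fewer than k members are
#' assigned round-robin with a warning.
#'
#' @param labels class label per sample (stratification key).
#' @param k number of folds.
#' @param seed integer seed.
#' @param test_fraction fraction per class held out before folding
#'   (default 0).
#' @return object of class \code{fold_assignment}: list with
#'   \code{fold_of} (integer per sample, \code{NA} for test samples),
#'   \code{folds} (list of index vectors) and \code{test_ids}.
#' @export
stratified_kfold_split <- function(labels, k = 5L, seed = NULL,
                                   test_fraction = 0) {
  if (!is.null(seed)) set.seed(seed)
  labels <- as.vector(labels)
  n <- length(labels)
  fold_of <- rep(NA_integer_, n)
  test_ids <- integer(0)
  small <- character(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    if (test_fraction > 0) {
      nt <- round(test_fraction * length(idx))
      if (nt > 0) {
        test_ids <- c(test_ids, idx[seq_len(nt)])
        idx <- idx[-seq_len(nt)]
      }
    }
    if (length(idx) < k) small <- c(small, as.character(cl))
    if (length(idx))
      fold_of[idx] <- ((sample.int(k, 1L) + seq_along(idx) - 2L) %% k) + 1L
  }
  if (length(small))
    warning("classes with fewer than ", k,
            " members assigned round-robin: ", paste(small, collapse = ", "))
  folds <- lapply(seq_len(k), function(j) which(fold_of == j))
  structure(list(fold_of = fold_of, folds = folds, test_ids = sort(test_ids)),
            class = "fold_assignment")
}

#' Reduce the hierarchy to a subset of leaf classes
#'
#' Keeps only the paths of the given classes, in the given order — the
#' leaf order a model trained on those classes uses for its probability
#' columns.
#'
#' @param hier a \code{body_hierarchy}.
#' @param codes SNOMED leaf codes to keep.
#' @return a \code{body_hierarchy} over those leaves.
#' @export
subset_hierarchy <- function(hier, codes) {
  i <- match(codes, hier$paths$leaf_code)
  if (anyNA(i)) stop("class not in hierarchy: ", codes[is.na(i)][1])
  p <- hier$paths[i, , drop = FALSE]
  rownames(p) <- NULL
  structure(list(paths = p,
                 level_labels = list(level1 = unique(p$level1),
                                     level2 = unique(p$level2),
                                     level3 = unique(p$level3))),
            class = "body_hierarchy")
}

.init_weights <- function(channels = c(8L, 16L, 32L, 32L), n_classes) {
  cin <- c(1L, channels[-4])
  w <- list()
  for (l in 1:4) {
    fan <- 9L * cin[l]
    w[[paste0("W", l)]] <- matrix(rnorm(fan * channels[l], sd = sqrt(2 / fan)),
                                  fan, channels[l])
    w[[paste0("b", l)]] <- rep(0, channels[l])
  }
  w$Wfc <- matrix(rnorm(channels[4] * n_classes, sd = sqrt(2 / channels[4])),
                  channels[4], n_classes)
  w$bfc <- rep(0, n_classes)
  w
}

.adam_init <- function(w) list(m = lapply(w, function(p) p * 0),
                               v = lapply(w, function(p) p * 0), t = 0L)

.adam_step <- function(w, g, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(w)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mh <- st$m[[nm]] / (1 - beta1^st$t)
    vh <- st$v[[nm]] / (1 - beta2^st$t)
    w[[nm]] <- w[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(w = w, st = st)
}

# Flatten a list of image matrices into the n x (s*s) model input matrix.
.images_to_matrix <- function(imgs, size) {
  t(vapply(imgs, function(px) as.vector(resize_image(px, size)),
           numeric(size * size)))
}

.encode_targets <- function(y, classes, task) {
  K <- length(classes)
  Y <- matrix(0, length(y), K)
  if (task == "examined") {
    i <- match(unlist(y), classes)
    if (anyNA(i)) stop("label outside the model's class list")
    Y[cbind(seq_along(y), i)] <- 1
  } else {
    for (r in seq_along(y)) {
      i <- match(y[[r]], classes)
      if (anyNA(i)) stop("label outside the model's class list")
      Y[r, i] <- 1
    }
  }
  Y
}

.softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

.loss_and_grad <- function(logits, Y, cfg, hier_red) {
  n <- nrow(logits)
  if (cfg$task == "examined") p <- .softmax(logits)
  else p <- 1 / (1 + exp(-logits))
  if (cfg$loss == "cross_entropy") {
    if (cfg$task == "examined") {
      loss <- -mean(log(pmax(rowSums(p * Y), 1e-12)))
      dlog <- (p - Y) / n
    } else {
      pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      loss <- -mean(rowSums(Y * log(pc) + (1 - Y) * log(1 - pc)))
      dlog <- (p - Y) / n
    }
  } else {
    loss <- hierarchical_loss(Y, p, hier_red, cfg$weights)
    g <- hierarchical_loss_grad(Y, p, hier_red, cfg$weights)
    if (cfg$task == "examined") {
      dlog <- p * (g - rowSums(g * p))
    } else {
      dlog <- g * p * (1 - p)
    }
  }
  list(loss = loss, dlogits = dlog, p = p)
}

.augment_rows <- function(xmat, size, cfg) {
  imgs <- lapply(seq_len(nrow(xmat)), function(i)
    matrix(xmat[i, ], size, size))
  imgs <- random_batch_transform(imgs, cfg$augment)
  imgs <- random_invert(imgs, p = cfg$invert_p, max_val = 1)
  t(vapply(imgs, as.vector, numeric(size * size)))
}

#' Train the reference CNN classifier
#'
#' Optimizes the configured loss (plain cross-entropy or the three-level
#' hierarchical loss) with Adam on the bundled 4-block convolutional
#' backbone with global average pooling. Training stops when the
#' validation loss has not improved for \code{patience} consecutive
#' epochs, or at \code{max_epochs}; the returned parameters are those of
#' the best validation epoch. The run is deterministic in
#' \code{cfg$seed}.
#'
#' @param data list with \code{x} (list of image matrices) and \code{y}
#'   (for the examined task a vector of SNOMED codes; for the visible
#'   task a list of code vectors per image).
#' @param cfg a [training_config()].
#' @param hier a \code{body_hierarchy} (required for the hierarchical
#'   loss; defaults to the packaged one).
#' @param classes class codes defining the output order; defaults to the
#'   sorted distinct labels of \code{data$y}.
#' @param val_idx optional explicit validation index vector; by default a
#'   stratified fifth of the data is held out for early stopping.
#' @return object of class \code{xr_cnn} with elements \code{weights},
#'   \code{classes}, \code{history} (per-epoch losses/accuracy),
#'   \code{best_epoch}, \code{config}.
#' @export
train_classifier <- function(data, cfg = training_config(), hier = NULL,
                             classes = NULL, val_idx = NULL) {
  stopifnot(inherits(cfg, "training_config"))
  if (length(data$x) == 0L) stop("empty training data")
  set.seed(cfg$seed)
  if (is.null(hier)) hier <- load_hierarchy()
  strat <- if (cfg$task == "examined") unlist(data$y)
           else vapply(data$y, function(v) v[1], numeric(1))
  if (is.null(classes)) classes <- sort(unique(if (cfg$task == "examined")
    unlist(data$y) else unlist(data$y)))
  hier_red <- subset_hierarchy(hier, classes)
  size <- cfg$image_size
  X <- .images_to_matrix(data$x, size)
  X <- X / max(X, 1)
  Y <- .encode_targets(data$y, classes, cfg$task)
  if (is.null(val_idx)) {
    sp <- stratified_kfold_split(strat, k = 5L)
    val_idx <- sp$folds[[1L]]
  }
  tr_idx <- setdiff(seq_len(nrow(X)), val_idx)

  w <- .init_weights(n_classes = length(classes))
  ad <- .adam_init(w)
  best <- list(loss = Inf, epoch = 0L, w = w)
  hist <- list()
  stall <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- if (cfg$shuffle) tr_idx[sample.int(length(tr_idx))] else tr_idx
    nb <- ceiling(length(ord) / cfg$batch)
    tr_loss <- 0
    for (b in seq_len(nb)) {
      take <- ord[((b - 1L) * cfg$batch + 1L):min(b * cfg$batch, length(ord))]
      xb <- X[take, , drop = FALSE]
      if (!is.null(cfg$augment)) xb <- .augment_rows(xb, size, cfg)
      yb <- Y[take, , drop = FALSE]
      step_loss <- NA_real_
      res <- .cnn_step(w, xb, size, size, function(logits) {
        lg <- .loss_and_grad(logits, yb, cfg, hier_red)
        step_loss <<- lg$loss
        lg$dlogits
      })
      tr_loss <- tr_loss + step_loss * length(take)
      up <- .adam_step(w, res$grads, ad, cfg$lr)
      w <- up$w; ad <- up$st
    }
    val <- .cnn_forward(w, X[val_idx, , drop = FALSE], size, size)
    lv <- .loss_and_grad(val$logits, Y[val_idx, , drop = FALSE], cfg, hier_red)
    acc <- .prediction_accuracy(lv$p, Y[val_idx, , drop = FALSE], cfg$task)
    hist[[epoch]] <- data.frame(epoch = epoch,
                                train_loss = tr_loss / length(tr_idx),
                                val_loss = lv$loss, val_accuracy = acc)
    if (lv$loss < best$loss - 1e-12) {
      best <- list(loss = lv$loss, epoch = epoch, w = w, acc = acc)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$patience) break
    }
  }
  structure(list(weights = best$w, classes = classes,
                 history = do.call(rbind, hist), best_epoch = best$epoch,
                 val_loss = best$loss, val_accuracy = best$acc,
                 config = cfg, hier = hier_red, image_size = size),
            class = "xr_cnn")
}

.prediction_accuracy <- function(p, Y, task) {
  if (task == "examined") {
    mean(max.col(p, ties.method = "first") == max.col(Y, ties.method = "first"))
  } else {
    mean(apply((p >= 0.5) == (Y == 1), 1, all))  # subset accuracy
  }
}

#' @export
print.xr_cnn <- function(x, ...) {
  cat("Reference CNN (", x$config$task, "task,", x$config$loss, "loss):",
      length(x$classes), "classes; best epoch", x$best_epoch,
      sprintf("(val loss %.4f, val accuracy %.3f)\n", x$val_loss,
              x$val_accuracy %||% NA))
  invisible(x)
}

#' Predict with a trained reference CNN
#'
#' @param object an \code{xr_cnn}.
#' @param x list of image matrices.
#' @param type \code{"prob"} (class probabilities), \code{"class"}
#'   (examined: argmax code; visible: list of codes above 0.5),
#'   \code{"embedding"} (global-average-pooled features) or
#'   \code{"feat"} (final convolutional maps, for CAM).
#' @param ... unused.
#' @return matrix, vector or list according to \code{type}.
#' @export
predict.xr_cnn <- function(object, x, type = c("prob", "class", "embedding", "feat"),
                           ...) {
  type <- match.arg(type)
  size <- object$image_size
  X <- .images_to_matrix(x, size)
  X <- X / max(X, 1)
  fw <- .cnn_forward(object$weights, X, size, size)
  p <- if (object$config$task == "examined") .softmax(fw$logits)
       else 1 / (1 + exp(-fw$logits))
  colnames(p) <- object$classes
  switch(type,
    prob = p,
    class = if (object$config$task == "examined")
      object$classes[max.col(p, ties.method = "first")]
    else lapply(seq_len(nrow(p)), function(i) object$classes[p[i, ] >= 0.5]),
    embedding = fw$gap,
    feat = structure(fw$feat, feat_dim = fw$feat_dim))
}

#' Grid search with stratified k-fold cross-validation
#'
#' For every configuration in the grid, trains on k-1 folds (one of the
#' training folds, rotating with the evaluation fold, is used for early
#' stopping) and evaluates accuracy on the held-out fold. Returns the
#' configuration with the best mean validation accuracy plus the full
#' per-fold metric table.
#'
#' @param data as in [train_classifier()].
#' @param grid list of [training_config()] objects.
#' @param k number of folds.
#' @param hier hierarchy passed through to training.
#' @param seed seed for the fold split.
#' @return list with \code{best_config}, \code{best_index},
#'   \code{table} (config x fold accuracy rows) and \code{summary}
#'   (mean accuracy per config).
#' @export
grid_search_cv <- function(data, grid, k = 5L, hier = NULL, seed = 1L) {
  if (!length(grid)) stop("empty configuration grid")
  if (is.null(hier)) hier <- load_hierarchy()
  strat <- if (grid[[1]]$task == "examined") unlist(data$y)
           else vapply(data$y, function(v) v[1], numeric(1))
  classes <- sort(unique(unlist(data$y)))
  sp <- stratified_kfold_split(strat, k = k, seed = seed)
  rows <- list()
  for (ci in seq_along(grid)) {
    cfg <- grid[[ci]]
    for (j in seq_len(k)) {
      val_j <- (j %% k) + 1L     # early-stopping fold, rotating
      eval_idx <- sp$folds[[j]]
      tr_idx <- setdiff(seq_along(strat), eval_idx)
      sub <- list(x = data$x[tr_idx], y = if (is.list(data$y))
        data$y[tr_idx] else data$y[tr_idx])
      val_local <- match(intersect(sp$folds[[val_j]], tr_idx), tr_idx)
      fit <- train_classifier(sub, cfg, hier = hier, classes = classes,
                              val_idx = val_local)
      p <- predict(fit, data$x[eval_idx], type = "prob")
      Yev <- .encode_targets(if (is.list(data$y)) data$y[eval_idx]
                             else data$y[eval_idx], classes, cfg$task)
      acc <- .prediction_accuracy(p, Yev, cfg$task)
      rows[[length(rows) + 1L]] <- data.frame(config = ci, fold = j,
                                              accuracy = acc)
    }
  }
  tab <- do.call(rbind, rows)
  mean_acc <- tapply(tab$accuracy, tab$config, mean)
  best <- as.integer(names(mean_acc)[which.max(mean_acc)])
  list(best_config = grid[[best]], best_index = best, table = tab,
       summary = data.frame(config = as.integer(names(mean_acc)),
                            mean_accuracy = as.numeric(mean_acc)))
}
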