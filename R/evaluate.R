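# Labels may arrive as single-label vectors or as multi-label lists/
# binary matrices; everything is reduced to a binary indicator matrix
# over the union of observed classes before counting.
.as_label_matrix <- function(y, classes) {
  if (is.matrix(y)) { colnames(y) <- classes; return((y != 0) * 1) }
  Y <- matrix(0, length(y), length(classes), dimnames = list(NULL, classes))
  if (is.list(y)) {
    for (i in seq_along(y)) Y[i, match(y[[i]], classes)] <- 1
  } else {
    Y[cbind(seq_along(y), match(y, classes))] <- 1
  }
  Y
}

.label_universe <- function(y_true, y_pred) {
  pull <- function(y) if (is.matrix(y)) colnames(y) else unlist(y)
  sort(unique(c(pull(y_true), pull(y_pred))))
}

#' Per-class confusion counts (multi-label confusion matrix)
#'
#' Tallies per class the true positives, false positives, true negatives
#' and false negatives over all samples; for single-label inputs a
#' cross-class confusion table (true x predicted) is attached as well.
#'
#' @param y_true,y_pred single-label vectors, multi-label lists of label
#'   vectors, or binary indicator matrices (same convention for both).
#' @return object of class \code{ml_confusion}: data.frame with columns
#'   \code{class, tp, fp, tn, fn}; attribute \code{"cross"} holds the
#'   cross-class table when inputs are single-label.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop("empty input")
  classes <- .label_universe(y_true, y_pred)
  Yt <- .as_label_matrix(y_true, classes)
  Yp <- .as_label_matrix(y_pred, classes)
  if (!identical(dim(Yt), dim(Yp))) stop("length mismatch between truth and prediction")
  out <- data.frame(
    class = classes,
    tp = colSums(Yt == 1 & Yp == 1),
    fp = colSums(Yt == 0 & Yp == 1),
    tn = colSums(Yt == 0 & Yp == 0),
    fn = colSums(Yt == 1 & Yp == 0),
    row.names = NULL
  )
  if (!is.list(y_true) && !is.matrix(y_true) && !is.list(y_pred)) {
    attr(out, "cross") <- table(true = factor(y_true, classes),
                                predicted = factor(y_pred, classes))
  }
  class(out) <- c("ml_confusion", "data.frame")
  out
}

#' Classification metrics report
#'
#' Accuracy plus macro-averaged precision, recall and F1, with a
#' per-class report (precision, recall, F1, support). Accuracy is plain
#' accuracy for single-label input and subset (exact-match) accuracy for
#' multi-label input; \code{accuracy = "hamming"} switches to per-label
#' Hamming accuracy. Macro averaging treats every class equally,
#' \code{average = "micro"} pools the counts instead.
#'
#' @param y_true,y_pred labels as in [confusion_counts()].
#' @param average \code{"macro"} (default) or \code{"micro"}.
#' @param accuracy \code{"subset"} (default) or \code{"hamming"}
#'   (multi-label only).
#' @return object of class \code{metrics_report}: list with
#'   \code{accuracy, precision, recall, f1} and \code{per_class}
#'   data.frame.
#' @export
compute_metrics <- function(y_true, y_pred, average = c("macro", "micro"),
                            accuracy = c("subset", "hamming")) {
  average <- match.arg(average); accuracy <- match.arg(accuracy)
  cm <- confusion_counts(y_true, y_pred)
  classes <- .label_universe(y_true, y_pred)
  Yt <- .as_label_matrix(y_true, classes)
  Yp <- .as_label_matrix(y_pred, classes)
  acc <- if (accuracy == "subset") mean(apply(Yt == Yp, 1, all))
         else mean(Yt == Yp)
  prec_c <- ifelse(cm$tp + cm$fp > 0, cm$tp / (cm$tp + cm$fp), 0)
  rec_c <- ifelse(cm$tp + cm$fn > 0, cm$tp / (cm$tp + cm$fn), 0)
  f1_c <- ifelse(prec_c + rec_c > 0, 2 * prec_c * rec_c / (prec_c + rec_c), 0)
  if (average == "macro") {
    prec <- mean(prec_c); rec <- mean(rec_c); f1 <- mean(f1_c)
  } else {
    prec <- sum(cm$tp) / max(sum(cm$tp) + sum(cm$fp), 1)
    rec <- sum(cm$tp) / max(sum(cm$tp) + sum(cm$fn), 1)
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }
  structure(list(
    accuracy = acc, precision = prec, recall = rec, f1 = f1,
    per_class = data.frame(class = cm$class, precision = prec_c,
                           recall = rec_c, f1 = f1_c,
                           support = cm$tp + cm$fn, row.names = NULL),
    confusion = cm
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.3f | precision %.3f | recall %.3f | F1 %.3f (%d classes)\n",
              x$accuracy, x$precision, x$recall, x$f1, nrow(x$per_class)))
  invisible(x)
}

#' t-SNE projection of a feature matrix
#'
#' Exact (dense) t-distributed stochastic neighbor embedding of the
#' learned feature space into two dimensions, used to inspect how well
#' the classifier separates label groups. Pairwise Gaussian affinities
#' are calibrated per point to the target perplexity by bisection; the
#' embedding is optimized by momentum gradient descent with early
#' exaggeration. Deterministic for a fixed seed; quadratic in the number
#' of samples, intended for corpus-scale (hundreds to a few thousand)
#' inspection.
#'
#' @param features numeric matrix, one row per sample.
#' @param perplexity target perplexity (default
#'   \code{min(30, (n - 1) / 3)}).
#' @param n_iter gradient-descent iterations.
#' @param seed integer seed for the random initialization.
#' @param file optional CSV path; when given, coordinates (and
#'   \code{labels}, if provided) are written alongside.
#' @param labels optional per-sample labels exported with the CSV.
#' @return n x 2 matrix of embedding coordinates.
#' @export
tsne_projection <- function(features, perplexity = NULL, n_iter = 400L,
                            seed = 1L, file = NULL, labels = NULL) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (n < 3L) stop("t-SNE needs at least 3 samples")
  if (is.null(perplexity)) perplexity <- min(30, (n - 1) / 3)
  set.seed(seed)
  D2 <- as.matrix(dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { H <- 0; p[] <- 1 / length(p) }
      else {
        p <- p / sp
        H <- -sum(ifelse(p > 0, p * log(p), 0))
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
  inc <- matrix(0, n, 2)
  momentum <- 0.5
  for (iter in seq_len(n_iter)) {
    ex <- if (iter <= 100) 4 else 1
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (ex * P - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    if (iter == 20) momentum <- 0.8
    inc <- momentum * inc - 200 * grad
    Y <- Y + inc
    Y <- scale(Y, center = TRUE, scale = FALSE)
  }
  colnames(Y) <- c("x", "y")
  if (!is.null(file)) {
    out <- data.frame(x = Y[, 1], y = Y[, 2])
    if (!is.null(labels)) out$label <- labels
    write.csv(out, file, row.names = FALSE)
  }
  Y
}

#' Class activation map
#'
#' Heatmap of the image regions most influential for one class: the
#' classifier-weighted sum of the final convolutional feature maps of the
#' global-average-pooling backbone, bilinearly upsampled to the image
#' size and min-max normalized to [0, 1].
#'
#' @param model a trained \code{xr_cnn}.
#' @param image numeric image matrix.
#' @param class_id SNOMED code of the class to explain (must be in
#'   \code{model$classes}).
#' @return matrix of the same dimensions as \code{image}, values in
#'   [0, 1].
#' @export
class_activation_map <- function(model, image, class_id) {
  if (!inherits(model, "xr_cnn"))
    stop("unsupported architecture: CAM needs the GAP-headed reference CNN")
  k <- match(class_id, model$classes)
  if (is.na(k)) stop("class not in model: ", class_id)
  f <- predict(model, list(image), type = "feat")
  d <- attr(f, "feat_dim")
  maps <- array(f[1, ], dim = d)
  wk <- model$weights$Wfc[, k]
  cam <- matrix(0, d[1], d[2])
  for (c in seq_len(d[3])) cam <- cam + wk[c] * maps[, , c]
  cam <- resize_image(cam, dim(image))
  rng <- range(cam)
  if (rng[1] == rng[2]) return(matrix(0, nrow(image), ncol(image)))
  (cam - rng[1]) / diff(rng)
}
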