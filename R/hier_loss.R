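#' Loss weights for the three hierarchy levels
#'
#' The hierarchical loss is a weighted sum of per-level binary
#' cross-entropies. The defaults (0.4, 0.3, 0.3) give slightly more weight
#' to errors at the broadest anatomical level while still penalizing fine
#' distinctions; they sum to 1 so that equal per-level losses pass through
#' unchanged.
#'
#' @param w1,w2,w3 nonnegative weights for levels 1-3.
#' @return object of class \code{loss_weights} (numeric length 3).
#' @export
loss_weights <- function(w1 = 0.4, w2 = 0.3, w3 = 0.3) {
  w <- c(w1, w2, w3)
  if (any(!is.finite(w)) || any(w < 0)) stop("loss weights must be nonnegative")
  structure(w, names = paste0("w", 1:3), class = "loss_weights")
}

#' Leaf-to-level membership matrix
#'
#' @param hier a \code{body_hierarchy}.
#' @param level 1, 2 or 3.
#' @return binary matrix of dimension (number of level labels) x (number of
#'   leaves), rows in \code{hier$level_labels} order, columns in
#'   \code{hier$paths$leaf_code} order.
#' @export
level_membership <- function(hier, level) {
  stopifnot(inherits(hier, "body_hierarchy"))
  if (!level %in% 1:3) stop("level must be 1, 2 or 3")
  labs <- hier$level_labels[[level]]
  path <- hier$paths[[paste0("level", level)]]
  M <- outer(labs, path, "==") * 1
  dimnames(M) <- list(labs, hier$paths$leaf_code)
  M
}

#' Project leaf predictions or targets onto a coarser hierarchy level
#'
#' Leaf-level class probabilities aggregate to a coarse label as the sum of
#' the member-leaf probabilities, clipped to [0, 1] (mass-preserving for
#' the disjoint groups of a tree). Binary target indicators aggregate by
#' logical OR of the member indicators.
#'
#' @param leaf_pred numeric vector (one observation) or matrix
#'   (observations x leaves) in \code{hier$paths$leaf_code} column order.
#' @param hier a \code{body_hierarchy}.
#' @param level 1, 2 or 3.
#' @param type \code{"prob"} (clipped sum) or \code{"target"} (OR).
#' @return vector/matrix over that level's labels.
#' @export
project_to_level <- function(leaf_pred, hier, level, type = c("prob", "target")) {
  type <- match.arg(type)
  M <- level_membership(hier, level)
  vec <- is.null(dim(leaf_pred))
  x <- if (vec) matrix(leaf_pred, nrow = 1) else as.matrix(leaf_pred)
  if (ncol(x) != ncol(M))
    stop("leaf prediction length ", ncol(x), " does not match hierarchy (",
         ncol(M), " leaves)")
  out <- x %*% t(M)
  out <- if (type == "prob") pmin(pmax(out, 0), 1) else (out > 0) * 1
  colnames(out) <- rownames(M)
  if (vec) out[1, ] else out
}

#' Per-level binary cross-entropy loss
#'
#' Computes \eqn{lloss_n = -\sum_{c=1}^{N} y_{o,c} \log p_{o,c}} over the
#' \eqn{N} labels of one hierarchy level, for targets \eqn{y \in \{0,1\}}
#' and predicted probabilities \eqn{p}. Probabilities are clamped to
#' \eqn{[\epsilon, 1-\epsilon]} before the logarithm.
#'
#' @param y binary target vector (or matrix, observations in rows).
#' @param p probability vector/matrix of the same shape.
#' @param level optional level index (1-3), recorded on the result.
#' @param eps clamp width, default \code{1e-7}.
#' @return for vector input a scalar of class \code{level_loss} with
#'   attribute \code{level}; for matrix input a per-observation vector.
#' @export
level_loss <- function(y, p, level = NA_integer_, eps = 1e-7) {
  if (length(y) != length(p))
    stop("target and prediction lengths differ (", length(y), " vs ",
         length(p), ")")
  pc <- pmin(pmax(p, eps), 1 - eps)
  if (is.null(dim(y))) {
    v <- -sum(y * log(pc))
    return(structure(v, level = level, class = "level_loss"))
  }
  -rowSums(y * log(pc))
}

#' @export
print.level_loss <- function(x, ...) {
  cat("level", attr(x, "level"), "cross-entropy loss:",
      format(unclass(x)), "\n")
  invisible(x)
}

#' Hierarchical classification loss J(theta)
#'
#' The total loss over the three-level body-region hierarchy:
#' \deqn{J = w_1 \cdot lloss_1 + w_2 \cdot lloss_2 + w_3 \cdot lloss_3}
#' where each \eqn{lloss_n} is the per-level binary cross-entropy of the
#' leaf targets/predictions projected onto level \eqn{n} (see
#' [project_to_level()]). Misclassifications confined to the correct broad
#' body region leave the coarser levels correct and are therefore
#' penalized less than errors that cross regions. For a batch (matrix
#' input) the loss is the arithmetic mean over observations; in multi-label
#' mode the inner sum simply runs over all positive labels.
#'
#' @param y_leaf binary leaf target vector or matrix (observations x leaves,
#'   columns in \code{hier$paths$leaf_code} order).
#' @param p_leaf leaf probability vector/matrix of the same shape.
#' @param hier a \code{body_hierarchy}.
#' @param weights a [loss_weights()] object.
#' @param eps probability clamp, default \code{1e-7}.
#' @return nonnegative scalar.
#' @export
hierarchical_loss <- function(y_leaf, p_leaf, hier,
                              weights = loss_weights(), eps = 1e-7) {
  if (!inherits(weights, "loss_weights")) weights <- do.call(loss_weights, as.list(weights))
  vec <- is.null(dim(y_leaf))
  y <- if (vec) matrix(y_leaf, nrow = 1) else as.matrix(y_leaf)
  p <- if (vec) matrix(p_leaf, nrow = 1) else as.matrix(p_leaf)
  if (!identical(dim(y), dim(p))) stop("target and prediction shapes differ")
  total <- numeric(nrow(y))
  for (lv in 1:3) {
    yl <- project_to_level(y, hier, lv, type = "target")
    pl <- project_to_level(p, hier, lv, type = "prob")
    total <- total + weights[lv] * level_loss(yl, pl, level = lv, eps = eps)
  }
  mean(total)
}

# Gradient of the batch-mean hierarchical loss w.r.t. leaf probabilities.
# dJ/dp_leaf = sum_n w_n * M_n' (-y_n / clamp(P_n)) / nobs, zero where the
# projected probability was clipped at 1 (the clip is active there).
hierarchical_loss_grad <- function(y_leaf, p_leaf, hier,
                                   weights = loss_weights(), eps = 1e-7) {
  y <- as.matrix(y_leaf); p <- as.matrix(p_leaf)
  g <- matrix(0, nrow(p), ncol(p))
  for (lv in 1:3) {
    M <- level_membership(hier, lv)
    raw <- p %*% t(M)
    Pl <- pmin(pmax(raw, eps), 1 - eps)
    Yl <- ((y %*% t(M)) > 0) * 1
    dP <- -Yl / Pl
    dP[raw >= 1 - eps] <- 0  # clamp active: saturated coarse probability
    dP[raw <= eps] <- 0
    g <- g + weights[lv] * (dP %*% M)
  }
  g / nrow(p)
}
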