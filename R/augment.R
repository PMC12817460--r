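#' Augmentation configuration
#'
#' Defaults reproduce the training-time augmentation protocol: a dihedral
#' transform with probability 0.5; with probability 0.75 each, a random
#' extra rotation of up to 10 degrees, a random zoom in [0.9, 1.1] with
#' perspective warping of magnitude 0.2, and a brightness/contrast change
#' of maximal scale 0.2; plus a random resize-crop with scale sampled in
#' [0.9, 1.0]; and polarity inversion with probability 0.5.
#'
#' @param p_dihedral,p_rotate,p_zoom,p_light,p_invert application
#'   probabilities.
#' @param max_extra_deg rotation bound in degrees.
#' @param zoom_range zoom scale interval.
#' @param warp maximal perspective corner displacement as a fraction of
#'   the image half-size.
#' @param light_scale maximal brightness/contrast change.
#' @param crop_scale resize-crop scale interval.
#' @param smote_k SMOTE neighbor count.
#' @return object of class \code{augmentation_config}.
#' @export
augmentation_config <- function(p_dihedral = 0.5,
                                p_rotate = 0.75, max_extra_deg = 10,
                                p_zoom = 0.75, zoom_range = c(0.9, 1.1),
                                warp = 0.2,
                                p_light = 0.75, light_scale = 0.2,
                                crop_scale = c(0.9, 1.0),
                                p_invert = 0.5,
                                smote_k = 5L) {
  p <- c(p_dihedral, p_rotate, p_zoom, p_light, p_invert)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  if (diff(zoom_range) < 0 || diff(crop_scale) < 0)
    stop("zoom_range and crop_scale must be ordered")
  structure(list(p_dihedral = p_dihedral, p_rotate = p_rotate,
                 max_extra_deg = max_extra_deg, p_zoom = p_zoom,
                 zoom_range = zoom_range, warp = warp, p_light = p_light,
                 light_scale = light_scale, crop_scale = crop_scale,
                 p_invert = p_invert, smote_k = as.integer(smote_k)),
            class = "augmentation_config")
}

# 3x3 homography mapping 4 source points to 4 destination points in
# normalized [-1, 1]^2 coordinates (direct linear transform, 8 unknowns).
.homography_from_points <- function(src, dst) {
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u; b[2 * i] <- v
  }
  h <- solve(A, b)
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

.dihedral_H <- function(k) {
  # k in 0..7: rotation by 90*(k %% 4) degrees, then horizontal flip if k >= 4
  th <- (k %% 4) * pi / 2
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  if (k >= 4) R <- diag(c(-1, 1, 1)) %*% R
  R
}

# Resample a square image under a forward homography H (normalized coords).
.apply_homography <- function(px, H) {
  n <- nrow(px); m <- ncol(px)
  Hi <- solve(H)
  xs <- if (m > 1) (seq_len(m) - (m + 1) / 2) / ((m - 1) / 2) else 0
  ys <- if (n > 1) (seq_len(n) - (n + 1) / 2) / ((n - 1) / 2) else 0
  g <- expand.grid(y = ys, x = xs)
  w <- Hi[3, 1] * g$x + Hi[3, 2] * g$y + Hi[3, 3]
  sx <- (Hi[1, 1] * g$x + Hi[1, 2] * g$y + Hi[1, 3]) / w
  sy <- (Hi[2, 1] * g$x + Hi[2, 2] * g$y + Hi[2, 3]) / w
  ri <- sy * ((n - 1) / 2) + (n + 1) / 2
  ci <- sx * ((m - 1) / 2) + (m + 1) / 2
  matrix(.bilinear_sample(px, ri, ci), n, m)
}

#' Random batch transformation
#'
#' Applies, independently per image: a dihedral transform (one of the 8
#' axis flips/quarter rotations) with probability \code{p_dihedral}; a
#' random rotation of up to \code{max_extra_deg} degrees with probability
#' \code{p_rotate}; a random zoom in \code{zoom_range} combined with a
#' perspective warp of corner magnitude \code{warp} with probability
#' \code{p_zoom}; a brightness/contrast change of maximal scale
#' \code{light_scale} with probability \code{p_light}; and always a random
#' resize-crop with scale in \code{crop_scale}, resized back to the input
#' size. Output shape equals input shape; the operation is reproducible
#' under a fixed seed.
#'
#' @param batch list of numeric matrices (square images).
#' @param cfg an [augmentation_config()].
#' @param seed optional integer seed.
#' @return list of transformed matrices; attribute \code{"applied"} is a
#'   data.frame of per-image application indicators.
#' @export
random_batch_transform <- function(batch, cfg = augmentation_config(),
                                   seed = NULL) {
  stopifnot(inherits(cfg, "augmentation_config"), is.list(batch))
  if (!is.null(seed)) set.seed(seed)
  applied <- data.frame(dihedral = logical(length(batch)),
                        rotate = FALSE, zoom = FALSE, light = FALSE)
  out <- vector("list", length(batch))
  for (i in seq_along(batch)) {
    px <- batch[[i]]
    H <- diag(3)
    do_dih <- runif(1) < cfg$p_dihedral
    if (do_dih) H <- .dihedral_H(sample.int(8L, 1L) - 1L) %*% H
    do_rot <- runif(1) < cfg$p_rotate
    if (do_rot) {
      th <- runif(1, -cfg$max_extra_deg, cfg$max_extra_deg) * pi / 180
      H <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                  3, 3, byrow = TRUE) %*% H
    }
    do_zoom <- runif(1) < cfg$p_zoom
    if (do_zoom) {
      s <- runif(1, cfg$zoom_range[1], cfg$zoom_range[2])
      H <- diag(c(s, s, 1)) %*% H
      if (cfg$warp > 0) {
        corners <- rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1))
        dst <- corners + matrix(runif(8, -cfg$warp, cfg$warp), 4, 2)
        H <- .homography_from_points(corners, dst) %*% H
      }
    }
    cs <- runif(1, cfg$crop_scale[1], cfg$crop_scale[2])
    if (cs < 1) {
      # crop window of relative size cs at a random position, zoomed back up
      off <- runif(2, -(1 - cs), 1 - cs)
      H <- .homography_from_points(
        rbind(c(off[1] - cs, off[2] - cs), c(off[1] + cs, off[2] - cs),
              c(off[1] + cs, off[2] + cs), c(off[1] - cs, off[2] + cs)),
        rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1))) %*% H
    }
    if (!identical(H, diag(3))) px <- .apply_homography(px, H)
    do_light <- runif(1) < cfg$p_light
    if (do_light) {
      bc <- runif(2, -cfg$light_scale, cfg$light_scale)
      m <- mean(px); amp <- max(abs(range(px) - m), 1)
      px <- (px - m) * (1 + bc[1]) + m + bc[2] * amp
    }
    applied[i, ] <- c(do_dih, do_rot, do_zoom, do_light)
    out[[i]] <- px
  }
  attr(out, "applied") <- applied
  out
}

#' Random polarity inversion of a batch
#'
#' Each image is independently inverted (\eqn{v \mapsto max - v}) with
#' probability \code{p}. The inversion ceiling defaults to 255 (the 8-bit
#' pipeline range) so that double application is the identity.
#'
#' @param batch list of numeric matrices.
#' @param p inversion probability.
#' @param seed optional integer seed.
#' @param max_val inversion ceiling.
#' @return list of matrices; attribute \code{"inverted"} logical vector.
#' @export
random_invert <- function(batch, p = 0.5, seed = NULL, max_val = 255) {
  stopifnot(is.list(batch), p >= 0, p <= 1)
  if (!is.null(seed)) set.seed(seed)
  flip <- runif(length(batch)) < p
  out <- lapply(seq_along(batch), function(i)
    if (flip[i]) max_val - batch[[i]] else batch[[i]])
  attr(out, "inverted") <- flip
  out
}

#' SMOTE oversampling to balance class counts
#'
#' Synthetic Minority Oversampling: for every class with fewer than
#' \code{target_count} samples, synthetic rows are interpolated between a
#' random original and one of its \code{k} nearest same-class neighbors,
#' \eqn{x_{new} = x + u (x_{nn} - x)} with \eqn{u \sim U(0,1)}, until the
#' class reaches \code{target_count}. Originals are retained unchanged; a
#' single-sample class falls back to duplication with a warning.
#'
#' @param x numeric matrix, one sample per row (e.g. flattened downsampled
#'   images, or learned embeddings).
#' @param labels class label per row.
#' @param k neighbor count (capped at class size - 1).
#' @param target_count per-class count after balancing; defaults to the
#'   largest class count.
#' @param seed optional integer seed.
#' @return list with \code{x} (augmented matrix), \code{labels}, and
#'   \code{synthetic} (logical row indicator).
#' @export
smote_tail_oversample <- function(x, labels, k = 5L, target_count = NULL,
                                  seed = NULL) {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  if (!is.null(seed)) set.seed(seed)
  labels <- as.vector(labels)
  cnt <- table(labels)
  if (is.null(target_count)) target_count <- max(cnt)
  new_x <- list(); new_lab <- list()
  for (cl in names(cnt)) {
    need <- target_count - cnt[[cl]]
    if (need <= 0) next
    idx <- which(labels == cl)
    Xc <- x[idx, , drop = FALSE]
    if (length(idx) == 1L) {
      warning("class ", cl, " has a single sample; duplicating instead of SMOTE")
      syn <- Xc[rep(1L, need), , drop = FALSE]
    } else {
      kk <- min(k, length(idx) - 1L)
      D <- as.matrix(dist(Xc))
      diag(D) <- Inf
      nn <- apply(D, 1L, function(d) order(d)[seq_len(kk)], simplify = FALSE)
      base <- sample.int(length(idx), need, replace = TRUE)
      syn <- matrix(0, need, ncol(x))
      for (j in seq_len(need)) {
        b <- base[j]
        nb <- nn[[b]][sample.int(kk, 1L)]
        u <- runif(1)
        syn[j, ] <- Xc[b, ] + u * (Xc[nb, ] - Xc[b, ])
      }
    }
    new_x[[cl]] <- syn
    new_lab[[cl]] <- rep(cl, need)
  }
  add <- if (length(new_x)) do.call(rbind, new_x) else x[0, , drop = FALSE]
  lab_out <- c(labels, unlist(new_lab, use.names = FALSE))
  if (is.numeric(labels)) lab_out <- as.numeric(lab_out)
  list(x = rbind(x, add),
       labels = lab_out,
       synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, nrow(add))))
}
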