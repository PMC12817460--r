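# Bilinear sampling at fractional (row, col) coordinates with edge clamping.
# Shared by resize and the geometric augmentation warps.
.bilinear_sample <- function(px, ri, ci) {
  nr <- nrow(px); nc <- ncol(px)
  ri <- pmin(pmax(ri, 1), nr); ci <- pmin(pmax(ci, 1), nc)
  r0 <- floor(ri); c0 <- floor(ci)
  r1 <- pmin(r0 + 1, nr); c1 <- pmin(c0 + 1, nc)
  fr <- ri - r0; fc <- ci - c0
  v00 <- px[cbind(r0, c0)]; v01 <- px[cbind(r0, c1)]
  v10 <- px[cbind(r1, c0)]; v11 <- px[cbind(r1, c1)]
  (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11)
}

#' Resize an image by bilinear interpolation
#'
#' @param pixels numeric matrix.
#' @param target_size scalar (square) or \code{c(rows, cols)}.
#' @return matrix of the requested dimensions.
#' @export
resize_image <- function(pixels, target_size) {
  stopifnot(is.matrix(pixels))
  ts <- as.integer(rep(target_size, length.out = 2))
  if (any(ts <= 0)) stop("target_size must be positive")
  if (all(ts == dim(pixels))) return(pixels)
  sr <- nrow(pixels) / ts[1]; sc <- ncol(pixels) / ts[2]
  ri <- (seq_len(ts[1]) - 0.5) * sr + 0.5
  ci <- (seq_len(ts[2]) - 0.5) * sc + 0.5
  grid <- expand.grid(r = ri, c = ci)
  matrix(.bilinear_sample(pixels, grid$r, grid$c), nrow = ts[1], ncol = ts[2])
}

#' Otsu's automatic threshold
#'
#' Chooses the threshold \eqn{T} maximizing the between-class variance
#' \deqn{var(T) = P_0(T) \cdot P_1(T) \cdot (m_0(T) - m_1(T))^2} over a
#' 256-bin histogram, where \eqn{P_0, P_1} are the background/foreground
#' probabilities (pixels below / at-or-above \eqn{T}) and \eqn{m_0, m_1}
#' their mean intensities. Inputs wider than 8 bits are mapped linearly
#' onto the 256-bin grid regardless of bit depth; ties resolve to the
#' smallest maximizing threshold. All reported quantities are on the
#' original intensity scale.
#'
#' @param pixels numeric matrix with at least 2 distinct values.
#' @return object of class \code{otsu_threshold}: list with \code{T},
#'   \code{var_between}, \code{p0}, \code{p1}, \code{m0}, \code{m1}.
#' @export
otsu_threshold <- function(pixels) {
  v <- as.vector(pixels)
  if (!all(is.finite(v))) stop("non-finite pixel values")
  rng <- range(v)
  if (rng[1] == rng[2])
    stop("degenerate input: constant image has no Otsu threshold")
  in_byte_grid <- rng[1] >= 0 && rng[2] <= 255 &&
    all(abs(v - round(v)) < 1e-9)
  if (in_byte_grid) {
    bins <- as.integer(round(v)); off <- 0; sc <- 1
  } else {
    sc <- (rng[2] - rng[1]) / 255; off <- rng[1]
    bins <- as.integer(round((v - rng[1]) / sc))
  }
  cnt <- tabulate(bins + 1L, nbins = 256L)
  w <- cnt / length(bins)
  lev <- 0:255
  cw <- cumsum(w)                 # P0 for T = t+1 (bins 0..t below T)
  cm <- cumsum(w * lev)
  mu <- cm[256]
  p0 <- cw[1:255]; p1 <- 1 - p0
  m0 <- ifelse(p0 > 0, cm[1:255] / p0, 0)
  m1 <- ifelse(p1 > 0, (mu - cm[1:255]) / p1, 0)
  var_b <- ifelse(p0 > 0 & p1 > 0, p0 * p1 * (m0 - m1)^2, 0)
  best <- which.max(var_b)        # which.max takes the first (lowest T) tie
  T_bin <- best                   # threshold = best (bins < T are class 0)
  structure(list(
    T = off + T_bin * sc,
    var_between = var_b[best] * sc^2,
    p0 = p0[best], p1 = p1[best],
    m0 = off + m0[best] * sc, m1 = off + m1[best] * sc
  ), class = "otsu_threshold")
}

#' @export
print.otsu_threshold <- function(x, ...) {
  cat(sprintf(
    "Otsu threshold T = %.4g (P0 = %.3f, P1 = %.3f, m0 = %.4g, m1 = %.4g, var = %.4g)\n",
    x$T, x$p0, x$p1, x$m0, x$m1, x$var_between))
  invisible(x)
}

#' Remove the image background below the Otsu threshold
#'
#' Pixels with intensity below the automatically determined threshold are
#' set to 0; foreground pixels (at or above the threshold) are returned
#' bit-identical to the input.
#'
#' @param pixels numeric matrix.
#' @return matrix of the same dimensions.
#' @export
remove_background <- function(pixels) {
  th <- otsu_threshold(pixels)
  out <- pixels
  out[pixels < th$T] <- 0
  out
}

#' Top-hat/bottom-hat contrast enhancement
#'
#' Adds the morphological top-hat (bright detail smaller than the
#' structuring element) and subtracts the bottom-hat (dark detail):
#' \code{out = clip(x + (x - opening(x)) - (closing(x) - x))} with a disc
#' structuring element. A flat image passes through unchanged.
#'
#' @param pixels numeric matrix.
#' @param radius disc radius in pixels (default 15, sized for 224x224
#'   inputs).
#' @param clip_range output clamp, default \code{c(0, 255)}.
#' @return enhanced matrix.
#' @export
top_bottom_hat <- function(pixels, radius = 15, clip_range = c(0, 255)) {
  stopifnot(is.matrix(pixels), radius >= 1)
  kern <- EBImage::makeBrush(2 * as.integer(radius) + 1L, shape = "disc")
  # rank filters commute with positive scaling; EBImage's grayscale
  # morphology expects intensities in [0, 1]
  s <- max(abs(pixels), 1)
  opened <- EBImage::opening(pixels / s, kern) * s
  closed <- EBImage::closing(pixels / s, kern) * s
  out <- pixels + (pixels - opened) - (closed - pixels)
  pmin(pmax(out, clip_range[1]), clip_range[2])
}

#' Cartoon-texture decomposition
#'
#' Splits an image into a piecewise-smooth cartoon component and an
#' oscillatory texture residual using the nonlinear low-pass/residual
#' scheme: a Gaussian low-pass \eqn{L_\sigma} is blended with the original
#' pixel-wise according to the local total-variation reduction rate
#' \eqn{\lambda = (LTV(x) - LTV(L_\sigma x)) / LTV(x)} — where blurring
#' strongly reduces local oscillation (texture), the cartoon takes the
#' smoothed value; at contours and in flat areas it keeps the original.
#' The decomposition is exactly additive: \code{cartoon + texture ==
#' input}.
#'
#' @param pixels numeric matrix.
#' @param scale Gaussian scale sigma in pixels (default 3).
#' @param ramp soft-threshold interval for the blending weight, default
#'   \code{c(0.25, 0.5)}.
#' @return list with \code{cartoon} and \code{texture} matrices.
#' @export
cartoon_texture <- function(pixels, scale = 3, ramp = c(0.25, 0.5)) {
  stopifnot(is.matrix(pixels), scale > 0)
  grad_mag <- function(m) {
    gx <- m; gy <- m
    gx[] <- 0; gy[] <- 0
    gx[2:(nrow(m) - 1), ] <- (m[3:nrow(m), ] - m[1:(nrow(m) - 2), ]) / 2
    gy[, 2:(ncol(m) - 1)] <- (m[, 3:ncol(m)] - m[, 1:(ncol(m) - 2)]) / 2
    sqrt(gx^2 + gy^2)
  }
  L <- EBImage::gblur(pixels, sigma = scale)
  ltv_x <- EBImage::gblur(grad_mag(pixels), sigma = scale)
  ltv_l <- EBImage::gblur(grad_mag(L), sigma = scale)
  lam <- ifelse(ltv_x > 1e-12, (ltv_x - ltv_l) / ltv_x, 0)
  w <- pmin(pmax((lam - ramp[1]) / (ramp[2] - ramp[1]), 0), 1)
  cartoon <- w * L + (1 - w) * pixels
  list(cartoon = cartoon, texture = pixels - cartoon)
}
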