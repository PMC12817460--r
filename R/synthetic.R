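# Synthetic radiograph phantoms: each body-part class draws a distinct
# geometric motif (long bones as bright capsules, rib-like arcs, an
# ellipse-with-orbits skull, vertebral stacks, ...), so classes are
# separable by construction and the whole pipeline can be exercised
# without clinical data. The motif-to-class map is injective: every class
# has its own (family, parameter) combination.

.MAX_INTENSITY <- 1023L  # 10-bit pixel range of the generated DICOMs

# drawing helpers on normalized [-1, 1]^2 coordinates -----------------------

.grid_xy <- function(size) {
  s <- seq(-1, 1, length.out = size)
  list(x = matrix(rep(s, each = size), size, size),
       y = matrix(rep(s, times = size), size, size))
}

.ell <- function(g, cx, cy, rx, ry, th = 0) {
  xr <- (g$x - cx) * cos(th) + (g$y - cy) * sin(th)
  yr <- -(g$x - cx) * sin(th) + (g$y - cy) * cos(th)
  (xr / rx)^2 + (yr / ry)^2 <= 1
}

.cap <- function(g, x1, y1, x2, y2, r) {
  vx <- x2 - x1; vy <- y2 - y1
  L2 <- vx^2 + vy^2
  t <- pmin(pmax(((g$x - x1) * vx + (g$y - y1) * vy) / L2, 0), 1)
  (g$x - (x1 + t * vx))^2 + (g$y - (y1 + t * vy))^2 <= r^2
}

.ring <- function(g, cx, cy, r, w) {
  d <- sqrt((g$x - cx)^2 + (g$y - cy)^2)
  abs(d - r) <= w
}

.stack <- function(g, n, w, y0 = -0.8, y1 = 0.8, x0 = 0) {
  m <- matrix(FALSE, nrow(g$x), ncol(g$x))
  ys <- seq(y0, y1, length.out = n + 1)
  gap <- (ys[2] - ys[1]) * 0.2
  for (i in seq_len(n))
    m <- m | (abs(g$x - x0) <= w & g$y >= ys[i] + gap & g$y <= ys[i + 1] - gap)
  m
}

.rays <- function(g, n, cx, cy, len, r, spread = pi / 3, base = -pi / 2) {
  m <- matrix(FALSE, nrow(g$x), ncol(g$x))
  ang <- base + seq(-spread, spread, length.out = n)
  for (a in ang)
    m <- m | .cap(g, cx, cy, cx + len * cos(a), cy + len * sin(a), r)
  m
}

.arcs <- function(g, n, w = 0.035, r = 0.85) {
  m <- matrix(FALSE, nrow(g$x), ncol(g$x))
  for (i in seq_len(n)) {
    cy <- -1.6 + 0.25 * i
    m <- m | (.ring(g, 0, cy, r, w) & g$y > cy + 0.3)
  }
  m
}

# one motif per class; f(g) returns a mask (or weighted mask) in [0, 1]
.MOTIFS <- list(
  "89546000" = function(g) .ell(g, 0, 0, .65, .8) & !.ell(g, -.25, -.2, .14, .1) & !.ell(g, .25, -.2, .14, .1),
  "45206002" = function(g) .cap(g, 0, -.5, 0, .3, .12) & !.ell(g, 0, -.4, .05, .18),
  "91609006" = function(g) .ring(g, 0, -.25, .6, .07) & g$y > 0,
  "818983003" = function(g) 0.45 * .ell(g, 0, 0, .85, .9) + 0.25 * .ring(g, -.25, .15, .22, .05) + 0.25 * .ring(g, .28, -.2, .18, .05),
  "76752008" = function(g) 0.8 * (.ell(g, -.55, 0, .75, .65) & g$x > -.55) + 0.2 * (.ell(g, -.55, 0, .95, .85) & g$x > -.55),
  "51185008" = function(g) 0.9 * .ell(g, 0, 0, .85, .95) - 0.55 * .ell(g, -.37, 0, .3, .6) - 0.55 * .ell(g, .37, 0, .3, .6),
  "51299004" = function(g) .cap(g, -.8, -.45, -.1, -.6, .06) | .cap(g, -.1, -.6, .8, -.5, .06),
  "113197003" = function(g) .arcs(g, 6),
  "56873002" = function(g) abs(g$x) < .1 & abs(g$y) < .65,
  "51282000" = function(g) .stack(g, 9, .14),
  "122494005" = function(g) .stack(g, 5, .1, y0 = -.85, y1 = .1),
  "122495006" = function(g) .stack(g, 7, .12, y0 = -.7, y1 = .7),
  "122496007" = function(g) .stack(g, 4, .2, y0 = -.1, y1 = .85),
  "264232007" = function(g) .stack(g, 6, .16, y0 = -.5, y1 = .8, x0 = .15),
  "120574008" = function(g) .cap(g, -.55, -.75, .45, .7, .13),
  "16982005" = function(g) .ell(g, -.35, -.35, .24, .24) | .cap(g, -.2, -.2, .55, .65, .12),
  "85856004" = function(g) .ell(g, -.3, -.3, .16, .16) | .ell(g, .12, -.32, .16, .16),
  "127949000" = function(g) .cap(g, -.7, -.6, 0, 0, .1) | .cap(g, 0, 0, .7, -.45, .09),
  "14975008" = function(g) .cap(g, -.45, -.7, .4, .7, .07) | .cap(g, -.25, -.72, .55, .62, .05),
  "85562004" = function(g) .ell(g, 0, .35, .4, .32) | .rays(g, 5, 0, .18, .85, .05),
  "8205005" = function(g) {m <- .cap(g, -.15, .4, -.1, .9, .08) | .cap(g, .12, .42, .17, .9, .06)
    for (p in list(c(-.2, .1), c(0, .05), c(.2, .1), c(-.1, -.18), c(.12, -.2)))
      m <- m | .ell(g, p[1], p[2], .11, .11)
    m},
  "7569003" = function(g) .cap(g, 0, .55, 0, .2, .06) | .cap(g, 0, .1, 0, -.25, .055) | .cap(g, 0, -.35, 0, -.6, .05),
  "76505004" = function(g) .cap(g, -.3, .5, 0, 0, .11) | .cap(g, .05, -.08, .35, -.45, .1),
  "120575009" = function(g) .cap(g, -.18, -.85, -.12, .85, .12) | .cap(g, .2, -.8, .25, .85, .06),
  "12921003" = function(g) (.ell(g, -.42, 0, .38, .5) & !.ell(g, -.42, .05, .2, .28)) | (.ell(g, .42, 0, .38, .5) & !.ell(g, .42, .05, .2, .28)),
  "54735007" = function(g) (g$y > -.4 & g$y < .5 & abs(g$x) < (.55 - .55 * (g$y + .4))) ,
  "29836001" = function(g) .ell(g, 0, .1, .22, .22) | (.ring(g, 0, .1, .32, .07) & g$y < .1) | .cap(g, .08, .25, .35, .8, .12),
  "302524008" = function(g) .cap(g, 0, -.8, 0, .35, .11) | .ell(g, -.16, .55, .17, .2) | .ell(g, .16, .55, .17, .2),
  "72696002" = function(g) .cap(g, 0, -.85, 0, -.15, .14) | .cap(g, 0, .2, 0, .85, .13) | .ell(g, -.3, 0, .12, .15),
  "64234005" = function(g) .ell(g, 0, 0, .3, .34),
  "344001" = function(g) .cap(g, 0, -.85, 0, .25, .1) | .cap(g, -.05, .3, .6, .45, .09),
  "56459004" = function(g) (.ell(g, -.1, .35, .65, .3) & g$y > .1) | .rays(g, 5, -.1, .3, .7, .04, spread = pi / 5, base = 0),
  "29707007" = function(g) .cap(g, 0, .3, 0, -.05, .07) | .cap(g, 0, -.15, 0, -.38, .06),
  "-1" = function(g) 0.15 * .ell(g, 0, 0, 2, 2),
  "-2" = function(g) {m <- matrix(0, nrow(g$x), ncol(g$x))
    for (yy in seq(-.8, .8, by = .16))
      m <- m + (abs(g$y - yy) < .04 & g$x > -.8 & g$x < runif(1, 0, .8))
    pmin(m, 1)}
)

#' Specification of one synthetic radiograph phantom
#'
#' @param body_part SNOMED code of the depicted class.
#' @param size square image size in pixels.
#' @param size_jitter relative scale jitter of the motif (uniform).
#' @param noise_sd Gaussian intensity noise standard deviation (10-bit
#'   intensity units).
#' @param inverted generate with a light background (inverted polarity).
#' @return object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(body_part, size = 64L, size_jitter = 0.1,
                         noise_sd = 25, inverted = FALSE) {
  if (!as.character(body_part) %in% names(.MOTIFS))
    stop("no phantom motif for class ", body_part)
  structure(list(body_part = body_part, size = as.integer(size),
                 size_jitter = size_jitter, noise_sd = noise_sd,
                 inverted = inverted),
            class = "phantom_spec")
}

#' Generate a synthetic radiograph phantom
#'
#' Draws the class-specific geometric motif with random scale/shift
#' jitter and additive Gaussian noise on a dark background; the
#' \code{inverted} flag yields the exact pixel-wise complement of the
#' non-inverted image at the same seed. Intensities are 10-bit integers
#' (0..1023). Deterministic for a fixed seed.
#'
#' @param spec a [phantom_spec()].
#' @param seed optional integer seed.
#' @return integer pixel matrix \code{size x size}.
#' @export
generate_phantom <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(seed)) set.seed(seed)
  g <- .grid_xy(spec$size)
  s <- runif(1, 1 - spec$size_jitter, 1 + spec$size_jitter)
  shift <- runif(2, -spec$size_jitter, spec$size_jitter)
  g$x <- (g$x - shift[1]) / s
  g$y <- (g$y - shift[2]) / s
  mask <- .MOTIFS[[as.character(spec$body_part)]](g)
  img <- 80 + 620 * pmin(pmax(mask, 0), 1) +
    rnorm(spec$size^2, sd = spec$noise_sd)
  img <- matrix(as.integer(round(pmin(pmax(img, 0), .MAX_INTENSITY))),
                spec$size, spec$size)
  if (spec$inverted) img <- .MAX_INTENSITY - img
  img
}

#' Emit a heterogeneous free-text header term for a class
#'
#' Samples one of the class's non-standard surface forms (abbreviations,
#' clinical synonyms including German terms, case variants, laterality
#' suffixes) from the built-in vocabulary — or, with probability
#' \code{unknown_rate}, an unmappable token. With \code{unknown_rate = 0}
#' every emitted term normalizes back to the true class.
#'
#' @param true_class SNOMED code of a non-sentinel class.
#' @param vocab a \code{body_part_vocab}.
#' @param unknown_rate probability of emitting an unmappable token.
#' @return character scalar.
#' @export
corrupt_body_part_term <- function(true_class, vocab, unknown_rate = 0) {
  stopifnot(true_class > 0)
  if (runif(1) < unknown_rate)
    return(sprintf("XX-NONSTANDARD-%02d", sample.int(99, 1)))
  forms <- .surface_forms(vocab)
  f <- forms$term[forms$snomed_code == true_class]
  if (!length(f)) stop("class has no surface forms: ", true_class)
  f[sample.int(length(f), 1)]
}

# cached per-vocabulary surface-form table
.surface_cache <- new.env(parent = emptyenv())
.surface_forms <- function(vocab) {
  key <- as.character(length(vocab$synonym_map))
  if (is.null(.surface_cache[[key]]))
    .surface_cache[[key]] <- nonstandard_vocabulary(vocab)
  .surface_cache[[key]]
}

#' Configuration of a synthetic DICOM corpus
#'
#' Defaults emulate the statistical structure reported for the clinical
#' archive: a long-tailed (Zipf-like) class distribution, 13\% of images
#' missing the body-part header entirely, heterogeneous non-standard
#' header spellings, a CR/DX modality mix of roughly 70/30, and half of
#' the images stored with inverted (light-background) polarity.
#'
#' @param n number of images.
#' @param classes SNOMED codes to generate; default: eight classes
#'   spanning several body regions.
#' @param class_probs sampling weights (default Zipf: 1/rank).
#' @param missing_header_rate fraction of images without tag (0018,0015).
#' @param unknown_term_rate fraction of non-blank headers corrupted to an
#'   unmappable token.
#' @param invert_rate fraction stored as MONOCHROME1 with complemented
#'   pixels.
#' @param visible_extra_rate probability that an image additionally shows
#'   an anatomically adjacent structure (same level-1 region).
#' @param cr_fraction modality mix: fraction of "CR" (rest "DX").
#' @param image_size phantom size in pixels.
#' @param noise_sd phantom noise level.
#' @param seed integer seed.
#' @return object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n = 100L,
                             classes = c(85562004, 51185008, 89546000,
                                         818983003, 72696002, 56459004,
                                         122496007, 76752008),
                             class_probs = NULL,
                             missing_header_rate = 0.13,
                             unknown_term_rate = 0,
                             invert_rate = 0.5,
                             visible_extra_rate = 0.3,
                             cr_fraction = 0.696,
                             image_size = 64L, noise_sd = 25,
                             seed = 1L) {
  if (n < 1) stop("n must be at least 1")
  rates <- c(missing_header_rate, unknown_term_rate, invert_rate,
             visible_extra_rate, cr_fraction)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (is.null(class_probs)) class_probs <- 1 / seq_along(classes)
  structure(list(n = as.integer(n), classes = classes,
                 class_probs = class_probs / sum(class_probs),
                 missing_header_rate = missing_header_rate,
                 unknown_term_rate = unknown_term_rate,
                 invert_rate = invert_rate,
                 visible_extra_rate = visible_extra_rate,
                 cr_fraction = cr_fraction,
                 image_size = as.integer(image_size), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic DICOM corpus with ground truth
#'
#' Writes \code{n} minimal DICOM Part-10 files (with modality,
#' photometric interpretation and a heterogeneous or missing body-part
#' header term) plus a \code{truth.csv} holding the examined label, the
#' visible label set (the examined class plus any adjacent structures,
#' separated by \code{";"}), the raw header term and the inversion flag
#' per image.
#'
#' @param cfg a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @param vocab vocabulary used for header-term surface forms; defaults
#'   to the packaged one.
#' @param hier hierarchy used for anatomical adjacency; defaults to the
#'   packaged one.
#' @return the truth data.frame, invisibly; files are in \code{dir}.
#' @export
generate_corpus <- function(cfg, dir, vocab = NULL, hier = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (is.null(vocab)) vocab <- load_vocabulary()
  if (is.null(hier)) hier <- load_hierarchy()
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  n <- cfg$n
  examined <- sample(cfg$classes, n, replace = TRUE, prob = cfg$class_probs)
  region_of <- setNames(hier$paths$level1, hier$paths$leaf_code)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cls <- examined[i]
    inverted <- runif(1) < cfg$invert_rate
    px <- generate_phantom(phantom_spec(cls, size = cfg$image_size,
                                        noise_sd = cfg$noise_sd,
                                        inverted = inverted))
    visible <- cls
    if (runif(1) < cfg$visible_extra_rate) {
      sibs <- hier$paths$leaf_code[region_of[as.character(hier$paths$leaf_code)] ==
                                     region_of[as.character(cls)]]
      sibs <- setdiff(sibs, cls)
      if (length(sibs)) visible <- c(cls, sample(sibs, 1))
    }
    header_raw <- if (runif(1) < cfg$missing_header_rate) NA_character_
                  else corrupt_body_part_term(cls, vocab, cfg$unknown_term_rate)
    id <- sprintf("img%05d", i)
    write_dicom(
      file.path(dir, paste0(id, ".dcm")), px,
      sop_uid = sprintf("1.2.826.0.1.3680043.9999.2.%d.%d", cfg$seed, i),
      modality = if (runif(1) < cfg$cr_fraction) "CR" else "DX",
      body_part = if (is.na(header_raw)) NULL else header_raw,
      photometric = if (inverted) "MONOCHROME1" else "MONOCHROME2",
      manufacturer = sample(c("ACME", "RADIX", "PHOSPHOR"), 1),
      acquisition_date = sprintf("20%02d%02d%02d", sample(0:23, 1),
                                 sample(1:12, 1), sample(1:28, 1)),
      bits_stored = 10L)
    rows[[i]] <- data.frame(
      id = id, examined_code = cls,
      visible_codes = paste(visible, collapse = ";"),
      header_raw = ifelse(is.na(header_raw), "", header_raw),
      inverted = inverted, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(truth)
}

#' Load a generated corpus into a training dataset
#'
#' Reads every DICOM of a corpus directory, normalizes polarity, and
#' pairs the pixel matrices with the ground-truth labels.
#'
#' @param dir corpus directory holding \code{*.dcm} and \code{truth.csv}.
#' @return list with \code{x} (list of matrices), \code{y} (examined
#'   codes), \code{y_visible} (list of code vectors), \code{ids},
#'   \code{header_raw}.
#' @export
load_corpus <- function(dir) {
  truth <- read.csv(file.path(dir, "truth.csv"), stringsAsFactors = FALSE,
                    colClasses = c(header_raw = "character"))
  recs <- lapply(truth$id, function(id)
    normalize_polarity(read_image(file.path(dir, paste0(id, ".dcm")))))
  list(x = lapply(recs, `[[`, "pixels"),
       y = truth$examined_code,
       y_visible = lapply(strsplit(truth$visible_codes, ";", fixed = TRUE),
                          as.numeric),
       ids = truth$id,
       header_raw = truth$header_raw)
}
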