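# Independent brute-force oracles, deliberately written without reusing
# the package's own code paths.

# Hierarchical loss by direct enumeration over the path table.
oracle_hier_loss <- function(y, p, hier, w = c(0.4, 0.3, 0.3), eps = 1e-7) {
  total <- 0
  for (lv in 1:3) {
    labs <- unique(hier$paths[[paste0("level", lv)]])
    ll <- 0
    for (lab in labs) {
      members <- which(hier$paths[[paste0("level", lv)]] == lab)
      P <- min(max(sum(p[members]), eps), 1 - eps)
      Y <- as.numeric(any(y[members] == 1))
      ll <- ll - Y * log(P)
    }
    total <- total + w[lv] * ll
  }
  total
}

# Otsu by exhaustive search over all 256 candidate thresholds.
oracle_otsu <- function(v) {
  v <- as.integer(round(v))
  best_var <- -1; best_T <- NA
  for (T in 1:255) {
    lo <- v[v < T]; hi <- v[v >= T]
    if (!length(lo) || !length(hi)) next
    p0 <- length(lo) / length(v); p1 <- 1 - p0
    vb <- p0 * p1 * (mean(lo) - mean(hi))^2
    if (vb > best_var + 1e-12) { best_var <- vb; best_T <- T }
  }
  list(T = best_T, var_between = best_var)
}

# Distance from point q to segment a-b.
point_segment_dist <- function(q, a, b) {
  ab <- b - a
  t <- sum((q - a) * ab) / max(sum(ab^2), 1e-300)
  t <- min(max(t, 0), 1)
  sqrt(sum((q - (a + t * ab))^2))
}

# One-hot leaf vector in the order of hier$paths$leaf_code.
one_hot <- function(codes, hier) {
  y <- rep(0, nrow(hier$paths))
  y[match(codes, hier$paths$leaf_code)] <- 1
  y
}

# Small in-memory phantom dataset for training tests.
make_phantom_dataset <- function(n, classes, seed = 1, size = 64) {
  set.seed(seed)
  y <- sample(classes, n, TRUE)
  x <- lapply(seq_len(n), function(i)
    generate_phantom(phantom_spec(y[i], size = size), seed = seed * 10000 + i))
  list(x = x, y = y)
}
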