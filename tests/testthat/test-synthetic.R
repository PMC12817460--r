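vocab <- load_vocabulary()
hier <- load_hierarchy()

test_that("phantoms are deterministic per seed and complement exactly when inverted", {
  sp <- phantom_spec(85562004)
  expect_identical(generate_phantom(sp, seed = 4), generate_phantom(sp, seed = 4))
  spi <- phantom_spec(85562004, inverted = TRUE)
  expect_identical(generate_phantom(spi, seed = 4),
                   1023L - generate_phantom(sp, seed = 4))
  expect_error(phantom_spec(42), "no phantom motif")
})

test_that("every vocabulary class has a drawable motif", {
  for (code in vocab$classes$snomed_code) {
    px <- generate_phantom(phantom_spec(code, size = 32), seed = 1)
    expect_equal(dim(px), c(32L, 32L))
    expect_true(all(is.finite(px)))
  }
})

test_that("phantom classes are separable by a nearest-centroid classifier", {
  classes <- c(85562004, 51185008, 89546000, 818983003, 72696002)
  set.seed(60)
  y <- rep(classes, each = 40)
  X <- t(vapply(seq_along(y), function(i)
    as.vector(generate_phantom(phantom_spec(y[i], size = 32), seed = 7000 + i)),
    numeric(32 * 32)))
  tr <- unlist(lapply(seq_along(classes) - 1, function(k) k * 40 + 1:20))
  te <- setdiff(seq_along(y), tr)
  centroids <- t(vapply(classes, function(cl)
    colMeans(X[tr[y[tr] == cl], , drop = FALSE]), numeric(ncol(X))))
  pred <- classes[apply(X[te, ], 1, function(v)
    which.min(colSums((t(centroids) - v)^2)))]
  expect_gt(mean(pred == y[te]), 0.8)
})

test_that("corrupted header terms stay mappable unless corruption is on", {
  set.seed(61)
  for (i in 1:40) {
    cl <- sample(vocab$classes$snomed_code[vocab$classes$snomed_code > 0], 1)
    expect_equal(normalize_codes(corrupt_body_part_term(cl, vocab, 0), vocab), cl)
    expect_equal(normalize_codes(corrupt_body_part_term(cl, vocab, 1), vocab), -1)
  }
  expect_error(corrupt_body_part_term(-1, vocab), "true_class > 0")
})

test_that("generated corpora carry the configured statistical structure", {
  d <- tempfile("corpus")
  cfg <- synthetic_config(n = 100, seed = 8)
  truth <- generate_corpus(cfg, d)
  expect_equal(nrow(truth), 100L)
  expect_length(list.files(d, pattern = "\\.dcm$"), 100L)

  n_missing <- sum(truth$header_raw == "")
  expect_gte(n_missing, 13 - 7); expect_lte(n_missing, 13 + 7)

  # non-blank headers normalize to the true class (corruption off)
  nb <- truth[truth$header_raw != "", ]
  expect_equal(normalize_codes(nb$header_raw, vocab), nb$examined_code)

  # visible sets contain the examined label; extras share the level-1 region
  vis <- strsplit(truth$visible_codes, ";", fixed = TRUE)
  region <- setNames(hier$paths$level1, hier$paths$leaf_code)
  for (i in seq_len(100)) {
    codes <- as.numeric(vis[[i]])
    expect_true(truth$examined_code[i] %in% codes)
    expect_length(unique(region[as.character(codes)]), 1L)
  }

  tab <- headers_to_table(file.path(d, paste0(truth$id, ".dcm")))
  expect_equal(nrow(tab), 100L)
  expect_true(all(tab$modality %in% c("CR", "DX")))
  expect_equal(sum(tab$body_part_examined == ""), n_missing)
})

test_that("corpus loading restores polarity-normalized images and labels", {
  d <- tempfile("corpus")
  cfg <- synthetic_config(n = 20, seed = 9, invert_rate = 1)
  truth <- generate_corpus(cfg, d)
  ds <- load_corpus(d)
  expect_length(ds$x, 20L)
  expect_equal(ds$y, truth$examined_code)
  # inverted storage + normalization = the original dark-background phantom
  for (i in 1:5) {
    expect_lt(median(ds$x[[i]][1:3, ]), median(ds$x[[i]]) + 1)
    expect_gt(max(ds$x[[i]]), 500)  # bright foreground restored
  }
})
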