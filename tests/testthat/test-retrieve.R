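vocab <- load_vocabulary()

toy_index <- function() {
  build_index(
    ids = sprintf("im%02d", 1:10),
    dl_examined = c(76752008, 76752008, 85562004, 51185008, 76752008,
                    85562004, 51185008, 76752008, 85562004, 51185008),
    dl_visible = list(76752008, c(76752008, 51185008), 85562004,
                      c(51185008, 76752008), 76752008, 85562004,
                      51185008, 76752008, 85562004, 51185008),
    header_class = c(76752008, 76752008, 85562004, 51185008, 76752008,
                     85562004, 51185008, 76752008, 85562004, -1),
    vectors = NULL, file = NULL)
}

test_that("index construction validates ids and supports self-retrieval", {
  expect_error(build_index(ids = c("a", "a")), "duplicate image id")
  idx <- toy_index()
  for (code in unique(idx$dl_examined)) {
    r <- keyword_search(idx, code, source = "examined", vocab = vocab)
    expect_setequal(r$ids, idx$ids[idx$dl_examined == code])
  }
  empty <- build_index(ids = character(0))
  expect_length(keyword_search(empty, "BREAST", vocab = vocab)$ids, 0L)
})

test_that("keyword search respects the annotation source semantics", {
  idx <- toy_index()
  ex <- keyword_search(idx, "BREAST", source = "examined", vocab = vocab)
  vis <- keyword_search(idx, "BREAST", source = "visible", vocab = vocab)
  expect_setequal(ex$ids, c("im01", "im02", "im05", "im08"))
  # im04's examined label differs but its visible set contains the query
  expect_true("im04" %in% vis$ids)
  expect_true(all(ex$ids %in% vis$ids))  # visible sets contain examined labels
  expect_length(keyword_search(idx, "ZEHEN", vocab = vocab)$ids, 0L)
  expect_error(keyword_search(idx, "NOTACLASS", vocab = vocab), "vocabulary")
})

test_that("cosine search matches a brute-force oracle and honors the threshold", {
  set.seed(50)
  V <- matrix(rnorm(5 * 6), 5, 6)
  idx <- build_index(ids = letters[1:5], vectors = V)
  ref <- V[3, ]
  r <- cosine_search(idx, ref, threshold = 0.3)
  cs <- apply(V, 1, function(v) sum(v * ref) / sqrt(sum(v^2) * sum(ref^2)))
  keep <- which(cs > 0.3)
  expect_setequal(r$ids, letters[keep])
  expect_equal(unname(r$scores[letters[keep][order(-cs[keep])]]),
               sort(cs[keep], decreasing = TRUE), tolerance = 1e-12)
  expect_equal(unname(r$scores["c"]), 1, tolerance = 1e-12)

  orth <- c(V[1, 2], -V[1, 1], 0, 0, 0, 0)
  idx1 <- build_index(ids = "a", vectors = V[1, , drop = FALSE])
  expect_length(cosine_search(idx1, orth, threshold = 0.3)$ids, 0L)
  expect_error(cosine_search(idx1, rep(0, 6)), "zero-norm")
  expect_error(cosine_search(idx1, 1:3), "length")
})

test_that("intersection fuses annotation sources and cancels disjoint errors", {
  a <- xrannotate:::.retrieval_result(c("a", "b", "c"),
         setNames(rep(1, 3), c("a", "b", "c")),
         setNames(rep(list("examined"), 3), c("a", "b", "c")))
  b <- xrannotate:::.retrieval_result(c("b", "c", "d"),
         setNames(rep(1, 3), c("b", "c", "d")),
         setNames(rep(list("header"), 3), c("b", "c", "d")))
  ab <- intersect_results(a, b)
  expect_equal(ab$ids, c("b", "c"))
  expect_setequal(unlist(ab$provenance), c("examined", "header"))
  expect_equal(intersect_results(b, a)$ids, ab$ids)  # commutative
  none <- xrannotate:::.retrieval_result(character(0), numeric(0), list())
  expect_length(intersect_results(a, none)$ids, 0L)
})

test_that("complementary single-source errors vanish in the intersection", {
  truth <- sprintf("t%02d", 1:20)
  dl <- c(truth[-1], "falseDL")        # misses t01, adds one false id
  hdr <- c(truth[-2], "falseHDR")      # misses t02, adds a different false id
  mk <- function(ids, src) xrannotate:::.retrieval_result(sort(ids),
    setNames(rep(1, length(ids)), sort(ids)),
    setNames(rep(list(src), length(ids)), sort(ids)))
  fused <- intersect_results(mk(dl, "examined"), mk(hdr, "header"))
  ev <- evaluate_retrieval(fused, truth)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 18 / 20)
  expect_gte(ev$precision,
             max(evaluate_retrieval(mk(dl, "e"), truth)$precision,
                 evaluate_retrieval(mk(hdr, "h"), truth)$precision))
})

test_that("retrieval metrics match hand counts", {
  truth <- as.character(1:50)
  res <- as.character(2:51)   # one miss, one false alarm
  ev <- evaluate_retrieval(res, truth, n_total = 100)
  expect_equal(ev$precision, 49 / 50)
  expect_equal(ev$recall, 49 / 50)
  expect_equal(ev$accuracy, 98 / 100)
  expect_equal(evaluate_retrieval(character(0), truth)$recall, 0)
  expect_error(evaluate_retrieval(res, character(0)), "empty ground truth")
})

test_that("the JSON-lines index export round-trips", {
  f <- tempfile(fileext = ".jsonl")
  V <- matrix(1:6 / 6, 2, 3)
  build_index(ids = c("x", "y"), dl_examined = c(76752008, -1),
              dl_visible = list(c(76752008, 51185008), numeric(0)),
              header_class = c(76752008, NA), vectors = V, file = f)
  lines <- readLines(f)
  expect_length(lines, 2L)
  rec <- jsonlite::fromJSON(lines[1])
  expect_equal(rec$id, "x")
  expect_equal(rec$examined, 76752008)
  expect_equal(rec$vector, V[1, ])
})
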