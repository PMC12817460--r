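vocab <- load_vocabulary()
hier <- load_hierarchy()

test_that("packaged vocabulary carries the expected mappings and sentinels", {
  expect_equal(nrow(vocab$classes), 35L)
  expect_equal(vocab_class(vocab, abbrev = "BREAST")$snomed_code, 76752008)
  expect_equal(vocab_class(vocab, abbrev = "DAUMEN")$snomed_code, 76505004)
  expect_equal(vocab_class(vocab, abbrev = "UNKNOWN")$snomed_code, -1)
  expect_equal(vocab_class(vocab, abbrev = "REPORT")$snomed_code, -2)
  sent <- vocab$classes[vocab$classes$snomed_code < 0, ]
  expect_true(all(is.na(sent$cui)))
  expect_false(anyDuplicated(vocab$classes$snomed_code) > 0)
  expect_false(anyDuplicated(vocab$classes$ukhs_abbrev) > 0)
})

test_that("normalize_term is total: matches, blanks and junk all resolve", {
  expect_equal(normalize_term("breast", vocab)$snomed_code, 76752008)
  expect_equal(normalize_term("", vocab)$snomed_code, -1)
  expect_equal(normalize_term(NA_character_, vocab)$snomed_code, -1)
  expect_equal(normalize_term("XX-NONSTANDARD-99", vocab)$snomed_code, -1)
  expect_equal(normalize_codes("  Breast  ", vocab), 76752008)
  expect_equal(normalize_codes("BREAST LINKS", vocab), 76752008)
  expect_equal(normalize_codes("head/skull", vocab), 89546000)
})

test_that("every non-sentinel abbreviation round-trips through normalization", {
  coded <- vocab$classes[vocab$classes$snomed_code > 0, ]
  expect_equal(normalize_codes(coded$ukhs_abbrev, vocab), coded$snomed_code)
  expect_equal(normalize_codes(tolower(coded$ukhs_abbrev), vocab),
               coded$snomed_code)
})

test_that("hierarchy paths follow the three-level body-region structure", {
  expect_equal(expand_to_levels(7569003, hier),
               c(level1 = "Upper extremity", level2 = "Hand", level3 = "Finger"))
  expect_equal(expand_to_levels(818983003, hier),
               c(level1 = "Abdomen", level2 = "Abdomen", level3 = "Abdomen"))
  expect_equal(expand_to_levels(29707007, hier),
               c(level1 = "Lower Extremity", level2 = "Foot", level3 = "Toe"))
  expect_error(expand_to_levels(999, hier), "not present")
  expect_lte(length(hier$level_labels$level1), 8L)
  expect_true(all(hier$level_labels$level1 %in%
    c("Cranium", "Abdomen", "Chest", "Spine", "Unknown", "Report",
      "Upper extremity", "Lower Extremity")))
})

test_that("packaged tables validate cleanly; injected defects are reported", {
  expect_equal(nrow(validate_hierarchy(vocab, hier)), 0L)

  broken <- hier
  broken$paths$level1[broken$paths$level3 == "Finger"] <- "Abdomen"
  rep1 <- validate_hierarchy(vocab, broken)
  expect_true(any(rep1$type == "refinement_violation"))

  extra <- vocab
  extra$classes <- rbind(extra$classes,
    data.frame(snomed_code = 12345, name = "Phantom limb",
               semantic_type = "Body Part, Organ, or Organ Component",
               cui = "C9999999", ukhs_abbrev = "PHANTOM"))
  rep2 <- validate_hierarchy(extra, hier)
  expect_true(any(rep2$type == "missing_path"))
})

test_that("malformed vocabulary files fail loudly at load", {
  f <- tempfile(fileext = ".csv")
  tab <- read.csv(system.file("extdata", "snomed_body_parts.csv",
                              package = "xrannotate"))
  tab$snomed_code[2] <- tab$snomed_code[1]
  write.csv(tab, f, row.names = FALSE)
  expect_error(load_vocabulary(f), "duplicate snomed_code")
})

test_that("the non-standard surface vocabulary is rich and closed", {
  nv <- nonstandard_vocabulary(vocab)
  expect_gte(nrow(nv), 116L)
  expect_equal(normalize_codes(nv$term, vocab), nv$snomed_code)
})
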