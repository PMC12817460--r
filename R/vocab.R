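#' @useDynLib xrannotate, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median quantile rnorm runif sd setNames dist
#' @importFrom utils read.csv write.csv head
NULL

# Tokens stripped from the ends of a raw header term during normalization.
# Laterality and view qualifiers carry no anatomical information.
.SITE_TOKENS <- c(
  "LINKS", "RECHTS", "LEFT", "RIGHT", "BDS", "BEIDSEITS", "BEIDSEITIG",
  "AP", "PA", "LAT", "SEITLICH", "OBLIQUE", "STEHEND", "LIEGEND", "AXIAL"
)

#' Normalize a raw body-part term to its canonical lookup form
#'
#' Uppercases, maps punctuation to spaces, collapses whitespace, and strips
#' leading/trailing laterality or view qualifiers (e.g. "LINKS", "AP").
#' This is the deterministic canonical form used for every vocabulary
#' lookup; no fuzzy matching is performed anywhere in the package.
#'
#' @param x character vector of raw terms.
#' @return character vector of normalized terms ("" for absent input).
#' @export
normalize_raw_term <- function(x) {
  x[is.na(x)] <- ""
  x <- toupper(trimws(x))
  x <- gsub("[^A-Z0-9ÄÖÜ]+", " ", x)
  x <- trimws(gsub("\\s+", " ", x))
  strip_ends <- function(s) {
    if (!nzchar(s)) return(s)
    toks <- strsplit(s, " ", fixed = TRUE)[[1]]
    while (length(toks) > 1L && toks[length(toks)] %in% .SITE_TOKENS)
      toks <- toks[-length(toks)]
    while (length(toks) > 1L && toks[1L] %in% .SITE_TOKENS)
      toks <- toks[-1L]
    paste(toks, collapse = " ")
  }
  vapply(x, strip_ends, character(1), USE.NAMES = FALSE)
}

.pkg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "xrannotate")
  if (!nzchar(path)) path <- file.path("inst", "extdata", file)
  path
}

#' Load the SNOMED CT body-part vocabulary
#'
#' Reads the packaged mapping of hospital abbreviations to SNOMED CT
#' concepts (33 coded body parts plus the two sentinel classes
#' \code{UNKNOWN} (-1) and \code{REPORT} (-2)) and builds the synonym
#' lookup used by [normalize_term()]. The synonym map contains, for every
#' class, the hospital abbreviation, the SNOMED preferred name, and the
#' packaged non-standard synonym list, all in normalized form.
#'
#' @param source path to a vocabulary CSV with columns
#'   \code{snomed_code,name,semantic_type,cui,ukhs_abbrev}; defaults to the
#'   packaged table.
#' @param synonyms path to a synonym CSV (\code{term,snomed_code});
#'   defaults to the packaged table.
#' @return an object of class \code{body_part_vocab}: a list with
#'   \code{classes} (data.frame, one row per class in file order),
#'   \code{synonym_map} (named integer vector, normalized term -> code) and
#'   \code{metadata}.
#' @export
load_vocabulary <- function(source = NULL, synonyms = NULL) {
  if (is.null(source)) source <- .pkg_extdata("snomed_body_parts.csv")
  if (is.null(synonyms)) synonyms <- .pkg_extdata("body_part_synonyms.csv")
  cls <- read.csv(source, stringsAsFactors = FALSE,
                  colClasses = c(snomed_code = "numeric"))
  need <- c("snomed_code", "name", "semantic_type", "cui", "ukhs_abbrev")
  if (!all(need %in% names(cls)))
    stop("vocabulary file lacks required columns: ",
         paste(setdiff(need, names(cls)), collapse = ", "))
  cls$cui[!nzchar(trimws(cls$cui))] <- NA_character_
  if (anyNA(cls$snomed_code))
    stop("malformed vocabulary row: non-numeric snomed_code at line ",
         which(is.na(cls$snomed_code))[1] + 1L)
  if (anyDuplicated(cls$snomed_code))
    stop("duplicate snomed_code in vocabulary: ",
         cls$snomed_code[duplicated(cls$snomed_code)][1])
  if (anyDuplicated(cls$ukhs_abbrev))
    stop("duplicate ukhs_abbrev in vocabulary: ",
         cls$ukhs_abbrev[duplicated(cls$ukhs_abbrev)][1])
  sent <- cls$snomed_code < 0
  if (!all(c(-1, -2) %in% cls$snomed_code))
    stop("vocabulary must contain sentinel classes -1 (UNKNOWN) and -2 (REPORT)")
  if (any(!is.na(cls$cui[sent])))
    stop("sentinel classes must not carry a CUI")

  syn <- read.csv(synonyms, stringsAsFactors = FALSE)
  bad <- setdiff(syn$snomed_code, cls$snomed_code)
  if (length(bad))
    stop("synonym refers to unknown snomed_code: ", bad[1])

  keys <- c(normalize_raw_term(cls$ukhs_abbrev),
            normalize_raw_term(cls$name),
            normalize_raw_term(syn$term))
  vals <- c(cls$snomed_code, cls$snomed_code, syn$snomed_code)
  keep <- nzchar(keys) & !duplicated(keys)
  map <- setNames(vals[keep], keys[keep])
  conf <- tapply(vals, keys, function(v) length(unique(v)))
  if (any(conf > 1))
    stop("conflicting synonym mapping for term: ", names(conf)[conf > 1][1])

  structure(list(
    classes = cls,
    synonym_map = map,
    metadata = list(
      n_classes = nrow(cls),
      n_coded = sum(!sent),
      declared_class_count = 36L,
      note = paste("The source mapping table declares 36 body parts but",
                   "yields 35 transcribable rows (33 SNOMED-coded + 2",
                   "sentinels); the discrepancy is recorded here rather",
                   "than guessed.")
    )
  ), class = "body_part_vocab")
}

#' @export
print.body_part_vocab <- function(x, ...) {
  cat("SNOMED CT body-part vocabulary:", nrow(x$classes), "classes (",
      x$metadata$n_coded, "coded + 2 sentinels ),",
      length(x$synonym_map), "lookup terms\n")
  invisible(x)
}

#' Look up one class of the vocabulary by code or abbreviation
#'
#' @param vocab a \code{body_part_vocab}.
#' @param code SNOMED code, or \code{abbrev} an UKSH abbreviation.
#' @param abbrev alternative key.
#' @return one-row data.frame (a \code{BodyPartClass}).
#' @export
vocab_class <- function(vocab, code = NULL, abbrev = NULL) {
  stopifnot(inherits(vocab, "body_part_vocab"))
  if (!is.null(code)) {
    i <- match(code, vocab$classes$snomed_code)
  } else {
    i <- match(abbrev, vocab$classes$ukhs_abbrev)
  }
  if (is.na(i)) stop("class not in vocabulary: ", c(code, abbrev)[1])
  vocab$classes[i, , drop = FALSE]
}

#' Normalize a free-text body-part term to a canonical class
#'
#' Case-insensitive, whitespace/punctuation-tolerant lookup of a raw
#' header term (DICOM tag (0018,0015) or similar) against the hospital
#' abbreviations and the synonym map. Absent, empty or unmatched terms map
#' to the UNKNOWN sentinel (-1): the function is total by design and never
#' fails on input text.
#'
#' @param raw a single raw term (character, possibly \code{NA} or "").
#' @param vocab a \code{body_part_vocab}.
#' @return one-row data.frame: the matched \code{BodyPartClass}.
#' @seealso [normalize_codes()] for the vectorized code-only variant.
#' @export
normalize_term <- function(raw, vocab) {
  code <- normalize_codes(raw, vocab)
  vocab$classes[match(code, vocab$classes$snomed_code), , drop = FALSE]
}

#' Vectorized term normalization returning SNOMED codes
#'
#' @param raws character vector of raw terms.
#' @param vocab a \code{body_part_vocab}.
#' @return numeric vector of SNOMED codes (-1 for unmatched/absent).
#' @export
normalize_codes <- function(raws, vocab) {
  stopifnot(inherits(vocab, "body_part_vocab"))
  if (length(raws) == 0L) return(numeric(0))
  key <- normalize_raw_term(as.character(raws))
  code <- unname(vocab$synonym_map[key])
  code[is.na(code)] <- -1
  code
}

#' Load the three-level body-region hierarchy
#'
#' Reads the packaged hierarchy assigning every vocabulary class (including
#' the sentinels) a path \code{(level1, level2, level3)}: level 1 holds the
#' broad body regions (Cranium, Abdomen, Chest, Spine, Unknown, Upper
#' extremity, Lower Extremity), and each deeper level refines the one
#' above. The hierarchy drives the hierarchical classification loss.
#'
#' @param source CSV with columns \code{leaf_code,level1,level2,level3};
#'   defaults to the packaged table.
#' @return object of class \code{body_hierarchy}: list with \code{paths}
#'   (data.frame) and \code{level_labels} (list of three ordered label
#'   vectors, sizes \code{N_1 <= N_2 <= N_3}).
#' @export
load_hierarchy <- function(source = NULL) {
  if (is.null(source)) source <- .pkg_extdata("body_part_hierarchy.csv")
  p <- read.csv(source, stringsAsFactors = FALSE,
                colClasses = c(leaf_code = "numeric"))
  need <- c("leaf_code", "level1", "level2", "level3")
  if (!all(need %in% names(p)))
    stop("hierarchy file lacks required columns")
  if (anyDuplicated(p$leaf_code))
    stop("duplicate leaf_code in hierarchy: ",
         p$leaf_code[duplicated(p$leaf_code)][1])
  structure(list(
    paths = p,
    level_labels = list(
      level1 = unique(p$level1),
      level2 = unique(p$level2),
      level3 = unique(p$level3)
    )
  ), class = "body_hierarchy")
}

#' @export
print.body_hierarchy <- function(x, ...) {
  n <- vapply(x$level_labels, length, integer(1))
  cat("Three-level body-region hierarchy:", nrow(x$paths), "leaves;",
      "level sizes", paste(n, collapse = "/"), "\n")
  invisible(x)
}

#' Expand a leaf class to its three hierarchy levels
#'
#' @param leaf a SNOMED code, an UKSH abbreviation resolvable through
#'   \code{vocab}, or a \code{BodyPartClass} row.
#' @param hier a \code{body_hierarchy}.
#' @param vocab optional \code{body_part_vocab}, needed only when
#'   \code{leaf} is an abbreviation.
#' @return named character vector \code{c(level1=, level2=, level3=)}.
#' @export
expand_to_levels <- function(leaf, hier, vocab = NULL) {
  stopifnot(inherits(hier, "body_hierarchy"))
  code <- if (is.data.frame(leaf)) leaf$snomed_code
          else if (is.character(leaf)) vocab_class(vocab, abbrev = leaf)$snomed_code
          else leaf
  i <- match(code, hier$paths$leaf_code)
  if (is.na(i)) stop("leaf class not present in hierarchy: ", code)
  c(level1 = hier$paths$level1[i],
    level2 = hier$paths$level2[i],
    level3 = hier$paths$level3[i])
}

#' Validate vocabulary/hierarchy consistency
#'
#' Checks that every vocabulary class has exactly one hierarchy path, that
#' no path references a class outside the vocabulary, and that each level
#' refines the one above it (every level-2 label has a unique level-1
#' parent, every level-3 label a unique level-2 parent).
#'
#' @param vocab a \code{body_part_vocab}.
#' @param hier a \code{body_hierarchy}.
#' @return data.frame report with columns \code{type, detail}; zero rows
#'   when the tables are consistent.
#' @export
validate_hierarchy <- function(vocab, hier) {
  stopifnot(inherits(vocab, "body_part_vocab"), inherits(hier, "body_hierarchy"))
  rep <- list()
  add <- function(type, detail)
    rep[[length(rep) + 1L]] <<- data.frame(type = type, detail = detail,
                                           stringsAsFactors = FALSE)
  missing_path <- setdiff(vocab$classes$snomed_code, hier$paths$leaf_code)
  for (m in missing_path) add("missing_path", paste("class", m, "has no hierarchy path"))
  unknown_leaf <- setdiff(hier$paths$leaf_code, vocab$classes$snomed_code)
  for (u in unknown_leaf) add("unknown_leaf", paste("path leaf", u, "not in vocabulary"))
  par1 <- tapply(hier$paths$level1, hier$paths$level2, function(v) length(unique(v)))
  for (l in names(par1)[par1 > 1])
    add("refinement_violation", paste("level-2 label", l, "has multiple level-1 parents"))
  par2 <- tapply(hier$paths$level2, hier$paths$level3, function(v) length(unique(v)))
  for (l in names(par2)[par2 > 1])
    add("refinement_violation", paste("level-3 label", l, "has multiple level-2 parents"))
  if (length(rep)) do.call(rbind, rep)
  else data.frame(type = character(0), detail = character(0))
}

#' Enumerate the built-in non-standard surface vocabulary
#'
#' Returns the full set of heterogeneous free-text surface forms the
#' synthetic corpus generator can emit for each coded class: hospital
#' abbreviations, SNOMED preferred names, packaged clinical synonyms
#' (including German terms), case variants, and laterality-suffixed
#' variants. Every listed form normalizes back to its class via
#' [normalize_codes()]; the table emulates the messy pre-standardization
#' header vocabulary of a real PACS archive.
#'
#' @param vocab a \code{body_part_vocab}.
#' @return data.frame \code{term, snomed_code}, terms unique.
#' @export
nonstandard_vocabulary <- function(vocab) {
  stopifnot(inherits(vocab, "body_part_vocab"))
  cls <- vocab$classes[vocab$classes$snomed_code > 0, ]
  syn_path <- .pkg_extdata("body_part_synonyms.csv")
  syn <- read.csv(syn_path, stringsAsFactors = FALSE)
  title_case <- function(s) {
    s <- tolower(s)
    gsub("(^|[ /_])([a-z])", "\\1\\U\\2", s, perl = TRUE)
  }
  out <- list()
  for (i in seq_len(nrow(cls))) {
    code <- cls$snomed_code[i]
    base <- c(cls$ukhs_abbrev[i], syn$term[syn$snomed_code == code])
    forms <- unique(c(base, tolower(base), title_case(base[1]),
                      paste(base[1], "LINKS"), paste(base[1], "RECHTS")))
    out[[i]] <- data.frame(term = forms, snomed_code = code,
                           stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  tab[!duplicated(tab$term), ]
}
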