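#' Build an in-process annotation index
#'
#' Collects per-image annotations from the three label sources — the
#' deep-learning examined prediction, the deep-learning visible label
#' set, and the (normalized) original header — together with an optional
#' embedding vector for content-based retrieval, into a single queryable
#' index with inverted-lookup semantics. A JSON-lines export allows
#' external search engines to ingest the same index.
#'
#' @param ids unique image identifiers.
#' @param dl_examined SNOMED code per image (or \code{NA}).
#' @param dl_visible list of SNOMED code vectors per image (or
#'   \code{NULL}).
#' @param header_class SNOMED code per image from the normalized header
#'   (or \code{NA}).
#' @param vectors optional numeric matrix of embedding vectors, one row
#'   per image, constant length.
#' @param file optional JSON-lines export path (one object per line:
#'   id, examined, visible, header, vector).
#' @return object of class \code{annotation_index}.
#' @export
build_index <- function(ids, dl_examined = NULL, dl_visible = NULL,
                        header_class = NULL, vectors = NULL, file = NULL) {
  ids <- as.character(ids)
  n <- length(ids)
  if (anyDuplicated(ids)) stop("duplicate image id: ", ids[duplicated(ids)][1])
  fill <- function(x, default) if (is.null(x)) rep(default, n) else x
  dl_examined <- fill(dl_examined, NA_real_)
  header_class <- fill(header_class, NA_real_)
  if (is.null(dl_visible)) dl_visible <- rep(list(numeric(0)), n)
  if (!is.null(vectors)) {
    vectors <- as.matrix(vectors)
    if (nrow(vectors) != n) stop("vector count does not match id count")
  }
  idx <- structure(list(ids = ids, dl_examined = dl_examined,
                        dl_visible = dl_visible, header_class = header_class,
                        vectors = vectors),
                   class = "annotation_index")
  if (!is.null(file)) {
    con <- file(file, "w")
    on.exit(close(con))
    for (i in seq_len(n)) {
      rec <- list(id = ids[i], examined = dl_examined[i],
                  visible = dl_visible[[i]], header = header_class[i])
      if (!is.null(vectors)) rec$vector <- unname(vectors[i, ])
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, na = "null"),
                 con)
    }
  }
  idx
}

#' @export
print.annotation_index <- function(x, ...) {
  cat("Annotation index:", length(x$ids), "images;",
      if (is.null(x$vectors)) "no" else ncol(x$vectors),
      "embedding dimensions\n")
  invisible(x)
}

.retrieval_result <- function(ids, scores, provenance) {
  structure(list(ids = ids, scores = scores, provenance = provenance),
            class = "retrieval_result")
}

#' @export
print.retrieval_result <- function(x, ...) {
  cat("Retrieval result:", length(x$ids), "images (sources:",
      paste(unique(unlist(x$provenance)), collapse = "+"), ")\n")
  invisible(x)
}

#' Keyword search over one annotation source
#'
#' Returns the images whose chosen annotation source carries the queried
#' class, in deterministic ascending-id order with score 1 per match.
#' The label may be a SNOMED code or an UKSH abbreviation resolvable
#' through \code{vocab}.
#'
#' @param index an \code{annotation_index}.
#' @param label class to search for.
#' @param source \code{"examined"}, \code{"visible"} or \code{"header"}.
#' @param vocab a \code{body_part_vocab} used to resolve/validate the
#'   label (defaults to the packaged vocabulary).
#' @return a \code{retrieval_result}.
#' @export
keyword_search <- function(index, label,
                           source = c("examined", "visible", "header"),
                           vocab = NULL) {
  stopifnot(inherits(index, "annotation_index"))
  source <- match.arg(source)
  if (is.null(vocab)) vocab <- load_vocabulary()
  code <- if (is.character(label)) {
    i <- match(toupper(label), vocab$classes$ukhs_abbrev)
    if (is.na(i)) stop("label not in vocabulary: ", label)
    vocab$classes$snomed_code[i]
  } else {
    if (!label %in% vocab$classes$snomed_code)
      stop("label not in vocabulary: ", label)
    label
  }
  hit <- switch(source,
    examined = !is.na(index$dl_examined) & index$dl_examined == code,
    header = !is.na(index$header_class) & index$header_class == code,
    visible = vapply(index$dl_visible, function(v) code %in% v, logical(1)))
  ids <- sort(index$ids[hit])
  .retrieval_result(ids, setNames(rep(1, length(ids)), ids),
                    setNames(rep(list(source), length(ids)), ids))
}

#' Cosine-similarity content-based search
#'
#' Ranks indexed embedding vectors by cosine similarity to a reference
#' vector and returns those strictly above the threshold, in descending
#' score order (ties broken by ascending id). The thresholds used in the
#' retrieval study were 0.55 (strict) and 0.3 (permissive).
#'
#' @param index an \code{annotation_index} with vectors.
#' @param reference_vector numeric vector of the indexed length.
#' @param threshold minimal cosine similarity (exclusive).
#' @return a \code{retrieval_result} with cosine scores.
#' @export
cosine_search <- function(index, reference_vector, threshold = 0.55) {
  stopifnot(inherits(index, "annotation_index"))
  if (is.null(index$vectors)) stop("index holds no embedding vectors")
  v <- as.numeric(reference_vector)
  if (length(v) != ncol(index$vectors))
    stop("reference length ", length(v), " does not match index vectors (",
         ncol(index$vectors), ")")
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("zero-norm reference vector")
  norms <- sqrt(rowSums(index$vectors^2))
  if (any(norms == 0)) stop("zero-norm vector stored in index")
  cs <- as.numeric(index$vectors %*% v) / (norms * nv)
  hit <- which(cs > threshold)
  ord <- hit[order(-cs[hit], index$ids[hit])]
  ids <- index$ids[ord]
  .retrieval_result(ids, setNames(cs[ord], ids),
                    setNames(rep(list("cbir"), length(ids)), ids))
}

#' Intersect two retrieval results
#'
#' Annotation-fusion: keeps the images found by both retrieval routes.
#' Complementary error sets cancel — an id wrongly retrieved by only one
#' source drops out — which is the mechanism that lets the DL-header
#' intersection outperform either source alone. Commutative; provenance
#' is unioned and scores are taken from the first argument.
#'
#' @param a,b \code{retrieval_result} objects.
#' @return a \code{retrieval_result} over the common ids (ascending id
#'   order).
#' @export
intersect_results <- function(a, b) {
  stopifnot(inherits(a, "retrieval_result"), inherits(b, "retrieval_result"))
  ids <- sort(intersect(a$ids, b$ids))
  prov <- lapply(ids, function(i)
    unique(c(a$provenance[[i]], b$provenance[[i]])))
  names(prov) <- ids
  .retrieval_result(ids, a$scores[ids], prov)
}

#' Evaluate a retrieval result against ground truth
#'
#' Standard set-retrieval metrics: precision = fraction of retrieved
#' images that are relevant, recall = fraction of relevant images
#' retrieved. When the retrieval universe size \code{n_total} is known,
#' accuracy over the universe ((TP + TN) / N) is reported as well.
#'
#' @param result a \code{retrieval_result} (or character id vector).
#' @param truth_ids character vector of relevant image ids (nonempty).
#' @param n_total optional size of the searched corpus.
#' @return list with \code{precision}, \code{recall}, \code{f1} and
#'   (when \code{n_total} given) \code{accuracy}.
#' @export
evaluate_retrieval <- function(result, truth_ids, n_total = NULL) {
  ids <- if (inherits(result, "retrieval_result")) result$ids else as.character(result)
  truth_ids <- as.character(truth_ids)
  if (!length(truth_ids)) stop("empty ground truth")
  tp <- length(intersect(ids, truth_ids))
  prec <- if (length(ids)) tp / length(ids) else 1
  rec <- tp / length(truth_ids)
  out <- list(precision = prec, recall = rec,
              f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0)
  if (!is.null(n_total)) {
    fp <- length(ids) - tp
    fn <- length(truth_ids) - tp
    out$accuracy <- (n_total - fp - fn) / n_total
  }
  out
}
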