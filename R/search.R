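#' Cosine similarity between two embeddings
#'
#' `dot(u, v) / (||u|| * ||v||)` — symmetric, scale-invariant, in
#' `[-1, 1]`. A zero-norm vector has no direction, so it is rejected rather
#' than silently scored.
#'
#' @param u,v Numeric vectors of equal length.
#' @param accession Optional accession used to identify the offending
#'   document in the degenerate-embedding error.
#' @return A single number in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v, accession = NULL) {
  if (length(u) != length(v)) {
    stop("embedding dimensions differ: ", length(u), " vs ", length(v),
         call. = FALSE)
  }
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("degenerate (all-zero) embedding",
         if (!is.null(accession)) paste0(" for accession ", accession),
         call. = FALSE)
  }
  sum(u * v) / (nu * nv)
}

#' Word-overlap similarity between two cleaned texts
#'
#' The word-counting baseline: the number of unique words the two texts
#' share (set semantics — token multiplicities never matter). Inputs are
#' expected to be cleaned and stop-word filtered already.
#'
#' @param a,b Cleaned text strings.
#' @return Non-negative integer overlap count.
#' @examples
#' word_overlap_similarity("parkinson disease brain",
#'                         "parkinson disease blood")
#' @export
word_overlap_similarity <- function(a, b) {
  length(intersect(text_word_set(a), text_word_set(b)))
}

text_word_set <- function(x) {
  tok <- stringr::str_split_1(stringr::str_squish(x), stringr::fixed(" "))
  unique(tok[nzchar(tok)])
}

# deterministic ranking: score descending, ties by ascending accession
order_ranked <- function(accession, score) {
  order(-score, accession, method = "radix")
}

#' Rank candidate embeddings against a reference embedding
#'
#' Scores every candidate by cosine similarity to the reference and sorts
#' by descending score, breaking ties by ascending accession so that
#' rankings are fully reproducible.
#'
#' @param candidates Numeric matrix of candidate embeddings, one row per
#'   candidate, accession row names.
#' @param reference Numeric vector: the (typically averaged) reference
#'   embedding.
#' @return A tibble with columns `rank`, `accession`, `score`.
#' @export
rank_candidates <- function(candidates, reference) {
  stopifnot(is.matrix(candidates), !is.null(rownames(candidates)))
  if (ncol(candidates) != length(reference)) {
    stop("candidate dimension ", ncol(candidates),
         " does not match reference dimension ", length(reference),
         call. = FALSE)
  }
  if (anyDuplicated(rownames(candidates))) {
    stop("duplicate candidate accession(s)", call. = FALSE)
  }
  scores <- vapply(seq_len(nrow(candidates)), function(i) {
    cosine_similarity(candidates[i, ], reference,
                      accession = rownames(candidates)[i])
  }, numeric(1))
  ord <- order_ranked(rownames(candidates), scores)
  tibble::tibble(rank = seq_along(ord),
                 accession = rownames(candidates)[ord],
                 score = scores[ord])
}

#' Search a corpus by a reference set of known-relevant series
#'
#' The core retrieval step: the embeddings of the reference accessions are
#' averaged into a single query profile, and every other series in the
#' corpus is ranked by cosine similarity to that profile. Reference series
#' are excluded from the output.
#'
#' @param embeddings Numeric matrix of corpus embeddings with accession row
#'   names (see [embed_corpus()]).
#' @param reference_accessions Character vector of known-relevant
#'   accessions; all must be present in the corpus.
#' @return A tibble with columns `rank`, `accession`, `score`.
#' @examples
#' corpus <- generate_corpus(corpus_config(
#'   n_conditions = 2, series_per_condition = 4,
#'   n_background_series = 10, seed = 1))
#' docs <- clean_documents(build_documents(corpus$series))
#' emb <- embed_corpus(docs, hashed_bow_embedder(512, seed = 7))
#' refs <- corpus$annotations$accession[corpus$annotations$condition ==
#'                                        "condition1"][1:2]
#' head(search_by_reference(emb, refs))
#' @export
search_by_reference <- function(embeddings, reference_accessions) {
  stopifnot(is.matrix(embeddings), !is.null(rownames(embeddings)))
  reference_accessions <- unique(reference_accessions)
  if (length(reference_accessions) == 0) {
    stop("at least one reference accession is required", call. = FALSE)
  }
  missing <- setdiff(reference_accessions, rownames(embeddings))
  if (length(missing) > 0) {
    stop("reference accession(s) not in corpus: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  profile <- average_embeddings(
    embeddings[reference_accessions, , drop = FALSE])
  rest <- setdiff(rownames(embeddings), reference_accessions)
  rank_candidates(embeddings[rest, , drop = FALSE], profile)
}

#' Rank candidates by word overlap with a reference set
#'
#' The baseline analogue of [search_by_reference()]. With
#' `rule = "union"` (default) a candidate is scored by its overlap with the
#' union of unique words across all reference documents — mirroring the
#' averaged-embedding profile; with `rule = "pairwise_max"` by its maximum
#' overlap with any single reference document.
#'
#' @param docs Cleaned, stop-word-filtered document tibble (`accession`,
#'   `text`).
#' @param reference_accessions Character vector of reference accessions
#'   present in `docs`.
#' @param rule Multi-reference scoring rule.
#' @return A tibble with columns `rank`, `accession`, `score`.
#' @export
rank_by_word_overlap <- function(docs, reference_accessions,
                                 rule = c("union", "pairwise_max")) {
  rule <- match.arg(rule)
  reference_accessions <- unique(reference_accessions)
  missing <- setdiff(reference_accessions, docs$accession)
  if (length(missing) > 0) {
    stop("reference accession(s) not in corpus: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sets <- lapply(docs$text, text_word_set)
  names(sets) <- docs$accession
  ref_sets <- sets[reference_accessions]
  cand <- setdiff(docs$accession, reference_accessions)
  score <- if (rule == "union") {
    ref_union <- unique(unlist(ref_sets, use.names = FALSE))
    vapply(sets[cand], function(s) length(intersect(s, ref_union)),
           numeric(1))
  } else {
    vapply(sets[cand], function(s) {
      max(vapply(ref_sets, function(r) length(intersect(s, r)), numeric(1)))
    }, numeric(1))
  }
  ord <- order_ranked(cand, score)
  tibble::tibble(rank = seq_along(ord), accession = cand[ord],
                 score = unname(score[ord]))
}

#' Read a reference accession list
#'
#' Accepts the selected-series export format: either one accession per
#' line, or a (possibly tab-separated) table whose first column holds the
#' accessions; a header line whose first field is `accession` and any
#' further columns are ignored. Lines starting with `#` are skipped.
#'
#' @param path Path to the accession list.
#' @return Character vector of unique accessions.
#' @export
read_accession_list <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- stringr::str_trim(lines)
  lines <- lines[nzchar(lines) & !stringr::str_starts(lines, "#")]
  acc <- stringr::str_split_i(lines, "\t", 1)
  acc <- acc[tolower(acc) != "accession"]
  unique(acc)
}

#' Write a ranked list as TSV
#'
#' Columns `rank`, `accession`, `score`, preceded by `#`-prefixed header
#' comments recording provenance (embedder name, chunking flag, seed) when
#' supplied. Deterministic for identical input.
#'
#' @param ranked A ranked tibble (see [rank_candidates()]).
#' @param path Output path.
#' @param embedder_name,chunking,seed Optional provenance fields for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_ranked_list <- function(ranked, path, embedder_name = NULL,
                              chunking = NULL, seed = NULL) {
  header <- c(
    if (!is.null(embedder_name)) paste0("# embedder: ", embedder_name),
    if (!is.null(chunking)) paste0("# chunking: ",
                                   if (isTRUE(chunking)) "true" else "false"),
    if (!is.null(seed)) paste0("# seed: ", seed),
    "rank\taccession\tscore"
  )
  body <- paste(ranked$rank, ranked$accession,
                formatC(ranked$score, format = "g", digits = 17), sep = "\t")
  write_atomic(c(header, body), path)
}
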