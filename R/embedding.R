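# memoised token hashes, keyed by "<seed>\r<token>"; values c(h1, h2)
.hash_cache <- new.env(parent = emptyenv())

# two seeded polynomial hash streams over the token's Unicode code points,
# modulo the Mersenne prime 2^31 - 1; exact in doubles (< 2^53), so
# platform-independent. h1 drives the index, h2 the sign.
token_hashes <- function(token, seed) {
  key <- paste0(seed, "\r", token)
  hit <- get0(key, envir = .hash_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  m <- 2147483647
  h1 <- (seed + 7919) %% m
  h2 <- (seed + 104729) %% m
  for (v in utf8ToInt(token)) {
    h1 <- (h1 * 131 + v) %% m
    h2 <- (h2 * 137 + v) %% m
  }
  out <- c(h1, h2)
  assign(key, out, envir = .hash_cache)
  out
}

#' Hashed bag-of-words embedding
#'
#' A deterministic, training-free embedding backend: each whitespace token
#' of the cleaned text is hashed (with a seeded hash) to a coordinate in
#' `[0, dimension)` and a sign in \{-1, +1\}, and the vector accumulates the
#' signed token counts. Identical `(text, dimension, seed)` always yields
#' identical vectors, word order never matters (bag semantics), and texts
#' over disjoint vocabularies are near-orthogonal at large dimensions. It
#' serves as the package's built-in reference backend; external language
#' models plug in through [embedder()].
#'
#' @param text One cleaned text string (see [clean_text()]).
#' @param dimension Embedding dimension (>= 1).
#' @param seed Integer seed of the token hash.
#' @return Numeric vector of length `dimension`; the zero vector for empty
#'   text.
#' @examples
#' v <- hashed_bow_embed("parkinson disease brain", 64, seed = 7)
#' identical(v, hashed_bow_embed("brain parkinson disease", 64, seed = 7))
#' @export
hashed_bow_embed <- function(text, dimension, seed = 1L) {
  stopifnot(length(text) == 1, dimension >= 1)
  v <- numeric(dimension)
  tokens <- stringr::str_split_1(stringr::str_squish(text), stringr::fixed(" "))
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0) return(v)
  counts <- table(tokens)
  hashes <- vapply(names(counts), token_hashes, numeric(2), seed = seed)
  idx <- (hashes[1, ] %% dimension) + 1
  sign <- ifelse(hashes[2, ] %% 2 == 0, 1, -1)
  contrib <- tapply(sign * as.numeric(counts), idx, sum)
  v[as.integer(names(contrib))] <- contrib
  v
}

#' Embedder specification
#'
#' The one-function embedding contract: a backend maps one cleaned text to
#' a numeric vector of a declared, fixed dimension. The spec also records
#' the per-model preprocessing policy — whether stop words are removed
#' before embedding and whether long texts are chunked and the chunk
#' embeddings averaged.
#'
#' @param name Model name (used in result tables and file headers).
#' @param fn Function of one argument (a cleaned text string) returning a
#'   numeric vector of length `dimension`.
#' @param dimension Declared output dimension (>= 1).
#' @param remove_stopwords Should stop words be removed from documents
#'   before embedding?
#' @param use_chunking Should texts longer than the chunk threshold be split
#'   into overlapping windows and the window embeddings averaged?
#' @return An object of class `embedder`.
#' @seealso [hashed_bow_embedder()], [embed_document()], [embed_corpus()]
#' @export
embedder <- function(name, fn, dimension, remove_stopwords = FALSE,
                     use_chunking = FALSE) {
  stopifnot(is.function(fn), dimension >= 1, nzchar(name))
  structure(
    list(name = name, fn = fn, dimension = as.integer(dimension),
         remove_stopwords = isTRUE(remove_stopwords),
         use_chunking = isTRUE(use_chunking)),
    class = "embedder"
  )
}

#' @export
print.embedder <- function(x, ...) {
  cat("<embedder> ", x$name, " (dimension ", x$dimension,
      if (x$remove_stopwords) ", stop words removed",
      if (x$use_chunking) ", chunked", ")\n", sep = "")
  invisible(x)
}

#' @rdname hashed_bow_embed
#' @param remove_stopwords,use_chunking Preprocessing policy recorded in the
#'   spec; the hashed backend is bag-style, so stop words are removed by
#'   default.
#' @param name Model name; defaults to `"hashed_bow_<dimension>"`.
#' @return `hashed_bow_embedder()` returns an [embedder()] wrapping
#'   `hashed_bow_embed()`.
#' @export
hashed_bow_embedder <- function(dimension = 4096, seed = 1L,
                                remove_stopwords = TRUE,
                                use_chunking = FALSE,
                                name = paste0("hashed_bow_", dimension)) {
  force(dimension); force(seed)
  embedder(name = name,
           fn = function(text) hashed_bow_embed(text, dimension, seed),
           dimension = dimension,
           remove_stopwords = remove_stopwords,
           use_chunking = use_chunking)
}

#' Embed one document
#'
#' Applies the embedder to the whole text, or — when the embedder's
#' chunking policy is on and the text exceeds `chunk_threshold` — embeds
#' each overlapping window from [chunk_text()] and returns the unweighted
#' component-wise mean of the window embeddings.
#'
#' @param text One cleaned text string.
#' @param embedder An [embedder()] object.
#' @param chunk_size,chunk_overlap,chunk_threshold Chunking parameters (see
#'   [chunk_text()]).
#' @return Numeric vector of length `embedder$dimension`.
#' @export
embed_document <- function(text, embedder, chunk_size = 256,
                           chunk_overlap = 20, chunk_threshold = 256) {
  stopifnot(inherits(embedder, "embedder"))
  embed_one <- function(txt) {
    v <- embedder$fn(txt)
    if (!is.numeric(v) || length(v) != embedder$dimension) {
      stop("backend '", embedder$name, "' returned a vector of length ",
           length(v), ", not its declared dimension ", embedder$dimension,
           call. = FALSE)
    }
    if (any(!is.finite(v))) {
      stop("backend '", embedder$name, "' returned non-finite values",
           call. = FALSE)
    }
    as.numeric(v)
  }
  if (embedder$use_chunking && nchar(text) > chunk_threshold) {
    chunks <- chunk_text(text, size = chunk_size, overlap = chunk_overlap,
                         threshold = chunk_threshold)
    pieces <- lapply(chunk_substrings(text, chunks), embed_one)
    average_embeddings(pieces)
  } else {
    embed_one(text)
  }
}

#' Embed a corpus of documents
#'
#' @param docs A cleaned document tibble with columns `accession` and
#'   `text` (see [clean_documents()]).
#' @inheritParams embed_document
#' @return A numeric matrix, one row per document, row names the
#'   accessions, `embedder$dimension` columns.
#' @export
embed_corpus <- function(docs, embedder, chunk_size = 256,
                         chunk_overlap = 20, chunk_threshold = 256) {
  mat <- t(vapply(docs$text, embed_document, numeric(embedder$dimension),
                  embedder = embedder, chunk_size = chunk_size,
                  chunk_overlap = chunk_overlap,
                  chunk_threshold = chunk_threshold, USE.NAMES = FALSE))
  rownames(mat) <- docs$accession
  mat
}

#' Average a set of embeddings
#'
#' Component-wise arithmetic mean — used both for chunk embeddings within a
#' document and for the reference-set profile that defines a query.
#'
#' @param x A list of equal-length numeric vectors, or a numeric matrix
#'   with one embedding per row.
#' @return Numeric vector: the component-wise mean.
#' @export
average_embeddings <- function(x) {
  if (is.list(x)) {
    if (length(x) == 0) stop("cannot average zero embeddings", call. = FALSE)
    dims <- lengths(x)
    if (length(unique(dims)) != 1) {
      stop("embeddings have mixed dimensions: ",
           paste(unique(dims), collapse = ", "), call. = FALSE)
    }
    x <- do.call(rbind, x)
  }
  stopifnot(is.matrix(x))
  if (nrow(x) == 0) stop("cannot average zero embeddings", call. = FALSE)
  colMeans(x)
}

#' Read and write embedding matrices
#'
#' The on-disk store is a plain TSV: one row per document, first column
#' `accession`, remaining columns the embedding coordinates. Writers emit
#' UTF-8 and full double precision, so a write/read round trip is exact.
#'
#' @param embeddings Numeric matrix with accession row names (see
#'   [embed_corpus()]).
#' @param path File path.
#' @return `write_embeddings()` returns `path` invisibly;
#'   `read_embeddings()` returns the matrix.
#' @export
write_embeddings <- function(embeddings, path) {
  stopifnot(is.matrix(embeddings), !is.null(rownames(embeddings)))
  lines <- paste(rownames(embeddings),
                 apply(embeddings, 1, function(r) {
                   paste(formatC(r, format = "g", digits = 17),
                         collapse = "\t")
                 }),
                 sep = "\t")
  write_atomic(c(paste0("accession\t",
                        paste0("d", seq_len(ncol(embeddings)),
                               collapse = "\t")),
                 lines), path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    accession = "c", .default = "d"), progress = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab$accession
  colnames(mat) <- NULL
  mat
}
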