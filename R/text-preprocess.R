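#' Assemble one document per series
#'
#' Joins each series' title, summary, and overall design (when available),
#' in that order, with single spaces — the text that is subsequently
#' cleaned and embedded.
#'
#' @param series A series tibble (see [read_series_metadata()]).
#' @return A tibble with columns `accession` and `text` (raw, uncleaned).
#' @export
build_documents <- function(series) {
  text <- purrr::pmap_chr(
    series[c("title", "summary", "overall_design")],
    function(title, summary, overall_design) {
      parts <- c(title, summary,
                 if (!is.na(overall_design)) overall_design)
      paste(parts, collapse = " ")
    }
  )
  tibble::tibble(accession = series$accession, text = text)
}

#' Clean free text for embedding
#'
#' Applies, in this fixed order: HTML tag stripping, URL removal
#' (scheme-prefixed `http`/`https`/`ftp` tokens and `www.`-prefixed tokens),
#' lowercasing, replacement of every non-alphanumeric character by a space
#' (so `"T-cells"` becomes `"t cells"`, preserving word boundaries),
#' collapsing of whitespace runs, trimming, and — when `remove_stopwords` is
#' true — dropping whitespace tokens found in `stopwords`. Alphanumeric is
#' decided by Unicode category (letters and digits), so accented names
#' survive cleaning. The result is idempotent: cleaning cleaned text is a
#' no-op.
#'
#' @param x Character vector of raw texts.
#' @param remove_stopwords Drop stop-word tokens after cleaning? Bag-style
#'   models (word overlap, hashed bag-of-words) typically set this; models
#'   that use sentence context typically do not.
#' @param stopwords Character vector of lowercase stop words (see
#'   [default_stopwords()]).
#' @return Character vector of cleaned texts.
#' @examples
#' clean_text("<b>RNA-Seq</b> of T-cells! see http://x.example/a")
#' clean_text("study of the brain", remove_stopwords = TRUE,
#'            stopwords = c("of", "the"))
#' @export
clean_text <- function(x, remove_stopwords = FALSE, stopwords = character()) {
  x <- stringr::str_replace_all(x, "<[^>]*>", " ")
  x <- stringr::str_replace_all(
    x,
    stringr::regex("(?:\\b(?:https?|ftp)://|\\bwww\\.)\\S*", ignore_case = TRUE),
    " "
  )
  x <- stringr::str_to_lower(x)
  x <- stringr::str_replace_all(x, "[^\\p{L}\\p{N}]+", " ")
  x <- stringr::str_squish(x)
  if (remove_stopwords && length(stopwords) > 0) {
    x <- purrr::map_chr(stringr::str_split(x, stringr::fixed(" ")),
                        function(tok) {
                          tok <- tok[nzchar(tok) & !(tok %in% stopwords)]
                          paste(tok, collapse = " ")
                        })
  }
  x
}

#' Clean a document table
#'
#' Applies [clean_text()] to the `text` column and records the cleaned
#' character count.
#'
#' @param docs Tibble with columns `accession` and `text` (see
#'   [build_documents()]).
#' @inheritParams clean_text
#' @return A tibble with columns `accession`, `text`, `char_count`.
#' @export
clean_documents <- function(docs, remove_stopwords = FALSE,
                            stopwords = character()) {
  cleaned <- clean_text(docs$text, remove_stopwords = remove_stopwords,
                        stopwords = stopwords)
  tibble::tibble(accession = docs$accession, text = cleaned,
                 char_count = nchar(cleaned))
}

#' Default English stop-word list
#'
#' Reads the package's bundled plain-text stop-word list (one lowercase word
#' per line). Any list in that format can be supplied instead through
#' [read_stopwords()].
#'
#' @return Character vector of stop words.
#' @export
default_stopwords <- function() {
  read_stopwords(system.file("extdata", "stopwords-english.txt",
                             package = "seriesfinder", mustWork = TRUE))
}

#' @rdname default_stopwords
#' @param path Path to a stop-word file, one word per line, UTF-8.
#' @export
read_stopwords <- function(path) {
  words <- readLines(path, warn = FALSE, encoding = "UTF-8")
  words <- stringr::str_trim(words)
  unique(words[nzchar(words)])
}

#' Split cleaned text into overlapping character windows
#'
#' Texts of at most `threshold` characters form a single chunk covering the
#' whole text. Longer texts are covered by windows of `size` characters
#' whose starts advance by `size - overlap`, so consecutive windows share
#' exactly `overlap` characters; the final window is truncated at the text
#' end, and generation stops as soon as a window reaches the end.
#'
#' @param text One cleaned text string.
#' @param size Window length in characters.
#' @param overlap Characters shared by consecutive windows; must be smaller
#'   than `size`.
#' @param threshold Maximum length embedded whole, without chunking.
#' @return A tibble of half-open 0-based character intervals, columns
#'   `start` and `end`.
#' @examples
#' chunk_text(strrep("a", 500))  # (0,256), (236,492), (472,500)
#' @export
chunk_text <- function(text, size = 256, overlap = 20, threshold = 256) {
  stopifnot(length(text) == 1, !is.na(text))
  if (overlap >= size) {
    stop("chunk overlap (", overlap, ") must be smaller than chunk size (",
         size, ")", call. = FALSE)
  }
  n <- nchar(text)
  if (n <= threshold) {
    return(tibble::tibble(start = 0L, end = as.integer(n)))
  }
  step <- size - overlap
  starts <- 0L
  repeat {
    last_end <- min(starts[length(starts)] + size, n)
    if (last_end >= n) break
    starts <- c(starts, starts[length(starts)] + step)
  }
  tibble::tibble(start = as.integer(starts),
                 end = as.integer(pmin(starts + size, n)))
}

#' Extract the chunk substrings of a text
#'
#' @param text The cleaned text that was chunked.
#' @param chunks A chunk table from [chunk_text()].
#' @return Character vector of chunk substrings, in order.
#' @export
chunk_substrings <- function(text, chunks) {
  stringr::str_sub(text, chunks$start + 1L, chunks$end)
}
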