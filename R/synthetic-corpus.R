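#' Configuration for the synthetic condition-annotated corpus
#'
#' The generator emulates a repository of condition-annotated series for
#' end-to-end testing without any downloads. Each condition has its own
#' vocabulary, disjoint from every other condition's and from a shared
#' background vocabulary; condition series draw each token from their
#' condition vocabulary with probability `signal` and from the background
#' otherwise, while background series draw all tokens from the background.
#' Summary lengths are drawn uniformly from `length_range` so that
#' documents fall on both sides of the 256-character chunking threshold.
#'
#' An optional near-miss mode adds one confuser condition per real
#' condition whose vocabulary shares a fraction of words with its target —
#' emulating clinically overlapping conditions (e.g. mood disorders) that
#' are the characteristic failure mode of lexical retrieval.
#'
#' @param n_conditions Number of annotated conditions.
#' @param series_per_condition Series per condition; a single value is
#'   recycled to `n_conditions`.
#' @param n_background_series Series annotated to no condition.
#' @param background_vocab_size,condition_vocab_size Urn sizes (distinct
#'   words).
#' @param signal Probability, in `[0, 1]`, that a token of a condition
#'   series comes from the condition vocabulary. 0 makes condition series
#'   indistinguishable from background; 1 makes them perfectly separable.
#' @param length_range Two integers: the inclusive range of summary token
#'   counts.
#' @param p_design_absent Probability that a series has no overall-design
#'   text (exercising the absent-field path).
#' @param near_miss Add confuser conditions?
#' @param near_miss_overlap Fraction of a confuser's vocabulary shared with
#'   its target condition.
#' @param seed Integer seed; generation is fully deterministic given the
#'   config.
#' @return An object of class `corpus_config`.
#' @export
corpus_config <- function(n_conditions = 6,
                          series_per_condition = 12,
                          n_background_series = 500,
                          background_vocab_size = 2000,
                          condition_vocab_size = 50,
                          signal = 0.75,
                          length_range = c(15, 60),
                          p_design_absent = 0.2,
                          near_miss = FALSE,
                          near_miss_overlap = 0.5,
                          seed = 1L) {
  series_per_condition <- rep_len(as.integer(series_per_condition),
                                  n_conditions)
  stopifnot(n_conditions >= 1, all(series_per_condition >= 1),
            n_background_series >= 0, background_vocab_size >= 1,
            condition_vocab_size >= 1,
            signal >= 0, signal <= 1,
            length(length_range) == 2,
            length_range[1] >= 1, length_range[1] <= length_range[2],
            p_design_absent >= 0, p_design_absent <= 1,
            near_miss_overlap >= 0, near_miss_overlap <= 1)
  structure(
    list(n_conditions = as.integer(n_conditions),
         series_per_condition = series_per_condition,
         n_background_series = as.integer(n_background_series),
         background_vocab_size = as.integer(background_vocab_size),
         condition_vocab_size = as.integer(condition_vocab_size),
         signal = signal,
         length_range = as.integer(length_range),
         p_design_absent = p_design_absent,
         near_miss = isTRUE(near_miss),
         near_miss_overlap = near_miss_overlap,
         seed = as.integer(seed)),
    class = "corpus_config"
  )
}

#' Generate a synthetic condition-annotated corpus
#'
#' Deterministic for a fixed config: the same config yields byte-identical
#' serialized output. All generated series carry metadata that passes the
#' default inclusion criteria (human, array, known vendor, not retired,
#' not a SubSeries), so the corpus flows through the whole pipeline.
#'
#' @param config A [corpus_config()].
#' @return A list with `series` (a series tibble, accessions `SYNnnnnn`)
#'   and `annotations` (tibble of `condition`, `accession`).
#' @examples
#' corpus <- generate_corpus(corpus_config(
#'   n_conditions = 2, series_per_condition = 3,
#'   n_background_series = 4, seed = 42))
#' corpus$annotations
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "corpus_config"))
  withr::with_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(config) {
  background_vocab <- sprintf("bg%05d", seq_len(config$background_vocab_size))
  conditions <- sprintf("condition%d", seq_len(config$n_conditions))
  condition_vocab <- lapply(seq_len(config$n_conditions), function(i) {
    sprintf("c%02dw%04d", i, seq_len(config$condition_vocab_size))
  })
  names(condition_vocab) <- conditions

  counts <- config$series_per_condition
  if (config$near_miss) {
    # confusers reuse a slice of the target vocabulary plus private words
    n_shared <- round(config$near_miss_overlap * config$condition_vocab_size)
    confuser_vocab <- lapply(seq_len(config$n_conditions), function(i) {
      c(utils::head(condition_vocab[[i]], n_shared),
        sprintf("x%02dw%04d", i,
                seq_len(config$condition_vocab_size - n_shared)))
    })
    names(confuser_vocab) <- sprintf("condition%d_confuser",
                                     seq_len(config$n_conditions))
    condition_vocab <- c(condition_vocab, confuser_vocab)
    conditions <- names(condition_vocab)
    counts <- c(counts, config$series_per_condition)
  }
  overlap_free <- !config$near_miss
  if (overlap_free &&
      anyDuplicated(c(background_vocab, unlist(condition_vocab)))) {
    stop("internal error: vocabularies overlap", call. = FALSE)
  }

  draw_tokens <- function(n, vocab, signal) {
    from_cond <- stats::runif(n) < signal
    tokens <- character(n)
    tokens[from_cond] <- sample(vocab, sum(from_cond), replace = TRUE)
    tokens[!from_cond] <- sample(background_vocab, sum(!from_cond),
                                 replace = TRUE)
    tokens
  }
  make_series <- function(accession, vocab, signal) {
    n_title <- sample(3:6, 1)
    n_summary <- sample(config$length_range[1]:config$length_range[2], 1)
    design_absent <- stats::runif(1) < config$p_design_absent
    n_design <- if (design_absent) 0L else sample(5:15, 1)
    new_series_tibble(
      accession = accession,
      title = paste(draw_tokens(n_title, vocab, signal), collapse = " "),
      summary = paste(draw_tokens(n_summary, vocab, signal), collapse = " "),
      overall_design = if (design_absent) NA_character_ else
        paste(draw_tokens(n_design, vocab, signal), collapse = " "),
      organisms = list("Homo sapiens"),
      experiment_types = list("expression profiling by array"),
      platform_vendor = "Affymetrix",
      is_retired = FALSE,
      is_subseries = FALSE
    )
  }

  rows <- list()
  ann <- list()
  k <- 0L
  for (i in seq_along(conditions)) {
    for (j in seq_len(counts[i])) {
      k <- k + 1L
      acc <- sprintf("SYN%05d", k)
      rows[[k]] <- make_series(acc, condition_vocab[[i]], config$signal)
      ann[[k]] <- tibble::tibble(condition = conditions[i], accession = acc)
    }
  }
  for (j in seq_len(config$n_background_series)) {
    k <- k + 1L
    rows[[k]] <- make_series(sprintf("SYN%05d", k), background_vocab, 0)
  }
  list(series = dplyr::bind_rows(rows), annotations = dplyr::bind_rows(ann))
}

#' Write a synthetic corpus to disk
#'
#' Emits the canonical JSON metadata dialect and the annotation TSV — the
#' formats consumed by [read_series_metadata()] and [read_annotations()].
#'
#' @param corpus A list as returned by [generate_corpus()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the two file paths, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  series_path <- file.path(dir, "series.json")
  ann_path <- file.path(dir, "annotations.tsv")
  write_series_json(corpus$series, series_path)
  write_annotations(corpus$annotations, ann_path)
  invisible(c(series = series_path, annotations = ann_path))
}
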