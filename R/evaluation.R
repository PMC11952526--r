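#' Split a condition's series into reference and comparison sets
#'
#' Randomly partitions the condition-annotated accessions into a reference
#' set and a comparison set A of (near-)equal size: with an even count the
#' two halves are the same size, with an odd count the reference set gets
#' the extra member. The partition is uniformly random under the seed and
#' fully reproducible.
#'
#' @param accessions Character vector (a set) of condition-annotated
#'   accessions; at least 2, otherwise the comparison set would be empty.
#' @param seed Integer seed.
#' @return A list with sorted character vectors `reference` and
#'   `comparison_a`.
#' @examples
#' split_condition_sets(sprintf("GSE%02d", 1:12), seed = 1)
#' @export
split_condition_sets <- function(accessions, seed) {
  accessions <- sort(unique(accessions))
  n <- length(accessions)
  if (n < 2) {
    stop("need at least 2 accessions to split (got ", n, ")", call. = FALSE)
  }
  n_ref <- ceiling(n / 2)
  ref_idx <- withr::with_seed(seed, sample.int(n, n_ref))
  list(reference = accessions[sort(ref_idx)],
       comparison_a = accessions[setdiff(seq_len(n), ref_idx)])
}

#' Build the non-relevant comparison pool
#'
#' Comparison set B: every evaluated series not annotated to the condition
#' (including series annotated to other conditions).
#'
#' @param all_accessions Character vector of all accessions in the
#'   evaluated corpus.
#' @param condition_accessions Accessions annotated to the condition; must
#'   all be members of `all_accessions`.
#' @return Sorted character vector, disjoint from `condition_accessions`.
#' @export
build_comparison_pool <- function(all_accessions, condition_accessions) {
  all_accessions <- unique(all_accessions)
  condition_accessions <- unique(condition_accessions)
  missing <- setdiff(condition_accessions, all_accessions)
  if (length(missing) > 0) {
    stop("condition accession(s) not in the evaluated corpus: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sort(setdiff(all_accessions, condition_accessions))
}

#' Subsample the comparison pool to a target imbalance ratio
#'
#' An imbalance ratio of r means the non-relevant pool has r times as many
#' series as the relevant test set (comparison set A); the sentinel
#' `"all"` keeps the full pool. Sizes are rounded half-to-even.
#'
#' @param pool Character vector: the comparison pool (see
#'   [build_comparison_pool()]).
#' @param ratio Positive number, or the string `"all"`.
#' @param a_size Size of comparison set A.
#' @param seed Integer seed.
#' @return Sorted character vector of `round(ratio * a_size)` accessions
#'   drawn uniformly without replacement (or the full pool for `"all"`).
#' @export
subsample_imbalance <- function(pool, ratio, a_size, seed) {
  if (identical(ratio, "all")) return(sort(pool))
  ratio <- as.numeric(ratio)
  stopifnot(is.finite(ratio), ratio > 0, a_size >= 1)
  size <- round(ratio * a_size)
  if (size > length(pool)) {
    stop("imbalance ratio ", ratio, " needs ", size, " series but the pool",
         " has only ", length(pool), " (maximum feasible ratio ",
         format(length(pool) / a_size), ")", call. = FALSE)
  }
  sort(withr::with_seed(seed, sample(pool, size)))
}

#' Average precision of a ranked binary label sequence
#'
#' The area under the precision-recall curve computed as average precision:
#' the mean, over the positions of the positive labels, of precision at
#' that position. Exact for ranked binary labels, 1.0 when all positives
#' are ranked first.
#'
#' @param ranked_labels Binary (0/1 or logical) labels in rank order, best
#'   first; at least one positive (the metric is undefined otherwise).
#' @return A number in `(0, 1]`.
#' @examples
#' average_precision(c(1, 0, 1))  # (1/1 + 2/3) / 2
#' @export
average_precision <- function(ranked_labels) {
  labels <- check_binary_labels(ranked_labels)
  cum_pos <- cumsum(labels)
  mean((cum_pos / seq_along(labels))[labels == 1])
}

check_binary_labels <- function(ranked_labels) {
  labels <- as.integer(ranked_labels)
  if (length(labels) == 0 || any(is.na(labels)) || !all(labels %in% 0:1)) {
    stop("ranked_labels must be a non-empty binary (0/1) sequence",
         call. = FALSE)
  }
  if (sum(labels) == 0) {
    stop("average precision is undefined with zero positive labels",
         call. = FALSE)
  }
  labels
}

#' Recall within the top n of a ranking
#'
#' The fraction of all positives that appear among the first `n` ranked
#' items; 1.0 means every relevant series was retrieved in the top n.
#'
#' @inheritParams average_precision
#' @param n Positive cutoff, at most the list length.
#' @return A number in `[0, 1]`, non-decreasing in `n`.
#' @export
recall_at_n <- function(ranked_labels, n) {
  labels <- check_binary_labels(ranked_labels)
  stopifnot(length(n) == 1, n >= 1)
  if (n > length(labels)) {
    stop("n (", n, ") exceeds the ranking length (", length(labels), ")",
         call. = FALSE)
  }
  sum(labels[seq_len(n)]) / sum(labels)
}

#' Expected average precision of a uniformly random ranking
#'
#' Closed form for the expectation of [average_precision()] when
#' `n_pos` positives are placed uniformly at random among `n_total` ranked
#' items: conditioning on a positive at rank k, the other positives are
#' uniform over the remaining positions, giving
#' `E[AP] = (1/n_total) * sum_k (1 + (k-1)(n_pos-1)/(n_total-1)) / k`.
#' This is the calibration target for random-ranking checks; it exceeds the
#' positive prevalence `n_pos / n_total` by O(log(n)/n).
#'
#' @param n_total Total number of ranked items (>= 1).
#' @param n_pos Number of positives (1..n_total).
#' @return The exact expectation, a number in `(0, 1]`.
#' @export
expected_random_ap <- function(n_total, n_pos) {
  stopifnot(n_total >= 1, n_pos >= 1, n_pos <= n_total)
  if (n_total == 1) return(1)
  k <- seq_len(n_total)
  sum((1 + (k - 1) * (n_pos - 1) / (n_total - 1)) / k) / n_total
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (midranks for ties); a validated
#' front end over [stats::cor()].
#'
#' @param x,y Numeric vectors of equal length, at least 3.
#' @return A number in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not supported", call. = FALSE)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    stop("rank correlation is undefined for a constant sequence",
         call. = FALSE)
  }
  stats::cor(x, y, method = "spearman")
}

#' Cross-condition model ranking by median rank
#'
#' Within each condition, models are ranked by descending AUPRC (midranks
#' for ties); each model is then summarised by its median rank across
#' conditions, and models are ordered by ascending median rank (ties by
#' model name). Low median rank = consistently strong across conditions.
#'
#' @param auprc_table A data frame with columns `model`, `condition`,
#'   `auprc` — exactly one row per (model, condition) cell.
#' @return A tibble with columns `model` and `median_rank`, ordered best
#'   first.
#' @export
median_rank_table <- function(auprc_table) {
  stopifnot(all(c("model", "condition", "auprc") %in% names(auprc_table)))
  models <- unique(auprc_table$model)
  conditions <- unique(auprc_table$condition)
  cells <- tidyr::expand_grid(model = models, condition = conditions)
  have <- dplyr::count(auprc_table, .data$model, .data$condition)
  check <- dplyr::left_join(cells, have, by = c("model", "condition"))
  bad <- dplyr::filter(check, is.na(.data$n) | .data$n != 1)
  if (nrow(bad) > 0) {
    stop("need exactly one AUPRC per (model, condition); offending cell: (",
         bad$model[1], ", ", bad$condition[1], ")", call. = FALSE)
  }
  auprc_table |>
    dplyr::group_by(.data$condition) |>
    dplyr::mutate(cond_rank = rank(-.data$auprc, ties.method = "average")) |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(median_rank = stats::median(.data$cond_rank),
                     .groups = "drop") |>
    dplyr::arrange(.data$median_rank, .data$model)
}

#' Read and write condition annotation tables
#'
#' A two-column TSV (`condition`, `accession`), one annotated series per
#' row — the ground-truth labels for evaluation.
#'
#' @param path File path.
#' @return `read_annotations()` returns a tibble with columns `condition`
#'   and `accession`.
#' @export
read_annotations <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("condition", "accession") %in% names(tab))) {
    stop("annotation file must have columns condition and accession",
         call. = FALSE)
  }
  tibble::as_tibble(tab[c("condition", "accession")])
}

#' @rdname read_annotations
#' @param annotations A tibble with columns `condition` and `accession`.
#' @export
write_annotations <- function(annotations, path) {
  write_atomic(c("condition\taccession",
                 paste(annotations$condition, annotations$accession,
                       sep = "\t")), path)
}

# normalize an imbalance-ratio specification: strictly increasing numeric
# ratios, optional trailing "all"
normalize_ratios <- function(ratios) {
  ratios <- as.list(ratios)
  is_all <- vapply(ratios, function(r) identical(r, "all"), logical(1))
  if (any(is_all[-length(is_all)])) {
    stop('"all" must come last in the ratio list', call. = FALSE)
  }
  nums <- suppressWarnings(as.numeric(unlist(ratios[!is_all])))
  if (anyNA(nums) || any(nums <= 0)) {
    stop('ratios must be positive numbers, optionally followed by "all"',
         call. = FALSE)
  }
  if (is.unsorted(nums, strictly = TRUE)) {
    stop("numeric ratios must be strictly increasing", call. = FALSE)
  }
  c(as.list(nums), if (any(is_all)) list("all"))
}

# deterministic 31-bit sub-seed from a base seed and string labels
derive_seed <- function(seed, ...) {
  m <- 2147483647
  h <- seed %% m
  for (part in c(...)) {
    for (v in utf8ToInt(as.character(part))) h <- (h * 131 + v) %% m
  }
  as.integer(h)
}

default_recall_grid <- function(len) {
  sort(unique(pmin(c(1, 2, 3, 5, 10, 20, 50, 100, 200, 500, 1000, len),
                   len)))
}

#' Benchmark retrieval models on a condition-annotated corpus
#'
#' Runs the full evaluation design. For every condition and seed, the
#' condition's series are split into a reference set and comparison set A
#' ([split_condition_sets()]); all remaining corpus series form comparison
#' set B ([build_comparison_pool()]), subsampled to each requested
#' imbalance ratio ([subsample_imbalance()]) — one subsample per
#' (condition, ratio, seed), shared across models so models face identical
#' candidates. Each model ranks comparison sets A and B together against
#' the averaged reference profile, and the ranking is scored by average
#' precision and a recall-at-n curve.
#'
#' @param series A series tibble (see [read_series_metadata()],
#'   [generate_corpus()]).
#' @param annotations Tibble with columns `condition` and `accession`; all
#'   accessions must be present in `series`.
#' @param models A single model or a list of models: [embedder()] objects
#'   and/or [word_overlap_model()].
#' @param seeds Integer vector of split seeds; each seed is one replicate
#'   of the random reference/comparison split.
#' @param ratios Imbalance ratios — positive numbers in increasing order,
#'   optionally ending with `"all"` (the full pool).
#' @param stopwords Stop-word list applied for models whose spec removes
#'   stop words.
#' @param chunk_size,chunk_overlap,chunk_threshold Chunking parameters for
#'   models whose spec chunks long texts.
#' @param recall_at Integer cutoffs for the recall curve; default is a
#'   logarithmic grid up to the ranking length.
#' @return A `retrieval_eval` object: a list with `results` (tibble of
#'   `model`, `condition`, `seed`, `imbalance_ratio`, `n_candidates`,
#'   `auprc`), `recall` (tibble of `model`, `condition`, `seed`,
#'   `imbalance_ratio`, `n`, `recall`), and `params`. Use [tidy()],
#'   [glance()], [ggplot2::autoplot()].
#' @examples
#' corpus <- generate_corpus(corpus_config(
#'   n_conditions = 2, series_per_condition = 6,
#'   n_background_series = 30, seed = 1))
#' ev <- evaluate_retrieval(corpus$series, corpus$annotations,
#'                          models = hashed_bow_embedder(512, seed = 7),
#'                          seeds = 1:2, ratios = list(1, "all"))
#' tidy(ev)
#' @export
evaluate_retrieval <- function(series, annotations, models,
                               seeds = 1L, ratios = list(1, 10, "all"),
                               stopwords = default_stopwords(),
                               chunk_size = 256, chunk_overlap = 20,
                               chunk_threshold = 256, recall_at = NULL) {
  if (inherits(models, "embedder") || inherits(models, "overlap_model")) {
    models <- list(models)
  }
  model_names <- vapply(models, function(m) m$name, character(1))
  if (anyDuplicated(model_names)) {
    stop("model names must be unique", call. = FALSE)
  }
  missing <- setdiff(annotations$accession, series$accession)
  if (length(missing) > 0) {
    stop("annotated accession(s) not in corpus: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  ratios <- normalize_ratios(ratios)
  docs_raw <- build_documents(series)

  # per-model document preparation (stop-word policy), then embeddings
  prepared <- lapply(models, function(m) {
    docs <- clean_documents(docs_raw, remove_stopwords = m$remove_stopwords,
                            stopwords = stopwords)
    if (inherits(m, "embedder")) {
      list(model = m,
           embeddings = embed_corpus(docs, m, chunk_size = chunk_size,
                                     chunk_overlap = chunk_overlap,
                                     chunk_threshold = chunk_threshold))
    } else {
      sets <- lapply(docs$text, text_word_set)
      names(sets) <- docs$accession
      list(model = m, word_sets = sets)
    }
  })
  names(prepared) <- model_names

  conditions <- sort(unique(annotations$condition))
  all_acc <- series$accession
  results <- list()
  recalls <- list()

  for (condition in conditions) {
    cond_acc <- annotations$accession[annotations$condition == condition]
    pool <- build_comparison_pool(all_acc, cond_acc)
    for (seed in seeds) {
      split <- split_condition_sets(cond_acc,
                                    seed = derive_seed(seed, condition))
      a_size <- length(split$comparison_a)
      for (ratio in ratios) {
        sub_b <- subsample_imbalance(pool, ratio, a_size,
                                     seed = derive_seed(seed, condition,
                                                        format(ratio)))
        candidates <- c(split$comparison_a, sub_b)
        ratio_label <- if (identical(ratio, "all")) "all" else format(ratio)
        for (nm in model_names) {
          ranked <- rank_model_candidates(prepared[[nm]], split$reference,
                                          candidates)
          labels <- as.integer(ranked$accession %in% split$comparison_a)
          grid <- recall_at %||% default_recall_grid(length(labels))
          grid <- grid[grid <= length(labels)]
          results[[length(results) + 1L]] <- tibble::tibble(
            model = nm, condition = condition, seed = seed,
            imbalance_ratio = ratio_label,
            n_candidates = length(labels),
            auprc = average_precision(labels))
          recalls[[length(recalls) + 1L]] <- tibble::tibble(
            model = nm, condition = condition, seed = seed,
            imbalance_ratio = ratio_label, n = as.integer(grid),
            recall = vapply(grid, recall_at_n, numeric(1),
                            ranked_labels = labels))
        }
      }
    }
  }

  structure(
    list(results = dplyr::bind_rows(results),
         recall = dplyr::bind_rows(recalls),
         params = list(models = model_names, seeds = seeds,
                       ratios = vapply(ratios, format, character(1)),
                       chunk_size = chunk_size, chunk_overlap = chunk_overlap,
                       chunk_threshold = chunk_threshold,
                       metric = "average_precision")),
    class = "retrieval_eval"
  )
}

# rank a fixed candidate subset for one prepared model
rank_model_candidates <- function(prep, reference, candidates) {
  if (inherits(prep$model, "embedder")) {
    profile <- average_embeddings(
      prep$embeddings[reference, , drop = FALSE])
    rank_candidates(prep$embeddings[candidates, , drop = FALSE], profile)
  } else {
    score <- overlap_scores(prep$word_sets, reference, candidates,
                            rule = prep$model$rule)
    ord <- order_ranked(candidates, score)
    tibble::tibble(rank = seq_along(ord), accession = candidates[ord],
                   score = score[ord])
  }
}

overlap_scores <- function(word_sets, reference, candidates, rule) {
  ref_sets <- word_sets[reference]
  if (rule == "union") {
    ref_union <- unique(unlist(ref_sets, use.names = FALSE))
    vapply(word_sets[candidates],
           function(s) length(intersect(s, ref_union)), numeric(1),
           USE.NAMES = FALSE)
  } else {
    vapply(word_sets[candidates], function(s) {
      max(vapply(ref_sets, function(r) length(intersect(s, r)), numeric(1)))
    }, numeric(1), USE.NAMES = FALSE)
  }
}

#' Word-overlap baseline model for the evaluation harness
#'
#' Wraps the word-counting baseline in the same model contract as
#' [embedder()] objects, so it can be benchmarked alongside embedding
#' models in [evaluate_retrieval()]. Stop words are removed by spec.
#'
#' @param rule Multi-reference scoring rule (see [rank_by_word_overlap()]).
#' @param name Model name.
#' @return An object of class `overlap_model`.
#' @export
word_overlap_model <- function(rule = c("union", "pairwise_max"),
                               name = "word_overlap") {
  structure(list(name = name, rule = match.arg(rule),
                 remove_stopwords = TRUE, use_chunking = FALSE),
            class = "overlap_model")
}

#' @export
print.retrieval_eval <- function(x, ...) {
  cat("<retrieval_eval> ", length(x$params$models), " model(s), ",
      length(unique(x$results$condition)), " condition(s), ",
      length(x$params$seeds), " seed(s), ratios ",
      paste(x$params$ratios, collapse = ", "), "\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' Tidy a retrieval evaluation
#'
#' @param x A `retrieval_eval` object.
#' @param ... Unused.
#' @return One row per (model, condition, seed, imbalance ratio) with the
#'   AUPRC and candidate count.
#' @method tidy retrieval_eval
#' @export
tidy.retrieval_eval <- function(x, ...) {
  x$results
}

#' @rdname tidy.retrieval_eval
#' @return `glance()` returns a one-row summary: counts and the mean and
#'   median AUPRC over all evaluation cells.
#' @method glance retrieval_eval
#' @export
glance.retrieval_eval <- function(x, ...) {
  tibble::tibble(
    n_models = length(x$params$models),
    n_conditions = length(unique(x$results$condition)),
    n_seeds = length(x$params$seeds),
    n_ratios = length(x$params$ratios),
    mean_auprc = mean(x$results$auprc),
    median_auprc = stats::median(x$results$auprc)
  )
}

#' Write evaluation results
#'
#' Two TSVs: the AUPRC results table and a companion recall-curve table.
#'
#' @param x A `retrieval_eval` object.
#' @param results_path,recall_path Output paths.
#' @return `results_path`, invisibly.
#' @export
write_evaluation <- function(x, results_path, recall_path) {
  stopifnot(inherits(x, "retrieval_eval"))
  r <- x$results
  write_atomic(c("model\tcondition\tseed\timbalance_ratio\tn_candidates\tauprc",
                 paste(r$model, r$condition, r$seed, r$imbalance_ratio,
                       r$n_candidates,
                       formatC(r$auprc, format = "g", digits = 17),
                       sep = "\t")), results_path)
  k <- x$recall
  write_atomic(c("model\tcondition\tseed\timbalance_ratio\tn\trecall",
                 paste(k$model, k$condition, k$seed, k$imbalance_ratio, k$n,
                       formatC(k$recall, format = "g", digits = 17),
                       sep = "\t")), recall_path)
  invisible(results_path)
}
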