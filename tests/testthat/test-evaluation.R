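test_that("condition splitting follows the half-and-half size rule", {
  acc12 <- sprintf("GSE%02d", 1:12)
  s <- split_condition_sets(acc12, seed = 1)
  expect_equal(length(s$reference), 6)
  expect_equal(length(s$comparison_a), 6)

  # odd count: the reference set gets the extra member
  acc13 <- sprintf("GSE%02d", 1:13)
  s13 <- split_condition_sets(acc13, seed = 1)
  expect_equal(length(s13$reference), 7)
  expect_equal(length(s13$comparison_a), 6)

  # a true partition, reproducible under the seed
  expect_length(intersect(s$reference, s$comparison_a), 0)
  expect_setequal(c(s$reference, s$comparison_a), acc12)
  expect_identical(s, split_condition_sets(acc12, seed = 1))
  expect_false(identical(s, split_condition_sets(acc12, seed = 2)))

  expect_error(split_condition_sets("GSE1", seed = 1), "at least 2")
})

test_that("splits are uniformly random over the condition set", {
  acc <- sprintf("GSE%02d", 1:6)
  freq <- rowMeans(sapply(1:400, function(s) {
    acc %in% split_condition_sets(acc, seed = s)$reference
  }))
  # each accession lands in the reference half about half the time
  expect_true(all(abs(freq - 0.5) < 0.12))
})

test_that("the comparison pool is the annotated corpus minus the condition", {
  all_acc <- sprintf("A%04d", 1:5997)
  cond <- sprintf("A%04d", 1:12)
  pool <- build_comparison_pool(all_acc, cond)
  expect_equal(length(pool), 5985)
  expect_length(intersect(pool, cond), 0)
  expect_equal(build_comparison_pool(cond, cond), character(0))
  expect_error(build_comparison_pool(all_acc, c("A0001", "MISSING")),
               "MISSING")
})

test_that("imbalance subsampling hits round(ratio * a_size) exactly", {
  pool <- sprintf("P%04d", 1:800)
  expect_equal(length(subsample_imbalance(pool, 10, 6, seed = 1)), 60)
  expect_equal(length(subsample_imbalance(pool, 1, 6, seed = 1)), 6)
  expect_equal(subsample_imbalance(pool, "all", 6, seed = 99), sort(pool))
  # round-half-to-even
  expect_equal(length(subsample_imbalance(pool, 2.5, 3, seed = 1)), 8)
  expect_identical(subsample_imbalance(pool, 10, 6, seed = 4),
                   subsample_imbalance(pool, 10, 6, seed = 4))
  expect_error(subsample_imbalance(pool, 200, 6, seed = 1),
               "maximum feasible ratio")
})

test_that("average precision matches hand values and the exhaustive oracle", {
  expect_equal(average_precision(c(1, 1, 0)), 1)
  expect_equal(average_precision(c(1, 0, 1)), 5 / 6)
  expect_equal(average_precision(c(0, 0, 1)), 1 / 3)
  expect_error(average_precision(c(0, 0, 0)), "zero positive")
  expect_error(average_precision(c(1, 2, 0)), "binary")

  withr::with_seed(31, {
    for (i in 1:50) {
      labels <- rbinom(10, 1, 0.4)
      if (sum(labels) == 0) labels[sample(10, 1)] <- 1
      expect_equal(average_precision(labels), ap_oracle(labels))
    }
  })
})

test_that("a perfect ranking maximises AP and its reversal minimises it", {
  for (case in list(c(n = 6, p = 2), c(n = 8, p = 3))) {
    n <- case["n"]; p <- case["p"]
    positions <- utils::combn(n, p)
    aps <- apply(positions, 2, function(pos) {
      labels <- rep(0, n); labels[pos] <- 1
      average_precision(labels)
    })
    perfect <- c(rep(1, p), rep(0, n - p))
    expect_equal(max(aps), average_precision(perfect))
    expect_equal(max(aps), 1)
    expect_equal(min(aps), average_precision(rev(perfect)))
  }
})

test_that("recall_at_n counts positives in the head of the ranking", {
  expect_equal(recall_at_n(c(1, 0, 1, 0), 2), 0.5)
  expect_equal(recall_at_n(c(1, 0, 1, 0), 4), 1)
  expect_equal(recall_at_n(c(0, 0, 1, 1), 2), 0)
  expect_error(recall_at_n(c(1, 0), 3), "exceeds")
  # non-decreasing in n
  withr::with_seed(17, {
    labels <- sample(c(1, 1, 1, rep(0, 17)))
    curve <- vapply(1:20, recall_at_n, numeric(1), ranked_labels = labels)
    expect_true(all(diff(curve) >= 0))
    expect_equal(curve[20], 1)
  })
})

test_that("expected_random_ap matches brute-force enumeration", {
  for (case in list(c(6, 2), c(7, 3), c(5, 1))) {
    n <- case[1]; p <- case[2]
    positions <- utils::combn(n, p)
    aps <- apply(positions, 2, function(pos) {
      labels <- rep(0, n); labels[pos] <- 1
      ap_oracle(labels)
    })
    expect_equal(expected_random_ap(n, p), mean(aps), tolerance = 1e-12)
  }
  expect_gt(expected_random_ap(500, 5), 5 / 500)
})

test_that("spearman_rho equals Pearson correlation of midranks", {
  expect_equal(spearman_rho(1:3, c(10, 20, 30)), 1)
  expect_equal(spearman_rho(1:3, c(30, 20, 10)), -1)

  # 6-point case with a tie, against an explicit midrank oracle
  x <- c(3.1, 1.2, 5.0, 5.0, 2.2, 0.4)
  y <- c(10, 4, 8, 12, 6, 2)
  midrank <- function(v) {
    sapply(v, function(vi) mean(which(sort(v) == vi)))
  }
  rx <- midrank(x); ry <- midrank(y)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman_rho(x, y), oracle, tolerance = 1e-12)

  expect_error(spearman_rho(c(1, 1, 1), 1:3), "constant")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("median_rank_table ranks models within conditions and orders by median", {
  tab <- tibble::tibble(
    model = rep(c("A", "B"), each = 2),
    condition = rep(c("c1", "c2"), 2),
    auprc = c(0.9, 0.8, 0.5, 0.7))
  out <- median_rank_table(tab)
  expect_equal(out$model, c("A", "B"))
  expect_equal(out$median_rank, c(1, 2))

  # all models identical -> equal medians, name-ordered
  tied <- tibble::tibble(model = rep(c("Z", "A", "M"), 2),
                         condition = rep(c("c1", "c2"), each = 3),
                         auprc = 0.5)
  out_tied <- median_rank_table(tied)
  expect_equal(out_tied$model, c("A", "M", "Z"))
  expect_equal(unique(out_tied$median_rank), 2)

  expect_error(median_rank_table(tab[-1, ]), "offending cell")
})

test_that("median_rank_table agrees with an exhaustive oracle on random tables", {
  withr::with_seed(41, {
    tab <- tidyr::expand_grid(model = paste0("m", 1:5),
                              condition = paste0("c", 1:3))
    tab$auprc <- runif(nrow(tab))
  })
  out <- median_rank_table(tab)
  # oracle: per condition, rank by explicit pairwise comparison counts
  oracle_medians <- sapply(paste0("m", 1:5), function(m) {
    ranks <- sapply(paste0("c", 1:3), function(cc) {
      scores <- tab$auprc[tab$condition == cc]
      names(scores) <- tab$model[tab$condition == cc]
      1 + sum(scores > scores[m]) + (sum(scores == scores[m]) - 1) / 2
    })
    median(ranks)
  })
  expect_equal(out$median_rank[match(paste0("m", 1:5), out$model)],
               unname(oracle_medians))
})

test_that("annotation files round-trip", {
  ann <- tibble::tibble(condition = c("jia", "jia", "pd"),
                        accession = c("GSE1", "GSE2", "GSE3"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(ann, path)
  expect_equal(read_annotations(path), ann)
})

test_that("evaluate_retrieval produces one result row per cell and shares subsamples", {
  corpus <- small_corpus(seed = 3, n_conditions = 2,
                         series_per_condition = 6, n_background = 40)
  models <- list(hashed_bow_embedder(512, seed = 7), word_overlap_model())
  ev <- evaluate_retrieval(corpus$series, corpus$annotations,
                           models = models, seeds = 1:2,
                           ratios = list(1, 5, "all"))
  res <- tidy(ev)
  # cartesian contract: model x condition x seed x ratio
  expect_equal(nrow(res), 2 * 2 * 2 * 3)
  expect_setequal(unique(res$imbalance_ratio), c("1", "5", "all"))

  # models face identical candidate counts per (condition, seed, ratio)
  counts <- res |>
    dplyr::group_by(condition, seed, imbalance_ratio) |>
    dplyr::summarise(k = dplyr::n_distinct(n_candidates), .groups = "drop")
  expect_true(all(counts$k == 1))

  # ratio-1 cells have a_size positives among 2*a_size candidates
  expect_true(all(res$n_candidates[res$imbalance_ratio == "1"] == 6))

  g <- glance(ev)
  expect_equal(g$n_models, 2)
  expect_true(g$mean_auprc >= 0 && g$mean_auprc <= 1)

  # recall curves are non-decreasing and end at 1
  rc <- ev$recall |>
    dplyr::group_by(model, condition, seed, imbalance_ratio) |>
    dplyr::summarise(ok = all(diff(recall) >= 0) &&
                       recall[dplyr::n()] == 1, .groups = "drop")
  expect_true(all(rc$ok))

  # determinism: identical config -> identical results
  ev2 <- evaluate_retrieval(corpus$series, corpus$annotations,
                            models = models, seeds = 1:2,
                            ratios = list(1, 5, "all"))
  expect_identical(tidy(ev), tidy(ev2))
})

test_that("evaluate_retrieval validates inputs", {
  corpus <- small_corpus(seed = 3, n_conditions = 2,
                         series_per_condition = 4, n_background = 10)
  bad_ann <- tibble::tibble(condition = "c", accession = "MISSING")
  expect_error(evaluate_retrieval(corpus$series, bad_ann,
                                  hashed_bow_embedder(64)),
               "MISSING")
  expect_error(evaluate_retrieval(corpus$series, corpus$annotations,
                                  hashed_bow_embedder(64),
                                  ratios = list(10, 1)),
               "strictly increasing")
  expect_error(evaluate_retrieval(corpus$series, corpus$annotations,
                                  hashed_bow_embedder(64),
                                  ratios = list("all", 1)),
               "last")
})

test_that("autoplot renders every figure type", {
  corpus <- small_corpus(seed = 5, n_conditions = 2,
                         series_per_condition = 4, n_background = 10)
  ev <- evaluate_retrieval(corpus$series, corpus$annotations,
                           models = hashed_bow_embedder(128, seed = 1),
                           seeds = 1, ratios = list(1, "all"))
  for (type in c("auprc", "condition", "imbalance", "recall")) {
    p <- ggplot2::autoplot(ev, type = type)
    expect_s3_class(p, "ggplot")
    built <- ggplot2::ggplot_build(p)
    expect_gt(length(built$data), 0)
  }
})
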