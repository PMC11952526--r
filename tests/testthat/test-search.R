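test_that("cosine similarity matches its definition and rejects degenerate input", {
  expect_equal(cosine_similarity(c(1, 0), c(1, 0)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 1), c(2, 2)), 1)  # scale invariance
  expect_equal(cosine_similarity(c(1, 0), c(-1, 0)), -1)
  expect_equal(cosine_similarity(c(1, 2), c(3, 4)),
               cosine_similarity(c(3, 4), c(1, 2)))  # symmetry
  expect_error(cosine_similarity(c(0, 0), c(1, 0), accession = "GSE7"),
               "degenerate.*GSE7")
  expect_error(cosine_similarity(c(1, 0, 0), c(1, 0)), "dimensions differ")
})

test_that("word overlap counts shared unique words", {
  expect_equal(word_overlap_similarity("parkinson disease brain",
                                       "parkinson disease blood"), 2)
  expect_equal(word_overlap_similarity("aa bb", "cc dd"), 0)
  expect_equal(word_overlap_similarity("a b c d e", "a b c d e"), 5)
  # set semantics: multiplicity never matters
  expect_equal(word_overlap_similarity("a a a b", "a b b"), 2)
  expect_equal(word_overlap_similarity("", "a b"), 0)
  # symmetric and bounded by the smaller unique-word count
  withr::with_seed(11, {
    for (i in 1:20) {
      a <- paste(sample(letters[1:10], 8, replace = TRUE), collapse = " ")
      b <- paste(sample(letters[5:15], 8, replace = TRUE), collapse = " ")
      s <- word_overlap_similarity(a, b)
      expect_identical(s, word_overlap_similarity(b, a))
      expect_lte(s, min(length(unique(strsplit(a, " ")[[1]])),
                        length(unique(strsplit(b, " ")[[1]]))))
    }
  })
})

test_that("rank_candidates sorts by score with accession tie-breaks", {
  cands <- rbind(A = c(1, 0), B = c(0, 1), C = c(-1, 0))
  ranked <- rank_candidates(cands, c(1, 0))
  expect_equal(ranked$accession, c("A", "B", "C"))
  expect_equal(ranked$score, c(1, 0, -1))
  expect_equal(ranked$rank, 1:3)

  # identical vectors -> ordered by accession string
  tie <- rbind(ZZ = c(1, 1), AA = c(2, 2), MM = c(0, 1))
  ranked_tie <- rank_candidates(tie, c(1, 1))
  expect_equal(ranked_tie$accession, c("AA", "ZZ", "MM"))
})

test_that("rank_candidates agrees with a brute-force sort oracle and is stable under permutation", {
  withr::with_seed(21, {
    mat <- matrix(rnorm(50 * 8), nrow = 50,
                  dimnames = list(sprintf("S%03d", sample(1:999, 50)), NULL))
    ref <- rnorm(8)
  })
  ranked <- rank_candidates(mat, ref)

  # oracle: score with plain arithmetic, sort with order()
  oracle_scores <- apply(mat, 1, function(r) {
    sum(r * ref) / sqrt(sum(r^2) * sum(ref^2))
  })
  ord <- order(-oracle_scores, names(oracle_scores))
  expect_equal(ranked$accession, names(oracle_scores)[ord])
  expect_equal(ranked$score, unname(oracle_scores[ord]), tolerance = 1e-12)

  # permuting candidate insertion order changes nothing
  perm <- withr::with_seed(22, sample(nrow(mat)))
  expect_equal(rank_candidates(mat[perm, ], ref), ranked)
  # scaling a candidate by a positive constant leaves the ranking unchanged
  mat2 <- mat
  mat2[5, ] <- mat2[5, ] * 100
  expect_equal(rank_candidates(mat2, ref)$accession, ranked$accession)
})

test_that("search_by_reference averages references and excludes them from output", {
  emb <- rbind(R1 = c(1, 0, 0), R2 = c(1, 0, 0),
               DUP = c(2, 0, 0), OTHER = c(0, 1, 0))
  res <- search_by_reference(emb, c("R1", "R2"))
  expect_equal(nrow(res), 2)
  expect_false(any(c("R1", "R2") %in% res$accession))
  # exact duplicate of the profile ranks first with score 1
  expect_equal(res$accession[1], "DUP")
  expect_equal(res$score[1], 1)

  # identical reference vectors behave like a single reference
  single <- search_by_reference(emb[-2, , drop = FALSE], "R1")
  expect_equal(res$score, single$score)

  expect_error(search_by_reference(emb, c("R1", "NOPE")), "NOPE")
  expect_error(search_by_reference(emb, character(0)), "at least one")
})

test_that("on a strong-signal synthetic corpus all same-condition series outrank others", {
  corpus <- small_corpus(seed = 7, n_conditions = 3,
                         series_per_condition = 6, n_background = 30,
                         signal = 1.0)
  docs <- clean_documents(build_documents(corpus$series))
  emb <- embed_corpus(docs, hashed_bow_embedder(4096, seed = 7))
  cond1 <- corpus$annotations$accession[
    corpus$annotations$condition == "condition1"]
  res <- search_by_reference(emb, cond1[1:3])
  held_out <- setdiff(cond1, cond1[1:3])
  expect_equal(sort(res$accession[seq_along(held_out)]), sort(held_out))
})

test_that("word-overlap ranking supports union and pairwise-max reference rules", {
  docs <- tibble::tibble(
    accession = c("R1", "R2", "X", "Y"),
    text = c("aa bb", "cc dd", "aa cc", "aa bb zz"))
  un <- rank_by_word_overlap(docs, c("R1", "R2"), rule = "union")
  expect_equal(un$accession[1], "X")  # overlaps 2 with the union
  pm <- rank_by_word_overlap(docs, c("R1", "R2"), rule = "pairwise_max")
  expect_equal(pm$accession[1], "Y")  # overlaps 2 with R1 alone
  expect_error(rank_by_word_overlap(docs, "NOPE"), "NOPE")
})

test_that("ranked lists and accession lists round-trip through their file formats", {
  ranked <- tibble::tibble(rank = 1:3, accession = c("A", "B", "C"),
                           score = c(0.9, 0.5, -0.1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ranked_list(ranked, path, embedder_name = "hashed_bow_64",
                    chunking = FALSE, seed = 3)
  lines <- readLines(path)
  expect_true(any(grepl("# embedder: hashed_bow_64", lines)))
  expect_true(any(grepl("# seed: 3", lines)))

  # GEOfinder-style upload: first column of a table, header and comments
  # ignored
  upload <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# selected series", "accession\ttitle",
               "GSE1\tsomething", "GSE2\telse", "GSE1\tdup"), upload)
  expect_equal(read_accession_list(upload), c("GSE1", "GSE2"))

  plain <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("GSE5", "GSE6"), plain)
  expect_equal(read_accession_list(plain), c("GSE5", "GSE6"))
})
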