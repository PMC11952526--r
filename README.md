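# seriesfinder

Semantic retrieval and benchmarking of gene-expression series metadata.

## The problem

Public repositories hold hundreds of thousands of transcriptomic series
(bulk and single-cell), described only by ad-hoc free text: a title, a
summary, and sometimes an overall-design paragraph. A researcher who has
already found a few series relevant to their topic — through a literature
search or a repository query — usually wants *more of the same*, but
keyword search over these descriptions is brittle and relevant series are
rare (often fewer than a dozen among thousands of candidates).

seriesfinder is for researchers and curators doing this kind of dataset
discovery, and for methodologists benchmarking retrieval models on it. It
implements content-based retrieval over series metadata:

1. each series' description (title + summary + overall design) is cleaned
   and summarised as a fixed-dimension embedding vector;
2. the embeddings of the known-relevant **reference set** are averaged
   component-wise into a query profile `m = (1/k) Σ e_i`;
3. every other series `j` is ranked by cosine similarity
   `cos(m, e_j) = m·e_j / (‖m‖‖e_j‖)`.

Around that core it provides metadata readers (a SOFT-dialect key-value
format, canonical JSON/TSV) and standard inclusion filters; cleaning and
overlapping-window chunking (256-character windows, 20-character overlap);
a deterministic hashed bag-of-words backend plus a plug-in contract for
external language models; a word-overlap baseline; a full evaluation
harness — random reference/comparison splits, imbalance subsampling,
average precision (AUPRC), recall@n, cross-condition median-rank model
comparison — and a synthetic condition-annotated corpus generator so the
entire pipeline runs and is testable offline.

## Worked example

Generate a synthetic annotated corpus, embed it, and search with four
known-relevant series as the reference set:

```r
library(seriesfinder)

corpus <- generate_corpus(corpus_config(
  n_conditions = 3, series_per_condition = 8,
  n_background_series = 100, signal = 0.75, seed = 42))

docs <- clean_documents(build_documents(corpus$series),
                        remove_stopwords = TRUE,
                        stopwords = default_stopwords())
emb  <- embed_corpus(docs, hashed_bow_embedder(4096, seed = 7))

refs <- corpus$annotations$accession[
  corpus$annotations$condition == "condition1"][1:4]
head(search_by_reference(emb, refs), 6)
#> # A tibble: 6 × 3
#>    rank accession  score
#>   <int> <chr>      <dbl>
#> 1     1 SYN00007  0.549
#> 2     2 SYN00008  0.534
#> 3     3 SYN00005  0.528
#> 4     4 SYN00006  0.425
#> 5     5 SYN00087  0.0427
#> 6     6 SYN00098  0.0426
```

The four held-out condition-1 series (SYN00005–SYN00008) occupy the top
four ranks with cosine scores 0.43–0.55; the best background series scores
0.04. The score gap is the retrieval signal.

Benchmarking models across conditions, seeds, and imbalance ratios:

```r
ev <- evaluate_retrieval(
  corpus$series, corpus$annotations,
  models = list(hashed_bow_embedder(4096, seed = 7), word_overlap_model()),
  seeds = 1:3, ratios = list(1, 10, "all"))

glance(ev)
#> # A tibble: 1 × 6
#>   n_models n_conditions n_seeds n_ratios mean_auprc median_auprc
#>      <int>        <int>   <int>    <int>      <dbl>        <dbl>
#> 1        2            3       3        3          1            1
```

At this signal strength both models achieve AUPRC 1.0 in every cell — every
held-out relevant series outranks every irrelevant one. `tidy(ev)` gives
the per-(model, condition, seed, ratio) rows, `autoplot(ev, "imbalance")`
and `autoplot(ev, "recall")` the standard figures, and
`median_rank_table()` the cross-condition model ranking. Lowering `signal`
toward 0 in `corpus_config()` degrades AUPRC toward the random-ranking
expectation (`expected_random_ap()`).

A command-line interface over the same functions ships at
`inst/cli/seriesfinder.R` with subcommands `synth`, `ingest`, `filter`,
`embed`, `rank`, and `evaluate`.

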