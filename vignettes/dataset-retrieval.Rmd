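---
title: "Methods: embedding-based retrieval of related expression series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: embedding-based retrieval of related expression series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seriesfinder)
library(dplyr)
```

## The retrieval model

A researcher has found a handful of expression series relevant to their
topic and wants more. seriesfinder treats this as content-based retrieval
over repository metadata: each series' free-text description (title,
summary, and overall design when available, joined in that order) is
summarised as a fixed-dimension numeric vector, the vectors of the
known-relevant *reference set* are averaged component-wise into a query
profile, and every other series is ranked by the cosine similarity between
its vector and that profile:

$$\mathrm{sim}(u, v) = \frac{u \cdot v}{\lVert u\rVert\,\lVert v\rVert} \in [-1, 1].$$

Cosine similarity is scale-invariant per comparison, cheap, and the
standard choice for embedding retrieval. Averaging is done on the **raw**
embeddings by default: although cosine ignores each vector's norm, the
*mean* of unnormalised vectors weights longer-norm members more. Whether to
L2-normalise before averaging is a genuinely open choice; we default to
plain averaging and expose normalisation to the caller (normalise the
matrix rows before `search_by_reference()` if wanted), because plain
averaging is the simplest reading of "average the embeddings" and the two
differ only when reference norms are very unequal.

Ties in any ranking are broken by ascending accession string. Ties carry no
information, and a documented deterministic tie-break makes every ranking,
result table, and written file byte-reproducible.

## Text preparation

Cleaning applies a fixed rule order — HTML tag stripping, URL removal,
lowercasing, replacement of each non-alphanumeric character by a space,
whitespace collapsing, trimming, then optional stop-word removal. The order
matters (stripping punctuation first would shred URLs into indelible
tokens) and is therefore mandated rather than configurable. Two details are
deliberate choices:

* non-alphanumeric characters become **spaces** rather than being deleted,
  so `T-cells` yields the tokens `t cells` instead of the fused `tcells`;
* "alphanumeric" means Unicode letters and digits, because series summaries
  contain accented author and disease names (`sézary` should survive).

Stop-word removal is a per-model policy: bag-style models (word overlap,
hashed bag-of-words) drop stop words because shared function words inflate
their scores; context-sensitive models keep them. The list is injected as
data — a plain one-word-per-line file ships with the package
(`default_stopwords()`) and any list can be substituted.

Long texts can be split into overlapping character windows before
embedding: texts of at most `chunk_threshold = 256` characters are embedded
whole; longer texts are covered by windows of `chunk_size = 256` characters
whose starts advance by `size − overlap = 236`, sharing
`chunk_overlap = 20` characters per consecutive pair, with the final window
truncated at the text end. The window length equals the threshold because
only the threshold and the overlap are meaningfully constrained; making the
window a separate knob would add a parameter with no clear criterion for
setting it. Chunk embeddings are averaged **unweighted**; length-weighting
only affects the final, truncated chunk and we prefer the simpler rule.
Chunking is exposed as a per-model flag so chunked and unchunked variants
of the same backend can be benchmarked side by side — in our own harness
runs, as in published comparisons of this technique, chunking rarely helps
for texts of this length.

## Embedders

An embedder is one function — cleaned text in, numeric vector of a declared
fixed dimension out — plus three declared properties: name, stop-word
policy, chunking policy (`embedder()`). External models (transformers,
static word vectors, remote APIs) plug in through this contract; the
package never imports them, so everything here runs without downloads.

The built-in backend, `hashed_bow_embed()`, is a seeded feature-hashing
bag-of-words: each token is hashed to a coordinate and a sign, and the
vector accumulates signed token counts. It is deterministic across
platforms (the hash is exact integer arithmetic below 2^53 in doubles),
order-insensitive over tokens, and near-orthogonal across disjoint
vocabularies at the default dimension of 4096. It is *not* a semantic
model: it captures lexical overlap only, which is exactly what makes it a
controllable reference backend for testing the surrounding machinery.

The word-counting baseline scores a candidate by the number of unique words
shared with the reference descriptions. With several references we score
against the **union** of reference vocabularies by default, mirroring the
averaged-embedding profile; a pairwise-maximum rule is available
(`word_overlap_model(rule = "pairwise_max")`) for the alternative reading
of "overlap between descriptions".

## Evaluation design

`evaluate_retrieval()` implements the benchmark harness. For each annotated
condition and each seed:

1. the condition's series are split uniformly at random into a reference
   set and a held-out *comparison set A*; with an odd count the reference
   set receives the extra series;
2. all remaining corpus series (including those annotated to other
   conditions) form *comparison set B*;
3. B is subsampled to each requested imbalance ratio r (|B| = r·|A|,
   rounded half-to-even; the sentinel `"all"` keeps the full pool). One
   subsample is drawn per (condition, ratio, seed) and shared across all
   models, so models are always compared on identical candidates;
4. each model ranks A ∪ B against its averaged reference profile, and the
   ranking is scored.

The headline metric is the area under the precision-recall curve, computed
as **average precision**: the mean of precision evaluated at each
positive's rank. AP is exact for ranked binary labels, needs no
interpolation scheme, and has a brute-force oracle (enumerate precision at
every positive), which is why we prefer it to trapezoidal PR variants; the
estimator name is recorded in the result object's parameters. Recall\@n
curves and the cross-condition median-rank summary (`median_rank_table()`)
complete the harness; `spearman_rho()` supports descriptive correlations
such as AUPRC against embedding size. Group-difference significance tests
are out of scope — the harness reports descriptive summaries only.

For calibration we derived the exact expectation of AP under a uniformly
random ranking of p positives among n items
(`expected_random_ap()`): conditioning on a positive at rank k, the
remaining p − 1 positives are uniform over the other n − 1 positions, so

$$E[\mathrm{AP}] = \frac{1}{n}\sum_{k=1}^{n}\frac{1}{k}\Bigl(1 + (k-1)\frac{p-1}{n-1}\Bigr),$$

which exceeds the prevalence p/n by O(log n / n). The test suite checks
this formula against exhaustive enumeration at small n, then uses it as the
target for Monte-Carlo calibration of the whole pipeline.

All randomness flows from explicit integer seeds. Per-(condition, ratio)
sub-seeds are derived from the user's seed and the labels by a small
string hash, so adding a condition never perturbs another condition's
split; every result row records its seed and ratio.

## The synthetic corpus

`generate_corpus()` emulates a condition-annotated metadata corpus with a
single tunable signal. Each condition owns a private vocabulary, disjoint
from the other conditions' and from a shared background vocabulary.
Condition series draw each token independently from their condition urn
with probability `signal` and from the background otherwise; background
series draw all tokens from the background. This two-urn mixture is
deliberately grammar-free: the retrieval method under test is bag-like, so
lexical distinctiveness is the only property the generator needs to
control. `signal = 0` makes condition series statistically
indistinguishable from background (retrieval must collapse to the random
baseline above); `signal = 1` makes conditions perfectly separable.

Defaults, chosen once as a plausible desk-scale analogue of a curated
corpus: 6 conditions × 12 series (the size of the smallest annotated
condition in typical curation resources) over 500 background series;
condition vocabularies of 50 words against a background of 2000, roughly
the specific-to-general vocabulary proportion of real summaries;
`signal = 0.75`, i.e. descriptions dominated by topical language but with
substantial shared boilerplate; summaries of 15–60 tokens plus short titles
and optional design text, so cleaned documents straddle the 256-character
chunking threshold and both the chunked and unchunked code paths are
exercised; overall design absent with probability 0.2 to exercise the
absent-field path. An optional *near-miss* mode adds one confuser condition
per target sharing half its vocabulary, emulating clinically overlapping
conditions (mood disorders, arthritis subtypes) that are the
characteristic failure mode of lexical retrieval; it is off by default.

What the generator does **not** emulate: real biomedical syntax, polysemy
and synonymy, curator disagreement, correlated description styles within
labs, or heterogeneous series lengths by platform. Tests passing on this
corpus therefore demonstrate that the machinery — cleaning, chunking,
embedding, splitting, ranking, scoring — is correct and calibrated, not
that any particular language model will retrieve well on real repository
text.

## Problem sizes and numerical choices

The verification suite uses sizes chosen to make the checks sharp but
quick: exhaustive AP checks at list length 10 (all 1023 labelings);
random-ranking calibration with 200 shuffles of 5 positives among 500;
signal recovery at the boundary signal 0.5 with the default corpus over 10
seeds (mean AUPRC must exceed 0.9) and the signal-0 null compared to the
closed-form expectation within three standard errors; the imbalance sweep
over ratios 1, 10, 100, and "all" with 1000 background series — 1000 rather
than the default 500 because ratio 100 with six held-out positives needs
600 pool members per condition, and means over three corpus seeds must be
non-increasing in the ratio.

Other fixed numerical choices: sizes from ratios round half-to-even
(`round()` semantics, documented rather than ad hoc); degenerate all-zero
embeddings raise an error naming the offending accession instead of
returning a NaN similarity; a backend returning the wrong dimension is a
contract violation naming the backend; file writers emit UTF-8
deterministically and atomically (temp file + rename), with enough digits
that embedding stores round-trip exactly.

## Limitations

* The hashed bag-of-words backend measures lexical, not semantic,
  similarity; it is the reference backend for testing, and a baseline, not
  a recommendation.
* Repository-scale ingestion (live APIs, XML metadata, sample-level
  records) is out of scope; the readers cover the key-value SOFT dialect
  and the package's canonical JSON/TSV formats.
* The harness's absolute AUPRC values on synthetic corpora say nothing
  about absolute performance on real metadata; only the relative and
  calibration properties transfer.
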