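# shared fixtures and independent oracles, built in code at test time

`%||%` <- rlang::`%||%`

soft_fixture_lines <- function() {
  c(
    "^SERIES = GSE1",
    "!Series_geo_accession = GSE1",
    "!Series_title = toy",
    "!Series_summary = part one",
    "!Series_summary = part two",
    "!Series_sample_organism = Homo sapiens",
    "!Series_type = expression profiling by array",
    "!Series_platform_id = GPL570",
    "!Series_status = Public on Jan 01 2010",
    "!Sample_title = ignored sample-level line",
    "",
    "^SERIES = GSE2",
    "!Series_geo_accession = GSE2",
    "!Series_title = mouse study",
    "!Series_summary = about mice",
    "!Series_overall_design = two groups",
    "!Series_sample_organism = Mus musculus",
    "!Series_type = expression profiling by array",
    "!Series_platform_id = GPL999",
    "",
    "^SERIES = GSE3",
    "!Series_geo_accession = GSE3",
    "!Series_title = sub study",
    "!Series_summary = child of a SuperSeries",
    "!Series_sample_organism = Homo sapiens",
    "!Series_type = expression profiling by high throughput sequencing",
    "!Series_platform_id = GPL111",
    "!Series_relation = SubSeries of: GSE99"
  )
}

write_soft_fixture <- function() {
  path <- withr::local_tempfile(fileext = ".soft",
                                .local_envir = parent.frame())
  writeLines(soft_fixture_lines(), path)
  path
}

platform_map_fixture <- function() {
  tibble::tibble(platform_id = c("GPL570", "GPL999", "GPL111"),
                 vendor = c("Affymetrix", "Affymetrix", "Illumina"))
}

# a hand-built series table exercising every filter criterion
make_filter_fixture <- function() {
  ok <- function(accession, ...) {
    args <- list(...)
    tibble::tibble(
      accession = accession,
      title = "t", summary = "s", overall_design = NA_character_,
      organisms = args$organisms %||% list("Homo sapiens"),
      experiment_types = args$experiment_types %||%
        list("expression profiling by array"),
      platform_vendor = args$platform_vendor %||% "Affymetrix",
      is_retired = args$is_retired %||% FALSE,
      is_subseries = args$is_subseries %||% FALSE
    )
  }
  dplyr::bind_rows(
    ok("KEEP1"),
    ok("KEEP2", platform_vendor = "illumina",
       experiment_types = list(
         "Expression profiling by high throughput sequencing")),
    ok("MOUSE", organisms = list("Mus musculus")),
    ok("RETIRED", is_retired = TRUE),
    ok("SUB", is_subseries = TRUE),
    ok("HTSAFFY", platform_vendor = "Affymetrix",
       experiment_types = list(
         "expression profiling by high throughput sequencing")),
    ok("NOVENDOR", platform_vendor = NA_character_),
    ok("NOORG", organisms = list(character(0)))
  )
}

# independent average-precision oracle: literal precision-at-each-positive
# loop, no shared code with the implementation
ap_oracle <- function(labels) {
  total <- 0
  hits <- 0
  precisions <- c()
  for (k in seq_along(labels)) {
    if (labels[k] == 1) {
      hits <- hits + 1
      precisions <- c(precisions, hits / k)
    }
  }
  mean(precisions)
}

# all binary label vectors of length n (rows), as a matrix
all_label_vectors <- function(n) {
  as.matrix(expand.grid(rep(list(0:1), n)))[, n:1, drop = FALSE]
}

small_corpus <- function(seed = 1, n_conditions = 2, series_per_condition = 4,
                         n_background = 20, signal = 0.75) {
  generate_corpus(corpus_config(
    n_conditions = n_conditions,
    series_per_condition = series_per_condition,
    n_background_series = n_background,
    signal = signal, seed = seed))
}

# mean AUPRC of the full pipeline (clean -> embed -> split -> rank -> AP)
# on a synthetic corpus, at ratio "all", averaged over conditions and seeds
pipeline_mean_auprc <- function(signal, seeds, dimension = 4096,
                                series_per_condition = 12,
                                n_background = 500, embed_seed = 11) {
  aps <- unlist(lapply(seeds, function(s) {
    corpus <- generate_corpus(corpus_config(
      series_per_condition = series_per_condition,
      n_background_series = n_background,
      signal = signal, seed = s))
    ev <- evaluate_retrieval(
      corpus$series, corpus$annotations,
      models = hashed_bow_embedder(dimension, seed = embed_seed),
      seeds = s, ratios = list("all"))
    tidy(ev)$auprc
  }))
  mean(aps)
}
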