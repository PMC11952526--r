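#' Read series metadata
#'
#' Reads gene-expression series metadata into a tidy table, one row per
#' series. Three dialects are supported:
#'
#' * `"soft"` — a minimal SOFT-style key-value format. Blocks start at a
#'   `^SERIES` line (or at the first `!Series_*` line); only series-level
#'   `!Series_<field> = value` lines are interpreted and sample-level lines
#'   are ignored. Repeated `!Series_summary` (or `!Series_title`) lines are
#'   concatenated with single spaces. A series is marked retired when any
#'   `!Series_status` value contains `"retired"`, and marked as a SubSeries
#'   when any `!Series_relation` value starts with `"SubSeries of"`. SOFT
#'   blocks carry platform identifiers rather than vendors, so the platform
#'   vendor is resolved through `platform_map` (see [read_platform_map()]);
#'   without a map the vendor is `NA`.
#' * `"json"` — the canonical JSON dialect written by [write_series_json()]:
#'   an array of objects with the same fields as the returned table.
#' * `"tsv"` — a tab-separated table with a header row; `organisms` and
#'   `experiment_types` are `;`-separated, and an absent overall design is
#'   encoded as an empty `overall_design` field with `has_overall_design`
#'   set to false.
#'
#' @param path Path to a metadata file (or a connection readable by
#'   [readLines()] / the readr readers).
#' @param dialect One of `"soft"`, `"json"`, `"tsv"`.
#' @param platform_map Optional tibble with columns `platform_id` and
#'   `vendor`, used only by the SOFT dialect.
#'
#' @return A tibble with columns `accession`, `title`, `summary`,
#'   `overall_design` (`NA` when absent — distinct from an empty string),
#'   `organisms` (list of character vectors), `experiment_types` (list of
#'   character vectors), `platform_vendor`, `is_retired`, `is_subseries`.
#'
#' @examples
#' soft <- c(
#'   "^SERIES = GSE1",
#'   "!Series_geo_accession = GSE1",
#'   "!Series_title = toy study",
#'   "!Series_summary = part one",
#'   "!Series_summary = part two",
#'   "!Series_sample_organism = Homo sapiens",
#'   "!Series_type = expression profiling by array"
#' )
#' f <- tempfile(fileext = ".soft")
#' writeLines(soft, f)
#' read_series_metadata(f, dialect = "soft")
#' @export
read_series_metadata <- function(path, dialect = c("soft", "json", "tsv"),
                                 platform_map = NULL) {
  dialect <- match.arg(dialect)
  out <- switch(dialect,
    soft = parse_series_soft(readLines(path, warn = FALSE, encoding = "UTF-8"),
                             platform_map = platform_map),
    json = parse_series_json(path),
    tsv  = parse_series_tsv(path)
  )
  check_unique_accessions(out)
  out
}

new_series_tibble <- function(accession, title, summary, overall_design,
                              organisms, experiment_types, platform_vendor,
                              is_retired, is_subseries) {
  tibble::tibble(
    accession = as.character(accession),
    title = as.character(title),
    summary = as.character(summary),
    overall_design = as.character(overall_design),
    organisms = organisms,
    experiment_types = experiment_types,
    platform_vendor = as.character(platform_vendor),
    is_retired = as.logical(is_retired),
    is_subseries = as.logical(is_subseries)
  )
}

check_unique_accessions <- function(series) {
  dup <- unique(series$accession[duplicated(series$accession)])
  if (length(dup) > 0) {
    stop("duplicate series accession(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(series$accession) | !nzchar(series$accession))) {
    stop("empty series accession", call. = FALSE)
  }
  invisible(series)
}

parse_series_soft <- function(lines, platform_map = NULL) {
  # block boundaries: ^SERIES lines; a file with none is one block
  starts <- grep("^\\^SERIES", lines)
  if (length(starts) == 0) starts <- 1L
  ends <- c(starts[-1] - 1L, length(lines))

  rows <- purrr::map2(starts, ends, function(s, e) {
    block <- lines[s:e]
    kv <- stringr::str_match(block, "^!Series_([A-Za-z0-9_]+)\\s*=\\s*(.*)$")
    keep <- !is.na(kv[, 1])
    keys <- kv[keep, 2]
    vals <- stringr::str_trim(kv[keep, 3])
    grab <- function(key) vals[keys == key]

    accession <- grab("geo_accession")
    if (length(accession) == 0 || !nzchar(accession[1])) {
      stop("SOFT parse error: block starting at line ", s,
           " has no !Series_geo_accession", call. = FALSE)
    }
    title <- paste(grab("title"), collapse = " ")
    if (!nzchar(title)) {
      stop("SOFT parse error: series ", accession[1], " (block at line ", s,
           ") has no title", call. = FALSE)
    }
    design <- grab("overall_design")
    organisms <- unique(c(grab("sample_organism"), grab("organism")))
    platform_id <- grab("platform_id")
    vendor <- NA_character_
    if (!is.null(platform_map) && length(platform_id) > 0) {
      hit <- match(platform_id[1], platform_map$platform_id)
      if (!is.na(hit)) vendor <- platform_map$vendor[hit]
    }
    new_series_tibble(
      accession = accession[1],
      title = title,
      summary = paste(grab("summary"), collapse = " "),
      overall_design = if (length(design) == 0) NA_character_
                       else paste(design, collapse = " "),
      organisms = list(organisms),
      experiment_types = list(unique(grab("type"))),
      platform_vendor = vendor,
      is_retired = any(stringr::str_detect(tolower(grab("status")), "retired")),
      is_subseries = any(stringr::str_detect(tolower(grab("relation")),
                                             "^subseries of"))
    )
  })
  dplyr::bind_rows(rows)
}

parse_series_json <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rows <- purrr::imap(recs, function(r, i) {
    if (is.null(r$accession) || !nzchar(r$accession)) {
      stop("JSON parse error: record ", i, " has no accession", call. = FALSE)
    }
    new_series_tibble(
      accession = r$accession,
      title = r$title %||% "",
      summary = r$summary %||% "",
      overall_design = r$overall_design %||% NA_character_,
      organisms = list(as.character(unlist(r$organisms))),
      experiment_types = list(as.character(unlist(r$experiment_types))),
      platform_vendor = r$platform_vendor %||% NA_character_,
      is_retired = isTRUE(r$is_retired),
      is_subseries = isTRUE(r$is_subseries)
    )
  })
  dplyr::bind_rows(rows)
}

parse_series_tsv <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("accession", "title", "summary") %in% names(tab))) {
    stop("TSV parse error: header must include accession, title, summary",
         call. = FALSE)
  }
  if (any(is.na(tab$accession) | !nzchar(tab$accession))) {
    stop("TSV parse error: row ",
         which(is.na(tab$accession) | !nzchar(tab$accession))[1],
         " has no accession", call. = FALSE)
  }
  split_set <- function(x) {
    purrr::map(x, function(v) {
      if (is.na(v) || !nzchar(v)) character(0)
      else stringr::str_trim(stringr::str_split_1(v, ";"))
    })
  }
  has_design <- if ("has_overall_design" %in% names(tab)) {
    tolower(tab$has_overall_design) %in% c("true", "t", "1", "yes")
  } else {
    !is.na(tab$overall_design) & nzchar(tab$overall_design)
  }
  design <- dplyr::coalesce(tab$overall_design, "")
  new_series_tibble(
    accession = tab$accession,
    title = dplyr::coalesce(tab$title, ""),
    summary = dplyr::coalesce(tab$summary, ""),
    overall_design = ifelse(has_design, design, NA_character_),
    organisms = split_set(tab$organisms %||% rep(NA_character_, nrow(tab))),
    experiment_types =
      split_set(tab$experiment_types %||% rep(NA_character_, nrow(tab))),
    platform_vendor = (tab$platform_vendor %||% rep(NA_character_, nrow(tab))),
    is_retired = tolower(tab$is_retired %||% "false") %in%
      c("true", "t", "1", "yes"),
    is_subseries = tolower(tab$is_subseries %||% "false") %in%
      c("true", "t", "1", "yes")
  )
}

#' Read a platform-to-vendor mapping file
#'
#' A two-column TSV (`platform_id`, `vendor`) used to resolve platform
#' vendors when reading SOFT-dialect metadata, which records platform
#' identifiers rather than vendor names.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `platform_id` and `vendor`.
#' @export
read_platform_map <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("platform_id", "vendor") %in% names(tab))) {
    stop("platform map must have columns platform_id and vendor",
         call. = FALSE)
  }
  tab
}

#' Write series metadata as canonical JSON
#'
#' The canonical dialect round-trips exactly through
#' [read_series_metadata()] (`dialect = "json"`): an absent overall design
#' is written as JSON `null`, organisms and experiment types as arrays.
#' Output is UTF-8 and deterministic for identical input.
#'
#' @param series A series tibble as returned by [read_series_metadata()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_series_json <- function(series, path) {
  check_unique_accessions(series)
  recs <- purrr::pmap(series, function(accession, title, summary,
                                       overall_design, organisms,
                                       experiment_types, platform_vendor,
                                       is_retired, is_subseries) {
    list(
      accession = accession,
      title = title,
      summary = summary,
      overall_design = if (is.na(overall_design)) NULL else overall_design,
      organisms = as.list(organisms),
      experiment_types = as.list(experiment_types),
      platform_vendor = if (is.na(platform_vendor)) NULL else platform_vendor,
      is_retired = is_retired,
      is_subseries = is_subseries
    )
  })
  json <- jsonlite::toJSON(recs, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, null = "null")
  write_atomic(json, path)
}

#' Write series metadata as TSV
#'
#' Set-valued fields are `;`-joined; an absent overall design becomes an
#' empty field with `has_overall_design` false.
#'
#' @inheritParams write_series_json
#' @return `path`, invisibly.
#' @export
write_series_tsv <- function(series, path) {
  check_unique_accessions(series)
  flat <- series |>
    dplyr::mutate(
      has_overall_design = !is.na(.data$overall_design),
      overall_design = dplyr::coalesce(.data$overall_design, ""),
      organisms = purrr::map_chr(.data$organisms, paste, collapse = ";"),
      experiment_types =
        purrr::map_chr(.data$experiment_types, paste, collapse = ";")
    )
  tmp <- tempfile(tmpdir = dirname(path))
  readr::write_tsv(flat, tmp, progress = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

# atomic text write: temp file in the target directory, then rename
write_atomic <- function(text, path) {
  tmp <- tempfile(tmpdir = dirname(path))
  con <- file(tmp, open = "wb")
  writeLines(enc2utf8(as.character(text)), con, useBytes = TRUE)
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

#' Series inclusion criteria
#'
#' Describes which series a study retains: a required organism, a set of
#' allowed (experiment type, platform vendor) combinations, and exclusion of
#' retired series and SubSeries. The defaults are the criteria used for
#' human expression-profiling studies: *Homo sapiens* samples, arrays from
#' Affymetrix, Illumina or Agilent, or high-throughput sequencing on
#' Illumina, excluding retired series and SubSeries (whose descriptions
#' duplicate their SuperSeries).
#'
#' @param required_organism Species name (case-insensitive exact match
#'   against the series' organism set).
#' @param allowed_combinations Tibble with columns `experiment_type` and
#'   `vendor`; a series passes when at least one of its experiment types,
#'   paired with its platform vendor, matches a row (case-insensitive).
#' @param exclude_retired,exclude_subseries Logical flags.
#' @return An object of class `filter_criteria`.
#' @seealso [filter_series()]
#' @export
filter_criteria <- function(required_organism = "Homo sapiens",
                            allowed_combinations = default_platform_combinations(),
                            exclude_retired = TRUE,
                            exclude_subseries = TRUE) {
  stopifnot(is.data.frame(allowed_combinations),
            all(c("experiment_type", "vendor") %in%
                  names(allowed_combinations)))
  if (nrow(allowed_combinations) == 0) {
    stop("allowed_combinations must be non-empty", call. = FALSE)
  }
  structure(
    list(
      required_organism = tolower(required_organism),
      allowed_combinations = dplyr::mutate(
        tibble::as_tibble(allowed_combinations),
        experiment_type = tolower(.data$experiment_type),
        vendor = tolower(.data$vendor)
      ),
      exclude_retired = isTRUE(exclude_retired),
      exclude_subseries = isTRUE(exclude_subseries)
    ),
    class = "filter_criteria"
  )
}

#' @rdname filter_criteria
#' @export
default_platform_combinations <- function() {
  tibble::tibble(
    experiment_type = c(rep("expression profiling by array", 3),
                        "expression profiling by high throughput sequencing"),
    vendor = c("Affymetrix", "Illumina", "Agilent", "Illumina")
  )
}

#' Filter series by inclusion criteria
#'
#' Keeps exactly the series that satisfy every criterion, preserving input
#' order. A series missing a criterion-relevant field (no organisms, no
#' experiment type, unknown vendor) fails that criterion.
#'
#' @param series A series tibble (see [read_series_metadata()]).
#' @param criteria A [filter_criteria()] object.
#' @return The retained rows of `series`, order preserved.
#' @examples
#' corpus <- generate_corpus(corpus_config(
#'   n_conditions = 2, series_per_condition = 3,
#'   n_background_series = 2, seed = 1))
#' nrow(filter_series(corpus$series, filter_criteria()))
#' @export
filter_series <- function(series, criteria = filter_criteria()) {
  stopifnot(inherits(criteria, "filter_criteria"))
  combos <- criteria$allowed_combinations
  keep <- purrr::pmap_lgl(
    series[c("organisms", "experiment_types", "platform_vendor",
             "is_retired", "is_subseries")],
    function(organisms, experiment_types, platform_vendor,
             is_retired, is_subseries) {
      if (criteria$exclude_retired && (is.na(is_retired) || is_retired)) {
        return(FALSE)
      }
      if (criteria$exclude_subseries && (is.na(is_subseries) || is_subseries)) {
        return(FALSE)
      }
      if (!criteria$required_organism %in% tolower(organisms)) return(FALSE)
      if (is.na(platform_vendor)) return(FALSE)
      any(combos$experiment_type %in% tolower(experiment_types) &
            combos$vendor == tolower(platform_vendor))
    }
  )
  series[keep, , drop = FALSE]
}
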